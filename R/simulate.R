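## Seeded genome simulator. Plants SINE-containing loci of known class
## (presence/absence configuration, multimapper decoys, contig-edge
## truncations) into synthetic genomes and emits a truth table, so the
## whole pipeline can be validated against known ground truth. Substitutions
## are uniform across sites; indel lengths are geometric (mean 3 by
## default). No attempt is made at realistic base composition, target-site
## duplications or poly-A tails: the simulator exercises the method's
## thresholds and locus taxonomy, not retrotransposition biology.

BASES <- c("A", "C", "G", "T")

.random_dna <- function(n) paste(sample(BASES, n, replace = TRUE),
                                 collapse = "")

## substitutions at rate per site; optional indels (insert/delete equally
## likely, geometric length). Applied right-to-left so indices stay valid.
.mutate_seq <- function(seq, sub_rate, indel_rate = 0, indel_mean = 3) {
  ch <- strsplit(seq, "")[[1]]
  n <- length(ch)
  if (n == 0L) return(seq)
  subs <- which(runif(n) < sub_rate)
  for (i in subs) ch[i] <- sample(setdiff(BASES, ch[i]), 1L)
  if (indel_rate > 0) {
    ev <- which(runif(n) < indel_rate)
    for (i in rev(ev)) {
      len <- rgeom(1L, 1 / indel_mean) + 1L
      if (runif(1) < 0.5) {
        ch <- ch[-(i:min(length(ch), i + len - 1L))]
      } else {
        ch <- append(ch, sample(BASES, len, replace = TRUE), after = i)
      }
    }
  }
  paste(ch, collapse = "")
}

PAIRWISE_CLASSES <- c("PP", "PM", "MP", "multimapper", "edge_truncated")
PATTERN_CLASSES <- c("shared_all", "informative", "contradicting", "unique")

#' Simulation configuration
#'
#' Defines the study conditions for a simulated genome set. Defaults match
#' the package's reference desk-scale scenario: two genomes, 50 PP + 30 PM
#' + 30 MP loci, 5% total flank divergence between the genomes (2.5% per
#' branch), copies diverged 10% from the consensus, 300-bp flanks.
#'
#' @param seed integer; fixes all outputs byte-for-byte.
#' @param genome_ids genome labels; for more than two genomes a `topology`
#'   over these labels is required.
#' @param topology newick string (tips = `genome_ids`) used both to evolve
#'   loci and to assign pattern classes; `NULL` for two genomes.
#' @param n_loci named integer vector of locus counts per class. Two-genome
#'   classes: `PP`, `PM`, `MP`, `multimapper` (a PP locus plus a decoy
#'   paralogous flank in the second genome), `edge_truncated` (a copy at a
#'   contig edge with a flank too short to anchor). Multi-genome classes:
#'   `shared_all`, `informative`, `contradicting`, `unique`.
#' @param divergence total expected substitution divergence between two
#'   sister genomes (each branch gets `divergence / 2`).
#' @param sine_divergence per-copy divergence of the planted SINE from the
#'   consensus.
#' @param indel_rate per-site indel probability on each branch (flanks
#'   only; planted SINEs accumulate substitutions but not indels, keeping
#'   truth coordinates and consensus coverage interpretable).
#' @param indel_mean geometric mean indel length.
#' @param flank_len planted flank length (default 300 nt).
#' @param decoy_identity flank identity of multimapper decoys to the true
#'   flank (default 0.85).
#' @param loci_per_contig loci placed per contig.
#' @param spacer_range min/max spacer length between planted loci. The
#'   default keeps spacers above twice the interval-extension length
#'   (SINE + 300), emulating the sparse copy spacing of real genomes,
#'   where retained copies lie tens of kilobases apart; spacers shorter
#'   than twice the extension chain neighbouring loci into multi-locus
#'   clusters by construction.
#' @param consensus consensus object (default [default_consensus()]).
#' @return list of class `"so_sim_config"`.
#' @export
sim_config <- function(seed = 1, genome_ids = c("A", "B"), topology = NULL,
                       n_loci = c(PP = 50, PM = 30, MP = 30),
                       divergence = 0.05, sine_divergence = 0.10,
                       indel_rate = 0.002, indel_mean = 3,
                       flank_len = 300, decoy_identity = 0.85,
                       loci_per_contig = 5, spacer_range = c(1400, 1800),
                       consensus = default_consensus()) {
  stopifnot(length(genome_ids) >= 2, divergence >= 0, divergence < 0.5,
            sine_divergence >= 0, sine_divergence < 0.5,
            indel_rate >= 0, indel_rate < 0.5, all(n_loci >= 0),
            flank_len > 0, loci_per_contig >= 1)
  if (length(genome_ids) > 2 && is.null(topology))
    stop("a topology is required for more than two genomes")
  valid <- if (length(genome_ids) == 2) PAIRWISE_CLASSES else
    PATTERN_CLASSES
  if (!all(names(n_loci) %in% valid))
    stop("unknown locus class(es): ",
         paste(setdiff(names(n_loci), valid), collapse = ", "),
         " (valid: ", paste(valid, collapse = ", "), ")")
  structure(list(seed = seed, genome_ids = genome_ids, topology = topology,
                 n_loci = n_loci, divergence = divergence,
                 sine_divergence = sine_divergence, indel_rate = indel_rate,
                 indel_mean = indel_mean, flank_len = flank_len,
                 decoy_identity = decoy_identity,
                 loci_per_contig = loci_per_contig,
                 spacer_range = spacer_range, consensus = consensus),
            class = "so_sim_config")
}

## presence vector per class, given genome ids and (for >2 genomes) the
## topology: informative = plus on the first non-trivial clade;
## contradicting = first clade tip + first outgroup tip; unique = first tip
.class_presence <- function(class, genome_ids, topology) {
  g <- genome_ids
  if (length(g) == 2) {
    return(switch(class,
      PP = , multimapper = , edge_truncated = c(TRUE, TRUE),
      PM = c(TRUE, FALSE), MP = c(FALSE, TRUE)))
  }
  clades <- .topology_clades(topology)
  nontrivial <- clades[lengths(clades) > 1 & lengths(clades) < length(g)]
  if (class %in% c("informative", "contradicting") &&
      length(nontrivial) == 0)
    stop("topology has no non-trivial clade for class ", class)
  pres <- setNames(rep(FALSE, length(g)), g)
  switch(class,
    shared_all = pres[] <- TRUE,
    unique = pres[g[1]] <- TRUE,
    informative = pres[nontrivial[[1]]] <- TRUE,
    contradicting = {
      clade <- nontrivial[[1]]
      pres[c(clade[1], setdiff(g, clade)[1])] <- TRUE
    })
  unname(pres[g])
}

## evolve a sequence down a topology: returns one evolved copy per tip,
## each edge applying branch_rate substitutions (+ indels when allowed)
.evolve_tips <- function(seq, tree, branch_rate, indel_rate, indel_mean) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  seqs <- list()
  recurse <- function(node, s) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    if (length(kids) == 0L) {
      seqs[[tree$tip.label[node]]] <<- s
      return(invisible())
    }
    for (k in kids)
      recurse(k, .mutate_seq(s, branch_rate, indel_rate, indel_mean))
  }
  recurse(root, s = seq)
  seqs[tree$tip.label]
}

#' Simulate genomes with truth-tabled SINE loci
#'
#' Generates one genome per configured id: ancestral flank-SINE-flank (or
#' flank-flank) cassettes are evolved per genome, placed on contigs with
#' random spacers, and recorded in a truth table with exact per-genome
#' coordinates. Orientation is randomized per locus (shared across genomes,
#' as for a true orthologous insertion). Identical configurations produce
#' bit-identical output.
#'
#' @param config an [sim_config()] object.
#' @return list of class `"so_simulation"`: `genomes` (named list of
#'   [Biostrings::DNAStringSet]), `truth` (data frame: `locus_id`, `class`,
#'   `strand`, then per genome `<id>_contig`, `<id>_start`, `<id>_end`,
#'   `<id>_present`), `consensus`, `config`.
#' @export
simulate_genomes <- function(config) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  g <- config$genome_ids
  ng <- length(g)
  fl <- config$flank_len
  cons_seq <- config$consensus$sequence
  tree <- if (!is.null(config$topology)) {
    tr <- ape::read.tree(text = if (grepl(";", config$topology))
      config$topology else paste0(config$topology, ";"))
    if (!setequal(tr$tip.label, g))
      stop("topology tips must equal genome_ids")
    tr
  } else ape::read.tree(text = paste0("(", g[1], ",", g[2], ");"))
  branch_rate <- config$divergence / 2

  classes <- rep(names(config$n_loci), config$n_loci)
  nloc <- length(classes)
  truth <- vector("list", nloc)
  ## per-genome piece lists for the contig under construction
  pieces <- setNames(rep(list(list()), ng), g)
  cur_pos <- setNames(rep(0L, ng), g)
  cur_contig <- ""
  ctg_idx <- 0L
  locus_in_ctg <- 0L
  contigs <- setNames(rep(list(list()), ng), g)

  flush_contig <- function() {
    if (!nzchar(cur_contig)) return(invisible())
    for (gi in g) {
      contigs[[gi]][[cur_contig]] <<-
        paste(unlist(pieces[[gi]]), collapse = "")
      pieces[[gi]] <<- list()
      cur_pos[gi] <<- 0L
    }
  }
  add_piece <- function(gi, s) {
    pieces[[gi]][[length(pieces[[gi]]) + 1L]] <<- s
    start <- cur_pos[[gi]]
    cur_pos[gi] <<- start + nchar(s)
    start
  }
  rspacer <- function() .random_dna(sample(
    seq(config$spacer_range[1], config$spacer_range[2]), 1L))

  for (i in seq_len(nloc)) {
    cls <- classes[i]
    ## edge-truncated loci must begin their contig; others roll over after
    ## loci_per_contig
    if (locus_in_ctg == 0L || locus_in_ctg >= config$loci_per_contig ||
        cls == "edge_truncated") {
      flush_contig()
      ctg_idx <- ctg_idx + 1L
      cur_contig <- sprintf("ctg%03d", ctg_idx)
      locus_in_ctg <- 0L
    }
    ctg <- cur_contig
    locus_in_ctg <- locus_in_ctg + 1L
    present <- .class_presence(cls, g, config$topology)
    strand <- if (cls == "edge_truncated") "+" else sample(c("+", "-"), 1L)
    lf_anc <- .random_dna(fl)
    rf_anc <- .random_dna(fl)
    sine_anc <- .mutate_seq(cons_seq, config$sine_divergence)
    lf_tips <- .evolve_tips(lf_anc, tree, branch_rate, config$indel_rate,
                            config$indel_mean)
    rf_tips <- .evolve_tips(rf_anc, tree, branch_rate, config$indel_rate,
                            config$indel_mean)
    sine_tips <- .evolve_tips(sine_anc, tree, branch_rate, 0, 0)

    rec <- list(locus_id = sprintf("locus%04d", i), class = cls,
                strand = strand)
    truncate_lf <- cls == "edge_truncated"
    for (k in seq_len(ng)) {
      gi <- g[k]
      lf_g <- lf_tips[[gi]]
      if (truncate_lf) lf_g <- substr(lf_g, nchar(lf_g) - 79L, nchar(lf_g))
      cassette <- paste0(lf_g, if (present[k]) sine_tips[[gi]] else "",
                         rf_tips[[gi]])
      if (strand == "-") cassette <- .revcomp(cassette)
      if (!truncate_lf) add_piece(gi, rspacer())
      start <- add_piece(gi, cassette)
      rec[[paste0(gi, "_contig")]] <- ctg
      rec[[paste0(gi, "_start")]] <- start
      rec[[paste0(gi, "_end")]] <- start + nchar(cassette)
      rec[[paste0(gi, "_present")]] <- present[k]
    }
    if (cls == "multimapper") {
      ## decoy paralogous flank (no SINE) elsewhere in the second genome
      decoy <- paste0(.mutate_seq(lf_anc, 1 - config$decoy_identity),
                      .random_dna(nchar(cons_seq) + fl))
      add_piece(g[2], rspacer())
      dstart <- add_piece(g[2], decoy)
      rec$decoy_contig <- ctg
      rec$decoy_start <- dstart
      rec$decoy_end <- dstart + nchar(decoy)
    }
    truth[[i]] <- rec
  }
  ## trailing spacers so rightward extension never runs off the contig
  if (nloc > 0) for (gi in g) add_piece(gi, rspacer())
  flush_contig()

  all_cols <- unique(unlist(lapply(truth, names)))
  truth_df <- do.call(rbind, lapply(truth, function(r) {
    for (cl in setdiff(all_cols, names(r))) r[[cl]] <- NA
    as.data.frame(r[all_cols], stringsAsFactors = FALSE)
  }))
  genomes <- lapply(g, function(gi) {
    x <- Biostrings::DNAStringSet(unlist(contigs[[gi]]))
    names(x) <- names(contigs[[gi]])
    x
  })
  names(genomes) <- g
  structure(list(genomes = genomes, truth = truth_df,
                 consensus = config$consensus, config = config),
            class = "so_simulation")
}

#' @export
print.so_simulation <- function(x, ...) {
  cat(sprintf("<simulation> %d genomes (%s), %d planted loci, seed %d\n",
              length(x$genomes), paste(names(x$genomes), collapse = ", "),
              nrow(x$truth), x$config$seed))
  print(table(x$truth$class))
  invisible(x)
}

#' Write a simulation to disk
#'
#' One FASTA per genome, the truth table as TSV, and the configuration
#' echoed as a key/value text file.
#'
#' @param sim an `"so_simulation"`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (gi in names(sim$genomes))
    write_fasta(sim$genomes[[gi]], file.path(dir, paste0(gi, ".fa")))
  write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  cfg <- sim$config
  keys <- setdiff(names(cfg), "consensus")
  writeLines(c(
    paste0("consensus: ", cfg$consensus$name),
    vapply(keys, function(k)
      paste0(k, ": ", paste(format(cfg[[k]]), collapse = " ")), "")),
    file.path(dir, "config.txt"))
  invisible(dir)
}

#' Compare a pipeline report against simulator truth
#'
#' Matches each truth locus of class PP/PM/MP/multimapper to report rows by
#' coordinate overlap in the first genome and tabulates predicted versus
#' true status (`multimapper` loci are expected to resolve to PP). Report
#' rows matching no truth locus are false positives; truth loci matching no
#' row are `missing`. `edge_truncated` loci are expected to be absent or
#' discarded and are scored separately.
#'
#' @param truth truth table from [simulate_genomes()].
#' @param report pairwise report data frame.
#' @param genome_a id of the first genome (report's `genome_A`).
#' @return list: `confusion` (table truth x predicted), `accuracy`
#'   (correct / classifiable truth loci), `false_positives`,
#'   `edge_ok` (edge-truncated loci absent or discarded).
#' @export
evaluate_report <- function(truth, report, genome_a = truth_genomes(truth)[1]) {
  sc <- paste0(genome_a, c("_contig", "_start", "_end"))
  classifiable <- truth[truth$class %in%
                          c("PP", "PM", "MP", "multimapper"), , drop = FALSE]
  expected <- ifelse(classifiable$class == "multimapper", "PP",
                     classifiable$class)
  predicted <- rep("missing", nrow(classifiable))
  used <- rep(FALSE, .rows(report))
  for (i in seq_len(nrow(classifiable))) {
    tr <- classifiable[i, ]
    hit <- which(report$contig_A == tr[[sc[1]]] &
                 report$start_A < tr[[sc[3]]] &
                 report$end_A > tr[[sc[2]]])
    if (length(hit) > 0) {
      hit <- hit[1]
      used[hit] <- TRUE
      predicted[i] <- report$status[hit]
    }
  }
  fp <- sum(!used & report$status != "discarded")
  edge <- truth[truth$class == "edge_truncated", , drop = FALSE]
  edge_ok <- TRUE
  for (i in seq_len(nrow(edge))) {
    tr <- edge[i, ]
    hit <- which(report$contig_A == tr[[sc[1]]] &
                 report$start_A < tr[[sc[3]]] &
                 report$end_A > tr[[sc[2]]] &
                 report$status != "discarded")
    if (length(hit) > 0) edge_ok <- FALSE
  }
  confusion <- table(truth = expected,
                     predicted = factor(predicted, levels = c(
                       "PP", "PM", "MP", "discarded", "missing")))
  accuracy <- if (nrow(classifiable) == 0) NA_real_ else
    sum(predicted == expected) / nrow(classifiable)
  list(confusion = confusion, accuracy = accuracy,
       false_positives = fp, edge_ok = edge_ok)
}

#' Genome ids present in a truth table
#' @param truth truth table from [simulate_genomes()].
#' @return character vector.
#' @export
truth_genomes <- function(truth) {
  sub("_contig$", "", grep("^(?!decoy).*_contig$", names(truth),
                           value = TRUE, perl = TRUE))
}
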