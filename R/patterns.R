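## Multi-genome presence/absence patterns. Pairwise verdict tables sharing
## one anchor genome are joined on anchor-interval overlap into per-locus
## presence vectors, and each vector is scored against a fixed tree
## topology: an insertion shared by exactly the tips of a clade is
## phylogenetically informative; a non-clade plus-set of two or more tips
## contradicts the topology.

#' Join pairwise verdict tables into presence/absence patterns
#'
#' Each verdict table must compare the anchor genome (as genome A) with one
#' other genome. Rows whose anchor intervals overlap are the same joined
#' locus. Statuses translate as PP = both plus, PM = anchor plus / other
#' minus, MP = anchor minus / other plus; discarded rows are skipped.
#' Conflicting statuses for one genome become `unknown` with
#' `conflict = TRUE`; genomes absent from a joined locus stay `unknown`.
#'
#' @param tables list of report data frames (from [classify_pairs()] or
#'   [sine_ortho_pair()]), each with the anchor as `genome_A`.
#' @param anchor_genome anchor genome id; default: `genome_A` of the first
#'   table.
#' @return data frame: `pattern_id`, `contig`, `start`, `end` (anchor
#'   coordinates of the joined locus), one `status_<genome>` column per
#'   genome (`"plus"`, `"minus"`, `"unknown"`), `conflict`.
#' @export
join_pairwise <- function(tables, anchor_genome = NULL) {
  tables <- tables[vapply(tables, .rows, 0L) > 0]
  if (length(tables) == 0L) stop("no non-empty verdict tables")
  if (is.null(anchor_genome)) anchor_genome <- tables[[1]]$genome_A[1]
  for (t in tables)
    if (!anchor_genome %in% t$genome_A)
      stop("table lacks anchor genome '", anchor_genome, "' as genome_A")
  tables <- lapply(tables, function(t)
    t[t$genome_A == anchor_genome & t$status != "discarded", , drop = FALSE])
  genomes <- c(anchor_genome,
               unique(unlist(lapply(tables, function(t) t$genome_B))))

  all_anchor <- do.call(rbind, lapply(seq_along(tables), function(i)
    data.frame(tbl = i, row = seq_len(nrow(tables[[i]])),
               contig = tables[[i]]$contig_A, start = tables[[i]]$start_A,
               end = tables[[i]]$end_A, stringsAsFactors = FALSE)))
  if (nrow(all_anchor) == 0L) stop("no classified loci to join")
  gr <- GenomicRanges::GRanges(all_anchor$contig,
                               IRanges::IRanges(all_anchor$start + 1L,
                                                all_anchor$end))
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L, with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap

  out <- vector("list", length(red))
  for (i in seq_along(red)) {
    members <- all_anchor[revmap[[i]], , drop = FALSE]
    status <- setNames(rep("unknown", length(genomes)), genomes)
    conflict <- FALSE
    seen <- setNames(vector("list", length(genomes)), genomes)
    for (j in seq_len(nrow(members))) {
      v <- tables[[members$tbl[j]]][members$row[j], ]
      calls <- list()
      calls[[anchor_genome]] <- if (v$status %in% c("PP", "PM")) "plus"
                                else "minus"
      calls[[v$genome_B]] <- if (v$status %in% c("PP", "MP")) "plus"
                             else "minus"
      for (g in names(calls)) seen[[g]] <- c(seen[[g]], calls[[g]])
    }
    for (g in genomes) {
      u <- unique(seen[[g]])
      if (length(u) == 1L) status[g] <- u
      else if (length(u) > 1L) { status[g] <- "unknown"; conflict <- TRUE }
    }
    row <- data.frame(
      contig = as.character(GenomicRanges::seqnames(red))[i],
      start = GenomicRanges::start(red)[i] - 1L,
      end = GenomicRanges::end(red)[i], conflict = conflict,
      stringsAsFactors = FALSE)
    for (g in genomes) row[[paste0("status_", g)]] <- status[[g]]
    out[[i]] <- row
  }
  res <- do.call(rbind, out)
  res <- res[order(res$contig, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res$pattern_id <- sprintf("pat%05d", seq_len(nrow(res)))
  res[, c("pattern_id", "contig", "start", "end",
          paste0("status_", genomes), "conflict")]
}

## tip sets of all internal nodes of a topology (root included)
.topology_clades <- function(topology) {
  tree <- if (inherits(topology, "phylo")) topology else
    ape::read.tree(text = if (grepl(";", topology)) topology
                   else paste0(topology, ";"))
  parts <- ape::prop.part(tree)
  lapply(parts, function(p) sort(tree$tip.label[p]))
}

#' Classify a presence/absence pattern against a topology
#'
#' Categories: `shared_all` (every known genome plus), `unique` (exactly
#' one plus), `informative` (the plus-set is the tip set of a clade of the
#' topology, neither a single tip nor all tips), `contradicting` (a
#' non-clade plus-set of two or more tips), `no_insertion` (no plus),
#' `incomplete` (fewer than two known statuses, or unknowns whose possible
#' values change the category).
#'
#' @param status named character vector (`"plus"`, `"minus"`, `"unknown"`)
#'   keyed by genome id, or a one-row data frame from [join_pairwise()]
#'   (its `status_*` columns are used).
#' @param topology newick string or `ape::phylo`; all pattern genomes must
#'   be tips.
#' @return category string.
#' @export
classify_pattern <- function(status, topology) {
  if (is.data.frame(status)) {
    cols <- grep("^status_", names(status), value = TRUE)
    status <- setNames(unlist(status[1, cols]), sub("^status_", "", cols))
  }
  clades <- .topology_clades(topology)
  tips <- clades[[which.max(lengths(clades))]]
  if (!all(names(status) %in% tips))
    stop("pattern genome(s) not in topology: ",
         paste(setdiff(names(status), tips), collapse = ", "))
  known <- names(status)[status != "unknown"]
  if (length(known) < 2L) return("incomplete")
  unknown <- setdiff(names(status), known)

  categorize_full <- function(st) {
    plus <- sort(names(st)[st == "plus"])
    if (length(plus) == 0L) return("no_insertion")
    if (length(plus) == length(st)) return("shared_all")
    if (length(plus) == 1L) return("unique")
    if (any(vapply(clades, identical, TRUE, y = plus))) "informative"
    else "contradicting"
  }
  if (length(unknown) == 0L) return(categorize_full(status))
  ## every completion of the unknowns must agree, else incomplete
  completions <- expand.grid(rep(list(c("plus", "minus")),
                                 length(unknown)),
                             stringsAsFactors = FALSE)
  cats <- apply(completions, 1, function(vals) {
    st <- status
    st[unknown] <- vals
    categorize_full(st)
  })
  if (length(unique(cats)) == 1L) cats[1] else "incomplete"
}

#' Summaries of verdicts and patterns
#'
#' `summarize_verdicts()` counts PP/PM/MP and discarded rows of a pairwise
#' report (count conservation: the four counts sum to the classified
#' pairs). `summarize_patterns()` counts joined loci per category and per
#' exact presence vector.
#'
#' @param report pairwise report data frame (may be empty or `NULL`).
#' @return `summarize_verdicts()`: named numeric vector `PP`, `PM`, `MP`,
#'   `discarded`.
#' @export
summarize_verdicts <- function(report) {
  counts <- c(PP = 0, PM = 0, MP = 0, discarded = 0)
  if (.rows(report) == 0L) return(counts)
  tab <- table(report$status)
  counts[names(tab)] <- as.numeric(tab)
  counts
}

#' @rdname summarize_verdicts
#' @param patterns data frame from [join_pairwise()].
#' @param topology topology for [classify_pattern()].
#' @return `summarize_patterns()`: list with `by_category` (named counts)
#'   and `by_vector` (data frame of presence vectors and counts).
#' @export
summarize_patterns <- function(patterns, topology) {
  cats <- vapply(seq_len(nrow(patterns)), function(i)
    classify_pattern(patterns[i, ], topology), "")
  cols <- grep("^status_", names(patterns), value = TRUE)
  vec <- apply(patterns[, cols, drop = FALSE], 1, function(s)
    paste(ifelse(s == "plus", "+", ifelse(s == "minus", "-", "?")),
          collapse = ""))
  by_vec <- as.data.frame(table(vector = vec, category = cats),
                          stringsAsFactors = FALSE)
  by_vec <- by_vec[by_vec$Freq > 0, , drop = FALSE]
  rownames(by_vec) <- NULL
  list(by_category = table(factor(cats, levels = c(
         "shared_all", "unique", "informative", "contradicting",
         "no_insertion", "incomplete"))),
       by_vector = by_vec)
}
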