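## Pairwise pipeline driver: find -> filter -> flank -> map (reciprocal) ->
## extend -> cluster -> link -> categorize -> resolve multiples -> classify
## -> report. All intermediates are kept on the returned object and can be
## written to a run directory for stage-by-stage inspection or re-runs.

#' Pairwise comparison parameters
#'
#' The printed defaults of the method: discovery thresholds (65% identity,
#' 80% consensus coverage), 300-bp proximity filter, 300-bp flanks, 100-bp
#' minimum mapped length, 150-nt flank / 100-nt SINE-region / 65% identity
#' classification cut-offs.
#'
#' @param min_identity,min_coverage copy acceptance (see [scan_genome()]).
#' @param min_gap proximity filter (see [filter_proximal()]).
#' @param flank_len flank length (see [extract_left_flanks()]).
#' @param min_mapped_len,seed_k,map_min_score,secondary_frac mapper
#'   settings (see [map_flanks()]).
#' @param pad right-flank allowance for [extend_right()].
#' @param min_overlap merge overlap (see [cluster_overlaps()]).
#' @param flank_min_len,flank_min_ident,sine_min_len,sine_min_ident
#'   classification thresholds (see [classify_pair()]).
#' @param member_sim_threshold resolver threshold (see [resolve_group()]).
#' @param scan_min_score discovery iteration floor (see [scan_genome()]).
#' @return list of class `"so_params"`.
#' @export
pair_params <- function(min_identity = 65, min_coverage = 0.80,
                        min_gap = 300, flank_len = 300,
                        min_mapped_len = 100, seed_k = 19,
                        map_min_score = 60, secondary_frac = 0.8,
                        pad = 300, min_overlap = 1,
                        flank_min_len = 150, flank_min_ident = 65,
                        sine_min_len = 100, sine_min_ident = 65,
                        member_sim_threshold = 65, scan_min_score = 100) {
  structure(as.list(environment()), class = "so_params")
}

#' Run the full pairwise comparison of two genomes
#'
#' Executes the complete workflow for one ordered genome pair and returns a
#' result object carrying every intermediate: copies found and retained,
#' flanks, reciprocal mappings, candidate and merged loci, linked groups by
#' category, resolver outcomes for multiple groups, the final classified
#' report, and summary counts.
#'
#' @param genome_a,genome_b genomes ([Biostrings::DNAStringSet], named
#'   character vector, or FASTA path).
#' @param consensus consensus object from [sine_consensus()] /
#'   [read_consensus()].
#' @param genome_ids length-2 character: ids for the two genomes.
#' @param params a [pair_params()] object.
#' @param outdir if non-`NULL`, intermediates and the report are written
#'   under this directory.
#' @return object of class `"sine_ortho_pair"`; see Details for elements.
#'   The final report is in `$report`, summary counts in `$summary`.
#' @details Elements: `hits_a`, `hits_b` (all copies), `distant_a`,
#'   `distant_b` (after the proximity filter), `flanks_a`, `flanks_b`,
#'   `map_ab`, `map_ba`, `loci` (candidate loci, four coordinate sets),
#'   `merged_a`, `merged_b`, `groups`, `report`, `multilocus`,
#'   `unresolved`, `summary`.
#' @examples
#' \donttest{
#' sim <- simulate_genomes(sim_config(seed = 1, n_loci = c(PP = 3)))
#' res <- sine_ortho_pair(sim$genomes$A, sim$genomes$B, sim$consensus)
#' summary(res)
#' }
#' @export
sine_ortho_pair <- function(genome_a, genome_b, consensus,
                            genome_ids = c("A", "B"),
                            params = pair_params(), outdir = NULL) {
  ga <- .as_dnastringset(genome_a)
  gb <- .as_dnastringset(genome_b)
  ia <- genome_ids[1]; ib <- genome_ids[2]
  p <- params
  genomes <- setNames(list(ga, gb), c(ia, ib))

  ## stage 1: discovery + proximity filter
  hits_a <- scan_genome(ga, consensus, p$min_identity, p$min_coverage,
                        min_score = p$scan_min_score, genome_id = ia)
  hits_b <- scan_genome(gb, consensus, p$min_identity, p$min_coverage,
                        min_score = p$scan_min_score, genome_id = ib)
  distant_a <- filter_proximal(hits_a, p$min_gap)
  distant_b <- filter_proximal(hits_b, p$min_gap)

  if (nrow(distant_a) == 0L && nrow(distant_b) == 0L) {
    warning("no SINE copies retained in either genome; empty report")
    return(.pair_result(hits_a, hits_b, distant_a, distant_b,
                        NULL, NULL, NULL, NULL, NULL, NULL, NULL, list(),
                        NULL, NULL, NULL, genome_ids, params, outdir))
  }

  ## stage 2: flanks + reciprocal mapping (each against both target strands)
  flanks_a <- extract_left_flanks(distant_a, ga, p$flank_len)
  flanks_b <- extract_left_flanks(distant_b, gb, p$flank_len)
  map_ab <- map_flanks(flanks_a, gb, target_genome_id = ib,
                       min_mapped_len = p$min_mapped_len, k = p$seed_k,
                       min_score = p$map_min_score,
                       secondary_frac = p$secondary_frac)
  map_ba <- map_flanks(flanks_b, ga, target_genome_id = ia,
                       min_mapped_len = p$min_mapped_len, k = p$seed_k,
                       min_score = p$map_min_score,
                       secondary_frac = p$secondary_frac)

  ## stage 3: extend all four coordinate sets over SINE + right flank
  sl <- consensus$length
  loci_aq <- extend_right(flanks_a, sl, p$pad, ga, genome_id = ia,
                          origin = "query_copy", id_prefix = paste0(ia, "q"))
  loci_bt <- extend_right(map_ab, sl, p$pad, gb, genome_id = ib,
                          origin = "mapped_flank",
                          id_prefix = paste0(ib, "t"))
  loci_bq <- extend_right(flanks_b, sl, p$pad, gb, genome_id = ib,
                          origin = "query_copy", id_prefix = paste0(ib, "q"))
  loci_at <- extend_right(map_ba, sl, p$pad, ga, genome_id = ia,
                          origin = "mapped_flank",
                          id_prefix = paste0(ia, "t"))
  loci <- rbind(loci_aq, loci_at, loci_bq, loci_bt)

  ## stage 4: per-genome merge, cross-genome links, connected groups
  merged_a <- cluster_overlaps(loci[loci$genome_id == ia, ], p$min_overlap)
  merged_b <- cluster_overlaps(loci[loci$genome_id == ib, ], p$min_overlap)
  links <- rbind(
    .mapping_links(map_ab, loci_aq, loci_bt),
    .mapping_links(map_ba, loci_bq, loci_at))
  groups <- if (.rows(links) > 0)
    link_groups(merged_a, merged_b, links) else list()

  ## stage 5: resolve multiples, classify doubles + promoted doubles
  all_merged <- rbind(merged_a, merged_b)
  seq_cache <- new.env(parent = emptyenv())
  get_seq <- function(id) {
    if (is.null(seq_cache[[id]])) {
      lx <- all_merged[all_merged$locus_id == id, ]
      seq_cache[[id]] <- fetch_sequence(lx, genomes[[lx$genome_id]])
    }
    seq_cache[[id]]
  }
  pair_rows <- list()
  multilocus <- list()
  unresolved <- list()
  for (grp in groups) {
    if (grp$category == "double") {
      la <- grp$loci$locus_id[grp$loci$genome_id == ia]
      lb <- grp$loci$locus_id[grp$loci$genome_id == ib]
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        group_id = grp$group_id, category = "double",
        locus_id_A = la, locus_id_B = lb, stringsAsFactors = FALSE)
    } else if (grp$category == "multiple") {
      seqs <- setNames(lapply(grp$loci$locus_id, get_seq),
                       grp$loci$locus_id)
      seqs <- unlist(seqs)
      if (length(unique(grp$loci$genome_id)) < 2L) {
        unresolved[[length(unresolved) + 1L]] <- inspection_table(grp)
        next
      }
      pair <- closest_cross_pair(grp, seqs)
      v <- classify_pair(
        align_triple(seqs[[pair$locus_a]], seqs[[pair$locus_b]], consensus),
        p$flank_min_len, p$flank_min_ident, p$sine_min_len, p$sine_min_ident)
      res <- resolve_group(grp, seqs, v, p$member_sim_threshold)
      if (res$outcome == "promoted_double") {
        a_first <- all_merged$genome_id[
          all_merged$locus_id == res$pair$locus_a] == ia
        pair_rows[[length(pair_rows) + 1L]] <- data.frame(
          group_id = grp$group_id, category = "promoted_double",
          locus_id_A = if (a_first) res$pair$locus_a else res$pair$locus_b,
          locus_id_B = if (a_first) res$pair$locus_b else res$pair$locus_a,
          stringsAsFactors = FALSE)
      } else if (res$outcome == "multilocus_set") {
        multilocus[[length(multilocus) + 1L]] <- inspection_table(grp, res)
      } else {
        unresolved[[length(unresolved) + 1L]] <- inspection_table(grp, res)
      }
    } else {
      unresolved[[length(unresolved) + 1L]] <- inspection_table(grp)
    }
  }
  pairs <- if (length(pair_rows) > 0) do.call(rbind, pair_rows) else NULL
  report <- if (!is.null(pairs))
    classify_pairs(pairs, all_merged, genomes, consensus,
                   flank_min_len = p$flank_min_len,
                   flank_min_ident = p$flank_min_ident,
                   sine_min_len = p$sine_min_len,
                   sine_min_ident = p$sine_min_ident) else NULL

  .pair_result(hits_a, hits_b, distant_a, distant_b, flanks_a, flanks_b,
               map_ab, map_ba, loci, merged_a, merged_b, groups, report,
               multilocus, unresolved, genome_ids, params, outdir)
}

.mapping_links <- function(mappings, query_loci, target_loci) {
  if (.rows(mappings) == 0L)
    return(data.frame(locus_a = character(0), locus_b = character(0),
                      stringsAsFactors = FALSE))
  data.frame(
    locus_a = query_loci$locus_id[match(mappings$copy_id,
                                        query_loci$source_id)],
    locus_b = target_loci$locus_id[match(mappings$mapping_id,
                                         target_loci$source_id)],
    stringsAsFactors = FALSE)
}

.pair_result <- function(hits_a, hits_b, distant_a, distant_b, flanks_a,
                         flanks_b, map_ab, map_ba, loci, merged_a, merged_b,
                         groups, report, multilocus, unresolved, genome_ids,
                         params, outdir) {
  cat_tab <- table(factor(vapply(groups, `[[`, "", "category"),
                          levels = c("double", "multiple", "poly")))
  res <- structure(list(
    genome_ids = genome_ids, params = params,
    hits_a = hits_a, hits_b = hits_b,
    distant_a = distant_a, distant_b = distant_b,
    flanks_a = flanks_a, flanks_b = flanks_b,
    map_ab = map_ab, map_ba = map_ba, loci = loci,
    merged_a = merged_a, merged_b = merged_b, groups = groups,
    report = report,
    multilocus = if (length(multilocus)) do.call(rbind, multilocus),
    unresolved = if (length(unresolved)) do.call(rbind, unresolved),
    summary = list(
      copies = c(setNames(c(.rows(hits_a), .rows(hits_b)), genome_ids)),
      distant = c(setNames(c(.rows(distant_a), .rows(distant_b)),
                           genome_ids)),
      groups = cat_tab,
      verdicts = summarize_verdicts(report))),
    class = "sine_ortho_pair")
  if (!is.null(outdir)) .write_intermediates(res, outdir)
  res
}

.write_intermediates <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name, bed = FALSE) {
    if (.rows(df) == 0L) return(invisible())
    if (bed) write_bed(df, file.path(outdir, name))
    else write.table(df, file.path(outdir, name), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  }
  ids <- res$genome_ids
  if (.rows(res$hits_a)) write_hits_bed(res$hits_a,
    file.path(outdir, paste0("copies_", ids[1], ".bed")))
  if (.rows(res$hits_b)) write_hits_bed(res$hits_b,
    file.path(outdir, paste0("copies_", ids[2], ".bed")))
  if (.rows(res$distant_a)) write_hits_bed(res$distant_a,
    file.path(outdir, paste0("distant_", ids[1], ".bed")))
  if (.rows(res$distant_b)) write_hits_bed(res$distant_b,
    file.path(outdir, paste0("distant_", ids[2], ".bed")))
  w(res$flanks_a, paste0("flanks_", ids[1], ".tsv"))
  w(res$flanks_b, paste0("flanks_", ids[2], ".tsv"))
  w(res$map_ab, paste0("map_", ids[1], "_to_", ids[2], ".tsv"))
  w(res$map_ba, paste0("map_", ids[2], "_to_", ids[1], ".tsv"))
  w(res$loci, "candidate_loci.tsv")
  w(res$merged_a, paste0("merged_", ids[1], ".tsv"))
  w(res$merged_b, paste0("merged_", ids[2], ".tsv"))
  w(groups_table(res$groups), "groups.tsv")
  if (.rows(res$report)) write_report(res$report,
                                      file.path(outdir, "report.tsv"))
  w(res$multilocus, "multilocus_sets.tsv")
  w(res$unresolved, "unresolved_groups.tsv")
  invisible(outdir)
}

#' @export
print.sine_ortho_pair <- function(x, ...) {
  s <- x$summary
  cat(sprintf("sineortho pairwise comparison: %s vs %s\n",
              x$genome_ids[1], x$genome_ids[2]))
  cat(sprintf("  copies (total):   %s\n",
              paste(names(s$copies), s$copies, collapse = ", ")))
  cat(sprintf("  copies (distant): %s\n",
              paste(names(s$distant), s$distant, collapse = ", ")))
  cat(sprintf("  groups: %s\n",
              paste(names(s$groups), as.integer(s$groups), sep = "=",
                    collapse = ", ")))
  cat(sprintf("  verdicts: %s\n",
              paste(names(s$verdicts), as.integer(s$verdicts), sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' @export
summary.sine_ortho_pair <- function(object, ...) {
  print(object)
  if (.rows(object$report) > 0) {
    ok <- object$report[object$report$status != "discarded", ]
    if (nrow(ok) > 0) {
      cat("\nmean segment identities over classified pairs:\n")
      for (pre in c("LF", "SINE", "RF"))
        cat(sprintf("  %s pct_AB: %.1f\n", pre,
                    mean(ok[[paste0(pre, "_pct_AB")]])))
    }
    tab <- table(object$report$discard_reason)
    tab <- tab[names(tab) != "none"]
    if (length(tab) > 0) {
      cat("discard reasons:\n")
      for (nm in names(tab)) cat(sprintf("  %s: %d\n", nm, tab[[nm]]))
    }
  }
  invisible(object$summary)
}
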