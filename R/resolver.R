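## Resolution of multiple (3-10 locus) groups: find the most similar
## cross-genome pair, classify it like a double, then keep only group
## members sufficiently similar to that pair. If exactly the pair remains
## it is promoted into the doubles stream; larger similar sets are exported
## as multilocus sets; poly groups (> 10) are never auto-resolved.

#' Pairwise whole-locus identity matrix of a group
#'
#' Global alignment identity (identical positions / shorter ungapped
#' length, percent) between every pair of member locus sequences.
#'
#' @param seqs named character vector of member sequences (names = locus
#'   ids).
#' @param scoring an [align_scoring()]; the standard scoring (gap
#'   extension 4) is deliberate here -- cheaper gap extension lets the
#'   aligner fish matches out of unrelated sequence and inflates the
#'   identity of true paralogs past the member-similarity threshold.
#' @return symmetric numeric matrix with 100 on the diagonal.
#' @export
locus_identity_matrix <- function(seqs, scoring = align_scoring()) {
  n <- length(seqs)
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    m[i, j] <- m[j, i] <- .global_identity(seqs[[i]], seqs[[j]],
                                           scoring)$identity
  }
  m
}

#' Most similar cross-genome pair of a group
#'
#' Over all (genome A locus, genome B locus) pairs of the group, returns
#' the pair with the highest whole-locus identity; ties are broken by the
#' higher identical-nucleotide count, then by lexicographically smaller
#' (A id, B id). Deterministic.
#'
#' @param group a group from [link_groups()] (or any data frame of loci
#'   with `locus_id` and `genome_id` as its `loci` element).
#' @param seqs named character vector of member sequences.
#' @param scoring see [locus_identity_matrix()].
#' @return list: `locus_a`, `locus_b` (ids), `identity`, `identical`.
#' @export
closest_cross_pair <- function(group, seqs,
                               scoring = align_scoring()) {
  loci <- group$loci
  gids <- unique(loci$genome_id)
  if (length(gids) < 2L)
    stop("group ", group$group_id %||% "", " has loci from only one genome")
  ids_a <- sort(loci$locus_id[loci$genome_id == gids[1]])
  ids_b <- sort(loci$locus_id[loci$genome_id == gids[2]])
  best <- NULL
  for (ia in ids_a) for (ib in ids_b) {
    gi <- .global_identity(seqs[[ia]], seqs[[ib]], scoring)
    cand <- list(locus_a = ia, locus_b = ib, identity = gi$identity,
                 identical = gi$identical)
    if (is.null(best) ||
        cand$identity > best$identity ||
        (cand$identity == best$identity &&
         cand$identical > best$identical))
      best <- cand
    ## equal identity and identical count: earlier (sorted) pair stands
  }
  best
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Resolve a multiple group around its closest cross-genome pair
#'
#' Members whose whole-locus identity to the closest pair (the better of
#' the identities to its two members) is below `member_sim_threshold` are
#' dropped. If exactly the cross-genome pair remains and its verdict is not
#' a discard, the group is promoted to the doubles stream; if more than two
#' similar members remain it becomes a multilocus set (exported, excluded
#' from pair statistics). Poly groups are returned unresolved.
#'
#' @param group a group from [link_groups()].
#' @param seqs named character vector of member sequences.
#' @param pair_verdict the `"so_verdict"` for the closest pair (from
#'   [classify_pair()]); `NULL` to skip the promotion-soundness check.
#' @param member_sim_threshold percent identity below which other members
#'   are dropped (default 65).
#' @param scoring see [locus_identity_matrix()].
#' @return list: `outcome` (`"promoted_double"`, `"multilocus_set"`,
#'   `"unresolved"`), `pair` (closest pair, if computed), `kept` (locus
#'   ids), `identity_matrix`.
#' @export
resolve_group <- function(group, seqs, pair_verdict = NULL,
                          member_sim_threshold = 65,
                          scoring = align_scoring()) {
  if (group$category == "poly")
    return(list(outcome = "unresolved", pair = NULL,
                kept = group$loci$locus_id, identity_matrix = NULL))
  if (length(unique(group$loci$genome_id)) < 2L)
    return(list(outcome = "unresolved", pair = NULL,
                kept = group$loci$locus_id, identity_matrix = NULL))
  pair <- closest_cross_pair(group, seqs, scoring)
  im <- locus_identity_matrix(seqs[group$loci$locus_id], scoring)
  others <- setdiff(group$loci$locus_id, c(pair$locus_a, pair$locus_b))
  sim_to_pair <- vapply(others, function(id)
    max(im[id, pair$locus_a], im[id, pair$locus_b]), 0)
  kept <- c(pair$locus_a, pair$locus_b,
            others[sim_to_pair >= member_sim_threshold])
  if (!is.null(pair_verdict) && pair_verdict$status == "discarded")
    return(list(outcome = "unresolved", pair = pair, kept = kept,
                identity_matrix = im))
  outcome <- if (length(kept) == 2L) "promoted_double" else "multilocus_set"
  list(outcome = outcome, pair = pair, kept = kept, identity_matrix = im)
}

#' Export unresolved and multilocus groups for manual inspection
#'
#' One row per member with coordinates; when a resolution carrying the
#' pairwise identity matrix is supplied, each row gets its identities to
#' all members as a comma-joined `member:pct` string.
#'
#' @param group a group from [link_groups()].
#' @param resolution the matching [resolve_group()] result (optional).
#' @return data frame.
#' @export
inspection_table <- function(group, resolution = NULL) {
  df <- group$loci[, c("locus_id", "genome_id", "contig", "start", "end")]
  df$group_id <- group$group_id
  df$category <- group$category
  df$kept <- if (!is.null(resolution))
    df$locus_id %in% resolution$kept else NA
  im <- resolution$identity_matrix
  df$identities <- if (!is.null(im))
    vapply(df$locus_id, function(id)
      paste(sprintf("%s:%.1f", setdiff(colnames(im), id),
                    im[id, setdiff(colnames(im), id)]), collapse = ","),
      "") else NA_character_
  df
}
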