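## Internal flank mapper: exact k-mer seeds, diagonal chaining into
## candidate windows, affine-gap local extension with Smith-Waterman over
## each window. All alignments above the score threshold are reported per
## flank (secondary hits retained down to a fraction of the best score);
## multimappers are an analysis target and must not be suppressed here.

## k-mer position index of one sequence: list keyed by k-mer -> 0-based
## start positions. Skips k-mers containing N.
.kmer_index <- function(seq_str, k) {
  n <- nchar(seq_str)
  if (n < k) return(list())
  starts <- seq_len(n - k + 1L)
  kmers <- substring(seq_str, starts, starts + k - 1L)
  keep <- !grepl("N", kmers, fixed = TRUE)
  split(starts[keep] - 1L, kmers[keep])
}

## Candidate windows on a target sequence for one query: seed matches are
## grouped by diagonal band, each band projected to a subject window, and
## overlapping windows merged.
.seed_windows <- function(query, index, k, qlen, tlen, band = 32L,
                          margin = 60L) {
  nq <- nchar(query)
  if (nq < k) return(NULL)
  qstarts <- seq_len(nq - k + 1L)
  qkmers <- substring(query, qstarts, qstarts + k - 1L)
  hit <- which(qkmers %in% names(index))
  if (length(hit) == 0L) return(NULL)
  qpos <- integer(0); tpos <- integer(0)
  for (i in hit) {
    tp <- index[[qkmers[i]]]
    qpos <- c(qpos, rep.int(qstarts[i] - 1L, length(tp)))
    tpos <- c(tpos, tp)
  }
  diag <- tpos - qpos
  ord <- order(diag, tpos)
  diag <- diag[ord]; tpos <- tpos[ord]; qpos <- qpos[ord]
  grp <- cumsum(c(1L, diff(diag) > band))
  win <- lapply(split(seq_along(grp), grp), function(ii) {
    c(max(0L, min(tpos[ii] - qpos[ii]) - margin),
      min(tlen, max(tpos[ii] + (qlen - qpos[ii])) + margin))
  })
  win <- do.call(rbind, win)
  win <- win[order(win[, 1]), , drop = FALSE]
  merged <- list(win[1, ])
  if (nrow(win) > 1) for (i in 2:nrow(win)) {
    last <- merged[[length(merged)]]
    if (win[i, 1] <= last[2]) merged[[length(merged)]][2] <-
        max(last[2], win[i, 2])
    else merged[[length(merged) + 1L]] <- win[i, ]
  }
  merged
}

## Best local alignments of query inside one window; iterative masking digs
## out secondary alignments within the same window.
.window_alignments <- function(query, subj_str, win0, scoring, min_score) {
  out <- list()
  repeat {
    aln <- .pairwise(query, Biostrings::DNAString(subj_str), "local", scoring)
    if (BiocGenerics::score(aln) < min_score) break
    s0 <- Biostrings::start(Biostrings::subject(aln)) - 1L
    s1 <- Biostrings::end(Biostrings::subject(aln))
    pat <- as.character(Biostrings::alignedPattern(aln))
    aligned_len <- nchar(gsub("-", "", pat, fixed = TRUE))
    out[[length(out) + 1L]] <- list(
      start = win0 + s0, end = win0 + s1,
      aligned_length = aligned_len, score = BiocGenerics::score(aln))
    substr(subj_str, s0 + 1L, s1) <- strrep("N", s1 - s0)
  }
  out
}

#' Map flanks to a target genome
#'
#' Seed-and-extend local alignment of each flank against both strands of
#' every target contig: exact `k`-mer seeds are chained by diagonal into
#' candidate windows, each window is aligned with an affine-gap local
#' alignment, and every alignment scoring at least `min_score` is kept.
#' Per flank, secondary alignments are retained down to
#' `secondary_frac` times the flank's best score; alignments with fewer
#' than `min_mapped_len` flank bases aligned are then removed. A hit whose
#' coordinates equal the flank's own (same genome id, contig and
#' coordinates) is treated as a self-hit and dropped.
#'
#' @param flanks flank table from [extract_left_flanks()].
#' @param target_genome genome to map onto.
#' @param target_genome_id label for the target genome.
#' @param min_mapped_len minimum aligned flank length in nt (default 100).
#' @param k exact seed length (default 19).
#' @param min_score minimum local alignment score (default 60).
#' @param secondary_frac retain alignments scoring at least this fraction
#'   of the flank's best alignment (default 0.8).
#' @param scoring an [align_scoring()] object.
#' @return data frame: `mapping_id`, `copy_id`, `flank_genome_id`,
#'   `target_genome_id`, `contig`, `start`, `end` (forward-strand 0-based
#'   half-open on the target), `strand` (orientation of the flank's SINE on
#'   the target forward strand), `aligned_length`, `score`.
#' @export
map_flanks <- function(flanks, target_genome, target_genome_id = "target",
                       min_mapped_len = 100, k = 19, min_score = 60,
                       secondary_frac = 0.8, scoring = align_scoring()) {
  target_genome <- .as_dnastringset(target_genome)
  empty <- .empty_df(c(mapping_id = "chr", copy_id = "chr",
                       flank_genome_id = "chr", target_genome_id = "chr",
                       contig = "chr", start = "int", end = "int",
                       strand = "chr", aligned_length = "int",
                       score = "num"))
  if (nrow(flanks) == 0L) return(empty)
  tseqs <- lapply(seq_along(target_genome),
                  function(i) as.character(target_genome[[i]]))
  names(tseqs) <- names(target_genome)
  indexes <- lapply(tseqs, .kmer_index, k = k)
  tlens <- vapply(tseqs, nchar, 0L)

  rows <- list()
  for (fi in seq_len(nrow(flanks))) {
    fl <- flanks[fi, ]
    if (nchar(fl$sequence) < k) {
      message("flank of ", fl$copy_id, " shorter than seed length (",
              nchar(fl$sequence), " < ", k, "); unmapped")
      next
    }
    fhits <- list()
    for (ori in c("+", "-")) {
      qseq <- if (ori == "+") fl$sequence else .revcomp(fl$sequence)
      qdna <- Biostrings::DNAString(qseq)
      for (ci in seq_along(tseqs)) {
        wins <- .seed_windows(qseq, indexes[[ci]], k, nchar(qseq),
                              tlens[[ci]])
        for (w in wins) {
          alns <- .window_alignments(
            qdna, substr(tseqs[[ci]], w[1] + 1L, w[2]), w[1],
            scoring, min_score)
          for (a in alns)
            fhits[[length(fhits) + 1L]] <- data.frame(
              copy_id = fl$copy_id, flank_genome_id = fl$genome_id,
              target_genome_id = target_genome_id,
              contig = names(tseqs)[ci], start = a$start, end = a$end,
              strand = ori, aligned_length = a$aligned_length,
              score = a$score, stringsAsFactors = FALSE)
        }
      }
    }
    if (length(fhits) == 0L) next
    fh <- do.call(rbind, fhits)
    ## merged windows can still yield duplicate alignments; keep best per span
    key <- paste(fh$contig, fh$start, fh$end, fh$strand)
    fh <- fh[order(key, -fh$score), , drop = FALSE]
    fh <- fh[!duplicated(paste(fh$contig, fh$start, fh$end, fh$strand)), ,
             drop = FALSE]
    fh <- fh[fh$score >= secondary_frac * max(fh$score), , drop = FALSE]
    fh <- fh[fh$aligned_length >= min_mapped_len, , drop = FALSE]
    self <- fh$flank_genome_id == target_genome_id &
      fh$contig == fl$contig & fh$start == fl$start & fh$end == fl$end &
      fh$strand == fl$strand
    fh <- fh[!self, , drop = FALSE]
    if (nrow(fh) > 0L) rows[[length(rows) + 1L]] <- fh
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$copy_id, out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out$mapping_id <- sprintf("map_%s_to_%s_%05d",
                            out$flank_genome_id[1], target_genome_id,
                            seq_len(nrow(out)))
  out[, c("mapping_id", "copy_id", "flank_genome_id", "target_genome_id",
          "contig", "start", "end", "strand", "aligned_length", "score")]
}
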