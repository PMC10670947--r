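## SINE copy discovery: iterative full Smith-Waterman search of each contig
## against the family consensus, masking each found region with N before the
## next pass, on both strands. This mirrors an ssearch-style repeated search
## in which accepted copies are removed until a pass finds nothing new.

#' Does a candidate alignment pass the copy-acceptance thresholds?
#'
#' The two acceptance criteria for a SINE copy: percent identity over the
#' aligned region and fraction of the consensus length covered by the
#' alignment. Comparisons are inclusive (a hit at exactly the threshold
#' passes).
#'
#' @param pct_identity percent identity over the aligned region, 0-100.
#' @param consensus_coverage aligned consensus span / consensus length.
#' @param min_identity,min_coverage acceptance thresholds
#'   (defaults 65 and 0.80).
#' @return logical.
#' @export
hit_passes <- function(pct_identity, consensus_coverage,
                       min_identity = 65, min_coverage = 0.80) {
  pct_identity >= min_identity & consensus_coverage >= min_coverage
}

## One strand of one contig: repeated best-local-alignment + N-masking.
## Every found region (accepted or not) is masked in the pass's working
## copy so the search cannot return it again; iteration stops when the
## best score drops below min_score. Only ACCEPTED hit regions belong to
## the mask shared between strands -- a rejected region (for example a
## weak antisense self-similarity of the element) must not hide the real
## copy from the other strand's pass.
.scan_strand <- function(seq_str, consensus, scoring, min_score,
                         min_identity, min_coverage) {
  cons <- Biostrings::DNAString(consensus$sequence)
  hits <- list()
  repeat {
    subj <- Biostrings::DNAString(seq_str)
    aln <- .pairwise(cons, subj, "local", scoring)
    if (BiocGenerics::score(aln) < min_score) break
    s0 <- Biostrings::start(Biostrings::subject(aln)) - 1L  # to 0-based
    s1 <- Biostrings::end(Biostrings::subject(aln))
    p_span <- Biostrings::end(Biostrings::pattern(aln)) -
      Biostrings::start(Biostrings::pattern(aln)) + 1L
    ident <- 100 * Biostrings::nmatch(aln) / Biostrings::nchar(aln)
    cov <- p_span / consensus$length
    if (hit_passes(ident, cov, min_identity, min_coverage))
      hits[[length(hits) + 1L]] <- list(start = s0, end = s1,
                                        pct_identity = ident,
                                        consensus_coverage = cov)
    substr(seq_str, s0 + 1L, s1) <- strrep("N", s1 - s0)
  }
  list(hits = hits)
}

.mask_intervals <- function(seq_str, hits) {
  for (h in hits)
    substr(seq_str, h$start + 1L, h$end) <- strrep("N", h$end - h$start)
  seq_str
}

#' Find all copies of a SINE consensus in a genome
#'
#' Iterative local-alignment search: on each pass the single best local
#' alignment of the consensus against the (progressively masked) contig is
#' taken; its region is masked with N and the search repeats until the best
#' remaining score falls below `min_score`. Alignments passing both the
#' identity and the consensus-coverage criterion are accepted as copies.
#' Both strands are searched against the shared mask, so reported hits
#' never overlap; minus-strand hits carry forward-strand coordinates with
#' strand "-".
#'
#' @param genome a [Biostrings::DNAStringSet], named character vector, or
#'   FASTA path.
#' @param consensus a consensus object from [sine_consensus()] /
#'   [read_consensus()].
#' @param min_identity minimum percent identity over the aligned region
#'   (default 65).
#' @param min_coverage minimum aligned-consensus-span / consensus-length
#'   (default 0.80).
#' @param scoring an [align_scoring()] object for the internal
#'   Smith-Waterman search.
#' @param min_score stop a contig's search when the best local score drops
#'   below this (default 100; termination control, not an acceptance
#'   criterion).
#' @param genome_id label recorded in the `genome_id` column.
#' @return data frame of accepted copies sorted by (contig, start):
#'   `copy_id`, `genome_id`, `contig`, `start`, `end` (0-based half-open),
#'   `strand`, `pct_identity`, `consensus_coverage`.
#' @examples
#' cons <- default_consensus()
#' set.seed(7)
#' bg <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
#' g <- paste0(substr(bg, 1, 1000), cons$sequence, substr(bg, 1001, 3000))
#' scan_genome(c(chr1 = g), cons)
#' @export
scan_genome <- function(genome, consensus, min_identity = 65,
                        min_coverage = 0.80, scoring = align_scoring(),
                        min_score = 100, genome_id = "genome") {
  if (is.null(consensus$sequence) || nchar(consensus$sequence) == 0L)
    stop("empty consensus")
  if (min_identity < 0 || min_identity > 100)
    stop("min_identity must be in [0,100]")
  if (min_coverage <= 0 || min_coverage > 1)
    stop("min_coverage must be in (0,1]")
  genome <- .as_dnastringset(genome)
  if (length(genome) == 0L) stop("empty genome")
  .check_iupac(genome)

  rows <- list()
  for (ci in seq_along(genome)) {
    contig <- names(genome)[ci]
    fwd <- as.character(genome[[ci]])
    clen <- nchar(fwd)
    if (clen < 1L) next
    fw <- .scan_strand(fwd, consensus, scoring, min_score,
                       min_identity, min_coverage)
    for (h in fw$hits)
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = genome_id, contig = contig, start = h$start,
        end = h$end, strand = "+", pct_identity = h$pct_identity,
        consensus_coverage = h$consensus_coverage,
        stringsAsFactors = FALSE)
    shared <- .mask_intervals(fwd, fw$hits)
    rv <- .scan_strand(.revcomp(shared), consensus, scoring, min_score,
                       min_identity, min_coverage)
    for (h in rv$hits)
      rows[[length(rows) + 1L]] <- data.frame(
        genome_id = genome_id, contig = contig,
        start = clen - h$end, end = clen - h$start, strand = "-",
        pct_identity = h$pct_identity,
        consensus_coverage = h$consensus_coverage,
        stringsAsFactors = FALSE)
  }
  out <- if (length(rows) == 0L)
    .empty_df(c(genome_id = "chr", contig = "chr", start = "int",
                end = "int", strand = "chr", pct_identity = "num",
                consensus_coverage = "num"))
  else do.call(rbind, rows)
  out <- out[order(out$contig, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out$copy_id <- if (nrow(out) > 0)
    sprintf("%s_copy%04d", genome_id, seq_len(nrow(out))) else character(0)
  out[, c("copy_id", "genome_id", "contig", "start", "end", "strand",
          "pct_identity", "consensus_coverage")]
}

#' Remove copies that lie too close to another copy
#'
#' The end-to-start gap between two copies on the same contig must be at
#' least `min_gap`; by default both members of any closer pair are removed
#' (a copy is kept only if it is at least `min_gap` away from every other
#' copy). Overlapping copies count as distance below any positive gap.
#'
#' @param hits hit table from [scan_genome()] (any data frame with
#'   `contig`, `start`, `end`).
#' @param min_gap minimum allowed gap in nt (default 300).
#' @param keep `"none"` removes both members of a close pair (default);
#'   `"first"` keeps the left member of each offending adjacent pair, for
#'   sensitivity analysis.
#' @return the retained rows, input order preserved.
#' @export
filter_proximal <- function(hits, min_gap = 300, keep = c("none", "first")) {
  keep <- match.arg(keep)
  if (min_gap < 0) stop("min_gap must be >= 0")
  n <- nrow(hits)
  if (n == 0L) return(hits)
  drop <- logical(n)
  ord <- order(hits$contig, hits$start, hits$end)
  o_contig <- hits$contig[ord]
  o_start <- hits$start[ord]
  o_end <- hits$end[ord]
  ## sweep: for each copy, examine following copies until their start is
  ## min_gap past this copy's end; covers all pairs closer than min_gap
  for (i in seq_len(n - 1L)) {
    j <- i + 1L
    while (j <= n && o_contig[j] == o_contig[i] &&
           o_start[j] - o_end[i] < min_gap) {
      if (keep == "none") drop[ord[i]] <- TRUE
      drop[ord[j]] <- TRUE
      j <- j + 1L
    }
  }
  hits[!drop, , drop = FALSE]
}
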