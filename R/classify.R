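## Triple alignment and pair classification. A locus pair is aligned
## globally (A x B), the SINE consensus is aligned to the better-matching
## ungapped locus row and threaded through the pairwise columns, and the
## resulting three-row alignment is segmented at the consensus row's
## non-gap span into left flank / SINE / right flank. Segment statistics
## drive the plus-plus / plus-minus / minus-plus call.

.aln_chars <- function(aln) {
  list(p = strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]],
       s = strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]])
}

## Thread the consensus (aligned to the ungapped sequence `via`) through an
## A x B alignment given as two character vectors. cons_aln has pattern =
## consensus (global), subject = via (local). Returns a 3 x ncol character
## matrix; consensus insertions relative to `via` add columns gapped in the
## other two rows.
.thread_consensus <- function(row_a, row_b, cons_aln, via = c("A", "B")) {
  via <- match.arg(via)
  ca <- .aln_chars(cons_aln)
  s0 <- Biostrings::start(Biostrings::subject(cons_aln))  # 1-based on via
  ## per via-position consensus characters; insertions keyed by preceding
  ## via position (0 = before the aligned region's first base)
  cons_at <- list()
  ins_after <- list()
  p <- s0 - 1L
  for (i in seq_along(ca$s)) {
    if (ca$s[i] != "-") {
      p <- p + 1L
      cons_at[[as.character(p)]] <- ca$p[i]
    } else if (ca$p[i] != "-") {
      key <- as.character(p)
      ins_after[[key]] <- c(ins_after[[key]], ca$p[i])
    }
  }
  via_row <- if (via == "A") row_a else row_b
  out_a <- character(0); out_b <- character(0); out_c <- character(0)
  vp <- 0L
  emit_ins <- function(key) {
    ins <- ins_after[[key]]
    if (!is.null(ins)) {
      out_a <<- c(out_a, rep("-", length(ins)))
      out_b <<- c(out_b, rep("-", length(ins)))
      out_c <<- c(out_c, ins)
    }
  }
  emit_ins("0")
  for (i in seq_along(via_row)) {
    cc <- "-"
    if (via_row[i] != "-") {
      vp <- vp + 1L
      hit <- cons_at[[as.character(vp)]]
      if (!is.null(hit)) cc <- hit
    }
    out_a <- c(out_a, row_a[i])
    out_b <- c(out_b, row_b[i])
    out_c <- c(out_c, cc)
    if (via_row[i] != "-") emit_ins(as.character(vp))
  }
  rbind(A = out_a, B = out_b, cons = out_c)
}

#' Triple alignment of a locus pair and the SINE consensus
#'
#' The two locus sequences are aligned globally with affine gaps; the
#' consensus is then aligned -- global over the consensus, local over the
#' locus -- to whichever ungapped locus sequence it matches better, and
#' threaded through the pairwise columns (consensus insertions become
#' columns gapped in both locus rows). The locus-versus-locus step uses a
#' gap extension of 1 by default so that a true SINE-length indel is
#' bridged by one long gap rather than smeared across unrelated sequence.
#'
#' @param seq_a,seq_b locus sequences (SINE orientation).
#' @param consensus consensus object from [sine_consensus()].
#' @param locus_scoring scoring for the A x B global alignment.
#' @param cons_scoring scoring for consensus placement.
#' @return object of class `"so_triple"`: list with `rows` (3 x n character
#'   matrix: A, B, cons), `sine_start_col`, `sine_end_col` (half-open,
#'   0-based columns of the consensus span), `cons_via`, `cons_score`.
#' @export
align_triple <- function(seq_a, seq_b, consensus,
                         locus_scoring = align_scoring(gap_extend = 1),
                         cons_scoring = align_scoring()) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty locus sequence")
  if (is.null(consensus$sequence) || !nzchar(consensus$sequence))
    stop("empty consensus")
  ab <- .pairwise(seq_a, seq_b, "global", locus_scoring)
  abc <- .aln_chars(ab)
  cons <- Biostrings::DNAString(consensus$sequence)
  aln_a <- .pairwise(cons, seq_a, "global-local", cons_scoring)
  aln_b <- .pairwise(cons, seq_b, "global-local", cons_scoring)
  if (BiocGenerics::score(aln_a) >= BiocGenerics::score(aln_b)) {
    rows <- .thread_consensus(abc$p, abc$s, aln_a, "A")
    via <- "A"; cs <- BiocGenerics::score(aln_a)
  } else {
    rows <- .thread_consensus(abc$p, abc$s, aln_b, "B")
    via <- "B"; cs <- BiocGenerics::score(aln_b)
  }
  non_gap <- which(rows["cons", ] != "-")
  structure(list(rows = rows,
                 sine_start_col = min(non_gap) - 1L,
                 sine_end_col = max(non_gap),
                 cons_via = via, cons_score = cs),
            class = "so_triple")
}

#' @export
print.so_triple <- function(x, ...) {
  cat(sprintf("<triple alignment> %d columns, SINE span [%d,%d) via %s\n",
              ncol(x$rows), x$sine_start_col, x$sine_end_col, x$cons_via))
  invisible(x)
}

.region_stats <- function(rows, cols, region) {
  a <- rows["A", cols]; b <- rows["B", cols]; cn <- rows["cons", cols]
  len_a <- sum(a != "-"); len_b <- sum(b != "-"); len_c <- sum(cn != "-")
  id_ab <- sum(a == b & a != "-")
  id_ac <- sum(a == cn & a != "-")
  id_bc <- sum(b == cn & b != "-")
  pct <- function(id, l1, l2) if (min(l1, l2) == 0L) 0 else
    100 * id / min(l1, l2)
  data.frame(
    region = region, len_A = len_a, len_B = len_b,
    identical_AB = id_ab, pct_AB = pct(id_ab, len_a, len_b),
    identical_Acons = id_ac, pct_Acons = pct(id_ac, len_a, len_c),
    identical_Bcons = id_bc, pct_Bcons = pct(id_bc, len_b, len_c),
    stringsAsFactors = FALSE)
}

#' Per-region statistics of a triple alignment
#'
#' The alignment is cut at the consensus row's non-gap span into left flank
#' (LF), SINE and right flank (RF). Per region: ungapped lengths of the two
#' locus rows, count of identical aligned positions, and percent identities
#' with the identical count divided by the smaller ungapped length (the
#' pairwise-identity convention of alignment-statistics tools; an
#' aligned-columns denominator is available via `denominator`).
#'
#' @param aln an `"so_triple"` from [align_triple()].
#' @param denominator `"min_ungapped"` (default) or `"aligned_columns"`.
#' @return list: `regions` (data frame LF/SINE/RF with `len_A`, `len_B`,
#'   `identical_AB`, `pct_AB`, `identical_Acons`, `pct_Acons`,
#'   `identical_Bcons`, `pct_Bcons`), `sine_at_left`, `sine_at_right`.
#' @export
segment_stats <- function(aln, denominator = c("min_ungapped",
                                               "aligned_columns")) {
  denominator <- match.arg(denominator)
  n <- ncol(aln$rows)
  lf <- seq_len(aln$sine_start_col)
  si <- seq(aln$sine_start_col + 1L, aln$sine_end_col)
  rf <- if (aln$sine_end_col < n) seq(aln$sine_end_col + 1L, n) else
    integer(0)
  regions <- rbind(.region_stats(aln$rows, lf, "LF"),
                   .region_stats(aln$rows, si, "SINE"),
                   .region_stats(aln$rows, rf, "RF"))
  if (denominator == "aligned_columns") {
    nc <- c(length(lf), length(si), length(rf))
    for (cl in c("pct_AB", "pct_Acons", "pct_Bcons"))
      regions[[cl]] <- ifelse(nc == 0, 0,
                              100 * regions[[sub("pct", "identical", cl)]] / nc)
  }
  list(regions = regions,
       sine_at_left = aln$sine_start_col == 0L,
       sine_at_right = aln$sine_end_col == n)
}

#' Classify a locus pair from its segment statistics
#'
#' Discard rules, in order: the SINE span touching the first or last
#' alignment column (`leftSINE` / `rightSINE`: a flank is absent); a flank
#' shorter than `flank_min_len` in either locus (`shortLF` / `shortRF`);
#' flank identity between the loci below `flank_min_ident`
#' (`low_flank_identity`). Surviving pairs get a per-genome presence call
#' in the SINE region -- plus iff that locus row has at least
#' `sine_min_len` ungapped nt there and at least `sine_min_ident` percent
#' identity to the consensus -- giving PP, PM (A plus, B minus), MP, or a
#' `minus_minus` discard. All threshold comparisons are inclusive.
#'
#' @param stats output of [segment_stats()] (or an `"so_triple"`, which is
#'   segmented first).
#' @param flank_min_len minimum flank length in nt (default 150).
#' @param flank_min_ident minimum flank percent identity (default 65).
#' @param sine_min_len minimum SINE-region length for a plus call
#'   (default 100).
#' @param sine_min_ident minimum identity to the consensus for a plus call
#'   (default 65).
#' @return list of class `"so_verdict"`: `status` (`"PP"`, `"PM"`, `"MP"`
#'   or `"discarded"`), `discard_reason` (`"none"`, `"shortLF"`,
#'   `"shortRF"`, `"leftSINE"`, `"rightSINE"`, `"low_flank_identity"`,
#'   `"minus_minus"`), `plus_A`, `plus_B`, `stats`.
#' @export
classify_pair <- function(stats, flank_min_len = 150, flank_min_ident = 65,
                          sine_min_len = 100, sine_min_ident = 65) {
  if (inherits(stats, "so_triple")) stats <- segment_stats(stats)
  r <- stats$regions
  lf <- r[r$region == "LF", ]; si <- r[r$region == "SINE", ]
  rf <- r[r$region == "RF", ]
  verdict <- function(status, reason, plus_a = NA, plus_b = NA)
    structure(list(status = status, discard_reason = reason,
                   plus_A = plus_a, plus_B = plus_b, stats = stats),
              class = "so_verdict")
  if (stats$sine_at_left) return(verdict("discarded", "leftSINE"))
  if (stats$sine_at_right) return(verdict("discarded", "rightSINE"))
  if (min(lf$len_A, lf$len_B) < flank_min_len)
    return(verdict("discarded", "shortLF"))
  if (min(rf$len_A, rf$len_B) < flank_min_len)
    return(verdict("discarded", "shortRF"))
  if (lf$pct_AB < flank_min_ident || rf$pct_AB < flank_min_ident)
    return(verdict("discarded", "low_flank_identity"))
  plus_a <- si$len_A >= sine_min_len && si$pct_Acons >= sine_min_ident
  plus_b <- si$len_B >= sine_min_len && si$pct_Bcons >= sine_min_ident
  if (plus_a && plus_b) verdict("PP", "none", TRUE, TRUE)
  else if (plus_a) verdict("PM", "none", TRUE, FALSE)
  else if (plus_b) verdict("MP", "none", FALSE, TRUE)
  else verdict("discarded", "minus_minus", FALSE, FALSE)
}

#' @export
print.so_verdict <- function(x, ...) {
  cat(sprintf("<verdict> %s%s\n", x$status,
              if (x$discard_reason != "none")
                paste0(" (", x$discard_reason, ")") else ""))
  invisible(x)
}

## flatten a verdict + locus pair into one report row
.verdict_row <- function(verdict, locus_a, locus_b, group_id, category) {
  r <- verdict$stats$regions
  row <- data.frame(
    group_id = group_id, category = category,
    locus_id_A = locus_a$locus_id, genome_A = locus_a$genome_id,
    contig_A = locus_a$contig, start_A = locus_a$start, end_A = locus_a$end,
    locus_id_B = locus_b$locus_id, genome_B = locus_b$genome_id,
    contig_B = locus_b$contig, start_B = locus_b$start, end_B = locus_b$end,
    status = verdict$status, discard_reason = verdict$discard_reason,
    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(r))) {
    pre <- r$region[i]
    row[[paste0(pre, "_len_A")]] <- r$len_A[i]
    row[[paste0(pre, "_len_B")]] <- r$len_B[i]
    row[[paste0(pre, "_identical_AB")]] <- r$identical_AB[i]
    row[[paste0(pre, "_pct_AB")]] <- round(r$pct_AB[i], 2)
  }
  si <- r[r$region == "SINE", ]
  row$SINE_identical_Acons <- si$identical_Acons
  row$SINE_pct_Acons <- round(si$pct_Acons, 2)
  row$SINE_identical_Bcons <- si$identical_Bcons
  row$SINE_pct_Bcons <- round(si$pct_Bcons, 2)
  row
}

#' Classify a set of locus pairs into the final report table
#'
#' Runs [align_triple()], [segment_stats()] and [classify_pair()] for each
#' (A locus, B locus) pair and flattens the verdicts into the report table
#' written by [write_report()].
#'
#' @param pairs data frame with columns `group_id`, `category`,
#'   `locus_id_A`, `locus_id_B`.
#' @param loci merged-locus table covering all ids in `pairs`.
#' @param genomes named list of genomes keyed by genome id.
#' @param consensus consensus object.
#' @param ... thresholds passed to [classify_pair()].
#' @return report data frame, one row per pair.
#' @export
classify_pairs <- function(pairs, loci, genomes, consensus, ...) {
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    la <- loci[loci$locus_id == pairs$locus_id_A[i], ]
    lb <- loci[loci$locus_id == pairs$locus_id_B[i], ]
    seq_a <- fetch_sequence(la, genomes[[la$genome_id]])
    seq_b <- fetch_sequence(lb, genomes[[lb$genome_id]])
    v <- classify_pair(align_triple(seq_a, seq_b, consensus), ...)
    rows[[i]] <- .verdict_row(v, la, lb, pairs$group_id[i],
                              pairs$category[i])
  }
  if (length(rows) == 0L) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
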