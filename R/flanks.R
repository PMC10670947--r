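## Flank extraction and interval extension. The orthology anchor of a SINE
## copy is its "left" flank in the element's own orientation: genomic left
## of a plus-strand copy, genomic right (reverse-complemented) of a
## minus-strand copy. Flank sequences are stored 5'->3' in SINE orientation.

#' Extract the left (SINE-orientation) flank of each copy
#'
#' For a plus-strand copy the flank is the `flank_len` bases immediately
#' upstream on the forward strand; for a minus-strand copy it is the
#' `flank_len` bases immediately downstream, reverse-complemented. Flanks
#' clipped by a contig edge are emitted at reduced length with
#' `truncated = TRUE`; zero-length flanks are dropped with a warning.
#'
#' @param copies hit table from [scan_genome()].
#' @param genome the genome the copies were found in.
#' @param flank_len flank length in nt (default 300).
#' @return data frame: `copy_id`, `genome_id`, `contig`, `start`, `end`
#'   (forward-strand, 0-based half-open), `strand`, `truncated`,
#'   `sequence` (SINE-orientation).
#' @export
extract_left_flanks <- function(copies, genome, flank_len = 300) {
  genome <- .as_dnastringset(genome)
  clens <- .contig_lengths(genome)
  n <- nrow(copies)
  out <- vector("list", n)
  dropped <- 0L
  for (i in seq_len(n)) {
    co <- copies[i, ]
    clen <- clens[[co$contig]]
    if (co$start < 0 || co$end > clen)
      stop("copy ", co$copy_id, " outside contig bounds")
    if (co$strand == "+") {
      s <- max(0L, co$start - flank_len); e <- co$start
    } else {
      s <- co$end; e <- min(clen, co$end + flank_len)
    }
    if (e - s == 0L) { dropped <- dropped + 1L; next }
    seq <- .slice(genome, co$contig, s, e)
    if (co$strand == "-") seq <- .revcomp(seq)
    out[[i]] <- data.frame(
      copy_id = co$copy_id, genome_id = co$genome_id, contig = co$contig,
      start = s, end = e, strand = co$strand,
      truncated = (e - s) < flank_len, sequence = seq,
      stringsAsFactors = FALSE)
  }
  if (dropped > 0L)
    warning(dropped, " cop", if (dropped == 1L) "y" else "ies",
            " at a contig edge yielded zero-length flanks and were dropped")
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L)
    return(.empty_df(c(copy_id = "chr", genome_id = "chr", contig = "chr",
                       start = "int", end = "int", strand = "chr",
                       truncated = "lgl", sequence = "chr")))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extend intervals rightward over the putative SINE and right flank
#'
#' Each flank (or mapped-flank) interval is grown by `sine_len + pad`
#' downstream in the flank's orientation -- genomic right for strand "+",
#' genomic left for strand "-" -- so the resulting locus spans the possible
#' insertion plus its right flank. Clamped to contig bounds. With
#' `strand_aware = FALSE` the extension is always genomic-right
#' (compatibility with strand-naive coordinate-file tools).
#'
#' @param intervals data frame with `contig`, `start`, `end`, `strand` and
#'   an id column (`copy_id` or `mapping_id`).
#' @param sine_len length of the SINE consensus in nt.
#' @param pad right-flank allowance in nt (default 300).
#' @param genome genome (for contig lengths), or a named integer vector of
#'   contig lengths.
#' @param genome_id genome label for the resulting loci; defaults to the
#'   intervals' `genome_id`/`target_genome_id` column.
#' @param origin `"query_copy"` or `"mapped_flank"`.
#' @param strand_aware extend downstream in flank orientation (default) or
#'   always genomic-right.
#' @param id_prefix prefix for generated locus ids (default: the genome
#'   id); give distinct prefixes when combining several coordinate sets of
#'   one genome.
#' @return data frame of candidate loci: `locus_id`, `genome_id`, `contig`,
#'   `start`, `end`, `strand`, `origin`, `source_id`.
#' @export
extend_right <- function(intervals, sine_len, pad = 300, genome,
                         genome_id = NULL, origin = "query_copy",
                         strand_aware = TRUE, id_prefix = NULL) {
  clens <- if (is.numeric(genome)) genome
           else .contig_lengths(.as_dnastringset(genome))
  n <- nrow(intervals)
  if (is.null(genome_id)) {
    genome_id <- if ("target_genome_id" %in% names(intervals) &&
                     origin == "mapped_flank")
      intervals$target_genome_id else intervals$genome_id
  } else genome_id <- rep_len(genome_id, n)
  src <- if ("mapping_id" %in% names(intervals) && origin == "mapped_flank")
    intervals$mapping_id else intervals$copy_id
  if (n == 0L)
    return(.empty_df(c(locus_id = "chr", genome_id = "chr", contig = "chr",
                       start = "int", end = "int", strand = "chr",
                       origin = "chr", source_id = "chr")))
  ext <- sine_len + pad
  start <- intervals$start
  end <- intervals$end
  right <- strand_aware & intervals$strand == "-"
  start[right] <- start[right] - ext
  end[!right] <- end[!right] + ext
  start <- pmax(0L, as.integer(start))
  end <- pmin(as.integer(unname(clens[intervals$contig])), as.integer(end))
  if (is.null(id_prefix)) id_prefix <- genome_id
  data.frame(
    locus_id = sprintf("%s_locus%05d", id_prefix, seq_len(n)),
    genome_id = genome_id, contig = intervals$contig,
    start = start, end = end, strand = intervals$strand,
    origin = origin, source_id = src, stringsAsFactors = FALSE)
}

#' Fetch the sequence of a candidate locus
#'
#' Slices `[start, end)` from the locus contig; minus-orientation loci are
#' reverse-complemented so all locus sequences read 5'->3' in SINE
#' orientation. A zero-width locus is an error.
#'
#' @param locus one-row data frame (or list) with `contig`, `start`, `end`,
#'   `strand`.
#' @param genome the genome to slice from.
#' @return character DNA string.
#' @export
fetch_sequence <- function(locus, genome) {
  genome <- .as_dnastringset(genome)
  if (locus$end <= locus$start)
    stop("zero-width locus [", locus$start, ",", locus$end, ")")
  seq <- .slice(genome, locus$contig, locus$start, locus$end)
  if (!is.null(locus$strand) && locus$strand == "-") seq <- .revcomp(seq)
  seq
}
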