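## Internal helpers: sequence handling, coordinate conversion, validation.
## Coordinates are 0-based half-open throughout; Biostrings is 1-based
## closed, so conversion happens only at subseq()/IRanges boundaries.

IUPAC_LETTERS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                   "B", "D", "H", "V", "N", "-")

#' Alignment scoring parameters
#'
#' Bundles match/mismatch scores and affine gap penalties for the package's
#' local and global alignments. The discovery search and flank mapper use
#' the defaults (+5/-4, gap open 12, extend 4, as positive costs). Locus
#' versus locus alignments, which must bridge true indels of SINE length,
#' use a cheaper gap extension (see [align_triple()]).
#'
#' @param match match score (positive).
#' @param mismatch mismatch score (negative).
#' @param gap_open gap opening cost (positive).
#' @param gap_extend gap extension cost (positive).
#' @return a list of class `"so_scoring"`.
#' @export
align_scoring <- function(match = 5, mismatch = -4, gap_open = 12,
                          gap_extend = 4) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend >= 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "so_scoring")
}

.substitution_matrix <- function(scoring) {
  Biostrings::nucleotideSubstitutionMatrix(match = scoring$match,
                                           mismatch = scoring$mismatch,
                                           baseOnly = FALSE)
}

.pairwise <- function(pattern, subject, type, scoring) {
  Biostrings::pairwiseAlignment(
    pattern = pattern, subject = subject, type = type,
    substitutionMatrix = .substitution_matrix(scoring),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
}

.as_dnastringset <- function(x, what = "genome") {
  if (is(x, "DNAStringSet")) return(x)
  if (is(x, "DNAString")) {
    out <- Biostrings::DNAStringSet(x)
    names(out) <- "seq1"
    return(out)
  }
  if (is.character(x) && length(x) == 1L && file.exists(x))
    return(read_genome(x))
  if (is.character(x)) {
    out <- Biostrings::DNAStringSet(toupper(x))
    if (is.null(names(x))) names(out) <- paste0("seq", seq_along(out))
    else names(out) <- names(x)
    return(out)
  }
  stop("cannot interpret ", what, " input of class ", class(x)[1])
}

.check_iupac <- function(genome) {
  for (i in seq_along(genome)) {
    freq <- Biostrings::alphabetFrequency(genome[[i]])
    bad <- freq[setdiff(names(freq), c(IUPAC_LETTERS, "+", "."))]
    if (any(bad > 0))
      stop("contig '", names(genome)[i],
           "' contains non-IUPAC characters: ",
           paste(names(bad)[bad > 0], collapse = ", "))
  }
  invisible(TRUE)
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## 0-based half-open slice of a contig, returned as character
.slice <- function(genome, contig, start, end) {
  if (!contig %in% names(genome))
    stop("contig '", contig, "' not found in genome")
  len <- Biostrings::width(genome[contig])
  if (start < 0 || end > len || start > end)
    stop("slice [", start, ",", end, ") out of bounds for contig '",
         contig, "' (length ", len, ")")
  if (start == end) return("")
  as.character(Biostrings::subseq(genome[[contig]], start + 1L, end))
}

.contig_lengths <- function(genome) {
  setNames(Biostrings::width(genome), names(genome))
}

## identity of two equal-role sequences from a global alignment:
## identical positions / min(ungapped lengths) * 100
.global_identity <- function(seq_a, seq_b, scoring = align_scoring(gap_extend = 1)) {
  if (nchar(seq_a) == 0L || nchar(seq_b) == 0L)
    return(list(identity = 0, identical = 0L, score = -Inf))
  aln <- .pairwise(seq_a, seq_b, "global", scoring)
  ident <- Biostrings::nmatch(aln)
  list(identity = 100 * ident / min(nchar(seq_a), nchar(seq_b)),
       identical = ident, score = BiocGenerics::score(aln))
}

.empty_df <- function(cols) {
  as.data.frame(setNames(lapply(cols, function(cl) {
    switch(cl, chr = character(0), int = integer(0), num = numeric(0),
           lgl = logical(0))
  }), names(cols)), stringsAsFactors = FALSE)
}

.rows <- function(df) if (is.null(df)) 0L else nrow(df)
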