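## Readers and writers for the formats the pipeline exchanges:
## FASTA (via Biostrings, gzip transparent), BED6(+), and the TSV report.

#' Read a genome or consensus FASTA file
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()]. `read_genome()`
#' returns the full record set with names truncated at the first
#' whitespace; `read_consensus()` expects a single record and returns the
#' consensus object used by [scan_genome()] and [align_triple()].
#'
#' @param path FASTA file, optionally gzip-compressed.
#' @return `read_genome()`: a [Biostrings::DNAStringSet];
#'   `read_consensus()`: a list with elements `name`, `sequence`, `length`.
#' @export
read_genome <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' @rdname read_genome
#' @export
read_consensus <- function(path) {
  x <- read_genome(path)
  if (length(x) != 1L)
    stop("consensus FASTA must contain exactly one record, found ",
         length(x))
  sine_consensus(names(x), as.character(x[[1]]))
}

#' Construct a SINE consensus object
#'
#' @param name identifier of the SINE family.
#' @param sequence consensus DNA (IUPAC letters allowed).
#' @return list with `name`, `sequence` (uppercase), `length`.
#' @export
sine_consensus <- function(name, sequence) {
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) < 1L) stop("consensus sequence is empty")
  letters_used <- unique(strsplit(sequence, "")[[1]])
  if (!all(letters_used %in% IUPAC_LETTERS))
    stop("consensus contains non-IUPAC characters: ",
         paste(setdiff(letters_used, IUPAC_LETTERS), collapse = ", "))
  list(name = name, sequence = sequence, length = nchar(sequence))
}

#' The bundled synthetic SINE consensus
#'
#' A fixed 360-nt synthetic consensus shipped with the package for examples,
#' tests and simulations. It is a stand-in sequence, not a biological
#' consensus: the pipeline treats the consensus as an opaque query, so any
#' fixed sequence of realistic length exercises the method identically.
#'
#' @return a consensus object as from [sine_consensus()].
#' @export
default_consensus <- function() {
  read_consensus(system.file("extdata", "sine_consensus_synthetic.fa",
                             package = "sineortho", mustWork = TRUE))
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector or DNAStringSet.
#' @param path output file.
#' @param width line wrap (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  x <- .as_dnastringset(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

BED6_COLS <- c("contig", "start", "end", "name", "score", "strand")

#' Read and write BED6(+) interval files
#'
#' BED intervals are 0-based, half-open. `write_bed()` accepts any data
#' frame with `contig`, `start`, `end` columns; `name`, `score` and
#' `strand` are filled with BED placeholders when absent, and any extra
#' columns named in `extra` are appended after the six standard ones.
#'
#' @param df data frame of intervals.
#' @param path file path.
#' @param extra character vector of additional column names to append.
#' @return `read_bed()`: a data frame with BED6 columns (plus any extras);
#'   `write_bed()`: `path`, invisibly.
#' @export
write_bed <- function(df, path, extra = character(0)) {
  out <- data.frame(
    contig = df$contig,
    start = as.integer(df$start),
    end = as.integer(df$end),
    name = if ("name" %in% names(df)) df$name else ".",
    score = if ("score" %in% names(df)) df$score else 0L,
    strand = if ("strand" %in% names(df)) df$strand else ".",
    stringsAsFactors = FALSE)
  for (cl in extra) out[[cl]] <- df[[cl]]
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed
#' @export
read_bed <- function(path, extra = character(0)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(.empty_df(c(contig = "chr", start = "int", end = "int",
                       name = "chr", score = "num", strand = "chr")))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  need <- 6L + length(extra)
  bad <- which(nf < need)
  if (length(bad) > 0L)
    stop("malformed BED line ", bad[1], ": expected >= ", need,
         " fields, found ", nf[bad[1]])
  df <- data.frame(
    contig = vapply(parts, `[`, "", 1L),
    start = suppressWarnings(as.integer(vapply(parts, `[`, "", 2L))),
    end = suppressWarnings(as.integer(vapply(parts, `[`, "", 3L))),
    name = vapply(parts, `[`, "", 4L),
    score = as.numeric(vapply(parts, `[`, "", 5L)),
    strand = vapply(parts, `[`, "", 6L),
    stringsAsFactors = FALSE)
  if (any(is.na(df$start)) || any(is.na(df$end)))
    stop("malformed BED line ",
         which(is.na(df$start) | is.na(df$end))[1],
         ": non-integer coordinates")
  for (i in seq_along(extra)) df[[extra[i]]] <- vapply(parts, `[`, "", 6L + i)
  df
}

#' Write SINE copies as BED6
#'
#' One line per accepted copy: name = copy id, score = `pct_identity * 10`
#' rounded to integer, strand column used.
#'
#' @param hits hit table from [scan_genome()].
#' @param path output BED file.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  df <- hits
  df$name <- hits$copy_id
  df$score <- as.integer(round(hits$pct_identity * 10))
  write_bed(df, path)
}

#' Read and write the final pairwise report
#'
#' Tab-separated, with a header; columns are documented in
#' [classify_pair()]. `report_version` is written as a `#` comment line.
#'
#' @param report verdict data frame.
#' @param path file path.
#' @return `read_report()`: the data frame; `write_report()`: `path`.
#' @export
write_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#sineortho_report_v1", con)
  write.table(report, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  read.table(path, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE)
}
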