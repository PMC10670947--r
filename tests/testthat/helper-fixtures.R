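## Shared fixtures and independent brute-force oracles. Oracles use only
## base R (plus direct Biostrings calls for alignment scores) and never
## share code paths with the package internals they check.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

revcomp_chr <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

## substitute exactly the given 1-based positions with a different base
mutate_positions <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (i in positions)
    ch[i] <- setdiff(c("A", "C", "G", "T"), ch[i])[1]
  paste(ch, collapse = "")
}

## substitute a fraction of sites, evenly spread (deterministic)
mutate_evenly <- function(seq, n_mut) {
  n <- nchar(seq)
  ## never mutate the two end bases so local alignment keeps full span
  pos <- unique(round(seq(2, n - 1, length.out = n_mut)))
  stopifnot(length(pos) == n_mut)
  mutate_positions(seq, pos)
}

## substitute each site independently with probability rate
mutate_rate <- function(seq, rate) {
  n <- nchar(seq)
  pos <- which(runif(n) < rate)
  if (length(pos) == 0) return(seq)
  mutate_positions(seq, pos)
}

test_consensus <- function() default_consensus()

## genome string with given sequences planted at given 0-based offsets
## over a random background
plant <- function(background, inserts, offsets) {
  stopifnot(length(inserts) == length(offsets))
  out <- background
  for (i in seq_along(inserts))
    substr(out, offsets[i] + 1, offsets[i] + nchar(inserts[i])) <-
      inserts[i]
  out
}

## ---- oracles ----

## all-pairs proximity filter: copy i is removed iff some other copy on the
## same contig lies closer than min_gap (end-to-start distance; overlap
## counts as closer than any positive gap)
bf_filter_proximal <- function(hits, min_gap) {
  n <- nrow(hits)
  if (n == 0) return(hits)
  drop <- logical(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j || hits$contig[i] != hits$contig[j]) next
    d <- max(hits$start[j] - hits$end[i], hits$start[i] - hits$end[j])
    if (d < min_gap) drop[i] <- TRUE
  }
  hits[!drop, , drop = FALSE]
}

## transitive-overlap partition of intervals (>= 1 bp, half-open): returns
## a list of sorted member index vectors
bf_merge_members <- function(df) {
  n <- nrow(df)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j || df$contig[i] != df$contig[j]) next
    if (df$start[i] < df$end[j] && df$start[j] < df$end[i]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  unname(lapply(split(seq_len(n), roots), sort))
}

## connected components of an undirected edge list over string node ids
bf_components <- function(edges) {
  nodes <- sort(unique(c(edges$a, edges$b)))
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
  for (k in seq_len(nrow(edges))) {
    ra <- find(edges$a[k]); rb <- find(edges$b[k])
    if (ra != rb) parent[[rb]] <- ra
  }
  comp <- split(nodes, vapply(nodes, find, ""))
  unname(lapply(comp, sort))
}

## exhaustive local-alignment hit set of one query (both orientations)
## against one target: repeated full Smith-Waterman with N-masking, no
## seeding. Returns data.frame(start, end, strand, score).
bf_map_oracle <- function(query, target, min_score,
                          match = 5, mismatch = -4,
                          gap_open = 12, gap_extend = 4) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match, mismatch,
                                                  baseOnly = FALSE)
  one <- function(q, strand) {
    subj <- target
    out <- NULL
    repeat {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(q), Biostrings::DNAString(subj),
        type = "local", substitutionMatrix = mat,
        gapOpening = gap_open, gapExtension = gap_extend)
      if (BiocGenerics::score(aln) < min_score) break
      s0 <- Biostrings::start(Biostrings::subject(aln)) - 1L
      s1 <- Biostrings::end(Biostrings::subject(aln))
      out <- rbind(out, data.frame(start = s0, end = s1, strand = strand,
                                   score = BiocGenerics::score(aln)))
      substr(subj, s0 + 1, s1) <- strrep("N", s1 - s0)
    }
    out
  }
  res <- rbind(one(query, "+"), one(revcomp_chr(query), "-"))
  if (is.null(res)) data.frame(start = integer(0), end = integer(0),
                               strand = character(0), score = numeric(0))
  else res[order(res$start, res$strand), , drop = FALSE]
}

## clade tip sets of a newick string, via a hand-rolled recursive parser
## (independent of ape)
bf_clades <- function(newick) {
  s <- gsub(";$", "", gsub("\\s", "", newick))
  pos <- 1
  clades <- list()
  parse_node <- function() {
    if (substr(s, pos, pos) == "(") {
      pos <<- pos + 1
      tips <- character(0)
      repeat {
        tips <- c(tips, parse_node())
        ch <- substr(s, pos, pos)
        if (ch == ",") { pos <<- pos + 1 } else if (ch == ")") {
          pos <<- pos + 1; break
        } else stop("bad newick near ", pos)
      }
      clades[[length(clades) + 1]] <<- sort(tips)
      tips
    } else {
      start <- pos
      while (pos <= nchar(s) && !substr(s, pos, pos) %in% c(",", ")", "("))
        pos <<- pos + 1
      substr(s, start, pos - 1)
    }
  }
  parse_node()
  clades
}

## expected pattern category from first principles
bf_pattern_category <- function(status, newick) {
  plus <- sort(names(status)[status == "plus"])
  if (length(plus) == 0) return("no_insertion")
  if (length(plus) == length(status)) return("shared_all")
  if (length(plus) == 1) return("unique")
  if (any(vapply(bf_clades(newick), identical, TRUE, y = plus)))
    "informative" else "contradicting"
}

## construct an "so_triple" directly from three equal-length strings
## (characters incl. "-"); sine span derived from the consensus row
make_triple <- function(row_a, row_b, row_cons) {
  rows <- rbind(A = strsplit(row_a, "")[[1]],
                B = strsplit(row_b, "")[[1]],
                cons = strsplit(row_cons, "")[[1]])
  ng <- which(rows["cons", ] != "-")
  structure(list(rows = rows, sine_start_col = min(ng) - 1L,
                 sine_end_col = max(ng), cons_via = "A", cons_score = NA),
            class = "so_triple")
}

## random locus cassette pieces for classification tests
make_cassette <- function(lf, sine, rf) paste0(lf, sine, rf)
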