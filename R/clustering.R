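## Per-genome interval merging and cross-genome linking. Candidate loci
## that overlap within a genome are merged (transitively, >= 1 bp by
## default); merged loci are linked through the flank mappings that
## produced them, and connected components of the link graph form groups
## categorized by size: double (2), multiple (3-10), poly (> 10).

#' Merge overlapping candidate loci within one genome
#'
#' Loci on the same contig of the same genome whose intervals overlap by at
#' least `min_overlap` bp are merged into one locus spanning their union;
#' merging is transitive. Member source ids are concatenated. Coordinates
#' are half-open, so book-ended intervals (`end == start`) do not merge
#' under the default `min_overlap = 1`.
#'
#' @param loci candidate loci from [extend_right()] (single genome or
#'   mixed; merging is per genome).
#' @param min_overlap minimum overlap in bp to merge (default 1).
#' @return data frame of merged loci: `locus_id`, `genome_id`, `contig`,
#'   `start`, `end`, `strand` (of the first member, by coordinate),
#'   `n_members`, `member_ids` and `member_sources` (comma-joined).
#' @export
cluster_overlaps <- function(loci, min_overlap = 1) {
  empty <- .empty_df(c(locus_id = "chr", genome_id = "chr", contig = "chr",
                       start = "int", end = "int", strand = "chr",
                       n_members = "int", member_ids = "chr",
                       member_sources = "chr"))
  if (nrow(loci) == 0L) return(empty)
  if (min_overlap < 1) stop("min_overlap must be >= 1")
  out <- list()
  for (gid in unique(loci$genome_id)) {
    sub <- loci[loci$genome_id == gid, , drop = FALSE]
    ## requiring overlap >= k on the originals is overlap >= 1 on intervals
    ## with ends pulled in by k - 1 (floored at width 1)
    gr <- GenomicRanges::GRanges(
      sub$contig,
      IRanges::IRanges(sub$start + 1L,
                       pmax(sub$start + 1L, sub$end - (min_overlap - 1L))))
    red <- GenomicRanges::reduce(gr, min.gapwidth = 0L, with.revmap = TRUE)
    revmap <- S4Vectors::mcols(red)$revmap
    for (i in seq_along(red)) {
      members <- sub[revmap[[i]], , drop = FALSE]
      members <- members[order(members$start, members$end), , drop = FALSE]
      out[[length(out) + 1L]] <- data.frame(
        genome_id = gid,
        contig = members$contig[1],
        start = min(members$start),
        end = max(members$end),
        strand = members$strand[1],
        n_members = nrow(members),
        member_ids = paste(members$locus_id, collapse = ","),
        member_sources = paste(members$source_id, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$genome_id, res$contig, res$start, res$end), ,
             drop = FALSE]
  rownames(res) <- NULL
  res$locus_id <- sprintf("%s_m%05d", res$genome_id, seq_len(nrow(res)))
  res[, c("locus_id", "genome_id", "contig", "start", "end", "strand",
          "n_members", "member_ids", "member_sources")]
}

## map each original candidate-locus id to its merged locus id
.member_lookup <- function(merged) {
  ids <- strsplit(merged$member_ids, ",", fixed = TRUE)
  setNames(rep(merged$locus_id, lengths(ids)), unlist(ids))
}

#' Link merged loci across genomes into connected groups
#'
#' Every mapping contributes one edge between the merged locus containing
#' its query-side candidate locus and the merged locus containing its
#' target-side candidate locus (loci merged within a genome are already one
#' node, which links clusters through shared loci). Groups are the
#' connected components of this graph; isolated loci (no surviving edge)
#' are not grouped.
#'
#' @param merged_a,merged_b merged loci of the two genomes from
#'   [cluster_overlaps()].
#' @param links data frame with columns `locus_a`, `locus_b`: candidate
#'   locus ids joined by a mapping (query-side, target-side).
#' @return list of `ClusterGroup`s, each a list with `group_id`, `loci`
#'   (data frame of member merged loci), `links` (edge data frame on merged
#'   locus ids) and `category` (`"double"`, `"multiple"` or `"poly"`).
#' @export
link_groups <- function(merged_a, merged_b, links) {
  all_merged <- rbind(merged_a, merged_b)
  lookup <- .member_lookup(all_merged)
  if (nrow(links) == 0L) return(list())
  ea <- lookup[links$locus_a]
  eb <- lookup[links$locus_b]
  if (any(is.na(ea)) || any(is.na(eb))) {
    bad <- c(links$locus_a[is.na(ea)], links$locus_b[is.na(eb)])
    stop("mapping endpoint(s) not contained in any merged locus: ",
         paste(unique(bad), collapse = ", "))
  }
  edges <- unique(data.frame(a = pmin(ea, eb), b = pmax(ea, eb),
                             stringsAsFactors = FALSE))
  edges <- edges[edges$a != edges$b, , drop = FALSE]
  if (nrow(edges) == 0L) return(list())
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  comp <- igraph::components(g)
  member_of <- split(names(comp$membership), comp$membership)
  member_of <- member_of[order(vapply(member_of, min, ""))]
  groups <- vector("list", length(member_of))
  for (i in seq_along(member_of)) {
    ids <- sort(member_of[[i]])
    loci <- all_merged[match(ids, all_merged$locus_id), , drop = FALSE]
    rownames(loci) <- NULL
    grp_links <- edges[edges$a %in% ids & edges$b %in% ids, , drop = FALSE]
    rownames(grp_links) <- NULL
    groups[[i]] <- structure(list(
      group_id = sprintf("group%05d", i),
      loci = loci, links = grp_links,
      category = categorize(nrow(loci))), class = "so_group")
  }
  groups
}

#' Categorize a linked group by size
#'
#' Two loci form a double; 3-10 a multiple; more than 10 a poly-matching
#' group.
#'
#' @param group a group from [link_groups()], or the number of member loci.
#' @return `"double"`, `"multiple"` or `"poly"`.
#' @export
categorize <- function(group) {
  n <- if (is.numeric(group)) group else nrow(group$loci)
  if (n < 2L) stop("a group has at least 2 loci, got ", n)
  if (n == 2L) "double" else if (n <= 10L) "multiple" else "poly"
}

#' @export
print.so_group <- function(x, ...) {
  cat(sprintf("<%s> %s, %d loci (%s)\n", x$group_id, x$category,
              nrow(x$loci),
              paste(table(x$loci$genome_id), names(table(x$loci$genome_id)),
                    collapse = " + ")))
  invisible(x)
}

#' Export linked groups as a table
#'
#' One row per member locus: `group_id`, `category`, `genome_id`, `contig`,
#' `start`, `end`, `locus_id`.
#'
#' @param groups list from [link_groups()].
#' @return data frame.
#' @export
groups_table <- function(groups) {
  if (length(groups) == 0L)
    return(.empty_df(c(group_id = "chr", category = "chr",
                       genome_id = "chr", contig = "chr", start = "int",
                       end = "int", locus_id = "chr")))
  do.call(rbind, lapply(groups, function(g) data.frame(
    group_id = g$group_id, category = g$category,
    genome_id = g$loci$genome_id, contig = g$loci$contig,
    start = g$loci$start, end = g$loci$end, locus_id = g$loci$locus_id,
    stringsAsFactors = FALSE)))
}
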