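make_loci <- function(starts, ends, genome = "A", contig = "c1",
                      prefix = genome) {
  data.frame(locus_id = sprintf("%s_locus%05d", prefix, seq_along(starts)),
             genome_id = genome, contig = contig, start = starts,
             end = ends, strand = "+", origin = "query_copy",
             source_id = sprintf("%s_src%d", prefix, seq_along(starts)),
             stringsAsFactors = FALSE)
}

test_that("one base of overlap merges; book-ended intervals stay apart", {
  m <- cluster_overlaps(make_loci(c(100, 399), c(400, 700)))
  expect_equal(nrow(m), 1L)
  expect_equal(c(m$start, m$end), c(100, 700))
  expect_equal(m$n_members, 2L)
  m2 <- cluster_overlaps(make_loci(c(100, 400), c(400, 700)))
  expect_equal(nrow(m2), 2L)
})

test_that("merging is transitive and matches the brute-force partition", {
  set.seed(41)
  for (rep in 1:25) {
    n <- sample(c(10, 100), 1)
    starts <- sample.int(5000, n, TRUE)
    df <- make_loci(starts, starts + sample.int(300, n, TRUE),
                    contig = sample(c("c1", "c2"), n, TRUE))
    df$contig <- sample(c("c1", "c2"), n, TRUE)
    m <- cluster_overlaps(df)
    want <- bf_merge_members(df)
    got <- lapply(strsplit(m$member_ids, ","), function(ids)
      sort(match(ids, df$locus_id)))
    expect_setequal(lapply(got, paste, collapse = ","),
                    lapply(want, paste, collapse = ","))
    ## spans equal the member hulls
    for (i in seq_len(nrow(m))) {
      mem <- df[got[[i]], ]
      expect_equal(m$start[i], min(mem$start))
      expect_equal(m$end[i], max(mem$end))
    }
  }
})

test_that("a single cross-link forms one double group", {
  ma <- cluster_overlaps(make_loci(100, 700, "A"))
  mb <- cluster_overlaps(make_loci(200, 800, "B"))
  links <- data.frame(locus_a = "A_locus00001", locus_b = "B_locus00001")
  g <- link_groups(ma, mb, links)
  expect_length(g, 1L)
  expect_equal(g[[1]]$category, "double")
  expect_equal(nrow(g[[1]]$loci), 2L)
})

test_that("links sharing nodes connect into one group of four", {
  ma <- cluster_overlaps(make_loci(c(100, 5000), c(700, 5600), "A"))
  mb <- cluster_overlaps(make_loci(c(200, 6000), c(800, 6600), "B"))
  links <- data.frame(
    locus_a = c("A_locus00001", "A_locus00001", "A_locus00002"),
    locus_b = c("B_locus00001", "B_locus00002", "B_locus00002"))
  g <- link_groups(ma, mb, links)
  expect_length(g, 1L)
  expect_equal(nrow(g[[1]]$loci), 4L)
  expect_equal(g[[1]]$category, "multiple")
})

test_that("group size boundaries give double, multiple, poly", {
  expect_equal(categorize(2), "double")
  expect_equal(categorize(3), "multiple")
  expect_equal(categorize(10), "multiple")
  expect_equal(categorize(11), "poly")
  expect_error(categorize(1), "at least 2")
})

test_that("twelve mutually linked loci form one poly group", {
  ma <- cluster_overlaps(make_loci(seq(0, 5e4, 1e4), seq(0, 5e4, 1e4) + 500,
                                   "A"))
  mb <- cluster_overlaps(make_loci(seq(0, 5e4, 1e4), seq(0, 5e4, 1e4) + 500,
                                   "B"))
  links <- expand.grid(locus_a = ma$member_ids, locus_b = mb$member_ids,
                       stringsAsFactors = FALSE)
  links$locus_a <- sub(",.*", "", links$locus_a)
  links$locus_b <- sub(",.*", "", links$locus_b)
  g <- link_groups(ma, mb, links)
  expect_length(g, 1L)
  expect_equal(nrow(g[[1]]$loci), 12L)
  expect_equal(g[[1]]$category, "poly")
})

test_that("grouping equals the union-find oracle on random link graphs", {
  set.seed(42)
  for (rep in 1:20) {
    na <- sample(5:30, 1); nb <- sample(5:30, 1)
    ma <- cluster_overlaps(make_loci(seq_len(na) * 2000,
                                     seq_len(na) * 2000 + 500, "A"))
    mb <- cluster_overlaps(make_loci(seq_len(nb) * 2000,
                                     seq_len(nb) * 2000 + 500, "B"))
    ne <- sample(1:60, 1)
    links <- unique(data.frame(
      locus_a = sprintf("A_locus%05d", sample.int(na, ne, TRUE)),
      locus_b = sprintf("B_locus%05d", sample.int(nb, ne, TRUE)),
      stringsAsFactors = FALSE))
    g <- link_groups(ma, mb, links)
    ## oracle works on merged ids
    la <- setNames(ma$locus_id, sub(",.*", "", ma$member_ids))
    lb <- setNames(mb$locus_id, sub(",.*", "", mb$member_ids))
    want <- bf_components(data.frame(a = unname(la[links$locus_a]),
                                     b = unname(lb[links$locus_b])))
    got <- lapply(g, function(x) sort(x$loci$locus_id))
    expect_setequal(lapply(got, paste, collapse = ","),
                    lapply(want, paste, collapse = ","))
    ## partition: no locus in two groups
    all_ids <- unlist(got)
    expect_equal(anyDuplicated(all_ids), 0L)
  }
})

test_that("groups are stable under input permutation", {
  set.seed(43)
  ma <- cluster_overlaps(make_loci(c(100, 5000, 9000),
                                   c(700, 5600, 9600), "A"))
  mb <- cluster_overlaps(make_loci(c(200, 6000), c(800, 6600), "B"))
  links <- data.frame(
    locus_a = c("A_locus00001", "A_locus00002", "A_locus00003"),
    locus_b = c("B_locus00001", "B_locus00001", "B_locus00002"))
  g1 <- link_groups(ma, mb, links)
  g2 <- link_groups(ma, mb, links[c(3, 1, 2), ])
  expect_equal(lapply(g1, `[[`, "loci"), lapply(g2, `[[`, "loci"))
})

test_that("a link endpoint outside every merged locus is an error", {
  ma <- cluster_overlaps(make_loci(100, 700, "A"))
  mb <- cluster_overlaps(make_loci(200, 800, "B"))
  links <- data.frame(locus_a = "A_locus00001", locus_b = "B_locus99999")
  expect_error(link_groups(ma, mb, links), "not contained")
})
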