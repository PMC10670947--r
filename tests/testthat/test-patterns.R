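## minimal verdict-table rows for joining
vrow <- function(ga, gb, status, start = 100, end = 1000, contig = "c1") {
  data.frame(genome_A = ga, genome_B = gb, contig_A = contig,
             start_A = start, end_A = end, status = status,
             stringsAsFactors = FALSE)
}

TOPO <- "((pra,pmu),dva,lag)"

test_that("consistent pairwise verdicts join into one presence vector", {
  tabs <- list(vrow("A", "B", "PP"), vrow("A", "C", "PP"))
  pat <- join_pairwise(tabs, "A")
  expect_equal(nrow(pat), 1L)
  expect_equal(pat$status_A, "plus")
  expect_equal(pat$status_B, "plus")
  expect_equal(pat$status_C, "plus")
  expect_false(pat$conflict)
})

test_that("PM and PP combine into mixed vectors", {
  tabs <- list(vrow("A", "B", "PM"), vrow("A", "C", "PP"))
  pat <- join_pairwise(tabs, "A")
  expect_equal(unlist(pat[, c("status_A", "status_B", "status_C")],
                      use.names = FALSE),
               c("plus", "minus", "plus"))
})

test_that("conflicting statuses for one genome become unknown and flagged", {
  ## B called plus by one table and minus by another at the same locus
  tabs <- list(vrow("A", "B", "PP"), vrow("A", "B", "PM", 150, 900))
  pat <- join_pairwise(tabs, "A")
  expect_equal(nrow(pat), 1L)
  expect_equal(pat$status_B, "unknown")
  expect_true(pat$conflict)
})

test_that("non-overlapping anchor intervals stay separate loci", {
  tabs <- list(rbind(vrow("A", "B", "PP", 100, 1000),
                     vrow("A", "B", "PM", 5000, 6000)))
  pat <- join_pairwise(tabs, "A")
  expect_equal(nrow(pat), 2L)
})

test_that("a missing anchor genome is an error", {
  expect_error(join_pairwise(list(vrow("X", "B", "PP")), "A"), "anchor")
})

test_that("pattern categories follow the topology", {
  st <- function(...) setNames(c(...), c("pra", "pmu", "dva", "lag"))
  expect_equal(classify_pattern(st("plus", "plus", "plus", "plus"), TOPO),
               "shared_all")
  expect_equal(classify_pattern(st("plus", "plus", "minus", "minus"), TOPO),
               "informative")
  expect_equal(classify_pattern(st("plus", "minus", "plus", "minus"), TOPO),
               "contradicting")
  expect_equal(classify_pattern(st("plus", "minus", "minus", "minus"), TOPO),
               "unique")
  expect_error(classify_pattern(setNames("plus", "zzz"), TOPO),
               "not in topology")
})

test_that("unknown statuses give incomplete only when they matter", {
  st <- function(...) setNames(c(...), c("pra", "pmu", "dva", "lag"))
  ## dva unknown: both completions are non-clade plus-sets
  expect_equal(classify_pattern(st("plus", "minus", "unknown", "plus"),
                                TOPO), "contradicting")
  ## dva unknown: completions split between shared_all and contradicting
  expect_equal(classify_pattern(st("plus", "plus", "unknown", "plus"),
                                TOPO), "incomplete")
  ## fewer than two known statuses
  expect_equal(classify_pattern(st("plus", "unknown", "unknown", "unknown"),
                                TOPO), "incomplete")
})

test_that("verdict summaries count statuses and conserve totals", {
  rep <- data.frame(status = c("PP", "PP", "PP", "PM", "PM"))
  expect_equal(summarize_verdicts(rep),
               c(PP = 3, PM = 2, MP = 0, discarded = 0))
  expect_equal(summarize_verdicts(NULL),
               c(PP = 0, PM = 0, MP = 0, discarded = 0))
  rep2 <- data.frame(status = sample(c("PP", "PM", "MP", "discarded"),
                                     57, TRUE))
  expect_equal(sum(summarize_verdicts(rep2)), nrow(rep2))
})

test_that("pattern summaries tabulate categories and vectors", {
  tabs <- list(rbind(vrow("pra", "pmu", "PP", 100, 1000),
                     vrow("pra", "pmu", "PP", 5000, 6000),
                     vrow("pra", "pmu", "PM", 9000, 9900)),
               rbind(vrow("pra", "dva", "PP", 100, 1000),
                     vrow("pra", "dva", "PM", 5000, 6000),
                     vrow("pra", "dva", "PM", 9000, 9900)),
               rbind(vrow("pra", "lag", "PP", 100, 1000),
                     vrow("pra", "lag", "PM", 5000, 6000),
                     vrow("pra", "lag", "PM", 9000, 9900)))
  pat <- join_pairwise(tabs, "pra")
  s <- summarize_patterns(pat, TOPO)
  expect_equal(as.integer(s$by_category["shared_all"]), 1L)
  expect_equal(as.integer(s$by_category["informative"]), 1L)  # pra+pmu
  expect_equal(as.integer(s$by_category["unique"]), 1L)
  expect_equal(sum(s$by_vector$Freq), nrow(pat))
})
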