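small_cfg <- function(...) sim_config(seed = 71,
                                      n_loci = c(PP = 3, PM = 2, MP = 2),
                                      ...)

test_that("identical configurations reproduce byte-identical output", {
  s1 <- simulate_genomes(small_cfg())
  s2 <- simulate_genomes(small_cfg())
  expect_identical(lapply(s1$genomes, as.character),
                   lapply(s2$genomes, as.character))
  expect_identical(s1$truth, s2$truth)
})

test_that("different seeds change sequences but not class counts", {
  s1 <- simulate_genomes(small_cfg())
  s2 <- simulate_genomes(sim_config(seed = 72,
                                    n_loci = c(PP = 3, PM = 2, MP = 2)))
  expect_false(identical(as.character(s1$genomes$A),
                         as.character(s2$genomes$A)))
  expect_identical(table(s1$truth$class), table(s2$truth$class))
})

test_that("every requested class appears exactly as requested", {
  cfg <- sim_config(seed = 73, n_loci = c(PP = 4, PM = 1, MP = 2,
                                          multimapper = 2,
                                          edge_truncated = 1))
  s <- simulate_genomes(cfg)
  tab <- table(s$truth$class)
  expect_equal(as.integer(tab[c("PP", "PM", "MP", "multimapper",
                                "edge_truncated")]),
               c(4L, 1L, 2L, 2L, 1L))
  ## truth coordinates are consistent with the emitted FASTA: the planted
  ## SINE must be discoverable inside each present cassette
  cons <- s$consensus
  for (i in which(s$truth$A_present & s$truth$class == "PP")[1]) {
    cass <- fetch_sequence(list(contig = s$truth$A_contig[i],
                                start = s$truth$A_start[i],
                                end = s$truth$A_end[i],
                                strand = s$truth$strand[i]),
                           s$genomes$A)
    hits <- scan_genome(c(x = cass), cons)
    expect_equal(nrow(hits), 1L)
  }
})

test_that("pattern classes follow the topology in multi-genome simulations", {
  cfg <- sim_config(seed = 74, genome_ids = c("pra", "pmu", "dva", "lag"),
                    topology = "((pra,pmu),dva,lag)",
                    n_loci = c(shared_all = 2, informative = 2,
                               contradicting = 1, unique = 1))
  s <- simulate_genomes(cfg)
  pres <- s$truth[, paste0(c("pra", "pmu", "dva", "lag"), "_present")]
  expect_true(all(unlist(pres[s$truth$class == "shared_all", ])))
  inf <- s$truth$class == "informative"
  expect_true(all(pres$pra_present[inf] & pres$pmu_present[inf] &
                    !pres$dva_present[inf] & !pres$lag_present[inf]))
  expect_equal(rowSums(pres[s$truth$class == "unique", ]), 1,
               ignore_attr = TRUE)
  expect_equal(rowSums(pres[s$truth$class == "contradicting", ]), 2,
               ignore_attr = TRUE)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_loci = c(XX = 3)), "unknown locus class")
  expect_error(sim_config(divergence = 0.7), "divergence")
  expect_error(sim_config(genome_ids = c("a", "b", "c")), "topology")
})

test_that("noiseless PP loci are recovered exactly", {
  cfg <- sim_config(seed = 75, n_loci = c(PP = 5), divergence = 0,
                    sine_divergence = 0, indel_rate = 0)
  s <- simulate_genomes(cfg)
  res <- sine_ortho_pair(s$genomes$A, s$genomes$B, s$consensus)
  expect_equal(unname(summarize_verdicts(res$report)["PP"]), 5)
  expect_equal(unname(summarize_verdicts(res$report)["PM"]), 0)
  ev <- evaluate_report(s$truth, res$report)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$false_positives, 0)
})

test_that("evaluation handles perfect and empty reports", {
  s <- simulate_genomes(small_cfg())
  fake <- data.frame(
    contig_A = s$truth$A_contig, start_A = s$truth$A_start,
    end_A = s$truth$A_end,
    status = ifelse(s$truth$class == "multimapper", "PP", s$truth$class),
    stringsAsFactors = FALSE)
  ev <- evaluate_report(s$truth, fake)
  expect_equal(ev$accuracy, 1)
  ev0 <- evaluate_report(s$truth,
                         fake[0, , drop = FALSE])
  expect_equal(ev0$accuracy, 0)
})

test_that("simulations round-trip through disk", {
  dir <- withr::local_tempdir()
  s <- simulate_genomes(small_cfg())
  write_simulation(s, dir)
  g <- read_genome(file.path(dir, "A.fa"))
  expect_identical(as.character(g), as.character(s$genomes$A))
  tr <- read.table(file.path(dir, "truth.tsv"), header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  expect_equal(nrow(tr), nrow(s$truth))
  expect_true(file.exists(file.path(dir, "config.txt")))
})
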