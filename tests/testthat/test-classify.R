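test_that("identical loci give a gapless PP triple alignment", {
  cons <- test_consensus()
  set.seed(51)
  lf <- rand_dna(300); rf <- rand_dna(300)
  a <- make_cassette(lf, cons$sequence, rf)
  tr <- align_triple(a, a, cons)
  expect_false(any(tr$rows["A", ] == "-"))
  expect_false(any(tr$rows["B", ] == "-"))
  expect_equal(c(tr$sine_start_col, tr$sine_end_col), c(300, 660))
  v <- classify_pair(tr)
  expect_equal(v$status, "PP")
  ss <- segment_stats(tr)$regions
  expect_equal(ss$pct_AB, c(100, 100, 100))
  expect_equal(ss$pct_Acons[ss$region == "SINE"], 100)
})

test_that("a locus lacking the SINE classifies as the minus partner", {
  cons <- test_consensus()
  set.seed(52)
  lf <- rand_dna(300); rf <- rand_dna(300)
  a <- make_cassette(lf, cons$sequence, rf)
  b <- paste0(lf, rf, rand_dna(360))       # minus allele + extension slack
  tr <- align_triple(a, b, cons)
  ss <- segment_stats(tr)
  expect_lt(ss$regions$len_B[ss$regions$region == "SINE"], 100)
  expect_equal(classify_pair(tr)$status, "PM")
  ## swapped arguments mirror to MP
  expect_equal(classify_pair(align_triple(b, a, cons))$status, "MP")
})

test_that("a consensus resembling neither locus yields a minus_minus discard", {
  cons <- test_consensus()
  set.seed(53)
  lf <- rand_dna(300); rf <- rand_dna(300)
  filler <- rand_dna(360)
  tr <- align_triple(make_cassette(lf, filler, rf),
                     make_cassette(lf, filler, rf), cons)
  v <- classify_pair(tr)
  expect_equal(v$status, "discarded")
  expect_equal(v$discard_reason, "minus_minus")
})

test_that("segment identity uses identical positions over the shorter length", {
  ## hand-countable gapless example: 9 of 10 positions identical
  tr <- make_triple(
    paste0("ACGTACGTAC", strrep("G", 6), "TTTT"),
    paste0("ACGTACGAAC", strrep("G", 6), "TTTT"),
    paste0("----------", strrep("G", 6), "----"))
  ss <- segment_stats(tr)$regions
  lf <- ss[ss$region == "LF", ]
  expect_equal(lf$identical_AB, 9)
  expect_equal(lf$pct_AB, 90)
  expect_equal(lf$len_A, 10)
  ## aligned-columns denominator agrees here (no gaps)
  ss2 <- segment_stats(tr, denominator = "aligned_columns")$regions
  expect_equal(ss2$pct_AB[ss2$region == "LF"], 90)
})

test_that("flank identity at 5% divergence stays in the binomial band", {
  cons <- test_consensus()
  set.seed(54)
  p <- replicate(60, {
    lf <- rand_dna(300); rf <- rand_dna(300)
    a <- make_cassette(lf, cons$sequence, rf)
    b <- make_cassette(mutate_rate(lf, 0.05), mutate_rate(cons$sequence, 0.05),
                       mutate_rate(rf, 0.05))
    ss <- segment_stats(align_triple(a, b, cons))$regions
    ss$pct_AB[ss$region == "LF"]
  })
  ## binomial(300, 0.05): essentially all mass has 3..30 mutated sites
  expect_true(all(p >= 90 & p <= 99.7))
  expect_gt(mean(p), 92)
  expect_lt(mean(p), 98)
})

test_that("discard rules fire at their boundaries", {
  flank_cols <- function(n, ident_n = n) {
    a <- strrep("A", n)
    b <- paste0(strrep("A", ident_n), strrep("C", n - ident_n))
    list(a = a, b = b)
  }
  sine_block <- function(n) strrep("G", n)
  build <- function(lf_n, rf_n, sine_n = 200) {
    make_triple(
      paste0(strrep("A", lf_n), sine_block(sine_n), strrep("T", rf_n)),
      paste0(strrep("A", lf_n), sine_block(sine_n), strrep("T", rf_n)),
      paste0(strrep("-", lf_n), sine_block(sine_n), strrep("-", rf_n)))
  }
  expect_equal(classify_pair(build(150, 150))$status, "PP")
  expect_equal(classify_pair(build(149, 150))$discard_reason, "shortLF")
  expect_equal(classify_pair(build(150, 149))$discard_reason, "shortRF")
  expect_equal(classify_pair(build(0, 150))$discard_reason, "leftSINE")
  expect_equal(classify_pair(build(150, 0))$discard_reason, "rightSINE")
})

test_that("the SINE presence call is sharp at 100 nt and 65% identity", {
  ## B's SINE row carries exactly `len` nt at exactly `ident` percent to
  ## the consensus; flanks are perfect and long
  build <- function(len_b, ident_b) {
    n_ident <- round(len_b * ident_b / 100)
    sine_a <- strrep("G", 200)
    sine_b <- paste0(strrep("G", n_ident), strrep("T", len_b - n_ident),
                     strrep("-", 200 - len_b))
    make_triple(
      paste0(strrep("A", 200), sine_a, strrep("C", 200)),
      paste0(strrep("A", 200), sine_b, strrep("C", 200)),
      paste0(strrep("-", 200), sine_a, strrep("-", 200)))
  }
  expect_equal(classify_pair(build(100, 65))$status, "PP")
  expect_equal(classify_pair(build(99, 100))$status, "PM")   # one nt short
  expect_equal(classify_pair(build(100, 64))$status, "PM")   # just under 65%
})

test_that("flank identity threshold is sharp at 65%", {
  build <- function(ident_pct) {
    n <- 200
    n_ident <- round(n * ident_pct / 100)
    lf_b <- paste0(strrep("A", n_ident), strrep("C", n - n_ident))
    make_triple(
      paste0(strrep("A", n), strrep("G", 200), strrep("A", n)),
      paste0(lf_b, strrep("G", 200), strrep("A", n)),
      paste0(strrep("-", n), strrep("G", 200), strrep("-", n)))
  }
  expect_equal(classify_pair(build(65))$status, "PP")
  v <- classify_pair(build(64.5))
  expect_equal(v$status, "discarded")
  expect_equal(v$discard_reason, "low_flank_identity")
})

test_that("segment identical counts never exceed the whole-row count", {
  cons <- test_consensus()
  set.seed(55)
  for (rep in 1:5) {
    a <- make_cassette(rand_dna(300), cons$sequence, rand_dna(300))
    b <- make_cassette(mutate_rate(rand_dna(300), 0.05),
                       mutate_rate(cons$sequence, 0.10), rand_dna(300))
    tr <- align_triple(a, b, cons)
    whole <- sum(tr$rows["A", ] == tr$rows["B", ] & tr$rows["A", ] != "-")
    ss <- segment_stats(tr)$regions
    expect_equal(sum(ss$identical_AB), whole)  # segmentation is exhaustive
  }
})

test_that("empty sequences are rejected", {
  cons <- test_consensus()
  expect_error(align_triple("", "ACGT", cons), "empty")
  expect_error(align_triple("ACGT", "ACGT", list(sequence = "")), "empty")
})
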