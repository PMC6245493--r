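test_that("alignment statistics classify columns and close to 100%", {
  perfect <- new_alignment(split_chars("ACGTACGTAC"), split_chars("ACGTACGTAC"),
                           10, 1, 10, 1, 10, "global", "linear")
  s <- alignment_stats(perfect, 10, 10)
  expect_equal(s$matches_pct, 100)
  expect_equal(s$gaps_pct, 0)
  expect_equal(s$coverage_pct, 100)
  # the high-scoring block of the worked local example: 5 perfect columns
  opt <- enumerate_optimal_local("TATAGGTAGCTA", "GAGCTATGAGGT")
  short <- opt[[which(vapply(opt, function(a) length(a$top), integer(1)) == 5)]]
  sb <- alignment_stats(short, 12, 12)
  expect_equal(sb$matches_pct, 100)
  expect_equal(sb$length, 5L)
  set.seed(60)
  for (t in 1:10) {
    a <- sw_align(rand_seq(40), rand_seq(40))
    if (length(a$top) == 0) next
    st <- alignment_stats(a, 40, 40)
    expect_equal(st$matches_pct + st$mismatches_pct + st$gaps_pct, 100,
                 tolerance = 1e-9)
    expect_true(st$coverage_pct >= 0 && st$coverage_pct <= 100)
  }
})

test_that("petacell accounting reproduces the published comparison sizes", {
  expect_equal(round(petacells(51304566, 49737984), 2), 2.55)
  expect_equal(round(petacells(48129895, 46489110), 2), 2.24)
  expect_equal(round(petacells(46944323, 32799110), 2), 1.54)
  expect_equal(round(petacells(59373566, 26342871), 2), 1.56)
  expect_equal(petacells(1e7, 1e8), 1.00)
})

test_that("GCUPS is exact cell-update arithmetic", {
  expect_equal(round(gcups(51304566 * 49737984, 11361.38), 2), 224.60)
  expect_equal(gcups(1e9, 1), 1.0)
  expect_equal(gcups(0, 5), 0)
  expect_error(gcups(10, 0), "domain")
})

test_that("energy and cost bookkeeping matches the published rows", {
  e <- energy_cost(101.33, 11361.38, 4, 0.13)
  expect_lt(abs(e$kj_per_device - 1151.27), 0.05)
  expect_lt(abs(e$total_cost - 0.1660), 1e-3)
  e2 <- energy_cost(160.21, 99.04, 1)
  expect_equal(e2$kj_per_device * 1000, 15867.19, tolerance = 0.01)
  expect_equal(energy_cost(120, 0, 3)$kj_per_device, 0)
})

test_that("the speculation break-even ratio matches brute-force search", {
  expect_equal(speculation_breakeven(-6.5, 11.0), 2L)
  expect_equal(speculation_breakeven(-10, 10), 1L)
  expect_equal(speculation_breakeven(-1, 9), 9L)
  expect_error(speculation_breakeven(6.5, 11), "domain")
  brute <- function(hit, miss) {
    for (r in 1:1000) if ((r * hit + miss) / (r + 1) <= 0) return(r)
    NA_integer_
  }
  set.seed(61)
  for (t in 1:25) {
    hit <- -round(runif(1, 0.5, 20), 2)
    miss <- round(runif(1, 0.5, 20), 2)
    expect_equal(speculation_breakeven(hit, miss), brute(hit, miss))
  }
})

test_that("expected time savings mix per-hit and per-miss effects", {
  expect_equal(expected_time_saving(2, 18, 0), 12)
  expect_equal(expected_time_saving(0, 50, 0), 0)
  for (r in c(0, 1, 5, 100)) expect_equal(expected_time_saving(r, 7, 7), 7)
})

test_that("the stats TSV mirrors the comparison-table rows", {
  a <- sw_align("TATAGGTAGCTA", "GAGCTATGAGGT")
  st <- alignment_stats(a, 12, 12)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_stats_tsv(st, 12, 12, f)
  tab <- read.delim(f, stringsAsFactors = FALSE)
  expect_equal(tab$metric,
               c("Petacells", "Score", "Length", "Coverage",
                 "Matches", "Mismatches", "Gaps"))
  expect_equal(tab$value[tab$metric == "Score"], "5")
})
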