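test_that("the anti-diagonal schedule partitions the grid with the known profile", {
  sched <- antidiagonal_schedule(5, 9)
  expect_length(sched, 13L)
  counts <- vapply(sched, nrow, integer(1))
  expect_equal(max(counts), 5L)
  expect_equal(sum(counts == 5L), 5L)                 # plateau d5..d9
  expect_equal(counts, c(1:4, rep(5, 5), 4:1))
  expect_length(antidiagonal_schedule(1, 1), 1L)
  set.seed(30)
  for (t in 1:10) {
    m <- sample(1:20, 1); n <- sample(1:20, 1)
    sc <- antidiagonal_schedule(m, n)
    expect_equal(sum(vapply(sc, nrow, integer(1))), m * n)
    # dependency safety: every diagonal's cells satisfy i + j - 1 == d
    for (d in seq_along(sc)) {
      expect_true(all(sc[[d]][, "i"] + sc[[d]][, "j"] - 1L == d))
    }
  }
})

test_that("maximum parallelism is the shorter dimension", {
  expect_equal(max_parallelism(5, 9), 5L)
  expect_equal(max_parallelism(1, 42), 1L)
  expect_equal(max_parallelism(7, 7), 7L)
})

test_that("a single band reproduces the monolithic last column", {
  set.seed(31)
  for (sch in list(scoring_scheme(), scoring_scheme(gap_open = 4, gap_extend = 1))) {
    for (mode in c("local", "global")) {
      s0 <- rand_seq(20); s1 <- rand_seq(17)
      res <- band_fill(s0, s1, sch, mode, k = 4)
      dp <- if (sch$gap_model == "affine") gotoh_fill(s0, s1, sch, mode)
            else if (mode == "local") sw_fill(s0, s1, sch) else nw_fill(s0, s1, sch)
      expect_equal(res$out_border$H, unname(dp$H[, 18]))
    }
  }
})

test_that("chained bands reproduce every border column and special row bit-exactly", {
  set.seed(32)
  for (t in 1:30) {
    m <- sample(6:50, 1); n <- sample(6:50, 1)
    s0 <- rand_seq(m); s1 <- rand_seq(n)
    affine <- t %% 2 == 0
    sch <- if (affine) scoring_scheme(gap_open = sample(2:5, 1), gap_extend = 1)
           else scoring_scheme(gap = sample(1:3, 1))
    mode <- if (t %% 3) "local" else "global"
    k <- sample(c(3, 7, m), 1)
    dp <- stagealign:::dp_fill(dna_sequence(s0), dna_sequence(s1), sch, mode)
    Ffull <- if (affine) dp$F else attr(dp, "Ffull")
    W <- sample(2:4, 1)
    parts <- partition_columns(n, W)
    bord <- NULL
    for (p in seq_len(W)) {
      pt <- parts[[p]]
      res <- band_fill(s0, substr(s1, pt$j_lo, pt$j_hi), sch, mode,
                       in_border = bord, k = k, j_lo = pt$j_lo,
                       partition = pt$index)
      expect_equal(res$out_border$H, unname(dp$H[, pt$j_hi + 1]))
      sp <- res$specials
      for (si in seq_along(sp$rows)) {
        expect_equal(sp$H[si, ], unname(dp$H[sp$rows[si] + 1, (pt$j_lo:pt$j_hi) + 1]))
        expect_equal(sp$F[si, ], unname(Ffull[sp$rows[si] + 1, (pt$j_lo:pt$j_hi) + 1]))
      }
      bord <- res$out_border
    }
  }
})

test_that("a coarse interval keeps only the last row as checkpoint", {
  res <- band_fill(rand_seq(10), rand_seq(10), scoring_scheme(), "local", k = 50)
  expect_equal(res$specials$rows, 10L)
})

test_that("a mismatched input border is a dataflow error", {
  s0 <- rand_seq(10)
  res <- band_fill(s0, rand_seq(5), scoring_scheme(), "local", k = 5)
  bad <- res$out_border
  bad$H <- bad$H[-1]
  expect_error(band_fill(s0, rand_seq(5), scoring_scheme(), "local",
                         in_border = bad, k = 5, j_lo = 6), "dataflow")
})

test_that("the band's best cell matches the monolithic local optimum", {
  set.seed(33)
  s0 <- rand_seq(40); s1 <- rand_seq(40)
  res <- band_fill(s0, s1, scoring_scheme(), "local", k = 10)
  expect_equal(res$local_best$score, max(sw_fill(s0, s1)$H))
})
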