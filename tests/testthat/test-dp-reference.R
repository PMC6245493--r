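test_that("global fill reproduces the boundary and recurrence", {
  sch <- scoring_scheme()
  dp <- nw_fill("A", "A", sch)
  expect_equal(unname(dp$H), matrix(c(0, -2, -2, 1), 2, 2))
  dp2 <- nw_fill("A", "", sch)
  expect_equal(dp2$H[2, 1], -2)
  expect_error(nw_fill("A", "A", scoring_scheme(gap_open = 3, gap_extend = 1)),
               "wrong-kernel")
})

test_that("global fill equals the textbook loop DP cell for cell", {
  set.seed(101)
  for (t in 1:25) {
    s0 <- rand_seq(sample(1:15, 1)); s1 <- rand_seq(sample(1:15, 1))
    G <- sample(1:3, 1)
    dp <- nw_fill(s0, s1, scoring_scheme(gap = G))
    expect_equal(unname(dp$H), loop_linear_dp(s0, s1, 1, 1, G))
  }
  # the worked 12-mer pair of the global-alignment walkthrough
  dp <- nw_fill("ATTGTCAGGAGG", "ACTTGTCCGAGA", scoring_scheme())
  expect_equal(unname(dp$H), loop_linear_dp("ATTGTCAGGAGG", "ACTTGTCCGAGA", 1, 1, 2))
})

test_that("global traceback yields optimal, self-consistent alignments", {
  sch <- scoring_scheme()
  a <- nw_align("ACGT", "ACGT", sch)
  expect_equal(a$score, 4)
  expect_equal(a$top, c("A", "C", "G", "T"))
  expect_equal(a$top, a$bottom)
  set.seed(5)
  for (t in 1:10) {
    s0 <- rand_seq(sample(0:12, 1)); s1 <- rand_seq(sample(0:12, 1))
    a <- nw_align(s0, s1, sch)
    dp <- nw_fill(s0, s1, sch)
    expect_equal(a$score, dp$H[dp$m + 1, dp$n + 1])
    expect_valid_alignment(a, sch, dna_sequence(s0), dna_sequence(s1))
  }
})

test_that("local fill clamps at zero and finds the worked-example optimum", {
  sch <- scoring_scheme()
  set.seed(6)
  for (t in 1:10) {
    dp <- sw_fill(rand_seq(sample(1:20, 1)), rand_seq(sample(1:20, 1)), sch)
    expect_gte(min(dp$H), 0)
  }
  expect_equal(max(sw_fill("AAAA", "TTTT", sch)$H), 0)
  dp <- sw_fill("TATAGGTAGCTA", "GAGCTATGAGGT", sch)
  expect_equal(max(dp$H), 5)
  expect_equal(unname(dp$H), loop_linear_dp("TATAGGTAGCTA", "GAGCTATGAGGT",
                                            1, 1, 2, local = TRUE))
})

test_that("best-cell search returns every argmax in row-major order", {
  sch <- scoring_scheme()
  b <- sw_best(sw_fill("TATAGGTAGCTA", "GAGCTATGAGGT", sch))
  expect_equal(b$score, 5)
  expect_equal(nrow(b$cells), 2L)
  expect_true(all(diff(b$cells[, "i"]) >= 0))
  g <- sw_best(sw_fill("G", "G", sch))
  expect_equal(g$score, 1)
  expect_equal(unname(g$cells[1, ]), c(1L, 1L))
  z <- sw_best(sw_fill("AAAA", "TTTT", sch))
  expect_equal(z$score, 0)
  expect_equal(nrow(z$cells), 0L)
})

test_that("local traceback reproduces the worked example and degenerate cases", {
  sch <- scoring_scheme()
  a <- sw_align("TATAGGTAGCTA", "GAGCTATGAGGT", sch)
  expect_equal(a$score, 5)
  expect_valid_alignment(a, sch)
  ident <- sw_align("ACGTACGT", "ACGTACGT", sch)
  expect_equal(ident$score, 8)
  expect_equal(length(ident$top), 8L)
  expect_equal(sw_align("ACGT", "", sch)$score, 0)
})

test_that("local scores match exhaustive enumeration on tiny inputs", {
  set.seed(7)
  for (t in 1:12) {
    s0 <- rand_seq(sample(2:6, 1)); s1 <- rand_seq(sample(2:6, 1))
    G <- sample(1:2, 1)
    a <- sw_align(s0, s1, scoring_scheme(gap = G))
    expect_equal(a$score, brute_local_score(s0, s1, 1, 1, G, G))
  }
})

test_that("affine fill matches the textbook loop DP and the worked example", {
  aff <- scoring_scheme(gap_open = 3, gap_extend = 1)
  dp <- gotoh_fill("AAA", "A", aff, "global")
  expect_equal(dp$H[4, 2], -3)   # one match minus gamma(2) = 1 - 4
  expect_error(gotoh_fill("A", "A", scoring_scheme()), "wrong-kernel")
  set.seed(8)
  for (t in 1:15) {
    s0 <- rand_seq(sample(1:12, 1)); s1 <- rand_seq(sample(1:12, 1))
    go <- sample(2:5, 1); ge <- sample(1:2, 1)
    local <- t %% 2 == 0
    sch <- scoring_scheme(gap_open = go, gap_extend = ge)
    dp <- gotoh_fill(s0, s1, sch, if (local) "local" else "global")
    ref <- loop_affine_dp(s0, s1, 1, 1, go, ge, local = local)
    expect_equal(unname(dp$H), ref$H)
    if (local) expect_gte(min(dp$H), 0)
  }
})

test_that("affine with equal open and extend reproduces the linear kernels", {
  set.seed(9)
  for (t in 1:30) {
    s0 <- rand_seq(sample(1:25, 1)); s1 <- rand_seq(sample(1:25, 1))
    G <- sample(1:3, 1)
    aff <- scoring_scheme(gap_open = G, gap_extend = G)
    lin <- scoring_scheme(gap = G)
    if (t %% 2 == 0) {
      expect_equal(gotoh_align(s0, s1, aff, "global")$score,
                   nw_align(s0, s1, lin)$score)
    } else {
      expect_equal(gotoh_align(s0, s1, aff, "local")$score,
                   sw_align(s0, s1, lin)$score)
    }
  }
})

test_that("affine alignment scores equal exhaustive run-aware enumeration", {
  set.seed(10)
  for (t in 1:10) {
    s0 <- rand_seq(sample(2:6, 1)); s1 <- rand_seq(sample(2:6, 1))
    go <- sample(2:4, 1); ge <- 1
    sch <- scoring_scheme(gap_open = go, gap_extend = ge)
    g <- gotoh_align(s0, s1, sch, "global")
    expect_equal(g$score, brute_global_score(s0, s1, 1, 1, go, ge))
    expect_valid_alignment(g, sch)
    l <- gotoh_align(s0, s1, sch, "local")
    expect_equal(l$score, brute_local_score(s0, s1, 1, 1, go, ge))
  }
})

test_that("tracebacks are deterministic", {
  set.seed(11)
  s0 <- rand_seq(30); s1 <- rand_seq(30)
  sch <- scoring_scheme(gap_open = 4, gap_extend = 1)
  expect_identical(gotoh_align(s0, s1, sch, "global"),
                   gotoh_align(s0, s1, sch, "global"))
  expect_identical(sw_align(s0, s1), sw_align(s0, s1))
})

test_that("co-optimal local enumeration finds the two worked-example optima", {
  opt <- enumerate_optimal_local("TATAGGTAGCTA", "GAGCTATGAGGT")
  expect_length(opt, 2L)
  expect_true(all(vapply(opt, `[[`, numeric(1), "score") == 5))
  sigs <- sort(vapply(opt, function(a) paste(a$top, collapse = ""), character(1)))
  expect_equal(sigs, c("AGCTA", "TAT-AGGT"))
  ident <- enumerate_optimal_local("ACGTA", "ACGTA")
  expect_length(ident, 1L)
})

test_that("co-optimal local enumeration matches brute-force path search", {
  set.seed(12)
  cases <- c(list(c("AG", "GA")),
             lapply(1:6, function(i) c(rand_seq(sample(3:5, 1)),
                                       rand_seq(sample(3:5, 1)))))
  for (cs in cases) {
    got <- enumerate_optimal_local(cs[1], cs[2])
    want <- brute_local_optima(cs[1], cs[2], 1, 1, 2)
    got_sigs <- sort(unique(vapply(got, function(a) {
      paste(paste(a$top, collapse = ""), paste(a$bottom, collapse = ""), sep = "/")
    }, character(1))))
    expect_equal(got_sigs, sort(want))
  }
  expect_error(enumerate_optimal_local(rand_seq(400), rand_seq(300)), "size error")
})
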