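aff <- scoring_scheme(gap_open = 4, gap_extend = 1)

test_that("forward vectors equal the corresponding full-matrix row", {
  set.seed(20)
  for (t in 1:10) {
    s0 <- rand_seq(sample(4:20, 1)); s1 <- rand_seq(sample(4:20, 1))
    i_star <- sample(seq_len(nchar(s0)), 1)
    fv <- forward_vectors(substr(s0, 1, i_star), s1, aff)
    full <- loop_affine_dp(s0, s1, 1, 1, 4, 1)
    expect_equal(fv$CC, unname(full$H[i_star + 1, ]))
    # the oracle leaves F's first column untouched (-Inf); the vectors carry
    # the all-vertical-gap value there, which is what midpoint matching needs
    expect_equal(fv$DD[-1], unname(full$F[i_star + 1, -1]))
    expect_equal(fv$DD[1], -gap_run_cost(i_star, aff))
  }
})

test_that("an empty prefix gives the all-gap boundary row", {
  fv <- forward_vectors("", "ACGT", aff)
  expect_equal(fv$CC, c(0, -4, -5, -6, -7))
  expect_true(all(fv$DD == -Inf))
})

test_that("reverse vectors are forward vectors of the reversed problem", {
  set.seed(21)
  s0 <- rand_seq(12); s1 <- rand_seq(15)
  rv <- reverse_vectors(s0, s1, aff)
  rev_str <- function(s) paste(rev(split_chars(s)), collapse = "")
  fw <- forward_vectors(rev_str(s0), rev_str(s1), aff)
  expect_equal(rv$RR, fw$CC)
  expect_equal(rv$SS, fw$DD)
})

test_that("the midpoint lies on an optimal path and attains the optimum", {
  expect_equal(mm_midpoint("ACGTACGT", "ACGTACGT", aff)[c("i_star", "j_star")],
               list(i_star = 4L, j_star = 4L))
  expect_error(mm_midpoint("A", "ACGT", aff), "base-case")
  set.seed(22)
  for (t in 1:40) {
    s0 <- rand_seq(sample(2:30, 1)); s1 <- rand_seq(sample(1:30, 1))
    go <- sample(2:5, 1); ge <- sample(1:2, 1)
    sch <- scoring_scheme(gap_open = go, gap_extend = ge)
    mp <- mm_midpoint(s0, s1, sch)
    expect_equal(mp$value, gotoh_align(s0, s1, sch, "global")$score)
  }
  expect_equal(mm_midpoint("ACGT", "", aff)$j_star, 0L)
})

test_that("linear-space global alignment equals the quadratic kernels", {
  lin <- scoring_scheme()
  a <- linear_align("ATTGTCAGGAGG", "ACTTGTCCGAGA", lin, "global",
                    base_case_area = 4)
  expect_equal(a$score, nw_align("ATTGTCAGGAGG", "ACTTGTCCGAGA", lin)$score)
  expect_valid_alignment(a, lin)
  set.seed(23)
  for (t in 1:40) {
    s0 <- rand_seq(sample(1:120, 1)); s1 <- rand_seq(sample(1:120, 1))
    sch <- if (t %% 2) scoring_scheme(gap = sample(1:3, 1))
           else scoring_scheme(gap_open = sample(2:5, 1), gap_extend = sample(1:2, 1))
    mode <- if (t %% 3) "global" else "local"
    la <- linear_align(s0, s1, sch, mode, base_case_area = 32)
    ref <- if (sch$gap_model == "affine") gotoh_align(s0, s1, sch, mode)
           else if (mode == "global") nw_align(s0, s1, sch)
           else sw_align(s0, s1, sch)
    expect_equal(la$score, ref$score)
    expect_valid_alignment(la, sch, dna_sequence(s0), dna_sequence(s1))
  }
})

test_that("a large base case degenerates to a single direct DP call", {
  set.seed(24)
  s0 <- rand_seq(40); s1 <- rand_seq(35)
  big <- linear_align(s0, s1, aff, "global", base_case_area = 1e6)
  ref <- gotoh_align(s0, s1, aff, "global")
  expect_equal(big$top, ref$top)
  expect_equal(big$bottom, ref$bottom)
  expect_equal(big$score, ref$score)
  small <- linear_align(s0, s1, aff, "global", base_case_area = 16)
  expect_equal(small$score, ref$score)
})
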