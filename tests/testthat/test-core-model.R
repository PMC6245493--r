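test_that("sequences normalize and validate their residues", {
  s <- dna_sequence("acgtn", id = "x")
  expect_equal(s$residues, "ACGTN")
  expect_equal(s$length, 5L)
  expect_error(dna_sequence("AC GT"), "alphabet")
  expect_equal(dna_sequence("")$length, 0L)
})

test_that("substitution scores follow match/mismatch with hook precedence", {
  sch <- scoring_scheme()   # +1 / -1
  expect_equal(p_score("A", "A", sch), 1L)
  expect_equal(p_score("A", "T", sch), -1L)
  # ambiguity codes mismatch everything, including themselves
  expect_equal(p_score("N", "N", sch), -1L)
  expect_error(p_score("a", "A", sch), "alphabet")
  hook <- scoring_scheme(substitution_hook = function(a, b) if (a == b) -5L else 3L)
  expect_equal(p_score("G", "G", hook), -5L)
  expect_equal(p_score("G", "C", hook), 3L)
})

test_that("p_score is symmetric without a hook", {
  sch <- scoring_scheme(match = 2, mismatch = 3)
  for (a in c("A", "C", "G", "T", "N")) for (b in c("A", "C", "G", "T", "N")) {
    expect_equal(p_score(a, b, sch), p_score(b, a, sch))
  }
})

test_that("gap run costs follow the affine formula and reduce to linear", {
  aff <- scoring_scheme(gap_open = 5, gap_extend = 1)
  expect_equal(gap_run_cost(1, aff), 5L)
  expect_equal(gap_run_cost(3, aff), 7L)
  expect_error(gap_run_cost(0, aff), "domain")
  lin <- scoring_scheme(gap = 2)
  expect_equal(gap_run_cost(1:4, lin), (1:4) * 2L)
  # marginal cost of extending a run is always the extension penalty
  expect_equal(diff(gap_run_cost(1:10, aff)), rep(1L, 9))
})

test_that("scoring scheme rejects inconsistent penalties", {
  expect_error(scoring_scheme(gap_open = 1, gap_extend = 2), "gap_open >= gap_extend")
  expect_error(scoring_scheme(gap_open = 3), "both")
})

test_that("score recomputation matches stored scores on known alignments", {
  sch <- scoring_scheme()
  perfect <- new_alignment(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                           4, 1, 4, 1, 4, "global", "linear")
  expect_equal(score_alignment(perfect, sch), 4)
  # one 3-run of gaps under affine (5,1): 7 matches - gamma(3) = 0
  aff <- scoring_scheme(gap_open = 5, gap_extend = 1)
  top <- c(rep("A", 4), rep("-", 3), rep("A", 3))
  bot <- rep("A", 10)
  aln <- new_alignment(top, bot, 0, 1, 7, 1, 10, "global", "affine")
  expect_equal(score_alignment(aln, aff), 0)
  expect_error(
    new_alignment(c("A", "-"), c("A", "-"), 0, 1, 1, 1, 1, "global", "linear"),
    "gap, gap")
})

test_that("global alignment scores agree with an exhaustive search", {
  sch <- scoring_scheme()
  a <- nw_align("ACTTGTCCG", "ATGTCAG", sch)
  expect_equal(a$score, brute_global_score("ACTTGTCCG", "ATGTCAG", 1, 1, 2, 2))
  expect_equal(score_alignment(a, sch), a$score)
})
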