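test_that("zero rates reproduce the ancestor exactly", {
  pair <- generate_homolog_pair(1000, sub_rate = 0, indel_rate = 0, seed = 42)
  expect_equal(pair$s0$residues, pair$s1$residues)
  expect_equal(nrow(pair$edits), 0L)
})

test_that("the realized substitution fraction is binomially consistent", {
  n <- 10000
  pair <- generate_homolog_pair(n, sub_rate = 0.05, indel_rate = 0, seed = 7)
  a <- split_chars(pair$s0$residues); b <- split_chars(pair$s1$residues)
  frac <- mean(a != b)
  sd3 <- 3 * sqrt(0.05 * 0.95 / n)
  expect_lt(abs(frac - 0.05), sd3)
})

test_that("the edit record reconciles the derived length exactly", {
  pair <- generate_homolog_pair(5000, sub_rate = 0.02, indel_rate = 0.001,
                                mean_indel_len = 5, seed = 1)
  ins <- sum(pair$edits$length[pair$edits$op == "ins"])
  del <- sum(pair$edits$length[pair$edits$op == "del"])
  expect_equal(pair$s1$length, 5000L + ins - del)
  expect_gt(nrow(pair$edits), 0L)
})

test_that("generation is reproducible under a fixed seed", {
  a <- generate_homolog_pair(800, 0.05, 0.002, 4, seed = 123)
  b <- generate_homolog_pair(800, 0.05, 0.002, 4, seed = 123)
  expect_identical(a, b)
  c <- generate_homolog_pair(800, 0.05, 0.002, 4, seed = 124)
  expect_false(identical(a$s1$residues, c$s1$residues))
  expect_error(generate_homolog_pair(100, 0.05, 0), "seed")
  expect_error(generate_homolog_pair(100, 1.2, 0, seed = 1), "domain")
})

test_that("realized substitution rates are calibrated across seeds", {
  fr <- vapply(1:20, function(s) {
    p <- generate_homolog_pair(5000, sub_rate = 0.05, indel_rate = 0, seed = s)
    mean(split_chars(p$s0$residues) != split_chars(p$s1$residues))
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.05) / 0.05, 0.02)
})

test_that("decoy planting is deterministic, guarded and identity at length 0", {
  pair <- generate_homolog_pair(400, 0.1, 0, seed = 5)
  expect_identical(plant_decoy_repeat(pair, 0, 10, seed = 1), pair)
  d1 <- plant_decoy_repeat(pair, 40, 300, seed = 2)
  d2 <- plant_decoy_repeat(pair, 40, 300, seed = 2)
  expect_identical(d1, d2)
  expect_equal(d1$s0$length, pair$s0$length)
  expect_error(plant_decoy_repeat(pair, 40, 390, seed = 2), "placement")
  expect_error(plant_decoy_repeat(pair, 40, 300, seed = 2, source = 290),
               "placement")
  expect_error(plant_decoy_repeat(pair, 300, 50, seed = 2), "placement")
})
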