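test_that("identical profiles align on the diagonal at 4 * b", {
  p <- alignment_params()
  x <- make_profile("ACGU", rep(0.3, 4), "x")
  y <- make_profile("UGCA", rep(0.3, 4), "y")  # shape-only ignores bases
  a <- gotoh_align(x, y, p)
  expect_equal(a$score, 8)
  expect_equal(a$columns, cbind(x = 1:4, y = 1:4))
})

test_that("an empty side yields one pure-gap run charged GOP + L*GEP", {
  p <- alignment_params()
  e <- make_profile("", numeric(0), "e")
  y <- make_profile("ACG", c(0.1, 0.2, 0.3), "y")
  a <- gotoh_align(e, y, p)
  expect_equal(a$score, -5 + 3 * -0.25)
  expect_true(all(is.na(a$columns[, 1])))
  expect_equal(gotoh_align(e, e, p)$score, 0)
  expect_equal(nrow(gotoh_align(e, e, p)$columns), 0L)
})

test_that("DP matches the exhaustive oracle on a bulged instance", {
  p <- alignment_params()
  x <- make_profile("AGA", c(0.1, 2.0, 0.1), "x")
  y <- make_profile("AA", c(0.1, 0.1), "y")
  g <- gotoh_align(x, y, p)
  ex <- exhaustive_align(x, y, p)
  expect_equal(g$score, ex$score)
  expect_true(alignment_key(g$columns) %in%
                vapply(ex$alignments, alignment_key, ""))
})

test_that("oracle handles the forced single-gap and single-diagonal cases", {
  p <- alignment_params()
  one <- make_profile("A", 0.4, "x")
  e <- make_profile("", numeric(0), "e")
  ex <- exhaustive_align(one, one, p)
  expect_equal(ex$score, p$b)
  expect_true(alignment_key(cbind(1L, 1L)) %in%
                vapply(ex$alignments, alignment_key, ""))
  expect_equal(exhaustive_align(one, e, p)$score, p$gop + p$gep)
  expect_error(exhaustive_align(random_profile(9), random_profile(9), p),
               "refused")
})

test_that("DP equals the oracle over random instances, params and modes", {
  set.seed(1234)
  for (k in 1:60) {
    px <- random_profile(sample(0:6, 1), "x")
    py <- random_profile(sample(0:6, 1), "y")
    prm <- random_valid_params()
    g <- gotoh_align(px, py, prm)
    ex <- exhaustive_align(px, py, prm)
    expect_equal(g$score, ex$score, tolerance = 1e-12)
    expect_true(alignment_key(g$columns) %in%
                  vapply(ex$alignments, alignment_key, ""))
  }
})

test_that("score_alignment reproduces the DP score and flags bad input", {
  set.seed(77)
  for (k in 1:30) {
    px <- random_profile(sample(0:25, 1), "x")
    py <- random_profile(sample(0:25, 1), "y")
    prm <- random_valid_params()
    g <- gotoh_align(px, py, prm)
    expect_equal(score_alignment(g, px, py, prm), g$score,
                 tolerance = 1e-9)
  }
  px <- make_profile("AC", c(0.1, 0.2))
  py <- make_profile("A", 0.1)
  expect_error(
    score_alignment(cbind(c(1L, NA), c(NA, NA)), px, py, alignment_params()),
    "all-gap")
  expect_error(
    score_alignment(cbind(c(2L, 1L), c(1L, NA)), px, py, alignment_params()),
    "in order")
})

test_that("one opened gap of length one costs b + GOP + GEP", {
  p <- alignment_params()
  px <- make_profile("AC", c(0.3, 0.3))
  py <- make_profile("A", 0.3)
  cols <- cbind(x = c(1L, 2L), y = c(1L, NA))
  expect_equal(score_alignment(cols, px, py, p), p$b + p$gop + p$gep)
})

test_that("alignment score is symmetric under argument swap", {
  set.seed(5150)
  for (k in 1:20) {
    px <- random_profile(sample(1:30, 1), "x")
    py <- random_profile(sample(1:30, 1), "y")
    prm <- random_valid_params()
    expect_equal(gotoh_align(px, py, prm)$score,
                 gotoh_align(py, px, prm)$score, tolerance = 1e-9)
  }
})

test_that("alignment is deterministic across repeated runs", {
  set.seed(8)
  px <- random_profile(40, "x")
  py <- random_profile(35, "y")
  a1 <- gotoh_align(px, py, alignment_params("combined"))
  a2 <- gotoh_align(px, py, alignment_params("combined"))
  expect_identical(a1$columns, a2$columns)
  expect_identical(a1$score, a2$score)
})

test_that("free end gaps stop terminal runs from being charged", {
  p <- alignment_params()
  px <- make_profile("ACGUA", c(0.2, 0.2, 0.2, 0.2, 0.2))
  py <- make_profile("ACG", c(0.2, 0.2, 0.2))
  a <- gotoh_align(px, py, p, free_endgaps = TRUE)
  expect_equal(a$score, 3 * p$b)  # three matches, trailing gaps free
  expect_equal(score_alignment(a, px, py, p), a$score)
})
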