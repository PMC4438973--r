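test_that("alignment sensitivity is the recovered fraction of reference pairs", {
  ref <- aligned_pairs(1:100, 1:100, "reference")
  expect_equal(alignment_sensitivity(ref, ref), 100)
  test <- aligned_pairs(1:100, c(1:50, 151:200), "predicted")
  expect_equal(alignment_sensitivity(test, ref), 50)
  expect_error(
    alignment_sensitivity(ref, aligned_pairs(integer(0), integer(0))),
    "empty reference")
})

test_that("sensitivity is 100 exactly when the reference is contained", {
  set.seed(31)
  for (k in 1:20) {
    n <- sample(3:30, 1)
    i <- sort(sample(1:60, n)); j <- sort(sample(1:60, n))
    ref <- aligned_pairs(i, j, "reference")
    keep <- runif(n) < 0.7
    test <- aligned_pairs(i[keep], j[keep], "predicted")
    expect_equal(alignment_sensitivity(test, ref) == 100, all(keep))
  }
})

test_that("structure_compare applies the one-end-fixed refolding criterion", {
  ident <- secondary_structure(60, c(10, 12), c(45, 43))
  expect_equal(structure_compare(ident, ident)$sens, 100)
  expect_equal(structure_compare(ident, ident)$ppv, 100)

  ref <- secondary_structure(60, 10, 45)
  hit <- secondary_structure(60, 10, 50)   # x fixed, |y - y'| = 5
  expect_equal(structure_compare(hit, ref, allowance = 5)$sens, 100)

  miss <- secondary_structure(60, 12, 48)  # neither coordinate fixed
  cmp <- structure_compare(miss, ref, allowance = 5)
  expect_equal(cmp$sens, 0)
  expect_equal(cmp$ppv, 0)

  expect_equal(structure_compare(hit, ref, allowance = 0)$sens, 0)
  expect_equal(structure_compare(ref, ref, allowance = 0)$sens, 100)
})

test_that("pseudoknotted and non-canonical pairs are filtered from both sides", {
  # (1,10) is G-C, (2,9) is A-A (non-canonical)
  ref <- secondary_structure(10, c(1, 2), c(10, 9), sequence = "GAAAAAAAAC")
  prd <- secondary_structure(10, 1, 10, sequence = "GAAAAAAAAC")
  cmp <- structure_compare(prd, ref)
  expect_equal(cmp$n_reference, 1L)  # the A-A pair dropped
  expect_equal(cmp$sens, 100)

  # a pseudoknot-flagged pair is removed even though it is canonical
  pk <- read_structure(write_tmp(c(">s", "GGAACCGAUC", "((..))[..]")),
                       "dotbracket")
  expect_equal(sum(pk$pseudoknot), 1L)
  base <- read_structure(write_tmp(c(">s", "GGAACCGAUC", "((..))....")),
                         "dotbracket")
  cmp2 <- structure_compare(pk, base)
  expect_equal(cmp2$n_predicted, 2L)
  expect_equal(cmp2$ppv, 100)
})

test_that("structure sens/ppv swap under argument swap", {
  set.seed(12)
  for (k in 1:15) {
    n <- 80
    mk <- function() {
      x <- sample(1:35, 6); y <- sample(45:80, 6)
      secondary_structure(n, x, y)
    }
    a <- mk(); b <- mk()
    ab <- structure_compare(a, b)
    ba <- structure_compare(b, a)
    expect_equal(ab$sens, ba$ppv)
    expect_equal(ab$ppv, ba$sens)
  }
})

test_that("increasing the allowance never decreases sens or ppv", {
  set.seed(21)
  for (k in 1:10) {
    n <- 100
    a <- secondary_structure(n, sample(1:40, 8), sample(50:100, 8))
    b <- secondary_structure(n, sample(1:40, 8), sample(50:100, 8))
    sens <- vapply(0:6, function(w) structure_compare(a, b, w)$sens, 0)
    ppv <- vapply(0:6, function(w) structure_compare(a, b, w)$ppv, 0)
    expect_true(all(diff(sens) >= 0))
    expect_true(all(diff(ppv) >= 0))
  }
})

test_that("difference histogram bins |delta| and conserves the pair count", {
  px <- make_profile("ACGU", c(0.5, 0.5, 0.5, NA), "x")
  py <- make_profile("ACGU", c(0.55, 0.75, NA, 0.5), "y")
  pairs <- aligned_pairs(1:4, 1:4)
  d <- reactivity_difference_distribution(pairs, px, py, bin_width = 0.1)
  expect_equal(d$n_pairs, 2L)            # two pairs lack a value
  expect_equal(sum(d$counts), d$n_pairs)
  expect_equal(d$counts[1:3], c(1L, 0L, 1L))  # 0.05 and 0.25

  same <- make_profile("ACGU", rep(1, 4))
  d2 <- reactivity_difference_distribution(pairs, same, same)
  expect_equal(d2$counts[1], 4L)
  expect_error(
    reactivity_difference_distribution(pairs, px, py, bin_width = 0),
    "positive")
})

test_that("randomized control conserves counts and is seed-deterministic", {
  set.seed(3)
  px <- random_profile(300, "x", missing_rate = 0.1)
  ry <- px$reactivities + rnorm(300, sd = 0.05)
  py <- reactivity_profile("y", px$sequence, pmax(ry, 0))
  pairs <- aligned_pairs(1:300, 1:300)
  c1 <- randomized_control(pairs, px, py, n_trials = 8, seed = 11)
  c2 <- randomized_control(pairs, px, py, n_trials = 8, seed = 11)
  expect_identical(c1$mean_counts, c2$mean_counts)
  expect_identical(c1$p_value, c2$p_value)
  expect_equal(sum(c1$mean_counts), c1$related$n_pairs)
})

test_that("permutation-invariant profiles give p close to 1", {
  const <- make_profile(paste(rep("A", 50), collapse = ""), rep(0.7, 50))
  pairs <- aligned_pairs(1:50, 1:50)
  ctrl <- randomized_control(pairs, const, const, seed = 5)
  expect_equal(ctrl$p_value, 1)
  expect_identical(ctrl$mean_counts, as.numeric(ctrl$related$counts))
})

test_that("correlated profiles separate from the randomized null", {
  cfg <- sim_config(length = 2000L, indel_rate = 0, substitution_rate = 0,
                    missing_rate = 0, seed = 99L)
  sim <- simulate_homolog_pair(cfg)
  ctrl <- randomized_control(sim$true_pairs, sim$px, sim$py,
                             n_trials = 8, seed = 13)
  expect_lt(ctrl$related_mean, ctrl$randomized_mean)
  expect_lt(ctrl$p_value, 0.01)
})

test_that("report writers emit the expected TSV layouts", {
  px <- make_profile("ACGU", c(0.5, 0.5, 0.5, 0.5), "x")
  pairs <- aligned_pairs(1:4, 1:4)
  ctrl <- randomized_control(pairs, px, px, seed = 2)
  f <- tempfile(fileext = ".tsv")
  write_histogram_tsv(ctrl, f)
  tab <- read.delim(f)
  expect_identical(names(tab), c("bin_low", "bin_high", "count",
                                 "randomized_mean", "randomized_sd"))
  expect_equal(sum(tab$count), 4)

  f2 <- tempfile(fileext = ".tsv")
  s <- secondary_structure(20, 1:3, 20:18)
  write_structure_tsv(list(rna1 = structure_compare(s, s)), f2)
  tab2 <- read.delim(f2)
  expect_equal(tab2$sens, 100)
  expect_equal(tab2$ppv, 100)
})
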