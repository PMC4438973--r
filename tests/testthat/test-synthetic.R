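test_that("profile simulation is deterministic and honors the missing rate", {
  cfg <- sim_config(length = 200L, seed = 17L)
  mask <- rep(c(TRUE, FALSE), 100)
  p1 <- simulate_reactivity_profile(mask, cfg)
  p2 <- simulate_reactivity_profile(mask, cfg)
  expect_identical(p1$sequence, p2$sequence)
  expect_identical(p1$reactivities, p2$reactivities)

  all_missing <- simulate_reactivity_profile(
    mask, sim_config(length = 200L, missing_rate = 1))
  expect_true(all(is.na(all_missing$reactivities)))
  expect_error(simulate_reactivity_profile(rep(TRUE, 3), cfg), "mask length")
})

test_that("paired positions are lowly reactive relative to unpaired", {
  cfg <- sim_config(length = 10000L, missing_rate = 0, seed = 23L)
  lo <- simulate_reactivity_profile(rep(TRUE, 10000L), cfg)
  hi <- simulate_reactivity_profile(rep(FALSE, 10000L), cfg, seed = 24L)
  expect_lt(mean(lo$reactivities), mean(hi$reactivities))
  expect_true(all(lo$reactivities >= 0))
})

test_that("no-mutation evolution returns the identity alignment", {
  cfg <- sim_config(length = 150L, substitution_rate = 0, indel_rate = 0,
                    related_delta_rate = 1e9, missing_rate = 0, seed = 3L)
  sim <- simulate_homolog_pair(cfg)
  expect_identical(sim$py$sequence, sim$px$sequence)
  expect_equal(unclass(sim$true_pairs)[, ],
               cbind(i = 1:150, j = 1:150), ignore_attr = TRUE)
  expect_equal(sim$px$reactivities, sim$py$reactivities, tolerance = 1e-6)
})

test_that("without indels the true alignment is the full diagonal", {
  cfg <- sim_config(length = 200L, indel_rate = 0, seed = 29L)
  sim <- simulate_homolog_pair(cfg)
  expect_equal(nrow(sim$true_pairs), 200L)
  expect_equal(sim$true_pairs[, 1], sim$true_pairs[, 2],
               ignore_attr = TRUE)
})

test_that("true pair sets are colinear and seeds control the draw", {
  for (s in c(1L, 2L, 3L)) {
    sim <- simulate_homolog_pair(sim_config(length = 300L, seed = s))
    expect_s3_class(sim$true_pairs, "aligned_pair_set")  # ctor enforces colinearity
    expect_true(all(diff(sim$true_pairs[, 1]) > 0))
    expect_true(all(diff(sim$true_pairs[, 2]) > 0))
  }
  a <- simulate_homolog_pair(sim_config(length = 300L, seed = 1L))
  b <- simulate_homolog_pair(sim_config(length = 300L, seed = 2L))
  expect_false(identical(a$px$sequence, b$px$sequence))
  a2 <- simulate_homolog_pair(sim_config(length = 300L, seed = 1L))
  expect_identical(a$py$reactivities, a2$py$reactivities)
})

test_that("related |delta| magnitudes follow the exponential model", {
  cfg <- sim_config(length = 10000L, substitution_rate = 0, indel_rate = 0,
                    missing_rate = 0, seed = 47L)
  sim <- simulate_homolog_pair(cfg)
  d <- abs(sim$px$reactivities[sim$true_pairs[, 1]] -
             sim$py$reactivities[sim$true_pairs[, 2]])
  ks <- suppressWarnings(
    stats::ks.test(d, "pexp", cfg$related_delta_rate))
  expect_gt(ks$p.value, 0.01)
})
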