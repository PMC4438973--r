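test_that("fold jobs validate alignment and profile consistency", {
  aln <- hairpin_alignment()
  expect_error(fold_job(aln[1]), ">= 2 rows")
  expect_error(fold_job(list(a = "AC-G", b = "ACG")), "unequal")
  expect_error(fold_job(aln, hairpin_profiles()[1:2]), "one SHAPE profile")
  bad <- hairpin_profiles()
  bad[[1]] <- make_profile("ACG", c(0.1, 0.2, 0.3))
  expect_error(fold_job(aln, bad), "do not match")
  expect_error(fold_job(aln, max_pair_distance = 0), "positive")
})

test_that("consensus folding recovers the hairpin stem with p > 0.95", {
  skip_if_not(engine_available(), "ViennaRNA executables not on PATH")
  job <- fold_job(hairpin_alignment(), hairpin_profiles())
  res <- run_consensus_fold(job)
  cp <- extract_consensus_pairs(res$probabilities, 0.95)
  stem <- hairpin_stem_pairs()
  found <- paste(cp$i, cp$j)
  expect_true(all(paste(stem[, 1], stem[, 2]) %in% found))
  expect_true(all(cp$prob > 0.95))
  expect_match(res$engine_version, "RNAalifold")
})

test_that("repeated consensus folding is deterministic", {
  skip_if_not(engine_available(), "ViennaRNA executables not on PATH")
  job <- fold_job(hairpin_alignment(), hairpin_profiles())
  r1 <- run_consensus_fold(job)
  r2 <- run_consensus_fold(job)
  expect_identical(r1$probabilities, r2$probabilities)
})

test_that("a missing engine raises an environment error naming it", {
  old <- Sys.getenv("PATH")
  on.exit(Sys.setenv(PATH = old))
  Sys.setenv(PATH = tempdir())
  expect_error(run_consensus_fold(fold_job(hairpin_alignment())),
               "RNAalifold")
})

test_that("consensus pair extraction is strictly greater-than", {
  probs <- data.frame(i = c(1L, 2L, 3L), j = c(20L, 19L, 18L),
                      prob = c(0.96, 0.95, 0.10))
  cp <- extract_consensus_pairs(probs, 0.95)
  expect_equal(cp$i, 1L)  # 0.95 exactly is dropped
  expect_equal(nrow(extract_consensus_pairs(
    data.frame(i = integer(0), j = integer(0), prob = numeric(0)))), 0L)
  expect_error(extract_consensus_pairs(probs, 1), "threshold")
  expect_error(extract_consensus_pairs(
    data.frame(i = 1L, j = 2L, prob = 1.2)), "probabilities")
  # lowering the threshold never removes pairs
  hi <- extract_consensus_pairs(probs, 0.9)
  lo <- extract_consensus_pairs(probs, 0.05)
  expect_true(all(paste(hi$i, hi$j) %in% paste(lo$i, lo$j)))
})

test_that("column pairs map through gaps onto sequence coordinates", {
  pairs <- structure(data.frame(i = c(3L, 1L), j = c(11L, 13L),
                                prob = c(0.99, 0.99)),
                     class = c("consensus_pairs", "data.frame"))
  # row: gap at column 2, so column 3 is sequence position 2
  row <- "G-GGGAAAACCCC"
  m <- map_consensus_to_sequence(pairs, row)  # input row order preserved
  expect_equal(m, data.frame(i = c(2L, 1L), j = c(10L, 12L)),
               ignore_attr = TRUE)

  # gap in the row at a paired column drops the pair
  m2 <- map_consensus_to_sequence(pairs, "G-AAGAAAAccCC")
  expect_equal(nrow(m2), 1L)

  # non-canonical mapped bases (A against C) drop the pair
  pairs_ac <- structure(data.frame(i = 1L, j = 5L, prob = 0.99),
                        class = c("consensus_pairs", "data.frame"))
  expect_equal(nrow(map_consensus_to_sequence(pairs_ac, "AAAAC")), 0L)
  expect_error(map_consensus_to_sequence(pairs, "ACG"), "outside")
})

test_that("constrained folding honors hard pair constraints", {
  skip_if_not(engine_available(), "ViennaRNA executables not on PATH")
  seqn <- "GGGGGGAAAAAACCCCCC"
  stem <- as.data.frame(hairpin_stem_pairs())
  names(stem) <- c("i", "j")
  st <- constrained_individual_fold(seqn, constraints = stem)
  have <- paste(st$pairs[, 1], st$pairs[, 2])
  expect_true(all(paste(stem$i, stem$j) %in% have))

  # no constraints, no SHAPE: plain MFE for this unambiguous hairpin
  mfe <- constrained_individual_fold(seqn)
  expect_equal(as_dotbracket(mfe), "((((((......))))))")
})

test_that("the two-step pipeline yields constraint-containing structures", {
  skip_if_not(engine_available(), "ViennaRNA executables not on PATH")
  job <- fold_job(hairpin_alignment(), hairpin_profiles())
  res <- consensus_structure_pipeline(job)
  expect_named(res$individual, names(hairpin_alignment()))
  for (nm in names(res$individual)) {
    st <- res$individual[[nm]]$structure
    constr <- res$individual[[nm]]$constraints
    have <- paste(st$pairs[, 1], st$pairs[, 2])
    expect_true(all(paste(constr$i, constr$j) %in% have))
  }
  # and the structures score perfectly against the designed stem
  truth <- secondary_structure(18, hairpin_stem_pairs()[, 1],
                               hairpin_stem_pairs()[, 2],
                               sequence = hairpin_alignment()$s1)
  cmp <- structure_compare(res$individual$s1$structure, truth)
  expect_equal(cmp$sens, 100)
})
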