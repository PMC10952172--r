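test_that("discretized truncated normal matches requested moments", {
  for (target in list(c(5.20, 1.95, 1, 10), c(2.06, 1.26, 1, 10))) {
    p <- discrete_truncnorm(target[1], target[2], target[3], target[4])
    support <- target[3]:target[4]
    m <- sum(support * p)
    s <- sqrt(sum((support - m)^2 * p))
    expect_equal(m, target[1], tolerance = 1e-4)
    expect_equal(s, target[2], tolerance = 1e-4)
    expect_equal(sum(p), 1)
  }
})

test_that("conditional Poisson sampling has the exact subset distribution", {
  set.seed(18)
  w <- c(4, 2, 1, 1, 0.5)
  draws <- replicate(4000, paste(sort(sample_cps(w, 2)), collapse = "-"))
  pairs <- combn(5, 2)
  pr <- apply(pairs, 2, function(s) prod(w[s]))
  pr <- pr / sum(pr)
  names(pr) <- apply(pairs, 2, paste, collapse = "-")
  freq <- table(factor(draws, levels = names(pr))) / 4000
  expect_lt(max(abs(as.numeric(freq) - pr)), 0.025)
  expect_equal(length(sample_cps(w, 5)), 5L)
  expect_error(sample_cps(c(1, 0, 0), 2), "exceeds")
})

test_that("generation is reproducible and validates as a survey dataset", {
  cfg <- generator_config(n_participants = 50, identity_vocab = 20,
                          behaviour_vocab = 12, seed = 99)
  s1 <- generate_survey(cfg)
  s2 <- generate_survey(cfg)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  cfg2 <- cfg
  cfg2$seed <- 100
  expect_false(identical(as.data.frame(s1), as.data.frame(generate_survey(cfg2))))
  # re-validation through the constructor is a no-op on the data columns
  expect_equal(as_survey(as.data.frame(s1)), s1, ignore_attr = TRUE)
})

test_that("default-scale generation recovers the configured marginals", {
  s <- generate_survey(generator_config(seed = 12)) # n = 286 study scale
  sm <- summary(s)
  expect_lt(abs(sm$identities_per_participant[["mean"]] - 5.20), 0.2)
  expect_equal(sm$identities_per_participant[["min"]] >= 1, TRUE)
  expect_lte(sm$identities_per_participant[["max"]], 10)

  # 10x scale pins the means down to Monte-Carlo error
  big <- generate_survey(generator_config(n_participants = 2860, seed = 13))
  smb <- summary(big)
  expect_lt(abs(smb$identities_per_participant[["mean"]] - 5.20), 0.1)
  expect_lt(abs(smb$behaviours_per_identity[["mean"]] - 2.06), 0.1)
})

test_that("infeasible planted structure is rejected at configuration", {
  expect_error(generator_config(
    identity_vocab = 20,
    blocks = list(list(identities = 1:6, boost = 10, rate = 0.5)),
    dyads = list(list(pair = c(2L, 3L), type = "avoided"))),
    "avoided dyad planted inside")
  expect_error(generator_config(
    identity_vocab = 20,
    blocks = list(list(identities = 1:3, boost = 2, rate = 0.6),
                  list(identities = 4:6, boost = 2, rate = 0.6))),
    "rates sum")
  # avoided dyad merely overlapping an unboosted block is fine
  expect_s3_class(generator_config(
    identity_vocab = 20,
    blocks = list(list(identities = 1:6, boost = 1, rate = 0.5)),
    dyads = list(list(pair = c(2L, 3L), type = "avoided"))),
    "generator_config")
})

test_that("planted dyads shape co-report counts as configured", {
  set.seed(19)
  cfg <- generator_config(
    identity_vocab = 30, behaviour_vocab = 10, p_no_behaviours = 1,
    dyads = list(list(pair = c(5L, 8L), type = "preferred", effect = 0.1),
                 list(pair = c(1L, 2L), type = "avoided")))
  s <- generate_survey(cfg)
  occ <- build_occurrence(s, "identity_by_identity")
  expect_gte(sum(occ[, "id005"] * occ[, "id008"]), 15)
  expect_equal(sum(occ[, "id001"] * occ[, "id002"]), 0)
  gt <- ground_truth(s)
  expect_equal(gt$dyads[[1]]$pair, c("id005", "id008"))
  expect_equal(gt$dyads[[2]]$type, "avoided")
})

test_that("the null generator passes its data through the survey invariants", {
  s <- null_survey(generator_config(n_participants = 60, identity_vocab = 15,
                                    behaviour_vocab = 10, seed = 20))
  ids <- participant_identities(s)
  expect_true(all(lengths(ids) >= 1 & lengths(ids) <= 10))
  # identity labels unique within participant by construction
  expect_true(all(vapply(ids, anyDuplicated, numeric(1)) == 0))
})
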