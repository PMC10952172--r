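test_that("the defining checkerboard move flips and conserves margins", {
  occ <- make_occ(rbind(c(1L, 0L), c(0L, 1L)))
  set.seed(1)
  swapped <- checkerboard_swap(occ)
  expect_equal(unname(unclass(swapped)), rbind(c(0L, 1L), c(1L, 0L)),
               ignore_attr = TRUE)
  expect_equal(rowSums(swapped), rowSums(occ))
  expect_equal(colSums(swapped), colSums(occ))
})

test_that("long chains never violate margins", {
  set.seed(2)
  occ <- random_occurrence(30, 12)
  out <- swap_chain(occ, 10000)
  expect_equal(rowSums(out), rowSums(occ))
  expect_equal(colSums(out), colSums(occ))
  expect_true(all(out %in% c(0L, 1L)))
})

test_that("single-incidence rows and columns stay single after swapping", {
  set.seed(3)
  occ <- make_occ(diag(1L, 5))
  out <- swap_chain(occ, 200)
  expect_true(all(rowSums(out) == 1L))
  expect_true(all(colSums(out) == 1L))
})

test_that("a matrix with no checkerboard freezes with a warning", {
  # nested (staircase) matrix: no 2x2 checkerboard exists
  occ <- make_occ(rbind(c(1L, 1L), c(1L, 0L)))
  expect_warning(out <- checkerboard_swap(occ, max_tries = 500), "frozen")
  expect_equal(unclass(out), unclass(occ), ignore_attr = TRUE)
})

test_that("permutation p-values follow both conventions", {
  expect_equal(perm_pvalue(0, 9999, "plus_one"), 1e-4)
  expect_equal(perm_pvalue(1000, 1000, "plus_one"), 1)
  expect_equal(perm_pvalue(50, 1000, "raw"), 0.05)
  expect_error(perm_pvalue(11, 10, "raw"))
})

test_that("chain occupancy matches exhaustive enumeration on 4x4 margins", {
  # all matrices with unit row/column margins are the 24 permutation
  # matrices; under uniformity each cell is occupied 1/4 of the time
  set.seed(4)
  occ <- make_occ(diag(1L, 4))
  acc <- matrix(0, 4, 4)
  n_samples <- 1500
  cur <- occ
  for (i in seq_len(n_samples)) {
    cur <- swap_chain(cur, 3)
    acc <- acc + unclass(cur)
  }
  expect_true(max(abs(acc / n_samples - 0.25)) < 0.06)
})

test_that("the null chain reproduces R-side statistics on its final state", {
  set.seed(9)
  occ <- random_occurrence(25, 8)
  net <- assoc_network(occ)
  res <- coocnet:::cpp_null_chain(
    matrix(as.integer(occ), nrow(occ), ncol(occ)), net$weights,
    50L, 20L, 100L, 0L, 1L, TRUE, TRUE)
  final <- make_occ(res$matrix)
  expect_equal(unname(rowSums(final)), unname(rowSums(occ)))
  expect_equal(unname(colSums(final)), unname(colSums(occ)))
  fnet <- assoc_network(final)
  v <- fnet$weights[upper.tri(fnet$weights)]
  expect_equal(res$null_cv[50], sd(v) / mean(v), tolerance = 1e-12)
})

test_that("reports are reproducible under a fixed seed", {
  occ <- random_occurrence(30, 10)
  cfg <- perm_config(n_permutations = 200, seed = 77)
  r1 <- permutation_test(occ, cfg)
  r2 <- permutation_test(occ, cfg)
  expect_identical(r1$null_cv, r2$null_cv)
  expect_identical(r1$dyads, r2$dyads)
  r3 <- permutation_test(occ, perm_config(n_permutations = 200, seed = 78))
  expect_false(identical(r1$null_cv, r3$null_cv))
})

test_that("global p respects the plus-one floor and dyad classes are exclusive", {
  set.seed(12)
  occ <- random_occurrence(40, 10)
  rep_ <- permutation_test(occ, perm_config(n_permutations = 300))
  expect_gte(rep_$global_p, 1 / 301)
  expect_lte(rep_$global_p, 1)
  d <- rep_$dyads
  expect_true(all(d$class %in% c("preferred", "avoided", "neutral")))
  expect_true(all(d$p_upper[d$class == "preferred"] <= 0.025))
  expect_true(all(d$p_lower[d$class == "avoided"] <= 0.025))
  # ties count toward both tails, so the two p's always overshoot 1 together
  expect_true(all(d$p_upper + d$p_lower > 1))
})

test_that("a planted co-occurring pair is flagged preferred", {
  set.seed(31)
  # two labels always together in 20 samples, 30 independent background labels
  n <- 60
  m <- cbind(matrix(rbinom(n * 30, 1, 0.25), n, 30),
             c(rep(1L, 20), rep(0L, n - 20)),
             c(rep(1L, 20), rep(0L, n - 20)))
  keep <- rowSums(m) > 0
  occ <- make_occ(m[keep, ])
  rep_ <- permutation_test(occ, perm_config(n_permutations = 500))
  d <- rep_$dyads
  planted <- d[d$node_a == "i31" & d$node_b == "i32", ]
  expect_equal(planted$class, "preferred")
})

test_that("a user-supplied global statistic runs through the chain", {
  set.seed(41)
  # the total co-occurrence count equals sum_i C(row_i, 2), a function of
  # the conserved row margins, so it is constant along the chain ...
  total_x <- function(o) {
    m <- unclass(o)
    x <- crossprod(m)
    (sum(x) - sum(diag(x))) / 2
  }
  occ <- random_occurrence(30, 10)
  rep_ <- permutation_test(occ, perm_config(n_permutations = 50),
                           statistic = total_x)
  expect_equal(rep_$observed_cv, total_x(occ))
  expect_equal(unique(rep_$null_cv), total_x(occ))
  expect_equal(rep_$global_p, 1)

  # ... while its square sum redistributes and genuinely varies
  sum_x2 <- function(o) {
    m <- unclass(o)
    x <- crossprod(m)
    sum((x - diag(diag(x)))^2)
  }
  rep2 <- permutation_test(occ, perm_config(n_permutations = 100),
                           statistic = sum_x2)
  expect_gt(length(unique(rep2$null_cv)), 1)
  expect_gte(rep2$global_p, 1 / 101)
  expect_null(rep2$dyads)
})

test_that("the sequential swap kernel remains available", {
  set.seed(13)
  occ <- random_occurrence(30, 10)
  cfg <- perm_config(n_permutations = 100, kernel = "swap")
  expect_equal(cfg$swaps_per_permutation, 1L)
  expect_equal(cfg$burn_in_swaps, 1000L)
  rep_ <- permutation_test(occ, cfg, dyads = FALSE)
  expect_equal(length(rep_$null_cv), 100L)
  expect_equal(rep_$n_accepted, 1100)
})
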