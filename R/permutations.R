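#' Permutation configuration
#'
#' Settings for the datastream permutation chain: 10,000 recorded
#' permutations by default, a two-tailed dyadic level of .95, and the
#' `(k + 1) / (n + 1)` p-value convention for permutation proportions.
#'
#' Two chain kernels are available. The default, `"trial"`, makes each chain
#' step a single uniformly drawn (row pair, column pair) proposal, applied
#' only when it forms a checkerboard. This kernel is symmetric, so the chain
#' is uniform over all matrices with the observed margins -- the distribution
#' the null hypothesis asserts -- and the test is calibrated. `"swap"`
#' retries proposals until one is accepted (the classic sequential
#' datastream convention); its stationary distribution over-weights matrices
#' with many swappable submatrices, which measurably inflates the test's
#' type-I error on matrices with heavy-tailed margins, so it is provided for
#' comparability only.
#'
#' With `kernel = "trial"`, `swaps_per_permutation` and `burn_in_swaps` count
#' proposals; left `NULL` they scale with the data (one proposal per
#' incidence between recorded samples, 20 per incidence of burn-in). With
#' `kernel = "swap"` they count accepted swaps and default to 1 and 1,000.
#'
#' @param n_permutations Number of recorded permutations.
#' @param swaps_per_permutation Chain steps between recorded samples
#'   (`NULL` = automatic, see Details).
#' @param burn_in_swaps Chain steps discarded before recording starts
#'   (`NULL` = automatic).
#' @param seed Optional RNG seed set before the chain runs.
#' @param alpha Two-tailed level for dyad classification; preferred/avoided
#'   thresholds are `(1 - alpha) / 2` in each tail.
#' @param p_convention `"plus_one"` for `(k + 1) / (n + 1)` or `"raw"` for
#'   `k / n`.
#' @param kernel `"trial"` (uniform-stationary, default) or `"swap"`
#'   (sequential accepted swaps).
#' @param include_zero_pairs CV dyad set: include zero-weight dyads.
#' @param max_tries Proposal bound per accepted swap (`kernel = "swap"`)
#'   before the matrix is declared frozen.
#' @param check_margins Assert row/column totals after every recorded
#'   permutation.
#' @return A `perm_config` list.
#' @export
perm_config <- function(n_permutations = 10000,
                        swaps_per_permutation = NULL,
                        burn_in_swaps = NULL,
                        seed = NULL,
                        alpha = 0.95,
                        p_convention = c("plus_one", "raw"),
                        kernel = c("trial", "swap"),
                        include_zero_pairs = TRUE,
                        max_tries = 10000,
                        check_margins = TRUE) {
  kernel <- match.arg(kernel)
  if (is.null(swaps_per_permutation) && kernel == "swap") {
    swaps_per_permutation <- 1L
  }
  if (is.null(burn_in_swaps) && kernel == "swap") burn_in_swaps <- 1000L
  stopifnot(n_permutations >= 1, alpha > 0, alpha < 1, max_tries >= 1,
            is.null(swaps_per_permutation) || swaps_per_permutation >= 1,
            is.null(burn_in_swaps) || burn_in_swaps >= 0)
  structure(list(n_permutations = as.integer(n_permutations),
                 swaps_per_permutation =
                   if (!is.null(swaps_per_permutation)) {
                     as.integer(swaps_per_permutation)
                   },
                 burn_in_swaps =
                   if (!is.null(burn_in_swaps)) as.integer(burn_in_swaps),
                 seed = seed,
                 alpha = alpha,
                 p_convention = match.arg(p_convention),
                 kernel = kernel,
                 include_zero_pairs = isTRUE(include_zero_pairs),
                 max_tries = as.integer(max_tries),
                 check_margins = isTRUE(check_margins)),
            class = "perm_config")
}

#' Single checkerboard swap
#'
#' Draws a 2x2 submatrix of the form `[[1,0],[0,1]]` uniformly at random (by
#' rejection over uniform row-pair/column-pair proposals) and flips it to
#' `[[0,1],[1,0]]`. Row and column totals are conserved exactly. If no
#' swappable submatrix is found within `max_tries` proposals the input is
#' returned unchanged with a warning (frozen matrix).
#'
#' @param occ An `occurrence_matrix` with at least 2 rows and 2 columns.
#' @param max_tries Proposal bound.
#' @return An `occurrence_matrix` with one swap applied.
#' @export
checkerboard_swap <- function(occ, max_tries = 10000) {
  swap_chain(occ, n_swaps = 1, max_tries = max_tries)
}

#' Run a chain of checkerboard swaps
#'
#' @param occ An `occurrence_matrix`.
#' @param n_swaps Number of swaps to apply.
#' @param max_tries Proposal bound per swap.
#' @return An `occurrence_matrix` after `n_swaps` swaps; frozen swaps leave
#'   the matrix unchanged and are reported with a warning.
#' @export
swap_chain <- function(occ, n_swaps, max_tries = 10000) {
  stopifnot(inherits(occ, "occurrence_matrix"))
  if (nrow(occ) < 2 || ncol(occ) < 2) {
    stop("degenerate input: swaps need at least a 2x2 matrix")
  }
  m <- unclass(occ)
  kind <- attr(m, "kind")
  attr(m, "kind") <- NULL
  storage.mode(m) <- "integer"
  res <- cpp_swap_chain(m, as.integer(n_swaps), as.integer(max_tries))
  if (res$n_frozen > 0) {
    warning("matrix frozen for ", res$n_frozen, " of ", n_swaps, " swap(s)")
  }
  out <- res$matrix
  dimnames(out) <- dimnames(occ)
  structure(out, kind = kind, class = c("occurrence_matrix", "matrix", "array"))
}

#' Permutation p-value from a tail count
#'
#' @param count_geq Number of null values at least as extreme as observed.
#' @param n Number of permutations.
#' @param convention `"plus_one"` for `(k + 1) / (n + 1)` (the observed value
#'   is counted as one realization of its own null) or `"raw"` for `k / n`.
#' @return Probability.
#' @export
perm_pvalue <- function(count_geq, n, convention = c("plus_one", "raw")) {
  convention <- match.arg(convention)
  stopifnot(all(count_geq >= 0), all(count_geq <= n))
  if (convention == "plus_one") (count_geq + 1) / (n + 1) else count_geq / n
}

#' Datastream permutation test of an association network
#'
#' Tests non-random network structure against the null model that items are
#' assigned to samples at random, holding fixed the number of samples, the
#' number of items per sample (row totals) and each item's occurrence count
#' (column totals). Randomized datasets are produced by a sequential chain of
#' margin-preserving checkerboard swaps on the occurrence matrix; after each
#' block of swaps the SRI network is recomputed.
#'
#' Two results are produced from the same chain:
#'
#' * Global: the CV of edge weights of the observed network compared with its
#'   null distribution; `global_p` is the proportion of permuted CVs at least
#'   as large as observed (an elevated CV indicates structured association).
#' * Dyadic: for every unordered node pair, the proportion of permuted
#'   weights at least as large (`p_upper`) and at least as small (`p_lower`)
#'   as the observed weight, with ties counted in both tails. Pairs with
#'   `p_upper <= (1 - alpha) / 2` are classified `preferred`, pairs with
#'   `p_lower <= (1 - alpha) / 2` `avoided`, the rest `neutral`.
#'
#' @param occ The observed `occurrence_matrix` (already filtered).
#' @param config A [perm_config()].
#' @param dyads Compute the per-dyad table (default `TRUE`).
#' @param statistic Optional function `occurrence_matrix -> numeric(1)`
#'   replacing the CV of SRI edge weights as the global statistic. The chain
#'   then runs at the R level (slower); dyad tests are unavailable in this
#'   mode.
#' @return A `permutation_report`: list with `observed_cv`, `null_cv`,
#'   `global_p`, `dyads` (data frame `node_a`, `node_b`, `observed_weight`,
#'   `p_upper`, `p_lower`, `class`), `n_frozen`, `frozen` flag, `kind`,
#'   `config`.
#' @export
permutation_test <- function(occ, config = perm_config(), dyads = TRUE,
                             statistic = NULL) {
  stopifnot(inherits(occ, "occurrence_matrix"), inherits(config, "perm_config"))
  if (!is.null(config$seed)) set.seed(config$seed)

  net_obs <- assoc_network(occ)
  observed_cv <- cv_edge_weights(net_obs,
                                 include_zeros = config$include_zero_pairs)

  m <- unclass(occ)
  attr(m, "kind") <- NULL
  storage.mode(m) <- "integer"
  nnz <- sum(m)
  swaps_per <- config$swaps_per_permutation
  if (is.null(swaps_per)) swaps_per <- max(100L, nnz)
  burn_in <- config$burn_in_swaps
  if (is.null(burn_in)) burn_in <- 20L * max(100L, nnz)

  if (!is.null(statistic)) {
    return(null_chain_statistic(occ, m, config, statistic,
                                swaps_per, burn_in))
  }
  res <- cpp_null_chain(m, net_obs$weights,
                        config$n_permutations,
                        as.integer(swaps_per),
                        as.integer(burn_in),
                        if (config$kernel == "trial") 0L else 1L,
                        config$max_tries,
                        config$include_zero_pairs,
                        config$check_margins)

  n <- config$n_permutations
  count_geq_cv <- sum(res$null_cv >= observed_cv - 1e-12, na.rm = TRUE)
  global_p <- perm_pvalue(count_geq_cv, n, config$p_convention)

  dyad_df <- NULL
  if (dyads) {
    p_nodes <- length(net_obs$nodes)
    ut <- which(upper.tri(net_obs$weights), arr.ind = TRUE)
    p_upper <- perm_pvalue(res$count_geq[ut], n, config$p_convention)
    p_lower <- perm_pvalue(res$count_leq[ut], n, config$p_convention)
    thr <- (1 - config$alpha) / 2
    cls <- rep("neutral", nrow(ut))
    cls[p_upper <= thr] <- "preferred"
    cls[p_lower <= thr] <- "avoided"
    dyad_df <- data.frame(
      node_a = net_obs$nodes[ut[, 1]],
      node_b = net_obs$nodes[ut[, 2]],
      observed_weight = net_obs$weights[ut],
      p_upper = p_upper,
      p_lower = p_lower,
      class = cls,
      stringsAsFactors = FALSE
    )
  }

  frozen <- res$n_frozen > 0
  if (frozen) {
    warning("swap chain froze ", res$n_frozen,
            " time(s); null may be non-ergodic")
  }
  if (res$n_accepted == 0) {
    warning("no swap was accepted over the whole chain; null is degenerate")
  }
  structure(list(observed_cv = observed_cv,
                 null_cv = res$null_cv,
                 global_p = global_p,
                 dyads = dyad_df,
                 n_frozen = res$n_frozen,
                 frozen = frozen,
                 n_accepted = res$n_accepted,
                 chain = list(kernel = config$kernel,
                              swaps_per_permutation = swaps_per,
                              burn_in_swaps = burn_in),
                 kind = attr(occ, "kind"),
                 config = config),
            class = "permutation_report")
}

# R-level chain for a user-supplied global statistic
null_chain_statistic <- function(occ, m, config, statistic,
                                 swaps_per, burn_in) {
  observed <- statistic(occ)
  stopifnot(is.numeric(observed), length(observed) == 1L)
  tries <- if (config$kernel == "trial") 1L else config$max_tries
  kind <- attr(occ, "kind")
  wrap <- function(mat) {
    dimnames(mat) <- dimnames(occ)
    structure(mat, kind = kind,
              class = c("occurrence_matrix", "matrix", "array"))
  }
  cur <- m
  res <- cpp_swap_chain(cur, as.integer(burn_in), tries)
  cur <- res$matrix
  null_values <- numeric(config$n_permutations)
  n_frozen <- if (config$kernel == "swap") res$n_frozen else 0L
  for (i in seq_len(config$n_permutations)) {
    res <- cpp_swap_chain(cur, as.integer(swaps_per), tries)
    cur <- res$matrix
    if (config$kernel == "swap") n_frozen <- n_frozen + res$n_frozen
    if (config$check_margins) {
      stopifnot(all(rowSums(cur) == unname(rowSums(m))),
                all(colSums(cur) == unname(colSums(m))))
    }
    null_values[i] <- statistic(wrap(cur))
  }
  count_geq <- sum(null_values >= observed - 1e-12, na.rm = TRUE)
  structure(list(observed_cv = observed,
                 null_cv = null_values,
                 global_p = perm_pvalue(count_geq, config$n_permutations,
                                        config$p_convention),
                 dyads = NULL,
                 n_frozen = n_frozen,
                 frozen = n_frozen > 0,
                 n_accepted = NA_real_,
                 chain = list(kernel = config$kernel,
                              swaps_per_permutation = swaps_per,
                              burn_in_swaps = burn_in),
                 kind = kind,
                 config = config),
            class = "permutation_report")
}

#' @export
print.permutation_report <- function(x, ...) {
  cat("Datastream permutation test (", x$kind, ")\n", sep = "")
  cat("  permutations:", x$config$n_permutations,
      " observed CV:", round(x$observed_cv, 4),
      " null CV mean:", round(mean(x$null_cv, na.rm = TRUE), 4), "\n")
  cat("  global p (CV):", format.pval(x$global_p, digits = 3), "\n")
  if (!is.null(x$dyads)) {
    tab <- table(factor(x$dyads$class,
                        levels = c("preferred", "neutral", "avoided")))
    cat("  dyads: ", tab[["preferred"]], " preferred, ",
        tab[["avoided"]], " avoided, ", tab[["neutral"]], " neutral (alpha = ",
        x$config$alpha, ")\n", sep = "")
  }
  if (x$frozen) cat("  WARNING: chain froze", x$n_frozen, "time(s)\n")
  invisible(x)
}
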