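#' Mantel correlation between two association networks
#'
#' Restricts both weight matrices to their shared node labels (in a common
#' order), correlates the vectorized upper triangles (diagonal excluded) with
#' Pearson's r, and assesses significance by simultaneously permuting the
#' rows and columns of the second matrix. The reported p is two-tailed
#' (`P(|r_perm| >= |r_obs|)`) under the `(k + 1) / (n + 1)` convention.
#'
#' @param net1,net2 `assoc_network` objects sharing at least 3 node labels.
#' @param n_permutations Number of node relabelings (default 10,000).
#' @param seed Optional RNG seed.
#' @return A `mantel_result`: list with `r`, `p`, `n_shared_nodes`,
#'   `shared_nodes`, `n_permutations`, `seed`.
#' @export
mantel_test <- function(net1, net2, n_permutations = 10000, seed = NULL) {
  stopifnot(inherits(net1, "assoc_network"), inherits(net2, "assoc_network"))
  shared <- intersect(net1$nodes, net2$nodes)
  if (length(shared) < 3) {
    stop("degenerate input: Mantel test needs at least 3 shared nodes, got ",
         length(shared))
  }
  if (!is.null(seed)) set.seed(seed)
  m1 <- net1$weights[shared, shared]
  m2 <- net2$weights[shared, shared]
  ut <- upper.tri(m1)
  v1 <- m1[ut]
  r_obs <- stats::cor(v1, m2[ut])

  k <- length(shared)
  count_geq <- 0L
  for (i in seq_len(n_permutations)) {
    idx <- sample.int(k)
    r_perm <- stats::cor(v1, m2[idx, idx][ut])
    if (abs(r_perm) >= abs(r_obs) - 1e-12) count_geq <- count_geq + 1L
  }
  p <- (count_geq + 1) / (n_permutations + 1)

  structure(list(r = r_obs, p = p, n_shared_nodes = k,
                 shared_nodes = shared, n_permutations = n_permutations,
                 seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat("Mantel matrix correlation\n")
  cat("  r =", round(x$r, 4), " n =", x$n_shared_nodes,
      " p =", format.pval(x$p, digits = 3),
      "(", x$n_permutations, "permutations, two-tailed )\n")
  invisible(x)
}
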