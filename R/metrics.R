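#' Network density
#'
#' The number of edges (unordered pairs with positive weight) as a proportion
#' of the possible number: `2E / (n (n - 1))`.
#'
#' @param net An `assoc_network` with at least 2 nodes.
#' @return Density in `[0, 1]`.
#' @export
network_density <- function(net) {
  stopifnot(inherits(net, "assoc_network"))
  n <- length(net$nodes)
  if (n < 2) stop("degenerate input: density needs at least 2 nodes")
  e <- sum(net$weights[upper.tri(net$weights)] > 0)
  2 * e / (n * (n - 1))
}

#' Coefficient of variation of edge weights
#'
#' Sample SD divided by mean of the dyadic edge weights. By default the
#' statistic is taken over all unordered node pairs including zero-weight
#' dyads, the convention of association-matrix analysis (the permutation null
#' varies the zeros too); `include_zeros = FALSE` restricts to realized edges.
#'
#' @param net An `assoc_network`.
#' @param include_zeros Include zero-weight dyads (default `TRUE`).
#' @return CV (a nonnegative ratio).
#' @export
cv_edge_weights <- function(net, include_zeros = TRUE) {
  stopifnot(inherits(net, "assoc_network"))
  w <- net$weights[upper.tri(net$weights)]
  if (!include_zeros) w <- w[w > 0]
  if (length(w) < 2) stop("degenerate input: CV needs at least 2 dyads")
  m <- mean(w)
  if (m == 0) stop("undefined statistic: mean edge weight is 0")
  stats::sd(w) / m
}

#' Weighted betweenness centrality
#'
#' Freeman betweenness over weighted shortest paths, with fractional credit
#' across equally short paths. Two weight conventions are exposed:
#' `"cost"` passes the association weights directly as path lengths (the
#' convention of the graph libraries whose weighted betweenness treats the
#' weight attribute as a distance), and `"similarity_reciprocal"` uses
#' `1/weight` so that strong associations give short paths. Disconnected
#' pairs contribute nothing.
#'
#' @param net An `assoc_network` with at least 3 nodes.
#' @param weight_mode `"cost"` (default) or `"similarity_reciprocal"`.
#' @return Named numeric vector of betweenness scores.
#' @export
node_betweenness <- function(net, weight_mode = c("cost",
                                                  "similarity_reciprocal")) {
  stopifnot(inherits(net, "assoc_network"))
  weight_mode <- match.arg(weight_mode)
  if (length(net$nodes) < 3) {
    stop("degenerate input: betweenness needs at least 3 nodes")
  }
  g <- as_igraph(net)
  w <- igraph::E(g)$weight
  if (weight_mode == "similarity_reciprocal") w <- 1 / w
  b <- igraph::betweenness(g, weights = w, directed = FALSE)
  b[net$nodes]
}

#' Betweenness table
#'
#' @param net An `assoc_network`.
#' @param weight_mode See [node_betweenness()].
#' @return Data frame `node`, `betweenness`, sorted decreasing.
#' @export
betweenness_table <- function(net, weight_mode = "cost") {
  b <- node_betweenness(net, weight_mode)
  out <- data.frame(node = names(b), betweenness = unname(b))
  out <- out[order(-out$betweenness, out$node), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Walktrap community detection
#'
#' Detects subgroups with the walktrap algorithm (short random walks, 4 steps
#' by default, transition probabilities proportional to edge weight), cutting
#' the agglomerative dendrogram at the level maximizing modularity. Connected
#' components are handled independently; isolated nodes form singleton
#' modules.
#'
#' @param net An `assoc_network`.
#' @param steps Random-walk length (default 4).
#' @return A `community_partition`: list with `assignment` (named integer,
#'   node to module id), `n_modules`, and `modularity` (weighted Newman Q of
#'   the assignment on this network).
#' @export
walktrap_communities <- function(net, steps = 4) {
  stopifnot(inherits(net, "assoc_network"))
  g <- as_igraph(net)
  comp <- igraph::components(g)
  assignment <- stats::setNames(integer(length(net$nodes)), net$nodes)
  next_id <- 0L
  for (k in seq_len(comp$no)) {
    members <- names(comp$membership)[comp$membership == k]
    if (length(members) == 1L || sum(net$weights[members, members]) == 0) {
      assignment[members] <- next_id + 1L
      next_id <- next_id + 1L
      next
    }
    sub <- igraph::induced_subgraph(g, members)
    wt <- igraph::cluster_walktrap(sub, weights = igraph::E(sub)$weight,
                                   steps = steps)
    mem <- igraph::membership(wt)
    assignment[names(mem)] <- next_id + as.integer(mem)
    next_id <- next_id + max(as.integer(mem))
  }
  partition <- list(assignment = assignment,
                    n_modules = length(unique(assignment)),
                    modularity = newman_modularity(net, assignment))
  class(partition) <- "community_partition"
  partition
}

#' @export
print.community_partition <- function(x, ...) {
  cat("Community partition:", x$n_modules, "modules, modularity Q =",
      round(x$modularity, 4), "\n")
  invisible(x)
}

#' Weighted Newman modularity
#'
#' For a module assignment, `Q = sum_c ( w_in_c / W - (s_c / (2 W))^2 )`
#' where `W` is the total edge weight, `w_in_c` the weight within module `c`
#' and `s_c` the summed node strength of module `c`. Q is the proportion of
#' edge weight falling within modules minus its expectation under a
#' strength-preserving random graph, and lies in `[-0.5, 1]`.
#'
#' @param net An `assoc_network`.
#' @param assignment Named vector (or vector in node order) of module labels.
#' @return Q score.
#' @export
newman_modularity <- function(net, assignment) {
  stopifnot(inherits(net, "assoc_network"))
  if (!is.null(names(assignment))) {
    stopifnot(setequal(names(assignment), net$nodes))
    assignment <- assignment[net$nodes]
  } else {
    stopifnot(length(assignment) == length(net$nodes))
  }
  w <- net$weights
  total <- sum(w) / 2
  if (total == 0) return(0)
  strength <- rowSums(w)
  q <- 0
  for (mod in unique(assignment)) {
    sel <- assignment == mod
    w_in <- sum(w[sel, sel, drop = FALSE]) / 2
    s_c <- sum(strength[sel])
    q <- q + w_in / total - (s_c / (2 * total))^2
  }
  q
}

#' Structural metrics report
#'
#' Bundles density, coefficient of variation of edge weights, weighted
#' betweenness and the walktrap partition with its modularity.
#'
#' @param net An `assoc_network`.
#' @param weight_mode Betweenness weight convention (see
#'   [node_betweenness()]).
#' @param include_zeros CV dyad set (see [cv_edge_weights()]).
#' @param steps Walktrap walk length.
#' @return A `network_metrics` list with elements `kind`, `n_nodes`,
#'   `n_edges`, `density`, `cv_edge_weights`, `betweenness`, `partition`, and
#'   the options used.
#' @export
network_metrics <- function(net, weight_mode = "cost", include_zeros = TRUE,
                            steps = 4) {
  stopifnot(inherits(net, "assoc_network"))
  partition <- walktrap_communities(net, steps = steps)
  out <- list(
    kind = net$kind,
    n_nodes = length(net$nodes),
    n_edges = nrow(edge_list(net)),
    density = network_density(net),
    cv_edge_weights = cv_edge_weights(net, include_zeros = include_zeros),
    betweenness = node_betweenness(net, weight_mode),
    partition = partition,
    options = list(weight_mode = weight_mode, include_zeros = include_zeros,
                   steps = steps)
  )
  class(out) <- "network_metrics"
  out
}

#' @export
print.network_metrics <- function(x, ...) {
  cat("Network metrics (", x$kind, ")\n", sep = "")
  cat("  nodes:", x$n_nodes, " edges:", x$n_edges, "\n")
  cat("  density:", round(x$density, 3),
      " CV(edge weights):", round(x$cv_edge_weights, 3), "\n")
  cat("  modularity (walktrap,", x$options$steps, "steps):",
      round(x$partition$modularity, 3),
      "over", x$partition$n_modules, "modules\n")
  top <- utils::head(sort(x$betweenness, decreasing = TRUE), 5)
  cat("  top betweenness:",
      paste(names(top), round(top, 1), sep = "=", collapse = ", "), "\n")
  invisible(x)
}
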