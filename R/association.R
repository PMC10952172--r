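#' Simple Ratio Index between two items
#'
#' For items `a` and `b` of a binary occurrence matrix, counts the samples
#' containing both (`x`), only `a` (`y_a`) and only `b` (`y_b`), and returns
#' `x / (x + y_a + y_b)`: the proportion of samples containing either item in
#' which both co-occur. Because a sample here is a single response list, the
#' classical "seen in the same period but apart" term of the index is
#' structurally zero, so the denominator reduces to the three terms above.
#'
#' @param occ An `occurrence_matrix`.
#' @param a,b Distinct column labels.
#' @return A weight in `[0, 1]`; 0 when the denominator is 0 (neither item
#'   occurs), with a warning.
#' @export
sri <- function(occ, a, b) {
  stopifnot(inherits(occ, "occurrence_matrix"))
  if (identical(a, b)) stop("sri requires two distinct items")
  for (lab in c(a, b)) {
    if (!lab %in% colnames(occ)) stop("unknown item: ", lab)
  }
  va <- occ[, a] == 1L
  vb <- occ[, b] == 1L
  x <- sum(va & vb)
  denom <- sum(va | vb)
  if (denom == 0L) {
    warning("sri denominator is zero for pair (", a, ", ", b, "); returning 0")
    return(0)
  }
  x / denom
}

#' Build a Simple-Ratio-Index association network
#'
#' Computes the SRI for every unordered pair of items in an occurrence matrix,
#' yielding a symmetric weighted association network whose nodes are the
#' matrix's items. Node occurrence counts (column totals) are carried along;
#' they are the `y`-term inputs of the index and the counts the
#' node-frequency filter acts on.
#'
#' Pairs with a zero denominator (possible only in derived matrices where a
#' retained node shares no samples with another) receive weight 0; a single
#' warning reports how many such pairs occurred.
#'
#' @param occ An `occurrence_matrix` (see [build_occurrence()]).
#' @return An `assoc_network` object: list with `weights` (symmetric numeric
#'   matrix, zero diagonal), `nodes`, `node_counts`, `kind`, `n_samples`.
#' @examples
#' s <- as_survey(data.frame(
#'   participant_id = c("p1", "p1", "p2", "p3"),
#'   identity = c("a", "b", "a", "b"),
#'   behaviour = ""
#' ))
#' net <- assoc_network(build_occurrence(s, "identity_by_identity"))
#' net$weights
#' @export
assoc_network <- function(occ) {
  stopifnot(inherits(occ, "occurrence_matrix"))
  m <- unclass(occ)
  attr(m, "kind") <- NULL
  storage.mode(m) <- "double"
  x <- crossprod(m)                       # co-occurrence counts
  cnt <- diag(x)
  denom <- outer(cnt, cnt, "+") - x       # x + y_a + y_b
  zero_denom <- denom == 0
  w <- ifelse(zero_denom, 0, x / ifelse(zero_denom, 1, denom))
  diag(w) <- 0
  off_zero <- sum(zero_denom[upper.tri(zero_denom)])
  if (off_zero > 0) {
    warning(off_zero, " node pair(s) share no samples with nonzero margin; ",
            "assigned weight 0")
  }
  structure(
    list(weights = w,
         nodes = colnames(m),
         node_counts = stats::setNames(as.integer(cnt), colnames(m)),
         kind = attr(occ, "kind"),
         n_samples = nrow(m)),
    class = "assoc_network"
  )
}

#' @export
print.assoc_network <- function(x, ...) {
  el <- edge_list(x)
  cat("SRI association network (", x$kind, ")\n", sep = "")
  cat("  nodes:", length(x$nodes), " samples:", x$n_samples,
      " edges (weight > 0):", nrow(el), "\n")
  if (nrow(el) > 0) {
    cat("  edge weights: min ", signif(min(el$weight), 3),
        ", median ", signif(stats::median(el$weight), 3),
        ", max ", signif(max(el$weight), 3), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.assoc_network <- function(object, ...) {
  network_metrics(object, ...)
}

#' Edge list of an association network
#'
#' @param net An `assoc_network`.
#' @param keep_zero If `TRUE`, include all unordered pairs, not only the
#'   pairs with positive weight.
#' @return A data frame `node_a`, `node_b`, `weight`, each unordered pair at
#'   most once, sorted by decreasing weight.
#' @export
edge_list <- function(net, keep_zero = FALSE) {
  stopifnot(inherits(net, "assoc_network"))
  w <- net$weights
  ut <- upper.tri(w)
  idx <- which(ut, arr.ind = TRUE)
  el <- data.frame(node_a = net$nodes[idx[, 1]],
                   node_b = net$nodes[idx[, 2]],
                   weight = w[ut])
  if (!keep_zero) el <- el[el$weight > 0, , drop = FALSE]
  el <- el[order(-el$weight, el$node_a, el$node_b), , drop = FALSE]
  rownames(el) <- NULL
  el
}

#' Convert an association network to an igraph graph
#'
#' Zero-weight pairs become absent edges; node occurrence counts are attached
#' as the vertex attribute `count`.
#'
#' @param net An `assoc_network`.
#' @return An undirected weighted [igraph][igraph::graph_from_adjacency_matrix]
#'   graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "assoc_network"))
  g <- igraph::graph_from_adjacency_matrix(net$weights, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$count <- as.numeric(net$node_counts[igraph::V(g)$name])
  g
}

#' Export an association network to GraphML
#'
#' @param net An `assoc_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  g <- as_igraph(net)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Plot an association network
#'
#' Thin wrapper over igraph plotting: vertex size scales with node occurrence
#' count, edge width with SRI weight.
#'
#' @param x An `assoc_network`.
#' @param ... Passed to [igraph::plot.igraph()].
#' @export
plot.assoc_network <- function(x, ...) {
  g <- as_igraph(x)
  cnt <- igraph::V(g)$count
  igraph::plot.igraph(
    g,
    vertex.size = 4 + 10 * cnt / max(cnt),
    edge.width = 0.5 + 4 * igraph::E(g)$weight / max(igraph::E(g)$weight),
    vertex.label.cex = 0.7, ...)
  invisible(x)
}
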