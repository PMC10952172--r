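# Independent oracles and fixture builders. Everything here is deliberately
# brute-force and shares no code with the package internals it checks.

make_occ <- function(m, kind = "identity_by_identity") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("s%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("i%02d", seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  structure(m, kind = kind, class = c("occurrence_matrix", "matrix", "array"))
}

make_net <- function(w, kind = "identity_by_identity") {
  if (is.null(colnames(w))) {
    dimnames(w) <- list(sprintf("n%02d", seq_len(ncol(w))),
                        sprintf("n%02d", seq_len(ncol(w))))
  }
  structure(list(weights = w, nodes = colnames(w),
                 node_counts = stats::setNames(rep(1L, ncol(w)), colnames(w)),
                 kind = kind, n_samples = 0L),
            class = "assoc_network")
}

# random binary matrix guaranteed to have no empty row or column (empty rows
# and columns get one incidence planted at a uniform position)
random_occurrence <- function(n, p, fill = 0.3) {
  m <- matrix(rbinom(n * p, 1, fill), n, p)
  for (i in which(rowSums(m) == 0)) m[i, sample.int(p, 1)] <- 1L
  for (j in which(colSums(m) == 0)) m[sample.int(n, 1), j] <- 1L
  make_occ(m)
}

# double-loop counting oracle for the Simple Ratio Index
oracle_sri_matrix <- function(m) {
  p <- ncol(m)
  w <- matrix(0, p, p)
  for (a in seq_len(p)) {
    for (b in seq_len(p)) {
      if (a == b) next
      x <- ya <- yb <- 0
      for (i in seq_len(nrow(m))) {
        if (m[i, a] == 1 && m[i, b] == 1) x <- x + 1
        else if (m[i, a] == 1) ya <- ya + 1
        else if (m[i, b] == 1) yb <- yb + 1
      }
      w[a, b] <- if (x + ya + yb > 0) x / (x + ya + yb) else 0
    }
  }
  dimnames(w) <- list(colnames(m), colnames(m))
  w
}

# exhaustive simple-path enumeration oracle for weighted betweenness;
# lengths must be exactly representable so ties are detected exactly
oracle_betweenness <- function(w, mode = c("cost", "similarity_reciprocal")) {
  mode <- match.arg(mode)
  n <- nrow(w)
  len <- ifelse(w > 0, if (mode == "cost") w else 1 / w, Inf)
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- list()
      rec <- function(path) {
        v <- path[length(path)]
        if (v == t) {
          paths[[length(paths) + 1]] <<- path
          return()
        }
        for (u in which(is.finite(len[v, ]))) {
          if (!(u %in% path)) rec(c(path, u))
        }
      }
      rec(s)
      if (length(paths) == 0) next
      lens <- vapply(paths, function(p)
        sum(len[cbind(p[-length(p)], p[-1])]), numeric(1))
      short <- paths[lens == min(lens)]
      for (p in short) {
        for (v in setdiff(p, c(s, t))) btw[v] <- btw[v] + 1 / length(short)
      }
    }
  }
  names(btw) <- colnames(w)
  btw
}

# all set partitions of n elements, as restricted-growth assignments
all_partitions <- function(n) {
  out <- list()
  rec <- function(assign, k) {
    if (length(assign) == n) {
      out[[length(out) + 1]] <<- assign
      return()
    }
    for (g in seq_len(k + 1)) rec(c(assign, g), max(k, g))
  }
  rec(integer(0), 0L)
  out
}

oracle_max_modularity <- function(net) {
  parts <- all_partitions(length(net$nodes))
  qs <- vapply(parts, function(a) newman_modularity(net, a), numeric(1))
  list(q = max(qs), partition = parts[[which.max(qs)]])
}

# random connected weighted graph with exactly representable edge lengths:
# weights k/64 for "cost" mode, 64/k (so 1/w = k/64) for reciprocal mode
random_connected_net <- function(n, mode = c("cost", "similarity_reciprocal"),
                                 p_edge = 0.6) {
  mode <- match.arg(mode)
  repeat {
    adj <- matrix(0, n, n)
    for (a in seq_len(n - 1)) {
      for (b in (a + 1):n) {
        if (runif(1) < p_edge) {
          k <- sample(1:32, 1)
          adj[a, b] <- adj[b, a] <- if (mode == "cost") k / 64 else 64 / k
        }
      }
    }
    # BFS connectivity check
    seen <- logical(n)
    seen[1] <- TRUE
    queue <- 1L
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      nb <- which(adj[v, ] > 0 & !seen)
      seen[nb] <- TRUE
      queue <- c(queue, nb)
    }
    if (all(seen)) return(make_net(adj))
  }
}

# weight matrix of two disjoint equally weighted cliques
two_cliques <- function(size = 3, weight = 1) {
  n <- 2 * size
  w <- matrix(0, n, n)
  w[seq_len(size), seq_len(size)] <- weight
  w[(size + 1):n, (size + 1):n] <- weight
  diag(w) <- 0
  w
}

toy_survey <- function() {
  as_survey(data.frame(
    participant_id = c("p1", "p1", "p2", "p3", "p3"),
    identity = c("a", "b", "a", "b", "c"),
    behaviour = c("x", "", "x", "y", "")
  ))
}
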