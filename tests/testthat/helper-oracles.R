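# Independent brute-force oracles used to validate the fast implementations.

# Coreness by definition: the largest k such that the node survives in the
# maximal subgraph of minimum degree k, found by repeated deletion at each
# candidate k independently (no bucket peeling shared with the implementation).
oracle_coreness <- function(graph) {
  labels <- igraph::V(graph)$name
  n <- length(labels)
  ks <- stats::setNames(integer(n), labels)
  maxdeg <- if (n && igraph::ecount(graph)) max(igraph::degree(graph)) else 0L
  for (k in seq_len(maxdeg)) {
    sub <- graph
    repeat {
      low <- which(igraph::degree(sub) < k)
      if (length(low) == 0L) break
      sub <- igraph::delete_vertices(sub, low)
    }
    survivors <- igraph::V(sub)$name
    ks[survivors] <- k
  }
  ks
}

# Closed-neighborhood Jaccard by explicit set enumeration.
oracle_jaccard <- function(graph, vi, vj) {
  labels <- igraph::V(graph)$name
  closed <- function(v) {
    i <- match(v, labels)
    union(v, labels[as.integer(igraph::adjacent_vertices(graph, i)[[1]])])
  }
  a <- closed(vi); b <- closed(vj)
  length(intersect(a, b)) / length(union(a, b))
}

# Kendall tau-a by exhaustive double loop over all pairs.
oracle_kendall <- function(x, y) {
  n <- length(x)
  nc <- 0L; nd <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- x[i] - x[j]; b <- y[i] - y[j]
      if (a * b > 0) nc <- nc + 1L
      else if (a * b < 0) nd <- nd + 1L
    }
  }
  list(nc = nc, nd = nd, tau = 2 * (nc - nd) / (n * (n - 1)))
}

# GLI influence computed naively from first principles (per-node helper
# functions are avoided; only definitions are used).
oracle_gli <- function(graph) {
  labels <- igraph::V(graph)$name
  deg <- igraph::degree(graph)
  ks <- igraph::coreness(graph)   # independent coreness route
  maxD <- if (length(deg) && max(deg) > 0) max(deg) else 0
  vapply(labels, function(v) {
    nbrs <- names(igraph::neighbors(graph, v))
    s <- sum(vapply(nbrs, function(u)
      deg[[u]] * oracle_jaccard(graph, v, u) + ks[[u]], numeric(1)))
    unname(deg[[v]] + (if (maxD > 0) s / maxD else 0) + ks[[v]])
  }, numeric(1))
}

random_named_gnp <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::set_vertex_attr(g, "name", value = paste0("n", seq_len(n)))
}

# Relabel a graph's vertices by a fixed permutation of fresh labels.
relabel_graph <- function(graph, seed = 1) {
  set.seed(seed)
  labels <- igraph::V(graph)$name
  new <- paste0("x", sample(seq_along(labels)))
  igraph::set_vertex_attr(graph, "name", value = new)
}

# Absolute-tolerance comparison for published table cells (printed to 6-7
# significant digits; truncation makes relative comparison too strict).
expect_close <- function(object, expected, tol = 1e-6) {
  testthat::expect_lt(max(abs(object - expected)), tol)
}
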