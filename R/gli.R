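#' Closed neighborhood of a node
#'
#' The node itself together with all of its neighbors. This is the set the
#' GLI similarity coefficient operates on; including the focal node makes the
#' similarity of two adjacent nodes count their shared edge.
#'
#' @param graph an undirected [igraph::igraph] with named vertices.
#' @param v node label.
#' @return character vector of node labels, sorted.
#' @export
closed_neighborhood <- function(graph, v) {
  graph <- as_glinet_graph(graph)
  i <- node_index(graph, v)
  labels <- igraph::V(graph)$name
  sort(unique(c(labels[i],
                labels[as.integer(igraph::adjacent_vertices(graph, i)[[1]])])))
}

#' Jaccard similarity of closed neighborhoods
#'
#' \deqn{Jacc(v_i, v_j) = \frac{|n(v_i) \cap n(v_j)|}{|n(v_i) \cup n(v_j)|}}
#' where \eqn{n(v)} is the closed neighborhood of v (neighbors plus v
#' itself). Because each closed set contains its own node the union is never
#' empty, so the ratio is defined for every node pair, including isolated
#' nodes; `jaccard_similarity(g, v, v)` is always 1.
#'
#' @inheritParams closed_neighborhood
#' @param vi,vj node labels.
#' @return a number in \[0, 1\].
#' @examples
#' g <- worked_example_graph()
#' jaccard_similarity(g, "v1", "v2")  # 0.625
#' @export
jaccard_similarity <- function(graph, vi, vj) {
  graph <- as_glinet_graph(graph)
  idx <- node_index(graph, c(vi, vj))
  cl <- closed_index(graph)
  a <- cl[[idx[1]]]
  b <- cl[[idx[2]]]
  inter <- sum(a %in% b)
  inter / (length(a) + length(b) - inter)
}

# Closed neighborhoods as sorted integer index vectors, one per vertex.
closed_index <- function(graph) {
  adj <- adjacency_index(graph)
  lapply(seq_along(adj), function(i) sort(c(i, adj[[i]])))
}

#' Given value of a neighbor
#'
#' The influence contribution a neighbor vj donates to a focal node vi:
#' \deqn{\Pi(v_j) = d(v_j) \times Jacc(v_i, v_j) + Ks(v_j)}
#' i.e. the neighbor's degree scaled by how much its closed neighborhood
#' overlaps the focal node's, plus the neighbor's shell index. Neighbors with
#' identical degree and shell but different overlap therefore contribute
#' differently, which is what lets the score separate nodes that coarser
#' methods tie.
#'
#' @inheritParams closed_neighborhood
#' @param shells named integer vector from [kshell_decompose()]; computed if
#'   missing.
#' @param vi focal node label.
#' @param vj neighbor label; must be adjacent to `vi`.
#' @return the given value, a non-negative number.
#' @examples
#' g <- worked_example_graph()
#' given_value(g, vi = "v1", vj = "v2")  # 5 * 0.625 + 3 = 6.125
#' @export
given_value <- function(graph, shells = NULL, vi, vj) {
  graph <- as_glinet_graph(graph)
  idx <- node_index(graph, c(vi, vj))
  adj <- adjacency_index(graph)
  if (!idx[2] %in% adj[[idx[1]]]) {
    stop(vj, " is not adjacent to ", vi, call. = FALSE)
  }
  if (is.null(shells)) shells <- kshell_decompose(graph)
  d <- igraph::degree(graph)
  unname(d[idx[2]] * jaccard_similarity(graph, vi, vj) +
           shells[[as.character(vj)]])
}

#' Sum of neighbor given values
#'
#' Adds up the given value of every neighbor of `vi`; 0 for an isolated
#' node. Values are sorted before summation so the result does not depend on
#' adjacency storage order even at floating-point rounding level.
#'
#' @inheritParams given_value
#' @return a non-negative number.
#' @export
neighbor_sum <- function(graph, shells = NULL, vi) {
  graph <- as_glinet_graph(graph)
  i <- node_index(graph, vi)
  if (is.null(shells)) shells <- kshell_decompose(graph)
  labels <- igraph::V(graph)$name
  nbrs <- labels[adjacency_index(graph)[[i]]]
  if (length(nbrs) == 0L) return(0)
  vals <- vapply(nbrs, function(u) given_value(graph, shells, vi, u),
                 numeric(1))
  sum(sort(unname(vals)))
}

#' Local influence of a node
#'
#' The local term of the GLI score: the node's own degree (its personal
#' influence P) plus the sum of its neighbors' given values normalized by the
#' network maximum degree, N = Sum / maxD. Normalizing by maxD puts the
#' neighbor contribution on the scale of the best-connected node in the
#' network; maxD is the global maximum, computed once per graph.
#'
#' @inheritParams given_value
#' @param maxD the network-wide maximum degree; computed from `graph` if
#'   missing. When the graph is edgeless, N is defined as 0.
#' @return a list with components `P`, `N` and `Local = P + N`.
#' @export
local_influence <- function(graph, shells = NULL, vi, maxD = NULL) {
  graph <- as_glinet_graph(graph)
  i <- node_index(graph, vi)
  if (is.null(shells)) shells <- kshell_decompose(graph)
  if (is.null(maxD)) maxD <- degree_map(graph)$max_degree
  P <- unname(igraph::degree(graph)[i])
  s <- neighbor_sum(graph, shells, vi)
  N <- if (maxD > 0) s / maxD else 0
  list(P = P, N = N, Local = P + N)
}

#' GLI influence score for every node of a network
#'
#' Scores each node by combining global and local information:
#' \deqn{I(v_i) = Local(v_i) + Global(v_i)}
#' where the global term is the K-shell index Ks(vi) and the local term is
#' \deqn{Local(v_i) = d(v_i) + \frac{1}{maxD}\sum_{v_j \in \Gamma(v_i)}
#'   \left[ d(v_j) \, Jacc(v_i, v_j) + Ks(v_j) \right].}
#' The K-shell term places the node in the network's global hierarchy; the
#' local term refines that coarse layering using the node's degree and its
#' neighbors' degree, shell and closed-neighborhood Jaccard overlap. Higher
#' scores mean more influential nodes. Degree-0 nodes score exactly 0.
#'
#' The result is deterministic for a given graph and invariant (up to label
#' mapping) under relabeling and edge-list order.
#'
#' @param graph an undirected, unweighted [igraph::igraph] with named
#'   vertices, e.g. from [read_edge_list()] or [synthetic_network()].
#' @return an object of class `"gli"`: a list with components
#'   \describe{
#'     \item{table}{data frame with one row per node and columns `node`,
#'       `P` (degree), `Sum`, `N`, `Local`, `Global` (Ks) and `I`, in vertex
#'       order, plus `rank` (1 = most influential, ties broken by ascending
#'       node label);}
#'     \item{max_degree}{the maxD normalizer used;}
#'     \item{n_nodes, n_edges}{graph size.}
#'   }
#' @examples
#' fit <- gli(worked_example_graph())
#' fit
#' top_k(fit, 4)  # "v1" "v2" "v4" "v3"
#' @seealso [rank_nodes()], [top_k()], [baseline_scores()]
#' @export
gli <- function(graph) {
  graph <- as_glinet_graph(graph)
  n <- igraph::vcount(graph)
  labels <- igraph::V(graph)$name
  adj <- adjacency_index(graph)
  d <- lengths(adj)
  maxD <- if (n > 0L) max(d, 0L) else 0L
  ks <- unname(kshell_decompose(graph))
  cl <- closed_index(graph)

  Sum <- numeric(n)
  for (i in seq_len(n)) {
    nbrs <- adj[[i]]
    if (length(nbrs) == 0L) next
    a <- cl[[i]]
    vals <- vapply(nbrs, function(j) {
      b <- cl[[j]]
      inter <- sum(a %in% b)
      jac <- inter / (length(a) + length(b) - inter)
      d[j] * jac + ks[j]
    }, numeric(1))
    Sum[i] <- sum(sort(vals))
  }
  N <- if (maxD > 0) Sum / maxD else numeric(n)
  Local <- d + N
  I <- Local + ks
  tab <- data.frame(node = labels, P = as.integer(d), Sum = Sum, N = N,
                    Local = Local, Global = as.integer(ks), I = I,
                    stringsAsFactors = FALSE, row.names = NULL)
  ord <- order(-I, labels, method = "radix")
  tab$rank <- integer(n)
  tab$rank[ord] <- seq_len(n)
  structure(list(table = tab, max_degree = maxD, n_nodes = n,
                 n_edges = igraph::ecount(graph)),
            class = "gli")
}

#' @export
print.gli <- function(x, n = 10L, ...) {
  cat(sprintf("GLI influence scores: %d nodes, %d edges (maxD = %d)\n",
              x$n_nodes, x$n_edges, x$max_degree))
  tab <- x$table[order(x$table$rank), , drop = FALSE]
  show <- utils::head(tab, n)
  print(format(show, digits = 6), row.names = FALSE)
  if (nrow(tab) > n) cat("... and", nrow(tab) - n, "more nodes\n")
  invisible(x)
}

#' @export
summary.gli <- function(object, ...) {
  tab <- object$table
  cat(sprintf("GLI scores over %d nodes, %d edges\n",
              object$n_nodes, object$n_edges))
  cat(sprintf("  maxD = %d, shells 0..%d\n", object$max_degree,
              if (nrow(tab)) max(tab$Global) else 0L))
  cat("  influence I: ")
  print(summary(tab$I))
  invisible(object)
}

#' @export
as.data.frame.gli <- function(x, ...) x$table

#' @export
coef.gli <- function(object, ...) {
  stats::setNames(object$table$I, object$table$node)
}

#' Rank-order plot of GLI scores
#'
#' Plots influence against rank, split into the global (Ks) and local
#' contributions, which shows how the local term refines the coarse K-shell
#' layering.
#'
#' @param x a `"gli"` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.gli <- function(x, ...) {
  tab <- x$table[order(x$table$rank), , drop = FALSE]
  graphics::plot(seq_len(nrow(tab)), tab$I, type = "b", pch = 16,
                 xlab = "rank", ylab = "influence I", ...)
  graphics::points(seq_len(nrow(tab)), tab$Global, type = "s", col = 2)
  graphics::legend("topright", legend = c("I = Local + Ks", "Ks (global term)"),
                   col = c(1, 2), pch = c(16, NA), lty = c(1, 1), bty = "n")
  invisible(x)
}

#' Rank nodes by score
#'
#' Orders nodes by non-increasing score; ties are broken by ascending node
#' label, so the ranking is stable and fully documented.
#'
#' @param scores a `"gli"` object or a named numeric vector of scores.
#' @return character vector of node labels, most influential first.
#' @export
rank_nodes <- function(scores) {
  s <- as_score_vector(scores)
  names(s)[order(-s, names(s), method = "radix")]
}

as_score_vector <- function(scores) {
  if (inherits(scores, "gli")) {
    return(stats::setNames(scores$table$I, scores$table$node))
  }
  if (is.numeric(scores) && !is.null(names(scores))) return(scores)
  stop("`scores` must be a \"gli\" object or a named numeric vector",
       call. = FALSE)
}
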