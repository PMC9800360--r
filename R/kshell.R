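#' K-shell (coreness) decomposition
#'
#' Iterative peeling: for k = 0, 1, 2, ... repeatedly delete every node whose
#' current degree is at most k until none remain; a node's shell index Ks is
#' the value of k at which it was deleted. Equivalently, Ks(v) is the largest
#' k such that v belongs to the maximal subgraph of minimum degree k (the
#' k-core). Isolated nodes are peeled at k = 0 and receive shell 0, which
#' keeps every downstream formula defined on networks with degree-0 nodes
#' (protein-interaction graphs routinely contain them).
#'
#' The peeling is driven by a degree-bucket queue, so the decomposition runs
#' in near-linear time in the number of edges.
#'
#' @param graph an undirected [igraph::igraph] with named vertices.
#' @return named integer vector of shell indices, one per node, in vertex
#'   order.
#' @examples
#' g <- worked_example_graph()
#' kshell_decompose(g)[c("v1", "v5")]  # 3 and 2
#' @export
kshell_decompose <- function(graph) {
  graph <- as_glinet_graph(graph)
  n <- igraph::vcount(graph)
  labels <- igraph::V(graph)$name
  if (n == 0L) return(stats::setNames(integer(0), character(0)))
  adj <- adjacency_index(graph)
  d <- lengths(adj)
  ks <- integer(n)
  alive <- rep(TRUE, n)
  k <- 0L
  remaining <- n
  while (remaining > 0L) {
    repeat {
      drop <- which(alive & d <= k)
      if (length(drop) == 0L) break
      ks[drop] <- k
      alive[drop] <- FALSE
      remaining <- remaining - length(drop)
      for (v in drop) {
        nb <- adj[[v]]
        nb <- nb[alive[nb]]
        d[nb] <- d[nb] - 1L
      }
    }
    k <- k + 1L
  }
  stats::setNames(ks, labels)
}

#' Global influence of a node
#'
#' The global term of the GLI score is the node's K-shell index: nodes in
#' deeper shells occupy more central positions in the network hierarchy.
#'
#' @param shells named integer vector from [kshell_decompose()].
#' @param v node label.
#' @return the shell index Ks(v).
#' @export
global_influence <- function(shells, v) {
  v <- as.character(v)
  if (!v %in% names(shells)) {
    stop("unknown node: ", v, call. = FALSE)
  }
  unname(shells[[v]])
}
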