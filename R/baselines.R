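#' Classical baseline centralities
#'
#' Standard textbook centralities used as comparison methods when
#' benchmarking influence rankings: degree (dc), closeness (cc), betweenness
#' (bc), eigenvector (ec), PageRank (pr, damping 0.85) and the K-shell index
#' itself. All are deterministic; the iterative measures run to igraph's
#' default convergence tolerance.
#'
#' Closeness on a disconnected graph is computed within each node's connected
#' component and scaled by the component's share of the network,
#' `(nc - 1) / (n - 1)` (the Wasserman–Faust correction), so that scores from
#' different components remain comparable and degree-0 nodes score 0.
#'
#' @param graph an undirected [igraph::igraph] with named vertices.
#' @param method one of `"dc"`, `"cc"`, `"bc"`, `"ec"`, `"pr"`, `"kshell"`.
#' @return named numeric vector of scores, one per node, in vertex order.
#' @examples
#' baseline_scores(worked_example_graph(), "dc")[["v1"]]  # 6
#' @export
baseline_scores <- function(graph,
                            method = c("dc", "cc", "bc", "ec", "pr", "kshell")) {
  method <- match.arg(method)
  graph <- as_glinet_graph(graph)
  labels <- igraph::V(graph)$name
  s <- switch(method,
    dc = igraph::degree(graph),
    cc = closeness_by_component(graph),
    bc = igraph::betweenness(graph, directed = FALSE),
    ec = igraph::eigen_centrality(graph, directed = FALSE)$vector,
    pr = igraph::page_rank(graph, damping = 0.85)$vector,
    kshell = as.numeric(kshell_decompose(graph))
  )
  stats::setNames(as.numeric(s), labels)
}

closeness_by_component <- function(graph) {
  n <- igraph::vcount(graph)
  out <- numeric(n)
  comp <- igraph::components(graph)$membership
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    nc <- length(members)
    if (nc < 2L) next           # isolated node: closeness 0
    dmat <- igraph::distances(graph, v = members, to = members)
    tot <- rowSums(dmat)
    out[members] <- (nc - 1) / tot * (nc - 1) / (n - 1)
  }
  out
}
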