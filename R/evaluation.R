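#' Kendall rank correlation (tau-a) between two score sequences
#'
#' Counts, over all unordered item pairs, those ordered the same strict way
#' by both sequences (concordant, nc) and those ordered strictly oppositely
#' (discordant, nd); pairs tied in either sequence count in neither. The
#' statistic is
#' \deqn{\tau(X, Y) = \frac{2 (n_c - n_d)}{n (n - 1)}}
#' the tau-a form, whose denominator is the total number of pairs. Note this
#' differs from the tau-b returned by [stats::cor()] when ties are present
#' (the two agree on tie-free input); tau-b is available via
#' `variant = "b"` as a cross-check.
#'
#' @param x,y numeric vectors of scores over the same items, aligned by
#'   position (names, if present on both, must agree).
#' @param variant `"a"` (default) or `"b"`.
#' @return for `variant = "a"`, an object of class `"rank_comparison"`: a
#'   list with elements `n`, `concordant`, `discordant` and `tau`. For
#'   `variant = "b"`, the tau-b number from [stats::cor()].
#' @examples
#' kendall_tau(1:5, c(2, 1, 4, 3, 5))$tau
#' @export
kendall_tau <- function(x, y, variant = c("a", "b")) {
  variant <- match.arg(variant)
  if (length(x) != length(y)) {
    stop("`x` and `y` must have the same length", call. = FALSE)
  }
  n <- length(x)
  if (n < 2L) stop("need at least two items", call. = FALSE)
  if (!is.null(names(x)) && !is.null(names(y)) &&
      !identical(names(x), names(y))) {
    stop("`x` and `y` are named but their names disagree", call. = FALSE)
  }
  if (variant == "b") return(stats::cor(x, y, method = "kendall"))
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  up <- upper.tri(dx)
  s <- dx[up] * dy[up]
  nc <- sum(s > 0)
  nd <- sum(s < 0)
  structure(list(n = n, concordant = nc, discordant = nd,
                 tau = 2 * (nc - nd) / (n * (n - 1))),
            class = "rank_comparison")
}

#' @export
print.rank_comparison <- function(x, ...) {
  cat(sprintf("Kendall tau-a: %.6f (n = %d, concordant = %d, discordant = %d)\n",
              x$tau, x$n, x$concordant, x$discordant))
  invisible(x)
}

#' Kendall tau of score methods against epidemic ground truth over an
#' alpha grid
#'
#' For each infection probability in `alphas`, computes the spreading power
#' of every node (single-seed Monte-Carlo epidemics, see
#' [spreading_power()]) and correlates it, via tau-a, with each supplied
#' score vector. The default grid is alpha = 0.01 to 0.10 in steps of 0.01,
#' chosen so the epidemic is neither too slow nor saturating.
#'
#' Ground truth is simulated once per alpha and shared by all scorers, so
#' the output is invariant to scorer ordering; with a fixed `seed` the whole
#' sweep is reproducible.
#'
#' @param graph an undirected [igraph::igraph] with named vertices.
#' @param scorers named list of score vectors (each a named numeric covering
#'   all nodes) and/or `"gli"` objects.
#' @param alphas numeric vector of infection probabilities.
#' @param model `"sir"` or `"si"` ground truth.
#' @param beta recovery probability (SIR only).
#' @param iterations Monte-Carlo repetitions per node and alpha.
#' @param max_steps step cap per run.
#' @param seed integer seed for the experiment.
#' @return data frame with columns `method`, `alpha`, `tau`.
#' @export
alpha_sweep_kendall <- function(graph, scorers,
                                alphas = seq(0.01, 0.10, by = 0.01),
                                model = "sir", beta = 1, iterations = 1000L,
                                max_steps = 100L, seed = NULL) {
  graph <- as_glinet_graph(graph)
  if (is.null(names(scorers)) || any(!nzchar(names(scorers)))) {
    stop("`scorers` must be a named list", call. = FALSE)
  }
  labels <- igraph::V(graph)$name
  score_mat <- lapply(scorers, function(s) {
    v <- as_score_vector(s)
    if (!all(labels %in% names(v))) {
      stop("a scorer does not cover every node", call. = FALSE)
    }
    v[labels]
  })
  res <- vector("list", length(alphas))
  for (a in seq_along(alphas)) {
    truth <- spreading_power(graph, nodes = labels, model = model,
                             alpha = alphas[a], beta = beta,
                             iterations = iterations, max_steps = max_steps,
                             seed = if (is.null(seed)) NULL else
                               substream_seed(seed, a))
    taus <- vapply(score_mat, function(s) {
      kendall_tau(unname(s), unname(truth))$tau
    }, numeric(1))
    res[[a]] <- data.frame(method = names(score_mat), alpha = alphas[a],
                           tau = unname(taus), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  row.names(out) <- NULL
  out
}

#' Top-k nodes of a score table
#'
#' The first k entries of [rank_nodes()]; k defaults to 15, the usual list
#' length when comparing the most influential nodes found by different
#' methods. If k exceeds the node count the full ranking is returned with a
#' warning.
#'
#' @param scores a `"gli"` object or a named numeric vector.
#' @param k number of nodes to return.
#' @return character vector of node labels, most influential first.
#' @examples
#' top_k(gli(worked_example_graph()), 4)  # "v1" "v2" "v4" "v3"
#' @export
top_k <- function(scores, k = 15L) {
  stopifnot(k >= 1L)
  ranked <- rank_nodes(scores)
  if (k > length(ranked)) {
    warning("k = ", k, " exceeds the number of nodes (", length(ranked),
            "); returning the full ranking", call. = FALSE)
    k <- length(ranked)
  }
  ranked[seq_len(k)]
}
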