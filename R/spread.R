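#' Discrete-time stochastic SIR epidemic on a network
#'
#' Synchronous updates: at each step every currently infected node
#' independently attempts to infect each of its susceptible neighbors with
#' probability `alpha` (a node contacted by several infected neighbors in the
#' same step gets one independent chance per contact but becomes infected at
#' most once); afterwards every node that was infected at the start of the
#' step recovers with probability `beta`. Newly infected nodes start
#' transmitting at the following step, so with `beta = 1` each node transmits
#' during exactly one step. The run ends when no infected nodes remain or
#' `max_steps` is reached.
#'
#' @param graph an undirected [igraph::igraph] with named vertices.
#' @param seeds character vector of initially infected node labels.
#' @param alpha per-contact, per-step infection probability in \[0, 1\].
#' @param beta per-step recovery probability in \[0, 1\].
#' @param max_steps cap on the number of steps.
#' @param seed optional integer; when given, the RNG is seeded so the run is
#'   bit-reproducible.
#' @return a `"spread_trajectory"`: a data frame with columns `t` (0 =
#'   initial state), `S`, `I`, `R`, with attributes `model`, `alpha`, `beta`
#'   and `seeds`. `S + I + R` equals the node count at every step.
#' @seealso [simulate_si()], [spreading_power()], [meanfield_sir()]
#' @export
simulate_sir <- function(graph, seeds, alpha, beta = 1, max_steps = 100L,
                         seed = NULL) {
  graph <- as_glinet_graph(graph)
  check_spread_params(alpha, beta, max_steps)
  seeds_idx <- seed_indices(graph, seeds)
  if (!is.null(seed)) set.seed(seed)
  adj <- adjacency_index(graph)
  traj <- epidemic_run(adj, igraph::vcount(graph), seeds_idx, alpha, beta,
                       max_steps, recover = TRUE)
  spread_trajectory(traj, "sir", alpha, beta, seeds)
}

#' Discrete-time stochastic SI epidemic on a network
#'
#' Same transmission rule as [simulate_sir()] but without recovery: infection
#' is irreversible, so the infected count is non-decreasing and the removed
#' count is identically zero. The default infection rate is
#' `alpha = (1/2)^3 = 0.125`. The run stops once no susceptible node has an
#' infected neighbor (all reachable nodes infected) or at `max_steps`.
#'
#' @inheritParams simulate_sir
#' @return a `"spread_trajectory"` data frame; see [simulate_sir()].
#' @export
simulate_si <- function(graph, seeds, alpha = 0.125, max_steps = 100L,
                        seed = NULL) {
  graph <- as_glinet_graph(graph)
  check_spread_params(alpha, 0, max_steps)
  seeds_idx <- seed_indices(graph, seeds)
  if (!is.null(seed)) set.seed(seed)
  adj <- adjacency_index(graph)
  traj <- epidemic_run(adj, igraph::vcount(graph), seeds_idx, alpha, 0,
                       max_steps, recover = FALSE)
  spread_trajectory(traj, "si", alpha, 0, seeds)
}

#' Mean-field SIR compartment iteration
#'
#' Deterministic forward iteration (step size 1) of the aggregate SIR
#' increments
#' \deqn{\Delta S = -\alpha S I, \quad \Delta I = \alpha S I - \beta I,
#'       \quad \Delta R = \beta I,}
#' the population-level counterpart of the network simulation. The three
#' increments sum to zero, so the total is conserved exactly.
#'
#' @param s0,i0,r0 initial compartment counts (non-negative).
#' @param alpha infection rate.
#' @param beta recovery rate.
#' @param steps number of iterations.
#' @return a `"spread_trajectory"` data frame with columns `t`, `S`, `I`,
#'   `R` (real-valued).
#' @export
meanfield_sir <- function(s0, i0, r0, alpha, beta, steps) {
  stopifnot(s0 >= 0, i0 >= 0, r0 >= 0, steps >= 0)
  S <- numeric(steps + 1L); I <- numeric(steps + 1L); R <- numeric(steps + 1L)
  S[1] <- s0; I[1] <- i0; R[1] <- r0
  for (t in seq_len(steps)) {
    new_inf <- alpha * S[t] * I[t]
    rec <- beta * I[t]
    S[t + 1L] <- S[t] - new_inf
    I[t + 1L] <- I[t] + new_inf - rec
    R[t + 1L] <- R[t] + rec
  }
  spread_trajectory(data.frame(t = 0:steps, S = S, I = I, R = R),
                    "meanfield_sir", alpha, beta, seeds = character(0))
}

#' Per-node spreading power (epidemic ground truth)
#'
#' Seeds an epidemic at a single node and averages, over independent
#' Monte-Carlo runs, the final number of ever-infected nodes (infected +
#' removed at termination; the seed counts itself, so an isolated node or an
#' `alpha = 0` run scores exactly 1). This per-node value is the ground-truth
#' influence against which centrality rankings are evaluated.
#'
#' Each run uses its own RNG substream derived from `seed` and a run counter,
#' so results are reproducible and independent of evaluation order.
#'
#' @inheritParams simulate_sir
#' @param nodes labels of the nodes to evaluate; defaults to every node.
#' @param model `"sir"` or `"si"`.
#' @param alpha infection probability; defaults to 0.01 for SIR and 0.125
#'   for SI.
#' @param iterations Monte-Carlo repetitions per node.
#' @param seed integer seed for the experiment.
#' @return named numeric vector of mean final ever-infected counts.
#' @export
spreading_power <- function(graph, nodes = NULL, model = c("sir", "si"),
                            alpha = NULL, beta = 1, iterations = 1000L,
                            max_steps = 100L, seed = NULL) {
  model <- match.arg(model)
  graph <- as_glinet_graph(graph)
  if (is.null(alpha)) alpha <- if (model == "sir") 0.01 else 0.125
  check_spread_params(alpha, beta, max_steps)
  stopifnot(iterations >= 1L)
  labels <- igraph::V(graph)$name
  if (is.null(nodes)) nodes <- labels
  idx <- node_index(graph, nodes)
  adj <- adjacency_index(graph)
  n <- igraph::vcount(graph)
  recover <- model == "sir"
  b <- if (recover) beta else 0
  out <- numeric(length(idx))
  counter <- 0L
  for (k in seq_along(idx)) {
    tot <- 0
    for (it in seq_len(iterations)) {
      counter <- counter + 1L
      if (!is.null(seed)) set.seed(substream_seed(seed, counter))
      tot <- tot + epidemic_final_size(adj, n, idx[k], alpha, b, max_steps,
                                       recover)
    }
    out[k] <- tot / iterations
  }
  stats::setNames(out, nodes)
}

#' Joint infection curve of a set of top-ranked nodes
#'
#' Seeds all listed nodes simultaneously and reports F(t), the mean number of
#' ever-infected nodes at each time step, averaged over Monte-Carlo
#' iterations. Used to compare the collective infection capability of the
#' top-k nodes selected by different ranking methods; defaults follow the
#' usual benchmarking protocol (`alpha = 0.01`, `beta = 1`, 30 steps, 1000
#' iterations).
#'
#' @inheritParams spreading_power
#' @param top_nodes character vector of seed node labels.
#' @param steps number of time steps reported.
#' @return data frame with columns `t` (1..steps) and `F` (mean ever-infected
#'   count); `F` is non-decreasing.
#' @export
topk_infection_curve <- function(graph, top_nodes, alpha = 0.01, beta = 1,
                                 steps = 30L, iterations = 1000L,
                                 seed = NULL) {
  graph <- as_glinet_graph(graph)
  check_spread_params(alpha, beta, steps)
  seeds_idx <- seed_indices(graph, top_nodes)
  adj <- adjacency_index(graph)
  n <- igraph::vcount(graph)
  acc <- numeric(steps)
  for (it in seq_len(iterations)) {
    if (!is.null(seed)) set.seed(substream_seed(seed, it))
    traj <- epidemic_run(adj, n, seeds_idx, alpha, beta, steps,
                         recover = TRUE)
    ever <- traj$I + traj$R               # ever-infected at each recorded t
    # pad: once the epidemic dies the ever-infected count stays constant
    ft <- ever[pmin(seq_len(steps) + 1L, length(ever))]
    acc <- acc + ft
  }
  data.frame(t = seq_len(steps), F = acc / iterations)
}

## ------------------------------------------------------------------ internals

# One synchronous-update epidemic; returns a data.frame t/S/I/R.
# state codes: 0 susceptible, 1 infected, 2 removed
epidemic_run <- function(adj, n, seeds_idx, alpha, beta, max_steps, recover) {
  state <- integer(n)
  state[seeds_idx] <- 1L
  S <- integer(max_steps + 1L); I <- integer(max_steps + 1L)
  R <- integer(max_steps + 1L)
  S[1] <- n - length(seeds_idx); I[1] <- length(seeds_idx); R[1] <- 0L
  t <- 0L
  while (t < max_steps) {
    infected <- which(state == 1L)
    if (length(infected) == 0L) break
    contacts <- unlist(adj[infected], use.names = FALSE)
    contacts <- contacts[state[contacts] == 0L]
    newly <- integer(0)
    if (length(contacts)) {
      hit <- contacts[stats::runif(length(contacts)) < alpha]
      newly <- unique(hit)
    }
    if (recover && beta > 0) {
      rec <- infected[stats::runif(length(infected)) < beta]
      state[rec] <- 2L
    }
    state[newly] <- 1L
    t <- t + 1L
    S[t + 1L] <- sum(state == 0L)
    I[t + 1L] <- sum(state == 1L)
    R[t + 1L] <- sum(state == 2L)
    # SI: stop once no susceptible node can ever be reached
    if (!recover && length(newly) == 0L && length(contacts) == 0L) break
  }
  data.frame(t = 0:t, S = S[1:(t + 1L)], I = I[1:(t + 1L)], R = R[1:(t + 1L)])
}

# Final ever-infected count of a single run, without trajectory bookkeeping.
epidemic_final_size <- function(adj, n, seed_idx, alpha, beta, max_steps,
                                recover) {
  state <- integer(n)
  state[seed_idx] <- 1L
  ever <- length(seed_idx)
  t <- 0L
  while (t < max_steps) {
    infected <- which(state == 1L)
    if (length(infected) == 0L) break
    contacts <- unlist(adj[infected], use.names = FALSE)
    contacts <- contacts[state[contacts] == 0L]
    newly <- integer(0)
    if (length(contacts)) {
      hit <- contacts[stats::runif(length(contacts)) < alpha]
      newly <- unique(hit)
    }
    if (recover && beta > 0) {
      rec <- infected[stats::runif(length(infected)) < beta]
      state[rec] <- 2L
    }
    state[newly] <- 1L
    ever <- ever + length(newly)
    if (!recover && length(newly) == 0L && length(contacts) == 0L) break
    t <- t + 1L
  }
  ever
}

spread_trajectory <- function(df, model, alpha, beta, seeds) {
  structure(df, model = model, alpha = alpha, beta = beta, seeds = seeds,
            class = c("spread_trajectory", "data.frame"))
}

#' @export
print.spread_trajectory <- function(x, ...) {
  cat(sprintf("%s trajectory: %d step(s), alpha = %g, beta = %g, %d seed(s)\n",
              toupper(attr(x, "model")), nrow(x) - 1L, attr(x, "alpha"),
              attr(x, "beta"), length(attr(x, "seeds"))))
  print(as.data.frame(x), ...)
  invisible(x)
}

#' @export
plot.spread_trajectory <- function(x, ...) {
  graphics::matplot(x$t, cbind(x$S, x$I, x$R), type = "l", lty = 1,
                    col = c(3, 2, 4), xlab = "t", ylab = "count", ...)
  graphics::legend("right", legend = c("S", "I", "R"), col = c(3, 2, 4),
                   lty = 1, bty = "n")
  invisible(x)
}

check_spread_params <- function(alpha, beta, max_steps) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha >= 0, alpha <= 1,
            is.numeric(beta), length(beta) == 1L, beta >= 0, beta <= 1,
            max_steps >= 1L)
}

seed_indices <- function(graph, seeds) {
  if (length(seeds) == 0L) {
    stop("`seeds` must name at least one node", call. = FALSE)
  }
  unique(node_index(graph, seeds))
}

# Deterministic per-run substream seed below 2^31.
substream_seed <- function(seed, counter) {
  as.integer((as.double(seed) + 48271 * as.double(counter)) %% 2147483647)
}
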