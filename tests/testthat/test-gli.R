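tol6 <- 1e-6

test_that("closed neighborhoods include the node itself", {
  g <- worked_example_graph()
  expect_setequal(closed_neighborhood(g, "v1"),
                  c("v1", "v2", "v3", "v4", "v5", "v6", "v8"))
  iso <- read_edge_list(c("a b", "c"))
  expect_identical(closed_neighborhood(iso, "c"), "c")
  pair <- read_edge_list("a b")
  expect_setequal(closed_neighborhood(pair, "a"), closed_neighborhood(pair, "b"))
  expect_error(closed_neighborhood(g, "zz"), "unknown node")
})

test_that("jaccard similarity reproduces the published values", {
  g <- worked_example_graph()
  expected <- c(v2 = 0.625, v3 = 0.5, v4 = 0.444444, v5 = 0.375,
                v6 = 0.4285714, v8 = 0.3)
  for (v in names(expected)) {
    expect_close(jaccard_similarity(g, "v1", v), expected[[v]])
  }
})

test_that("jaccard is 1 on identical nodes and matches the set oracle", {
  for (seed in 1:6) {
    g <- random_named_gnp(15, 0.25, seed)
    labels <- igraph::V(g)$name
    for (v in labels[1:3]) {
      expect_equal(jaccard_similarity(g, v, v), 1)
    }
    set.seed(seed)
    for (rep in 1:10) {
      pair <- sample(labels, 2)
      expect_equal(jaccard_similarity(g, pair[1], pair[2]),
                   oracle_jaccard(g, pair[1], pair[2]))
    }
  }
})

test_that("given values reproduce the published worked-example cells", {
  g <- worked_example_graph()
  expect_equal(given_value(g, vi = "v1", vj = "v2"), 6.125, tolerance = tol6)
  expect_equal(given_value(g, vi = "v1", vj = "v8"), 3.5, tolerance = tol6)
  expected <- c(v2 = 6.125, v3 = 5.0, v4 = 5.222222, v5 = 3.125,
                v6 = 2.857143, v8 = 3.5)
  ks <- kshell_decompose(g)
  for (v in names(expected)) {
    expect_equal(given_value(g, ks, "v1", v), expected[[v]], tolerance = tol6)
  }
  expect_error(given_value(g, vi = "v1", vj = "v9"), "not adjacent")
})

test_that("given value of a star leaf follows the closed form", {
  for (k in c(3, 5, 9)) {
    star <- synthetic_network("star", k + 1)       # v1 hub, k leaves
    # leaf degree 1, leaf ks 1, jacc(hub, leaf) = 2/(k+1)
    expect_equal(given_value(star, vi = "v1", vj = "v2"), 2 / (k + 1) + 1,
                 tolerance = tol6)
  }
})

test_that("neighbor_sum adds the given values (order-independent)", {
  g <- worked_example_graph()
  expect_equal(neighbor_sum(g, vi = "v1"),
               6.125 + 5.0 + 5.222222 + 3.125 + 2.857143 + 3.5,
               tolerance = tol6)
  iso <- read_edge_list(c("a b", "c"))
  expect_identical(neighbor_sum(iso, vi = "c"), 0)
})

test_that("local influence composes P, N and Local as published", {
  g <- worked_example_graph()
  li <- local_influence(g, vi = "v1")
  expect_equal(li$P, 6)
  expect_equal(li$N, 25.829365 / 6, tolerance = tol6)
  expect_equal(li$Local, 10.304894, tolerance = tol6)

  iso <- read_edge_list(c("a b", "c"))
  expect_equal(local_influence(iso, vi = "c"), list(P = 0, N = 0, Local = 0))

  k <- 6
  star <- synthetic_network("star", k + 1)
  lh <- local_influence(star, vi = "v1")
  expect_equal(lh$P, k)
  expect_equal(lh$N, 2 / (k + 1) + 1, tolerance = tol6)
})

test_that("gli reproduces the worked-example influence and ranking", {
  fit <- gli(worked_example_graph())
  tab <- fit$table
  expect_equal(tab$I[tab$node == "v1"], 13.304894, tolerance = tol6)
  expect_equal(max(tab$I), tab$I[tab$node == "v1"])
  expect_identical(top_k(fit, 4), c("v1", "v2", "v4", "v3"))
  expect_identical(rank_nodes(fit),
                   c("v1", "v2", "v4", "v3", "v8", "v5", "v9", "v6", "v10",
                     "v13", "v14", "v15", "v11", "v7", "v12"))
})

test_that("score identities hold exactly on arbitrary graphs", {
  for (seed in 1:8) {
    g <- random_named_gnp(30, 0.12, seed)
    fit <- gli(g)
    tab <- fit$table
    expect_equal(tab$Local, tab$P + tab$N)
    expect_equal(tab$I, tab$Local + tab$Global)
    expect_true(all(tab$Sum >= 0))
    if (fit$max_degree > 0) expect_equal(tab$N, tab$Sum / fit$max_degree)
  }
})

test_that("gli agrees with a first-principles recomputation", {
  for (seed in 1:4) {
    g <- random_named_gnp(25, 0.18, seed)
    fit <- gli(g)
    expect_equal(stats::setNames(fit$table$I, fit$table$node),
                 oracle_gli(g), tolerance = 1e-12)
  }
})

test_that("edgeless and isolated nodes score zero", {
  g0 <- synthetic_network("er", 6, p = 0, seed = 1)
  expect_true(all(gli(g0)$table$I == 0))
  mix <- read_edge_list(c("a b", "b c", "lone"))
  tab <- gli(mix)$table
  expect_equal(tab$I[tab$node == "lone"], 0)
  expect_true(all(tab$I[tab$node != "lone"] > 0))
})

test_that("gli is invariant under relabeling and edge order", {
  g <- random_named_gnp(20, 0.2, 9)
  fit <- gli(g)
  gr <- relabel_graph(g, seed = 2)
  map <- stats::setNames(igraph::V(gr)$name, igraph::V(g)$name)
  fitr <- gli(gr)
  s1 <- stats::setNames(fit$table$I, map[fit$table$node])
  s2 <- stats::setNames(fitr$table$I, fitr$table$node)
  expect_equal(s2[names(s1)], s1)
})

test_that("the star hub strictly dominates every leaf", {
  star <- synthetic_network("star", 10)
  tab <- gli(star)$table
  hub <- tab$I[tab$node == "v1"]
  expect_true(all(hub > tab$I[tab$node != "v1"]))
})

test_that("ranking breaks ties by ascending label", {
  scores <- c(b = 1, a = 1, c = 1)
  expect_identical(rank_nodes(scores), c("a", "b", "c"))
  set.seed(4)
  s <- stats::setNames(sample(5, 12, replace = TRUE), paste0("n", 1:12))
  expect_setequal(rank_nodes(s), names(s))
})

test_that("gli methods print, summarise and coerce", {
  fit <- gli(worked_example_graph())
  expect_output(print(fit), "15 nodes, 20 edges")
  expect_output(summary(fit), "maxD = 6")
  expect_s3_class(as.data.frame(fit), "data.frame")
  expect_equal(unname(coef(fit)[1]), 13.304894, tolerance = tol6)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
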