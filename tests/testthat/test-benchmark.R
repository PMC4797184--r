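test_that("degree sequences respect the power-law truncation and parity", {
  cfg <- benchmark_config(n = 1000, mu = 0.1, d_avg = 10, d_max = 20,
                          k_min = 30, k_max = 60, seed = 1)
  set.seed(1)
  d <- sample_degree_sequence(cfg)
  expect_length(d, 1000)
  expect_lte(max(d), 20)
  expect_lt(abs(mean(d) - 10), 0.5)
  expect_equal(sum(d) %% 2, 0)

  # d_avg == d_max collapses to the degenerate all-d_max sequence
  cfg2 <- benchmark_config(n = 50, mu = 0, d_avg = 12, d_max = 12,
                           k_min = 20, k_max = 50, seed = 2)
  set.seed(2)
  expect_true(all(sample_degree_sequence(cfg2) == 12))

  expect_error(benchmark_config(n = 100, mu = 0.1, d_avg = 30, d_max = 20,
                                k_min = 40, k_max = 50), "d_avg")
})

test_that("community sizes sum to n within the configured bounds", {
  cfg <- benchmark_config(n = 30, mu = 0.1, d_avg = 5, d_max = 8,
                          k_min = 10, k_max = 10, seed = 1)
  set.seed(1)
  expect_equal(sample_community_sizes(cfg), c(10L, 10L, 10L))

  for (seed in 1:20) {
    set.seed(seed)
    cfg2 <- benchmark_config(n = sample(200:500, 1), mu = 0.1, d_avg = 8,
                             d_max = 15, k_min = 25, k_max = 60, seed = seed)
    set.seed(seed)
    sizes <- sample_community_sizes(cfg2)
    expect_equal(sum(sizes), cfg2$n)
    expect_true(all(sizes >= 25 & sizes <= 60))
  }

  cfg3 <- benchmark_config(n = 25, mu = 0.1, d_avg = 5, d_max = 8,
                           k_min = 10, k_max = 20, seed = 3)
  set.seed(3)
  sizes3 <- sample_community_sizes(cfg3)
  expect_equal(sum(sizes3), 25)
  expect_length(sizes3, 2)
})

test_that("generated networks realize the requested mixing", {
  cfg <- benchmark_config(n = 300, mu = 0.05, d_avg = 10, d_max = 20,
                          k_min = 30, k_max = 60, seed = 1)
  pn <- generate_benchmark(cfg)
  expect_lte(abs(pn$realized_mu - 0.05), 0.02)
  expect_equal(length(pn$truth), 300)
  sizes <- table(pn$truth)
  expect_true(all(sizes >= 30 & sizes <= 60))

  # determinism
  pn2 <- generate_benchmark(cfg)
  expect_identical(igraph::as_edgelist(pn$graph), igraph::as_edgelist(pn2$graph))
  expect_identical(pn$truth, pn2$truth)

  # mu = 0: every edge internal, planted partition strictly positive Q
  pn0 <- generate_benchmark(benchmark_config(n = 150, mu = 0, d_avg = 8,
                                             d_max = 15, k_min = 25, k_max = 50,
                                             seed = 4))
  expect_equal(pn0$realized_mu, 0)
  expect_gt(modularity_q(pn0$graph, pn0$truth), 0)
})

test_that("degree statistics hold across seeds", {
  mus <- numeric(5)
  for (seed in 1:5) {
    pn <- generate_benchmark(benchmark_config(n = 300, mu = 0.2, d_avg = 10,
                                              d_max = 20, k_min = 30, k_max = 60,
                                              seed = seed))
    d <- igraph::degree(pn$graph)
    expect_lte(max(d), 20)
    mus[seed] <- pn$realized_mu
  }
  expect_lte(abs(mean(mus) - 0.2), 0.03)
})

test_that("planted modularity decreases with mixing", {
  qs <- vapply(c(0.05, 0.2, 0.4), function(mu) {
    mean(vapply(1:3, function(s) {
      pn <- small_benchmark(mu = mu, seed = s, n = 200)
      modularity_q(pn$graph, pn$truth)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(qs) < 0))
})

test_that("add_random_edges adds the exact count of fresh non-edges", {
  g <- small_benchmark(mu = 0.1, seed = 2, n = 150)$graph
  m <- igraph::gsize(g)
  expect_identical(igraph::gsize(add_random_edges(g, 0)), m)

  set.seed(10)
  g2 <- add_random_edges(g, 0.05)
  expect_equal(igraph::gsize(g2), m + floor(0.05 * m))
  expect_true(igraph::is_simple(g2))
  # original edges untouched
  k1 <- apply(igraph::as_edgelist(g), 1, function(e) paste(sort(e), collapse = "|"))
  k2 <- apply(igraph::as_edgelist(g2), 1, function(e) paste(sort(e), collapse = "|"))
  expect_true(all(k1 %in% k2))

  tiny <- complete_graph(3)
  expect_error(add_random_edges(tiny, 1), "non-adjacent")
})

test_that("delete_random_edges preserves connectivity and degree >= 1", {
  g <- small_benchmark(mu = 0.1, seed = 3, n = 150)$graph
  g <- giant_connected_component(g)
  m <- igraph::gsize(g)
  expect_identical(igraph::gsize(delete_random_edges(g, 0)), m)

  set.seed(11)
  g2 <- delete_random_edges(g, 0.05)
  expect_equal(igraph::gsize(g2), m - floor(0.05 * m))
  expect_equal(igraph::components(g2)$no, 1)
  expect_gte(min(igraph::degree(g2)), 1)

  tree <- path_graph(sprintf("t%d", 1:6))
  expect_error(delete_random_edges(tree, 0.5), "removable")
})
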