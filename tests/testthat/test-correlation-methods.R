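test_that("weight matrix is the true matrix product A %*% S", {
  p3 <- path_graph(c("a", "b", "c"))
  m <- weight_matrix(p3, all_pairs_shortest_paths(p3))
  expect_equal(m["a", ], c(a = 1, b = 0, c = 1))
  expect_equal(m["b", ], c(a = 2, b = 2, c = 2))
  expect_equal(m["c", ], c(a = 1, b = 0, c = 1))

  e <- pin_graph(rbind(c("a", "b")))
  # S has no 3 columns here, but M itself is fine: each row copies the other's S row
  me <- weight_matrix(e, igraph::distances(e))
  expect_equal(unname(me), rbind(c(1, 0), c(0, 1)))

  bg <- two_triangles_bridged()
  mb <- weight_matrix(bg, all_pairs_shortest_paths(bg))
  expect_false(isSymmetric(mb))
})

test_that("correlation distance handles perfect, inverse and constant rows", {
  x <- rbind(r1 = c(1, 2, 3), r2 = c(2, 4, 6), r3 = c(3, 2, 1))
  d <- correlation_distance(x, "pearson")
  expect_equal(d["r1", "r2"], 0)
  expect_equal(d["r1", "r3"], 2)
  expect_true(all(diag(d) == 0))

  p3 <- path_graph(c("a", "b", "c"))
  m <- weight_matrix(p3, all_pairs_shortest_paths(p3))
  dm <- correlation_distance(m, "pearson")
  expect_equal(dm["a", "c"], 0)     # identical rows
  expect_equal(dm["a", "b"], 1)     # row b is constant
  expect_equal(dm["b", "c"], 1)

  expect_error(correlation_distance(matrix(1:4, 2), "pearson"), "3 columns")
})

test_that("spearman uses average ranks and detects monotone agreement", {
  x <- rbind(r1 = c(1, 5, 30, 2), r2 = c(2, 7, 90, 3), r3 = c(9, 2, 1, 8))
  d <- correlation_distance(x, "spearman")
  expect_equal(d["r1", "r2"], 0)   # same ranking
  expect_gt(d["r1", "r3"], 1)      # reversed ranking
})

test_that("ward clustering merges tight pairs first and is permutation-invariant", {
  d <- matrix(10, 4, 4, dimnames = list(c("a", "b", "c", "d"), c("a", "b", "c", "d")))
  d["a", "b"] <- d["b", "a"] <- 1
  d["c", "d"] <- d["d", "c"] <- 1
  diag(d) <- 0
  h <- ward_cluster(d)
  first_two <- lapply(1:2, function(s) sort(h$labels[-h$merge[s, ]]))
  expect_setequal(vapply(first_two, paste, "", collapse = ""), c("ab", "cd"))

  perm <- c("d", "b", "a", "c")
  h2 <- ward_cluster(d[perm, perm])
  expect_equal(nmi(cutree(h, 2), cutree(h2, 2)), 1.0)

  dd <- d; dd[1, 2] <- NaN
  expect_error(ward_cluster(dd), "NA/NaN")
  expect_error(ward_cluster(d[1, 1, drop = FALSE]), "2 nodes")
})

test_that("modularity-optimal cut maximizes Q over all dendrogram levels", {
  # a clique never profits from splitting
  k5 <- complete_graph(5)
  p <- detect_communities(k5, "sp", "pearson")
  expect_equal(max(p), 1)

  # two cliques joined by one edge split into the cliques
  labs1 <- sprintf("a%d", 1:5); labs2 <- sprintf("b%d", 1:5)
  edges <- rbind(t(combn(labs1, 2)), t(combn(labs2, 2)), c("a1", "b1"))
  g2 <- pin_graph(edges)
  p2 <- detect_communities(g2, "sp", "pearson")
  expect_equal(max(p2), 2)
  expect_equal(length(unique(p2[labs1])), 1)
  expect_equal(length(unique(p2[labs2])), 1)

  # the returned cut dominates every other cut of the same dendrogram
  g <- random_connected_graph(15, p_edge = 0.3, seed = 42)
  s <- all_pairs_shortest_paths(g)
  dend <- ward_cluster(correlation_distance(s, "pearson"))
  best <- cut_by_modularity(dend, g)
  qs <- vapply(seq_len(15), function(k) {
    memb <- stats::cutree(dend, k = k)
    modularity_q(g, memb)
  }, numeric(1))
  expect_equal(attr(best, "q"), max(qs), tolerance = 1e-12)
  expect_equal(attr(best, "k"), which.max(qs))
})

test_that("all four method specs recover bridged triangles and are deterministic", {
  g <- two_triangles_bridged()
  truth <- c(a = 1, b = 1, c = 1, d = 2, e = 2, f = 2)
  for (base in c("sp", "M")) for (corr in c("pearson", "spearman")) {
    p <- detect_communities(g, base, corr)
    expect_equal(nmi(truth, p), 1.0, info = paste(base, corr))
    p2 <- detect_communities(g, base, corr)
    expect_identical(unclass(p), unclass(p2))
  }
  expect_equal(max(detect_communities(complete_graph(6), "M", "spearman")), 1)
})

test_that("detection is equivariant under node relabeling", {
  g <- two_triangles_bridged()
  el <- igraph::as_edgelist(g)
  ren <- setNames(sprintf("z%d", 6:1), igraph::V(g)$name)  # reverses sort order
  g2 <- pin_graph(cbind(ren[el[, 1]], ren[el[, 2]]))
  p1 <- detect_communities(g, "sp", "pearson")
  p2 <- detect_communities(g2, "sp", "pearson")
  p2_back <- setNames(unname(p2[ren[names(p1)]]), names(p1))
  expect_equal(nmi(p1, p2_back), 1.0)
})

test_that("planted communities at low mixing are recovered nearly perfectly", {
  pn <- small_benchmark(mu = 0.05, seed = 11, n = 300)
  g <- giant_connected_component(pn$graph)
  p <- detect_communities(g, "sp", "pearson")
  expect_gte(nmi(pn$truth[names(p)], p), 0.9)
})
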