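# small graph builders used across tests

triangle <- function(labels = c("a", "b", "c")) {
  pin_graph(cbind(labels, labels[c(2, 3, 1)]))
}

two_triangles_bridged <- function() {
  pin_graph(rbind(c("a", "b"), c("b", "c"), c("a", "c"),
                  c("d", "e"), c("e", "f"), c("d", "f"),
                  c("c", "d")))
}

two_disjoint_triangles <- function() {
  pin_graph(rbind(c("a", "b"), c("b", "c"), c("a", "c"),
                  c("d", "e"), c("e", "f"), c("d", "f")))
}

complete_graph <- function(n, prefix = "k") {
  labs <- sprintf("%s%02d", prefix, seq_len(n))
  pairs <- t(combn(labs, 2))
  pin_graph(pairs)
}

path_graph <- function(labels) {
  pin_graph(cbind(labels[-length(labels)], labels[-1]))
}

cycle_graph <- function(n) {
  labs <- sprintf("c%02d", seq_len(n))
  pin_graph(cbind(labs, labs[c(2:n, 1)]))
}

# Erdos-Renyi-ish random connected graph on n nodes (retries until connected)
random_connected_graph <- function(n, p_edge = 0.25, seed = 1) {
  set.seed(seed)
  labs <- sprintf("r%02d", seq_len(n))
  repeat {
    pairs <- t(combn(labs, 2))
    keep <- runif(nrow(pairs)) < p_edge
    if (!any(keep)) next
    g <- pin_graph(pairs[keep, , drop = FALSE], nodes = labs)
    if (igraph::components(g)$no == 1) return(g)
  }
}

random_partition <- function(nodes, k, seed = 1) {
  set.seed(seed)
  canonicalize_partition(setNames(sample.int(k, length(nodes), replace = TRUE), nodes))
}

# brute-force modularity straight from the definition: enumerate e and a
modularity_oracle <- function(g, p) {
  m <- igraph::gsize(g)
  el <- igraph::as_edgelist(g)
  ids <- sort(unique(p))
  q <- 0
  for (i in ids) {
    members <- names(p)[p == i]
    internal <- sum(el[, 1] %in% members & el[, 2] %in% members)
    degsum <- sum(igraph::degree(g)[members])
    q <- q + internal / m - (degsum / (2 * m))^2
  }
  q
}

# Floyd-Warshall oracle for shortest paths
floyd_warshall_oracle <- function(g) {
  labs <- igraph::V(g)$name
  n <- length(labs)
  d <- matrix(Inf, n, n, dimnames = list(labs, labs))
  diag(d) <- 0
  el <- igraph::as_edgelist(g)
  for (r in seq_len(nrow(el))) {
    d[el[r, 1], el[r, 2]] <- 1
    d[el[r, 2], el[r, 1]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# hypergeometric upper-tail by direct enumeration of the sampling density
fisher_tail_oracle <- function(k, K, t, N) {
  ks <- k:min(K, t)
  sum(choose(t, ks) * choose(N - t, K - ks)) / choose(N, K)
}

small_benchmark <- function(mu = 0.1, seed = 1, n = 150) {
  generate_benchmark(benchmark_config(n = n, mu = mu, d_avg = 8, d_max = 15,
                                      k_min = 25, k_max = 50, seed = seed))
}
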