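#' Fast-greedy modularity agglomeration
#'
#' Starts from singleton communities with pair scores
#' `dq[i, j] = 1/(2m) - k_i k_j / (2m)^2` for adjacent pairs, repeatedly
#' merges the connected pair with the largest score (ties broken by the
#' smallest community-index pair), and maintains the scores as
#' `w_ij / (2m) - a_i a_j` where `w_ij` counts edges between the two
#' communities and `a_i` is the community degree fraction. The true
#' modularity change of a merge is twice the stored pair score (the score is
#' kept on the conventional half scale of the singleton initialization);
#' `Q` is tracked exactly along the full merge sequence and the partition at
#' the maximal-`Q` step is returned.
#'
#' @param g connected graph with at least one edge.
#' @return list of class `pin_fastgreedy` with elements `partition`
#'   (canonical, at the best step), `merges` (data frame: `step`, `from`,
#'   `to`, `dq`, `q` after the merge), `q_trace` (`Q` for `n, n-1, ..., 1`
#'   communities), `best_step`, `m`.
#' @examples
#' g <- pin_graph(rbind(c("a","b"), c("b","c"), c("a","c")))
#' fg <- fast_greedy(g)
#' fg$merges$dq[1]  # 1/18 for a triangle
#' @export
fast_greedy <- function(g) {
  m <- igraph::gsize(g)
  if (m == 0) stop("fast-greedy requires at least one edge")
  labs <- node_names(g)
  n <- length(labs)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)[labs, labs]
  w <- adj  # w[i, j]: edges between communities i and j; w[i, i]: 2 * internal
  a <- igraph::degree(g)[labs] / (2 * m)
  dq <- w / (2 * m) - outer(a, a)
  dq[w == 0] <- -Inf
  diag(dq) <- -Inf
  active <- rep(TRUE, n)
  member <- seq_len(n)           # node -> community slot
  q <- -sum(a^2)                 # all-singleton partition (no self-loops)
  q_trace <- numeric(n)
  q_trace[1] <- q
  merges <- data.frame(step = seq_len(max(n - 1, 0)), from = NA_integer_,
                       to = NA_integer_, dq = NA_real_, q = NA_real_)
  for (step in seq_len(n - 1)) {
    mx <- max(dq)
    if (!is.finite(mx)) break    # no connected pair left (disconnected input)
    hits <- which(dq == mx, arr.ind = TRUE)
    hits <- hits[hits[, 1] < hits[, 2], , drop = FALSE]
    hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
    i <- hits[1, 1]; j <- hits[1, 2]
    q <- q + 2 * mx              # stored score is half the true change in Q
    w[i, ] <- w[i, ] + w[j, ]
    w[, i] <- w[, i] + w[, j]
    w[j, ] <- 0; w[, j] <- 0
    a[i] <- a[i] + a[j]
    active[j] <- FALSE
    member[member == j] <- i
    dq[j, ] <- -Inf; dq[, j] <- -Inf
    dq[i, ] <- -Inf; dq[, i] <- -Inf
    ks <- which(active & w[i, ] > 0)
    ks <- ks[ks != i]
    if (length(ks)) {
      vals <- w[i, ks] / (2 * m) - a[i] * a[ks]
      dq[i, ks] <- vals
      dq[ks, i] <- vals
    }
    merges$from[step] <- i; merges$to[step] <- j
    merges$dq[step] <- mx; merges$q[step] <- q
    q_trace[step + 1] <- q
  }
  done <- which(!is.na(merges$from))
  merges <- merges[done, , drop = FALSE]
  q_trace <- q_trace[seq_len(length(done) + 1)]
  best_step <- which.max(q_trace) - 1L  # number of merges applied
  member_best <- seq_len(n)
  for (s in seq_len(best_step)) {
    member_best[member_best == merges$to[s]] <- merges$from[s]
  }
  partition <- canonicalize_partition(setNames(member_best, labs))
  structure(list(partition = partition, merges = merges, q_trace = q_trace,
                 best_step = best_step, m = m),
            class = "pin_fastgreedy")
}

#' Label propagation
#'
#' Every node starts with a unique label; in seeded random order, each node
#' asynchronously adopts a label held by the maximum number of its
#' neighbours, breaking ties uniformly at random among the tied labels. A
#' node whose current label is already tied-maximal keeps it. The sweep
#' repeats until every node's label is maximal in its neighbourhood. With
#' the same seed the result is reproducible.
#'
#' @param g graph.
#' @param seed integer seed for the node order and tie breaks.
#' @param max_sweeps safety cap on sweeps (the algorithm converges in a
#'   handful on any realistic input).
#' @return canonical partition.
#' @export
label_propagation <- function(g, seed = 1L, max_sweeps = 100L) {
  n <- igraph::vcount(g)
  if (n == 0) return(canonicalize_partition(setNames(integer(), character())))
  labs <- node_names(g)
  set.seed(seed)
  adj <- igraph::as_adj_list(g)
  adj <- lapply(adj, as.integer)
  lab <- seq_len(n)
  for (sweep in seq_len(max_sweeps)) {
    changed <- FALSE
    for (i in sample.int(n)) {
      nb <- adj[[i]]
      if (length(nb) == 0) next
      tab <- table(lab[nb])
      winners <- as.integer(names(tab)[tab == max(tab)])
      if (!(lab[i] %in% winners)) {
        lab[i] <- winners[sample.int(length(winners), 1)]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  canonicalize_partition(setNames(lab, labs))
}

native_methods <- c("fastgreedy", "labelprop",
                    "dsp-pearson", "dsp-spearman", "dm-pearson", "dm-spearman")
external_methods <- c("walktrap", "spinglass", "multilevel")

#' Available detection method names
#'
#' The nine method names accepted by [run_algorithm()]: the four
#' correlation-distance methods, native `fastgreedy` and `labelprop`, and the
#' externally backed `walktrap`, `spinglass` and `multilevel`.
#'
#' @return character vector.
#' @export
detection_methods <- function() c(native_methods, external_methods)

#' Run a community detection algorithm by name
#'
#' Uniform dispatch over the nine methods. The correlation methods,
#' fast-greedy and label propagation run natively; `walktrap`, `spinglass`
#' and `multilevel` are delegated to the igraph library (`backend =
#' "external"`, their only backend — there is deliberately no native
#' re-implementation). Stochastic methods take `seed`; all returned
#' partitions are canonical.
#'
#' @param g connected graph.
#' @param method one of [detection_methods()].
#' @param seed integer seed forwarded to stochastic methods.
#' @param backend `"native"` or `"external"`; defaults to the method's
#'   natural backend. Requesting an unavailable combination is an error,
#'   never a silent fallback.
#' @return canonical partition.
#' @export
run_algorithm <- function(g, method, seed = 1L, backend = NULL) {
  method <- match.arg(method, detection_methods())
  if (is.null(backend)) {
    backend <- if (method %in% external_methods) "external" else "native"
  }
  if (method %in% external_methods) {
    if (backend != "external") {
      stop(sprintf("method '%s' has no native backend; use backend = \"external\"", method))
    }
    if (!requireNamespace("igraph", quietly = TRUE)) {
      stop(sprintf("method '%s' needs the igraph backend, which is not available", method))
    }
    set.seed(seed)
    cl <- switch(method,
                 walktrap   = igraph::cluster_walktrap(g),
                 spinglass  = igraph::cluster_spinglass(g),
                 multilevel = igraph::cluster_louvain(g))
    memb <- igraph::membership(cl)
    return(canonicalize_partition(setNames(as.integer(memb), node_names(g))))
  }
  if (backend != "native") {
    stop(sprintf("method '%s' only has a native backend", method))
  }
  switch(method,
         fastgreedy = fast_greedy(g)$partition,
         labelprop  = label_propagation(g, seed = seed),
         {
           row <- method_table[method_table$method == method, ]
           p <- detect_communities(g, base = row$base, correlation = row$correlation)
           attributes(p)[c("k", "q")] <- NULL
           p
         })
}
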