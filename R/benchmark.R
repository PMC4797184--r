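#' Benchmark configuration
#'
#' Parameters of the planted-community benchmark generator. Degrees follow a
#' truncated discrete power law `p(d) ~ d^-gamma` on `[d_min, d_max]`, with
#' `d_min` solved so the distribution mean matches `d_avg`; community sizes
#' follow a truncated power law with exponent `size_exponent` on
#' `[k_min, k_max]`. Each node shares a fraction `mu` of its edges with other
#' communities ("mixing") and `1 - mu` inside its own.
#'
#' @param n node count.
#' @param mu mixing fraction in `[0, 1)`.
#' @param d_avg target mean degree.
#' @param d_max maximum degree.
#' @param gamma degree power-law exponent.
#' @param k_min,k_max community size bounds; `k_max` must exceed `d_max` so
#'   every node can be hosted by some community.
#' @param size_exponent community-size power-law exponent.
#' @param seed integer seed.
#' @param max_rewire_sweeps cap on the clean-up sweeps that remove self-loops,
#'   duplicate edges and stub misclassifications.
#' @return list of class `benchmark_config`.
#' @export
benchmark_config <- function(n = 1000, mu = 0.1, d_avg = 10, d_max = 20,
                             gamma = 1, k_min = 30, k_max = 60,
                             size_exponent = 1, seed = 1L,
                             max_rewire_sweeps = 200L) {
  stopifnot(n >= 2, mu >= 0, mu < 1, d_avg <= d_max, k_min <= k_max)
  if (k_max <= d_max) stop("k_max must exceed d_max so that each node fits in a community")
  if (n < k_min) stop("n must be at least k_min")
  structure(list(n = n, mu = mu, d_avg = d_avg, d_max = d_max, gamma = gamma,
                 k_min = k_min, k_max = k_max, size_exponent = size_exponent,
                 seed = as.integer(seed),
                 max_rewire_sweeps = as.integer(max_rewire_sweeps)),
            class = "benchmark_config")
}

# mean of the truncated discrete power law d^-gamma on d_min..d_max
truncated_powerlaw_mean <- function(d_min, d_max, gamma) {
  d <- d_min:d_max
  w <- d^(-gamma)
  sum(d * w) / sum(w)
}

solve_d_min <- function(cfg) {
  if (cfg$d_avg > cfg$d_max) stop("d_avg exceeds d_max: no feasible minimum degree")
  means <- vapply(seq_len(cfg$d_max),
                  function(dm) truncated_powerlaw_mean(dm, cfg$d_max, cfg$gamma),
                  numeric(1))
  best <- which.min(abs(means - cfg$d_avg))
  if (abs(means[best] - cfg$d_avg) > 1) {
    stop(sprintf("no minimum degree makes the %s-truncated power law mean reach %g",
                 cfg$d_max, cfg$d_avg))
  }
  best
}

#' Sample a power-law degree sequence
#'
#' Draws `n` degrees from the truncated discrete power law of the
#' configuration, with the minimum degree solved numerically so the
#' distribution mean equals `d_avg`, and the sum adjusted to be even (one
#' node's degree is incremented if necessary).
#'
#' Uses R's global RNG; seed it (or call via [generate_benchmark()], which
#' does) for reproducibility.
#'
#' @param cfg a [benchmark_config()].
#' @return integer vector of `n` degrees.
#' @export
sample_degree_sequence <- function(cfg) {
  d_min <- solve_d_min(cfg)
  support <- d_min:cfg$d_max
  prob <- support^(-cfg$gamma)
  d <- support[sample.int(length(support), cfg$n, replace = TRUE, prob = prob)]
  if (sum(d) %% 2 == 1) {
    bump <- which(d < cfg$d_max)
    idx <- if (length(bump)) bump[sample.int(length(bump), 1)] else sample.int(cfg$n, 1)
    d[idx] <- d[idx] + 1L
  }
  as.integer(d)
}

#' Sample community sizes summing to n
#'
#' Draws sizes from the truncated power law on `[k_min, k_max]` until the
#' running sum reaches `n`; the final draw is trimmed to land exactly on `n`,
#' and if the trimmed remainder is below `k_min` it is redistributed over the
#' existing communities (each stays within `[k_min, k_max]`).
#'
#' @param cfg a [benchmark_config()].
#' @return integer vector of community sizes, `sum == n`, all in
#'   `[k_min, k_max]`.
#' @export
sample_community_sizes <- function(cfg) {
  support <- cfg$k_min:cfg$k_max
  prob <- support^(-cfg$size_exponent)
  for (attempt in 1:100) {
    sizes <- integer()
    while (sum(sizes) < cfg$n) {
      sizes <- c(sizes, support[sample.int(length(support), 1, prob = prob)])
    }
    excess <- sum(sizes) - cfg$n
    if (excess > 0) {
      last <- sizes[length(sizes)] - excess
      if (last >= cfg$k_min) {
        sizes[length(sizes)] <- last
      } else {
        sizes <- sizes[-length(sizes)]
        need <- cfg$n - sum(sizes)
        while (need > 0 && any(sizes < cfg$k_max)) {
          room <- which(sizes < cfg$k_max)
          take <- room[seq_len(min(length(room), need))]
          sizes[take] <- sizes[take] + 1L
          need <- cfg$n - sum(sizes)
        }
        if (need != 0) next
      }
    }
    if (sum(sizes) == cfg$n && all(sizes >= cfg$k_min & sizes <= cfg$k_max)) {
      return(as.integer(sizes))
    }
  }
  stop("could not partition n nodes into community sizes within [k_min, k_max]")
}

# assign nodes to communities: random assignment with displacement when a
# community is full; a node only enters a community larger than its internal
# degree
assign_communities <- function(int_deg, sizes, max_iter) {
  n <- length(int_deg)
  K <- length(sizes)
  if (any(int_deg >= max(sizes))) {
    stop("a node's internal degree reaches the largest community size; increase k_min")
  }
  comm <- rep(NA_integer_, n)
  fill <- integer(K)
  unassigned <- seq_len(n)
  iter <- 0
  while (length(unassigned) > 0) {
    iter <- iter + 1
    if (iter > max_iter) {
      stop("community assignment did not converge; increase k_min or lower d_max")
    }
    i <- unassigned[sample.int(length(unassigned), 1)]
    j <- sample.int(K, 1)
    if (int_deg[i] >= sizes[j]) next
    if (fill[j] < sizes[j]) {
      comm[i] <- j
      fill[j] <- fill[j] + 1L
      unassigned <- unassigned[unassigned != i]
    } else {
      members <- which(comm == j)
      out <- members[sample.int(length(members), 1)]
      comm[out] <- NA_integer_
      comm[i] <- j
      unassigned <- c(unassigned[unassigned != i], out)
    }
  }
  comm
}

# pair up stubs by random matching, then repair self-loops, duplicates (and,
# for the external pool, intra-community pairs) by targeted double-edge swaps:
# a bad edge (u,v) and a random partner (x,y) are rewired to (u,x),(v,y) only
# when both new edges are clean, so every accepted swap removes a defect
match_stubs <- function(stubs, comm, forbid_same_comm, existing_keys, max_sweeps) {
  if (length(stubs) == 0) return(matrix(integer(), ncol = 2))
  stopifnot(length(stubs) %% 2 == 0)
  edges <- matrix(sample(stubs), ncol = 2, byrow = TRUE)
  n_e <- nrow(edges)
  keyof <- function(a, b) paste(pmin(a, b), pmax(a, b))
  counts <- new.env(parent = emptyenv())      # multiset of current edge keys
  cnt <- function(k) { v <- counts[[k]]; if (is.null(v)) 0L else v }
  inc <- function(k) assign(k, cnt(k) + 1L, envir = counts)
  dec <- function(k) { v <- cnt(k) - 1L; if (v <= 0L) rm(list = k, envir = counts) else assign(k, v, envir = counts) }
  ext <- new.env(parent = emptyenv())
  for (k in existing_keys) assign(k, TRUE, envir = ext)
  for (k in keyof(edges[, 1], edges[, 2])) inc(k)
  is_bad <- function(i) {
    u <- edges[i, 1]; v <- edges[i, 2]
    if (u == v) return(TRUE)
    k <- keyof(u, v)
    cnt(k) > 1L || !is.null(ext[[k]]) ||
      (forbid_same_comm && comm[u] == comm[v])
  }
  valid_new <- function(u, v) {
    if (u == v) return(FALSE)
    k <- keyof(u, v)
    cnt(k) == 0L && is.null(ext[[k]]) &&
      !(forbid_same_comm && comm[u] == comm[v])
  }
  tries <- 0L
  max_tries <- max_sweeps * max(n_e, 50L)
  repeat {
    bad <- which(vapply(seq_len(n_e), is_bad, logical(1)))
    if (length(bad) == 0) return(edges)
    for (i in bad) {
      if (!is_bad(i)) next  # an earlier swap may have cleaned this copy
      fixed <- FALSE
      while (!fixed) {
        tries <- tries + 1L
        if (tries > max_tries) {
          stop("stub matching could not be cleaned of loops/duplicates within the sweep budget")
        }
        j <- sample.int(n_e, 1)
        if (j == i) next
        u <- edges[i, 1]; v <- edges[i, 2]
        x <- edges[j, 1]; y <- edges[j, 2]
        if (stats::runif(1) < 0.5) { tmp <- x; x <- y; y <- tmp }
        ki <- keyof(u, v); kj <- keyof(x, y)
        dec(ki); dec(kj)
        kux <- keyof(u, x); kvy <- keyof(v, y)
        if (valid_new(u, x) && kux != kvy) {
          inc(kux)
          if (valid_new(v, y)) {
            inc(kvy)
            edges[i, ] <- c(u, x)
            edges[j, ] <- c(v, y)
            fixed <- TRUE
          } else {
            dec(kux); inc(ki); inc(kj)
          }
        } else {
          inc(ki); inc(kj)
        }
      }
    }
  }
}

#' Generate a planted-community benchmark network
#'
#' The five-step construction: (1) sample a power-law degree sequence;
#' (2) split each node's degree into an internal part
#' `round((1 - mu) * d)` (round-half-even) and an external remainder;
#' (3) sample power-law community sizes summing to `n`; (4) assign nodes to
#' communities by iterative random placement with displacement when a
#' community is full, never placing a node whose internal degree cannot be
#' met; (5) wire internal stubs within communities and external stubs across
#' communities by configuration-model matching, with rewiring sweeps removing
#' self-loops, duplicates and intra-community external edges. With `mu = 0`
#' every edge is internal.
#'
#' Odd internal-stub sums within a community are fixed by converting one
#' internal stub to an external one (or dropping it when `mu = 0`, where no
#' external stubs may exist).
#'
#' @param cfg a [benchmark_config()]; `cfg$seed` fixes the whole
#'   construction.
#' @return list of class `planted_network`: `graph` (canonical igraph),
#'   `truth` (planted partition), `realized_mu` (fraction of edges running
#'   between communities), `config`.
#' @examples
#' pn <- generate_benchmark(benchmark_config(n = 120, mu = 0.1, k_min = 25,
#'                                           k_max = 50, seed = 7))
#' pn$realized_mu
#' @export
generate_benchmark <- function(cfg) {
  stopifnot(inherits(cfg, "benchmark_config"))
  set.seed(cfg$seed)
  d <- sample_degree_sequence(cfg)
  sizes <- sample_community_sizes(cfg)
  int_deg <- as.integer(round((1 - cfg$mu) * d))
  ext_deg <- d - int_deg
  comm <- assign_communities(int_deg, sizes, max_iter = 200L * cfg$n)
  # per-community parity of internal stubs
  for (j in seq_along(sizes)) {
    members <- which(comm == j)
    if (sum(int_deg[members]) %% 2 == 1) {
      cand <- members[int_deg[members] > 0]
      pick <- cand[sample.int(length(cand), 1)]
      int_deg[pick] <- int_deg[pick] - 1L
      if (cfg$mu > 0) ext_deg[pick] <- ext_deg[pick] + 1L
    }
  }
  labels <- sprintf("v%0*d", nchar(cfg$n), seq_len(cfg$n))
  existing <- character()
  edges <- matrix(integer(), ncol = 2)
  for (j in seq_along(sizes)) {
    members <- which(comm == j)
    stubs <- rep(members, int_deg[members])
    e <- match_stubs(stubs, comm, forbid_same_comm = FALSE,
                     existing_keys = existing, max_sweeps = cfg$max_rewire_sweeps)
    edges <- rbind(edges, e)
    if (nrow(e)) existing <- c(existing, paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
  }
  ext_stubs <- rep(seq_len(cfg$n), ext_deg)
  if (length(ext_stubs) %% 2 == 1) {
    # drop one external stub (can only arise from rounding interplay)
    ext_stubs <- ext_stubs[-sample.int(length(ext_stubs), 1)]
  }
  e <- match_stubs(ext_stubs, comm, forbid_same_comm = TRUE,
                   existing_keys = existing, max_sweeps = cfg$max_rewire_sweeps)
  edges <- rbind(edges, e)
  g <- pin_graph(cbind(labels[edges[, 1]], labels[edges[, 2]]))
  # nodes that ended with zero wired stubs would be isolated; register them
  g <- pin_graph(cbind(labels[edges[, 1]], labels[edges[, 2]]), nodes = labels)
  truth <- canonicalize_partition(setNames(comm, labels))
  el <- igraph::as_edgelist(g)
  inter <- mean(truth[el[, 1]] != truth[el[, 2]])
  structure(list(graph = g, truth = truth, realized_mu = inter, config = cfg),
            class = "planted_network")
}

#' Add random edges to a graph
#'
#' Adds `floor(fraction * m)` uniformly sampled distinct node pairs that are
#' not already edges (and are not self-loops); the original edges are kept.
#'
#' @param g graph.
#' @param fraction nonnegative fraction of the current edge count to add.
#' @return graph with the extra edges.
#' @export
add_random_edges <- function(g, fraction) {
  stopifnot(fraction >= 0)
  m <- igraph::gsize(g)
  n <- igraph::vcount(g)
  n_add <- floor(fraction * m)
  if (n_add == 0) return(g)
  if (n * (n - 1) / 2 - m < n_add) stop("not enough non-adjacent pairs to add")
  labs <- node_names(g)
  el <- igraph::as_edgelist(g)
  keys <- character(0)
  if (nrow(el)) keys <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "\t")
  have <- new.env(parent = emptyenv())
  for (k in keys) assign(k, TRUE, envir = have)
  added <- matrix(character(), ncol = 2)
  while (nrow(added) < n_add) {
    pair <- labs[sample.int(n, 2)]
    k <- paste(min(pair), max(pair), sep = "\t")
    if (!is.null(have[[k]])) next
    assign(k, TRUE, envir = have)
    added <- rbind(added, pair)
  }
  igraph::add_edges(g, t(added))
}

#' Delete random edges, preserving connectivity
#'
#' Removes `floor(fraction * m)` edges sampled uniformly among the current
#' candidates: edges whose endpoints both have degree at least 2 and whose
#' removal does not disconnect the graph (bridges are protected). The
#' candidate set is refreshed after each removal, so the output is always
#' connected with minimum degree at least 1.
#'
#' @param g connected graph.
#' @param fraction fraction of edges to delete, in `[0, 1)`.
#' @return connected graph with the edges removed.
#' @export
delete_random_edges <- function(g, fraction) {
  stopifnot(fraction >= 0, fraction < 1)
  if (igraph::components(g)$no > 1) stop("input graph must be connected")
  n_del <- floor(fraction * igraph::gsize(g))
  removed <- 0
  while (removed < n_del) {
    deg <- igraph::degree(g)
    el <- igraph::as_edgelist(g)
    ok <- deg[el[, 1]] >= 2 & deg[el[, 2]] >= 2
    bridge_ids <- igraph::bridges(g)
    ok[as.integer(bridge_ids)] <- FALSE
    cand <- which(ok)
    if (length(cand) == 0) {
      stop(sprintf("no removable edge left after deleting %d of %d requested", removed, n_del))
    }
    g <- igraph::delete_edges(g, cand[sample.int(length(cand), 1)])
    removed <- removed + 1
  }
  g
}
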