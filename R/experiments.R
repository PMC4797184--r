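#' Seed derivation
#'
#' All multi-run experiments derive per-run seeds deterministically from one
#' top-level seed: `derive_seed(seed, i, j, ...)` mixes the indices with
#' distinct odd multipliers modulo 2^31 - 1, so a rerun with the same
#' configuration and seed is bit-identical while runs differ from each other.
#'
#' @param seed top-level integer seed.
#' @param ... integer indices (replicate, grid position, ...).
#' @return derived integer seed in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  idx <- c(...)
  mult <- c(7919, 104729, 1299709, 15485863, 32452843)
  acc <- as.numeric(seed)
  for (i in seq_along(idx)) {
    acc <- (acc * 48271 + idx[i] * mult[((i - 1) %% length(mult)) + 1]) %% (2^31 - 1)
  }
  as.integer(acc %% (2^31 - 2)) + 1L
}

#' Detection sweep over networks and methods
#'
#' Runs every requested method on every network and records modularity and
#' module count (plus NMI against a supplied ground truth) in a long-format
#' result table. A method failing on one network is recorded as `NA` for
#' that cell and does not abort the sweep.
#'
#' @param networks named list; each element either a graph or a
#'   `planted_network` (whose truth enables `nmi_vs_truth`).
#' @param methods character vector of [detection_methods()] names.
#' @param seed top-level seed; per-cell seeds are derived with
#'   [derive_seed()].
#' @return data frame (`network`, `method`, `replicate`, `metric`, `value`)
#'   with the detected partitions in `attr(, "partitions")` (a list keyed
#'   `network::method`).
#' @export
run_detection_suite <- function(networks, methods, seed = 1L) {
  if (length(methods) == 0) stop("no detection method requested")
  methods <- vapply(methods, function(mm) match.arg(mm, detection_methods()), "")
  if (is.null(names(networks))) names(networks) <- sprintf("net%03d", seq_along(networks))
  rows <- list()
  partitions <- list()
  for (ni in seq_along(networks)) {
    net <- networks[[ni]]
    truth <- NULL
    if (inherits(net, "planted_network")) {
      truth <- net$truth
      net <- net$graph
    }
    for (mi in seq_along(methods)) {
      method <- methods[[mi]]
      cell_seed <- derive_seed(seed, ni, mi)
      res <- tryCatch({
        p <- run_algorithm(net, method, seed = cell_seed)
        vals <- c(Q = modularity_q(net, p), n_modules = max(p))
        if (!is.null(truth)) vals <- c(vals, nmi_vs_truth = nmi(truth, p))
        list(p = p, vals = vals)
      }, error = function(e) e)
      key <- paste(names(networks)[ni], method, sep = "::")
      if (inherits(res, "error")) {
        rows[[length(rows) + 1]] <- data.frame(
          network = names(networks)[ni], method = method, replicate = 1L,
          metric = "failed", value = NA_real_, stringsAsFactors = FALSE)
      } else {
        partitions[[key]] <- res$p
        rows[[length(rows) + 1]] <- data.frame(
          network = names(networks)[ni], method = method, replicate = 1L,
          metric = names(res$vals), value = unname(res$vals),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "partitions") <- partitions
  out
}

#' Perturbation (robustness) experiment
#'
#' For each replicate, perturbs the base network — `mode = "add"` adds a
#' fraction of random edges, `mode = "delete"` removes a fraction under the
#' degree-and-bridge guard of [delete_random_edges()] — reruns detection,
#' and records: in delete mode the NMI between the perturbed and the
#' unperturbed detection (computed over the shared node set, which deletion
#' leaves intact), in add mode the modularity of the perturbed detection.
#' Replicate seeds derive from `seed`.
#'
#' @param g base connected graph (or a `planted_network`).
#' @param methods method names.
#' @param mode `"add"` or `"delete"`.
#' @param fractions numeric vector of perturbation fractions.
#' @param replicates replicates per fraction.
#' @param seed top-level seed.
#' @return long data frame (`network`, `method`, `replicate`, `fraction`,
#'   `metric`, `value`); infeasible perturbations are recorded as `NA` rows.
#' @export
run_perturbation_experiment <- function(g, methods, mode = c("add", "delete"),
                                        fractions, replicates = 20L, seed = 1L) {
  mode <- match.arg(mode)
  if (inherits(g, "planted_network")) g <- g$graph
  methods <- vapply(methods, function(mm) match.arg(mm, detection_methods()), "")
  baseline <- list()
  for (mi in seq_along(methods)) {
    baseline[[methods[mi]]] <- run_algorithm(g, methods[mi], seed = derive_seed(seed, 0, mi))
  }
  rows <- list()
  for (fi in seq_along(fractions)) {
    f <- fractions[fi]
    for (r in seq_len(replicates)) {
      pert <- tryCatch({
        set.seed(derive_seed(seed, fi, r))
        if (mode == "add") add_random_edges(g, f) else delete_random_edges(g, f)
      }, error = function(e) e)
      for (mi in seq_along(methods)) {
        method <- methods[mi]
        val <- NA_real_
        metric <- if (mode == "add") "Q" else "nmi_vs_unperturbed"
        if (!inherits(pert, "error")) {
          val <- tryCatch({
            p <- run_algorithm(pert, method, seed = derive_seed(seed, 0, mi))
            if (mode == "add") {
              modularity_q(pert, p)
            } else {
              shared <- intersect(names(p), names(baseline[[method]]))
              nmi(baseline[[method]][shared], p[shared])
            }
          }, error = function(e) NA_real_)
        }
        rows[[length(rows) + 1]] <- data.frame(
          network = "base", method = method, replicate = r, fraction = f,
          metric = metric, value = val, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Column mean with table-style truncation
#'
#' Arithmetic mean of one method/metric across networks, reported both at
#' full precision and truncated toward zero at 4 decimals — the convention
#' of published summary rows (e.g. 0.47658 prints as 0.4765).
#'
#' @param table long result table ([run_detection_suite()]).
#' @param method method name.
#' @param metric metric name.
#' @return list: `mean`, `truncated`.
#' @export
column_mean <- function(table, method, metric) {
  sel <- table$method == method & table$metric == metric & !is.na(table$value)
  if (!any(sel)) stop(sprintf("no records for method '%s', metric '%s'", method, metric))
  m <- mean(table$value[sel])
  list(mean = m, truncated = trunc_decimals(m, 4))
}

#' @param x numeric vector.
#' @param digits decimals kept.
#' @rdname column_mean
#' @export
trunc_decimals <- function(x, digits) {
  trunc(x * 10^digits) / 10^digits
}

#' Modularity vs module-count regression
#'
#' Ordinary least squares of `Q` on the number of modules (order 1) or on
#' the count and its square (order 2), with the usual two-sided t-test
#' significance per coefficient.
#'
#' @param points data frame (or 2-column matrix) with columns `n_modules`
#'   and `Q`.
#' @param order 1 (linear) or 2 (quadratic).
#' @return list: `coefficients`, `p_values` (excluding the intercept),
#'   `fit` (the `lm` object).
#' @export
modularity_vs_count_regression <- function(points, order = 2) {
  stopifnot(order %in% c(1, 2))
  points <- as.data.frame(points)
  names(points)[1:2] <- c("n_modules", "Q")
  if (nrow(points) < order + 2) stop("too few points for the requested order")
  if (length(unique(points$n_modules)) < order + 1) stop("design is rank-deficient (too few distinct counts)")
  fit <- if (order == 2) {
    lm(Q ~ n_modules + I(n_modules^2), data = points)
  } else {
    lm(Q ~ n_modules, data = points)
  }
  coefs <- summary(fit)$coefficients
  pv <- coefs[-1, , drop = FALSE][, "Pr(>|t|)"]
  names(pv) <- rownames(coefs)[-1]
  list(coefficients = coefs[, "Estimate"],
       p_values = pv,
       fit = fit)
}

#' Planted-partition recovery sweep
#'
#' Generates `replicates` planted benchmarks per mixing value, runs every
#' requested method on the giant connected component of each, and records
#' the NMI between the detected partition and the planted truth (restricted
#' to the GCC nodes). Seeds derive from `seed`, so the sweep is fully
#' reproducible.
#'
#' @param mus numeric vector of mixing parameters.
#' @param methods method names (see [detection_methods()]).
#' @param replicates benchmarks per mixing value.
#' @param seed top-level seed.
#' @param n,d_avg,d_max,k_min,k_max benchmark dimensions passed to
#'   [benchmark_config()].
#' @return data frame (`mu`, `replicate`, `method`, `nmi`, `n_modules`, `q`).
#' @export
planted_recovery_sweep <- function(mus, methods, replicates = 20L, seed = 1L,
                                   n = 300, d_avg = 10, d_max = 20,
                                   k_min = 30, k_max = 60) {
  rows <- list()
  for (mi in seq_along(mus)) {
    for (r in seq_len(replicates)) {
      pn <- generate_benchmark(benchmark_config(
        n = n, mu = mus[mi], d_avg = d_avg, d_max = d_max,
        k_min = k_min, k_max = k_max, seed = derive_seed(seed, mi, r)))
      g <- giant_connected_component(pn$graph)
      for (ai in seq_along(methods)) {
        p <- run_algorithm(g, methods[ai], seed = derive_seed(seed, mi, r, ai))
        truth <- pn$truth[names(p)]
        rows[[length(rows) + 1]] <- data.frame(
          mu = mus[mi], replicate = r, method = methods[ai],
          nmi = nmi(truth, p), n_modules = max(p),
          q = modularity_q(g, p), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
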