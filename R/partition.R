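#' Partitions
#'
#' A partition is a named integer vector mapping every node label of a graph
#' to a community id. [canonicalize_partition()] relabels community ids to
#' `1..K`, numbering communities by the lexicographically smallest node they
#' contain, and sorts the vector by node name — two structurally identical
#' partitions canonicalize to identical vectors.
#'
#' @param x named vector (integer-like or character community ids).
#' @return named integer vector sorted by node name with ids `1..K`.
#' @export
canonicalize_partition <- function(x) {
  if (is.null(names(x)) || anyNA(names(x)) || any(!nzchar(names(x)))) {
    stop("a partition must be a named vector (node label -> community id)")
  }
  x <- x[order(names(x))]
  ids <- as.character(x)
  new_id <- seq_along(unique(ids))
  names(new_id) <- unique(ids)
  out <- as.integer(new_id[ids])
  names(out) <- names(x)
  out
}

#' Communities of a partition
#'
#' @param p partition.
#' @return list of character vectors of node labels, one per community id.
#' @export
communities <- function(p) {
  split(names(p), p)
}

check_same_nodes <- function(u, v) {
  du <- setdiff(names(u), names(v))
  dv <- setdiff(names(v), names(u))
  if (length(du) || length(dv)) {
    stop(sprintf("partitions cover different node sets (symmetric difference of size %d)",
                 length(du) + length(dv)))
  }
}

check_covers_graph <- function(g, p) {
  missing <- setdiff(node_names(g), names(p))
  if (length(missing)) {
    stop(sprintf("partition is missing node(s): %s",
                 paste(head(missing, 5), collapse = ", ")))
  }
}

#' Read / write a partition file
#'
#' Two-column TSV `node<TAB>community_id`, community ids nonnegative
#' integers. The writer emits nodes in lexicographic order.
#'
#' @param path file path.
#' @return `read_partition()` returns a canonical partition.
#' @export
read_partition <- function(path) {
  tab <- read.table(path, sep = "\t", header = FALSE, colClasses = "character",
                    col.names = c("node", "community"), comment.char = "#")
  p <- setNames(tab$community, tab$node)
  canonicalize_partition(p)
}

#' @param p partition.
#' @rdname read_partition
#' @export
write_partition <- function(p, path) {
  p <- canonicalize_partition(p)
  write.table(data.frame(node = names(p), community = unname(p)),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Modularity decomposition
#'
#' The community-pair edge fractions `e` and degree fractions `a` underlying
#' Newman modularity: `e[i, j]` is the fraction of edge ends running between
#' communities `i` and `j` (so `sum(e) == 1` and `e` is symmetric), and
#' `a[i] = sum_j e[i, j]` is the fraction of edge ends attached to community
#' `i`.
#'
#' @param g graph with at least one edge.
#' @param p partition covering the nodes of `g`.
#' @return list with `e` (K x K matrix), `a` (length-K vector), `m` (edge
#'   count).
#' @export
modularity_decomposition <- function(g, p) {
  check_covers_graph(g, p)
  m <- igraph::gsize(g)
  if (m == 0) stop("modularity is undefined for an edgeless graph")
  p <- canonicalize_partition(p[node_names(g)])
  K <- max(p)
  el <- igraph::as_edgelist(g)
  ci <- p[el[, 1]]
  cj <- p[el[, 2]]
  e <- matrix(0, K, K)
  for (row in seq_len(nrow(el))) {
    e[ci[row], cj[row]] <- e[ci[row], cj[row]] + 1
    e[cj[row], ci[row]] <- e[cj[row], ci[row]] + 1
  }
  e <- e / (2 * m)
  list(e = e, a = rowSums(e), m = m)
}

#' Newman modularity
#'
#' `Q = sum_i (e[i, i] - a[i]^2)`: the fraction of edges inside communities
#' minus its expectation under a degree-preserving random rewiring.
#'
#' @inheritParams modularity_decomposition
#' @return modularity score in `[-1, 1)`.
#' @examples
#' g <- pin_graph(rbind(c("a", "b"), c("b", "c"), c("a", "c")))
#' modularity_q(g, c(a = 1, b = 1, c = 1))  # single community: 0
#' @export
modularity_q <- function(g, p) {
  dec <- modularity_decomposition(g, p)
  sum(diag(dec$e) - dec$a^2)
}

#' Contingency table of two partitions
#'
#' Cell `(i, j)` counts the nodes shared by community `i` of `u` and
#' community `j` of `v`; the marginals `a`, `b` and total `N` feed the NMI.
#'
#' @param u,v partitions over the same node set.
#' @return list with `n` (R x C matrix), `a` (row sums), `b` (column sums),
#'   `N` (node count).
#' @export
contingency <- function(u, v) {
  check_same_nodes(u, v)
  u <- canonicalize_partition(u)
  v <- canonicalize_partition(v)[names(u)]
  n <- unclass(table(u, v))
  dimnames(n) <- NULL
  list(n = n, a = rowSums(n), b = colSums(n), N = length(u))
}

#' Normalized mutual information
#'
#' Information-theoretic agreement of two partitions built from their
#' contingency table. With entropies `H(U)`, `H(V)` and mutual information
#' `I(U, V)` (natural logarithm; `0 log 0 = 0`), the `"max"` variant returns
#' `I / max(H(U), H(V))` — 1 for identical partitions — and the `"sum"`
#' variant returns `I / (H(U) + H(V))`, which equals 0.5 for identical
#' partitions. `"max"` is the default; the `"sum"` normalization is retained
#' because some formulations divide by the entropy sum.
#'
#' If both partitions are single blocks (both entropies zero) the partitions
#' are identical: `"max"` returns 1 and `"sum"` returns 0.5 by the same
#' identical-partition convention. If exactly one entropy is zero the result
#' is 0.
#'
#' @param u,v partitions over the same node set.
#' @param variant `"max"` (default) or `"sum"`.
#' @return NMI score; in `[0, 1]` for `"max"`.
#' @export
nmi <- function(u, v, variant = c("max", "sum")) {
  variant <- match.arg(variant)
  ct <- contingency(u, v)
  N <- ct$N
  hu <- entropy_nat(ct$a / N)
  hv <- entropy_nat(ct$b / N)
  if (hu == 0 && hv == 0) return(if (variant == "max") 1 else 0.5)
  if (hu == 0 || hv == 0) return(0)
  pij <- ct$n / N
  expect <- outer(ct$a, ct$b) / N^2
  nz <- pij > 0
  i_uv <- sum(pij[nz] * log(pij[nz] / expect[nz]))
  if (variant == "max") i_uv / max(hu, hv) else i_uv / (hu + hv)
}

entropy_nat <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}
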