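#' Neighbourhood weight matrix
#'
#' The matrix product `M = A %*% S` of the adjacency matrix and the
#' shortest-path matrix: row `i` of `M` sums the shortest-path profiles of
#' `i`'s neighbours, giving each node a weight vector over all nodes. `M` is
#' in general asymmetric (a true matrix product, not an element-wise one —
#' the element-wise product of two symmetric matrices could never be
#' asymmetric).
#'
#' @param g connected graph.
#' @param s shortest-path matrix from [all_pairs_shortest_paths()] on `g`.
#' @return numeric matrix with the same dimnames as `s`.
#' @export
weight_matrix <- function(g, s) {
  a <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  a <- a[rownames(s), colnames(s), drop = FALSE]
  if (!identical(dim(a), dim(s))) stop("adjacency and shortest-path matrices disagree in dimension")
  m <- a %*% s
  dimnames(m) <- dimnames(s)
  m
}

#' Correlation distance between node profiles
#'
#' Pairwise correlation `rho` between the rows of `x` (each row is one
#' node's profile over all nodes), turned into the distance `D = 1 - rho`
#' in `[0, 2]`. Any pair involving a constant (zero-variance) row, where
#' correlation is undefined, gets the neutral distance 1; the diagonal is
#' forced to 0.
#'
#' @param x square numeric matrix with at least 3 columns (fewer points make
#'   a row correlation meaningless).
#' @param correlation `"pearson"` or `"spearman"` (average ranks for ties).
#' @return symmetric distance matrix with zero diagonal.
#' @export
correlation_distance <- function(x, correlation = c("pearson", "spearman")) {
  correlation <- match.arg(correlation)
  if (ncol(x) < 3) stop("correlation over rows needs at least 3 columns")
  rho <- suppressWarnings(cor(t(x), method = correlation))
  d <- 1 - rho
  d[is.na(d)] <- 1
  d <- (d + t(d)) / 2
  diag(d) <- 0
  dimnames(d) <- list(rownames(x), rownames(x))
  d
}

#' Ward clustering of a distance matrix
#'
#' Agglomerative hierarchical clustering of a precomputed distance matrix
#' under the Ward criterion. The default `"ward.D2"` dialect applies the
#' Lance–Williams recurrence to squared distances (the textbook Ward
#' objective); `"ward.D"` applies it to the distances as-is (the historical
#' variant). Both are deterministic.
#'
#' @param d symmetric distance matrix (e.g. from [correlation_distance()]).
#' @param dialect `"ward.D2"` (default) or `"ward.D"`.
#' @return an `hclust` dendrogram whose labels are the row names of `d`.
#' @export
ward_cluster <- function(d, dialect = c("ward.D2", "ward.D")) {
  dialect <- match.arg(dialect)
  if (any(is.na(d)) || any(is.nan(d))) stop("distance matrix contains NA/NaN")
  if (nrow(d) < 2) stop("clustering needs at least 2 nodes")
  hclust(as.dist(d), method = dialect)
}

#' Modularity-optimal dendrogram cut
#'
#' Evaluates Newman modularity for every cut level `k = 1..n` of a
#' dendrogram and returns the partition with maximal `Q`; ties go to the
#' smallest `k` (fewest communities).
#'
#' @param dend `hclust` object whose labels are the nodes of `g`.
#' @param g graph with at least one edge.
#' @return canonical partition, with attributes `k` (chosen level) and `q`
#'   (its modularity).
#' @export
cut_by_modularity <- function(dend, g) {
  labs <- dend$labels
  if (!setequal(labs, node_names(g))) stop("dendrogram leaves do not match graph nodes")
  n <- length(labs)
  cuts <- cutree(dend, k = seq_len(n))       # n x n membership matrix
  qs <- apply(cuts, 2, function(memb) modularity_fast(g, setNames(memb, labs)))
  k <- unname(which.max(qs))
  p <- canonicalize_partition(setNames(cuts[, k], labs))
  attr(p, "k") <- k
  attr(p, "q") <- unname(qs[k])
  p
}

# modularity without canonicalization overhead, for tight scan loops
modularity_fast <- function(g, p) {
  m <- igraph::gsize(g)
  el <- igraph::as_edgelist(g, names = TRUE)
  ci <- p[el[, 1]]
  cj <- p[el[, 2]]
  K <- max(p)
  internal <- sum(ci == cj) / m
  degsum <- tabulate(ci, K) + tabulate(cj, K)
  internal - sum((degsum / (2 * m))^2)
}

method_table <- data.frame(
  method = c("dsp-pearson", "dsp-spearman", "dm-pearson", "dm-spearman"),
  base = c("sp", "sp", "M", "M"),
  correlation = c("pearson", "spearman", "pearson", "spearman"),
  stringsAsFactors = FALSE
)

#' Correlation-distance community detection
#'
#' The full detection pipeline: all-pairs shortest paths, optionally the
#' weight matrix `M = A %*% S`, the correlation distance `1 - rho`, Ward
#' clustering, and the modularity-optimal cut. The four method names combine
#' the profile base (`sp` = shortest-path rows, `M` = weight-matrix rows)
#' with Pearson or Spearman correlation. Deterministic given the graph.
#'
#' @param g connected graph (pass the giant connected component).
#' @param base `"sp"` or `"M"`.
#' @param correlation `"pearson"` or `"spearman"`.
#' @param ward_dialect passed to [ward_cluster()].
#' @return canonical partition with attributes `k` and `q`.
#' @examples
#' g <- pin_graph(rbind(c("a","b"), c("b","c"), c("a","c"),
#'                      c("d","e"), c("e","f"), c("d","f"), c("c","d")))
#' p <- detect_communities(g, base = "sp", correlation = "pearson")
#' table(p)
#' @export
detect_communities <- function(g, base = c("sp", "M"),
                               correlation = c("pearson", "spearman"),
                               ward_dialect = c("ward.D2", "ward.D")) {
  base <- match.arg(base)
  correlation <- match.arg(correlation)
  s <- all_pairs_shortest_paths(g)
  x <- if (base == "M") weight_matrix(g, s) else s
  d <- correlation_distance(x, correlation)
  dend <- ward_cluster(d, match.arg(ward_dialect))
  cut_by_modularity(dend, g)
}
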