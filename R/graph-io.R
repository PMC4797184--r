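#' Construct a canonical network from an edge list
#'
#' Builds the undirected simple graph used throughout the package: string
#' vertex names, no self-loops, no duplicate edges, and vertices stored in
#' lexicographic name order so that every matrix derived from the graph is
#' reproducible bit-for-bit.
#'
#' @param edges two-column character matrix or data frame of endpoint labels;
#'   may have zero rows.
#' @param nodes optional character vector of node labels to register in
#'   addition to the edge endpoints (isolated nodes survive this way).
#' @return an `igraph` object (undirected, simple, named, lexicographic
#'   vertex order).
#' @examples
#' g <- pin_graph(rbind(c("a", "b"), c("b", "c")))
#' igraph::vcount(g)
#' @export
pin_graph <- function(edges, nodes = NULL) {
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (length(edges) == 0) {
    edges <- matrix(character(), ncol = 2)
  }
  if (ncol(edges) < 2) stop("`edges` must have two columns")
  storage.mode(edges) <- "character"
  edges <- edges[, 1:2, drop = FALSE]
  loops <- edges[, 1] == edges[, 2]
  if (any(loops)) {
    warning(sprintf("dropping %d self-loop(s)", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  # collapse duplicates irrespective of endpoint order
  if (nrow(edges) > 0) {
    key <- ifelse(edges[, 1] < edges[, 2],
                  paste(edges[, 1], edges[, 2], sep = "\t"),
                  paste(edges[, 2], edges[, 1], sep = "\t"))
    edges <- edges[!duplicated(key), , drop = FALSE]
  }
  vs <- sort(unique(c(as.vector(edges), as.character(nodes))))
  g <- igraph::make_empty_graph(n = length(vs), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = vs)
  if (nrow(edges) > 0) {
    g <- igraph::add_edges(g, t(edges))
  }
  g
}

#' Canonicalize an existing igraph object
#'
#' Simplifies (dropping loops/multi-edges) and reorders vertices
#' lexicographically by name. Unnamed graphs get names "1", "2", ...
#' in vertex-id order.
#'
#' @param g an `igraph` object.
#' @return a canonical undirected simple `igraph` object.
#' @export
as_pin_graph <- function(g) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
  if (is.null(igraph::V(g)$name)) {
    g <- igraph::set_vertex_attr(g, "name", value = as.character(seq_len(igraph::vcount(g))))
  }
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  nm <- igraph::V(g)$name
  igraph::permute(g, match(nm, sort(nm)))
}

node_names <- function(g) igraph::V(g)$name

#' Read an undirected edge list
#'
#' Parses a 2-column whitespace- or tab-separated edge list. Lines starting
#' with `#` are comments; self-loops are dropped with a warning; duplicate
#' edges (in either orientation) are collapsed.
#'
#' @param path file path.
#' @param directed_hint ignored except for validation; the file is always read
#'   as undirected (the convention for PIN exports).
#' @return a canonical `igraph` object.
#' @export
read_edge_list <- function(path, directed_hint = FALSE) {
  if (!file.exists(path)) stop(sprintf("cannot read edge list: '%s' does not exist", path))
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  toks <- strsplit(trimws(lines[idx]), "[ \t]+")
  bad <- lengths(toks) < 2
  if (any(bad)) {
    stop(sprintf("parse error: line %d has fewer than 2 fields", idx[which(bad)[1]]))
  }
  edges <- do.call(rbind, lapply(toks, function(x) x[1:2]))
  if (is.null(edges)) edges <- matrix(character(), ncol = 2)
  pin_graph(edges)
}

#' Write an undirected edge list
#'
#' Emits one `u<TAB>v` line per edge with `u < v` lexicographically, lines
#' sorted, so output is deterministic and round-trips through
#' [read_edge_list()].
#'
#' @param g graph.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  el <- igraph::as_edgelist(g)
  if (nrow(el) > 0) {
    swap <- el[, 1] > el[, 2]
    el[swap, ] <- el[swap, 2:1]
    lines <- sort(paste(el[, 1], el[, 2], sep = "\t"))
  } else {
    lines <- character()
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read / write GraphML
#'
#' Thin wrappers around igraph's GraphML support, returning/accepting the
#' package's canonical graph form.
#'
#' @param path file path.
#' @return `read_graphml()` returns a canonical `igraph` object.
#' @export
read_graphml <- function(path) {
  as_pin_graph(igraph::read_graph(path, format = "graphml"))
}

#' @param g graph.
#' @rdname read_graphml
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Giant connected component
#'
#' Induced subgraph on the largest connected component. If several components
#' tie for the largest size, the one containing the lexicographically smallest
#' node label is returned. An empty graph is returned unchanged.
#'
#' @param g graph.
#' @return a canonical `igraph` object.
#' @export
giant_connected_component <- function(g) {
  if (igraph::vcount(g) == 0) return(g)
  comp <- igraph::components(g)
  mx <- max(comp$csize)
  tied <- which(comp$csize == mx)
  if (length(tied) > 1) {
    # vertices are in lexicographic order, so the first vertex lying in a tied
    # component identifies the winner
    first <- which(comp$membership %in% tied)[1]
    winner <- comp$membership[first]
  } else {
    winner <- tied
  }
  sub <- igraph::induced_subgraph(g, which(comp$membership == winner))
  as_pin_graph(sub)
}

#' All-pairs shortest-path matrix
#'
#' Breadth-first hop counts between every pair of nodes of a connected graph,
#' indexed in the graph's lexicographic node order. Entries are unweighted hop
#' counts (edges), zero on the diagonal.
#'
#' @param g connected graph.
#' @return integer-valued symmetric matrix with node-name dimnames.
#' @export
all_pairs_shortest_paths <- function(g) {
  comp <- igraph::components(g)
  if (comp$no > 1) {
    stop(sprintf("graph is disconnected (%d components); pass the giant connected component", comp$no))
  }
  d <- igraph::distances(g, algorithm = "unweighted")
  d <- d[node_names(g), node_names(g), drop = FALSE]
  d
}

#' Edge density
#'
#' `2 m / (n (n - 1))` for an undirected simple graph with `n` nodes and `m`
#' edges, the convention used for summarizing PIN sizes.
#'
#' @param g graph with at least 2 nodes.
#' @return density in `[0, 1]`.
#' @export
edge_density <- function(g) {
  n <- igraph::vcount(g)
  if (n < 2) stop("edge density requires at least 2 nodes")
  2 * igraph::gsize(g) / (n * (n - 1))
}
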