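#' Read gene-set annotations
#'
#' Two dialects: GMT (per line: term, description, then member genes,
#' tab-separated) and two-column TSV (`gene<TAB>term`, accumulated into
#' term sets, duplicates collapsed).
#'
#' @param path file path.
#' @param format `"gmt"` or `"two_column"`.
#' @param organism optional organism tag stored on the result.
#' @return list of class `annotation_set`: `terms` (named list of gene
#'   character vectors), `names` (optional term descriptions), `organism`.
#' @export
read_annotations <- function(path, format = c("gmt", "two_column"), organism = NA_character_) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty annotation file")
    return(annotation_set(list(), organism = organism))
  }
  if (format == "gmt") {
    toks <- strsplit(lines, "\t")
    bad <- lengths(toks) < 3
    if (any(bad)) stop(sprintf("parse error: GMT line %d has fewer than 3 fields", which(bad)[1]))
    terms <- lapply(toks, function(x) unique(x[-(1:2)]))
    names(terms) <- vapply(toks, `[`, "", 1)
    descs <- setNames(vapply(toks, `[`, "", 2), names(terms))
    annotation_set(terms, names = descs, organism = organism)
  } else {
    toks <- strsplit(lines, "\t")
    bad <- lengths(toks) < 2
    if (any(bad)) stop(sprintf("parse error: line %d has fewer than 2 fields", which(bad)[1]))
    gene <- vapply(toks, `[`, "", 1)
    term <- vapply(toks, `[`, "", 2)
    terms <- lapply(split(gene, term), unique)
    annotation_set(terms, organism = organism)
  }
}

#' @param terms named list of gene character vectors.
#' @param names optional named character vector of term descriptions.
#' @rdname read_annotations
#' @export
annotation_set <- function(terms, names = NULL, organism = NA_character_) {
  stopifnot(is.list(terms))
  structure(list(terms = terms, names = names, organism = organism),
            class = "annotation_set")
}

#' Module-wise overrepresentation by Fisher's exact test
#'
#' For every (module, term) pair with a nonzero term intersection with the
#' background, computes the one-sided (over-representation) Fisher's exact
#' significance of the 2x2 table `[[k, K-k], [t-k, N-K-t+k]]`, where `k` is
#' the number of annotated genes in the module, `K` the module size, `t` the
#' number of annotated genes in the background and `N` the background size.
#' Term sets are intersected with the background before counting. The
#' one-sided tail equals the hypergeometric upper tail
#' `P(X >= k)`.
#'
#' The background defaults to all partitioned nodes (the analyzed network);
#' pass the annotated subset instead to use the annotated-only universe.
#'
#' @param p partition of the network under study.
#' @param ann an `annotation_set`.
#' @param background character vector of node labels, a subset of the
#'   partition's nodes.
#' @return data frame with columns `module`, `term`, `k`, `K`, `t`, `N`,
#'   `p_raw`, `significant` (all `NA` until [bonferroni_filter()]).
#' @export
fisher_enrichment <- function(p, ann, background = names(p)) {
  stopifnot(inherits(ann, "annotation_set"))
  if (length(background) == 0) stop("background node set is empty")
  extra <- setdiff(background, names(p))
  if (length(extra)) stop("background contains nodes absent from the partition")
  p <- p[names(p) %in% background]
  N <- length(background)
  mods <- communities(p)
  terms <- lapply(ann$terms, intersect, background)
  terms <- terms[lengths(terms) > 0]
  if (length(terms) == 0) stop("no annotation term intersects the background")
  rows <- list()
  for (mi in names(mods)) {
    members <- mods[[mi]]
    K <- length(members)
    for (ti in names(terms)) {
      t_n <- length(terms[[ti]])
      k <- length(intersect(members, terms[[ti]]))
      if (k == 0 && t_n == 0) next
      p_raw <- phyper(k - 1, t_n, N - t_n, K, lower.tail = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        module = mi, term = ti, k = k, K = K, t = t_n, N = N,
        p_raw = p_raw, significant = NA, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Bonferroni significance filter
#'
#' Marks results significant where `p_raw <= alpha / n_tests` (boundary
#' inclusive), `n_tests` being the number of rows — the whole family of
#' (module, term) tests run for the network. Set `per_term = TRUE` to divide
#' by the number of modules only, correcting within each term's family
#' instead.
#'
#' @param results data frame from [fisher_enrichment()].
#' @param alpha family significance level.
#' @param per_term correct per term rather than over all tests.
#' @return `results` with the `significant` flag set; attribute `threshold`
#'   holds the cutoff used.
#' @export
bonferroni_filter <- function(results, alpha = 0.001, per_term = FALSE) {
  stopifnot(alpha > 0, alpha < 1)
  if (is.null(results) || nrow(results) == 0) return(results)
  n_tests <- if (per_term) length(unique(results$module)) else nrow(results)
  thr <- alpha / n_tests
  results$significant <- results$p_raw <= thr
  attr(results, "threshold") <- thr
  results
}

#' Multi-module enrichment summary
#'
#' How many modules each term is significantly enriched in: per-term counts,
#' their histogram, and the maximum count (the number printed inside the bars
#' of per-algorithm enrichment barplots).
#'
#' @param results flagged data frame from [bonferroni_filter()].
#' @return list: `per_term` (named integer vector over significant terms),
#'   `histogram` (table: modules-per-term -> number of terms), `max_modules`.
#' @export
multi_module_summary <- function(results) {
  sig <- results[!is.na(results$significant) & results$significant, , drop = FALSE]
  if (is.null(sig) || nrow(sig) == 0) {
    return(list(per_term = integer(), histogram = table(integer()), max_modules = 0L))
  }
  per_term <- vapply(split(sig$module, sig$term), function(x) length(unique(x)), integer(1))
  list(per_term = per_term, histogram = table(per_term),
       max_modules = max(per_term))
}

#' Cross-organism shared enrichment
#'
#' Given one significant-term set per organism, groups terms by the number of
#' organisms in which they are significant.
#'
#' @param per_organism_terms list (length >= 2) of character vectors.
#' @return named list mapping shared-count (as character) to the terms seen
#'   in exactly that many organisms.
#' @export
cross_organism_overlap <- function(per_organism_terms) {
  stopifnot(length(per_organism_terms) >= 2)
  all_terms <- unlist(lapply(per_organism_terms, unique))
  counts <- table(all_terms)
  split(names(counts), as.integer(counts))
}

#' Synthetic annotations aligned to planted communities
#'
#' Builds an annotation fixture from a planted network so that enrichment is
#' testable without any ontology download: for each planted community,
#' `terms_per_community` terms each hold a `coverage` fraction of the
#' community's nodes plus `round(noise * |C|)` random outside nodes; in
#' addition `random_terms` unaligned terms of community-like size are drawn
#' as negatives. Deterministic given `seed`.
#'
#' @param pn a `planted_network`.
#' @param terms_per_community aligned terms per community.
#' @param coverage fraction of each community sampled into its terms.
#' @param noise fraction of the community size drawn as outside nodes.
#' @param random_terms number of unaligned negative-control terms.
#' @param seed integer seed.
#' @return an `annotation_set` (terms named `C<i>_t<j>` and `rand<k>`).
#' @export
synthetic_annotations <- function(pn, terms_per_community = 1, coverage = 0.8,
                                  noise = 0, random_terms = length(unique(pn$truth)),
                                  seed = 1L) {
  stopifnot(inherits(pn, "planted_network"),
            coverage >= 0, coverage <= 1, noise >= 0, noise <= 1)
  set.seed(seed)
  nodes <- names(pn$truth)
  comms <- communities(pn$truth)
  terms <- list()
  for (ci in names(comms)) {
    members <- comms[[ci]]
    outside <- setdiff(nodes, members)
    for (j in seq_len(terms_per_community)) {
      core <- sample(members, max(1, round(coverage * length(members))))
      extra <- if (noise > 0) sample(outside, min(length(outside), round(noise * length(members)))) else character()
      terms[[sprintf("C%s_t%d", ci, j)]] <- sort(c(core, extra))
    }
  }
  sizes <- lengths(comms)
  for (k in seq_len(random_terms)) {
    sz <- sizes[sample.int(length(sizes), 1)]
    terms[[sprintf("rand%d", k)]] <- sort(sample(nodes, sz))
  }
  annotation_set(terms, organism = "synthetic")
}
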