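# Degree-preserving randomization of the called interaction network and
# enrichment statistics for node-category edge counts.

#' Construct an interaction network
#'
#' Nodes are ORFs with optional (multi-label) category annotations; edges
#' are unordered ORF pairs. Duplicate edges are collapsed; homodimer edges
#' (self-pairs) are kept but flagged, and are excluded from rewiring and
#' from every enrichment statistic.
#'
#' @param edges Data frame with columns `orf_a`, `orf_b`, or a character
#'   vector of canonical keys from [canonical_pair()].
#' @param categories Optional named list: `categories[[node]]` is a
#'   character vector of category labels.
#' @return An object of class `bfg_network`.
#' @export
interaction_network <- function(edges, categories = NULL) {
  keys <- if (is.data.frame(edges)) {
    canonical_pair(edges$orf_a, edges$orf_b)
  } else {
    as.character(edges)
  }
  keys <- unique(keys)
  m <- split_pair(keys)
  nodes <- sort(unique(c(m[, 1L], m[, 2L], names(categories))))
  structure(
    list(edges = m, homodimer = m[, 1L] == m[, 2L], nodes = nodes,
         categories = categories %||% list()),
    class = "bfg_network")
}

#' @export
print.bfg_network <- function(x, ...) {
  cat(sprintf("Interaction network: %d nodes, %d edges (%d homodimers)\n",
              length(x$nodes), nrow(x$edges), sum(x$homodimer)))
  if (length(x$categories)) {
    cat("  categories:",
        paste(sort(unique(unlist(x$categories))), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a network from an edge-list TSV
#'
#' @param edge_path TSV with columns `orf_a`, `orf_b`.
#' @param category_path Optional TSV with columns `node`, `category` (one
#'   row per label; nodes may carry several).
#' @return A [interaction_network()] object.
#' @export
read_network <- function(edge_path, category_path = NULL) {
  ed <- utils::read.delim(edge_path, stringsAsFactors = FALSE,
                          colClasses = "character")
  cats <- NULL
  if (!is.null(category_path)) {
    cd <- utils::read.delim(category_path, stringsAsFactors = FALSE,
                            colClasses = "character")
    cats <- split(cd$category, cd$node)
  }
  interaction_network(ed, cats)
}

#' Degree-preserving edge rewiring
#'
#' Randomizes the network by repeated double-edge swaps: two edges (a,b)
#' and (c,d) are replaced by (a,d) and (c,b) (endpoint assignment
#' randomized), rejecting swaps that would create a self-edge or a
#' duplicate. The degree sequence is preserved exactly. Homodimer edges
#' are removed before rewiring and are not reattached. If no valid swap
#' exists (e.g. a triangle), the input edges are returned with a warning.
#'
#' @param network A [interaction_network()].
#' @param swaps_per_edge Accepted swaps per edge (default 10).
#' @param n_swaps Exact number of accepted swaps, overriding
#'   `swaps_per_edge` (useful for single-swap analyses).
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return A rewired `bfg_network` (homodimer-free).
#' @export
rewire_network <- function(network, swaps_per_edge = 10L, n_swaps = NULL,
                           seed = NULL) {
  stopifnot(inherits(network, "bfg_network"))
  if (!is.null(seed)) set.seed(seed)
  e <- network$edges[!network$homodimer, , drop = FALSE]
  n <- nrow(e)
  target <- n_swaps %||% (swaps_per_edge * n)
  if (n < 2L || target < 1L) {
    if (n < 2L) warning("fewer than 2 rewirable edges; returning input")
    return(interaction_network(canonical_pair(e[, 1L], e[, 2L]),
                               network$categories))
  }
  seen <- new.env(hash = TRUE, parent = emptyenv())
  key <- function(a, b) if (a <= b) paste(a, b) else paste(b, a)
  for (i in seq_len(n)) assign(key(e[i, 1L], e[i, 2L]), TRUE, envir = seen)

  accepted <- 0L
  attempts <- 0L
  max_attempts <- max(1000L, 200L * target)
  while (accepted < target && attempts < max_attempts) {
    attempts <- attempts + 1L
    ij <- sample.int(n, 2L)
    a <- e[ij[1L], 1L]; b <- e[ij[1L], 2L]
    c_ <- e[ij[2L], 1L]; d <- e[ij[2L], 2L]
    if (stats::runif(1L) < 0.5) { tmp <- c_; c_ <- d; d <- tmp }
    if (a == d || c_ == b) next
    k1 <- key(a, d); k2 <- key(c_, b)
    if (k1 == k2 || exists(k1, envir = seen) || exists(k2, envir = seen)) next
    rm(list = c(key(a, b), key(c_, d)), envir = seen)
    assign(k1, TRUE, envir = seen)
    assign(k2, TRUE, envir = seen)
    e[ij[1L], ] <- c(a, d)
    e[ij[2L], ] <- c(c_, b)
    accepted <- accepted + 1L
  }
  if (accepted < target) {
    warning("only ", accepted, " of ", target,
            " swaps possible; network may be too constrained to rewire")
  }
  out <- interaction_network(canonical_pair(e[, 1L], e[, 2L]),
                             network$categories)
  out$nodes <- network$nodes
  out
}

.count_category_edges <- function(network, category_a, category_b) {
  has <- function(node, cat) {
    labs <- network$categories[[node]]
    !is.null(labs) && cat %in% labs
  }
  e <- network$edges[!network$homodimer, , drop = FALSE]
  if (!nrow(e)) return(0L)
  a1 <- vapply(e[, 1L], has, TRUE, cat = category_a)
  b2 <- vapply(e[, 2L], has, TRUE, cat = category_b)
  a2 <- vapply(e[, 2L], has, TRUE, cat = category_a)
  b1 <- vapply(e[, 1L], has, TRUE, cat = category_b)
  sum((a1 & b2) | (a2 & b1))
}

.count_shared_annotation_edges <- function(network, annotations) {
  e <- network$edges[!network$homodimer, , drop = FALSE]
  if (!nrow(e)) return(0L)
  shared <- vapply(seq_len(nrow(e)), function(i) {
    length(intersect(annotations[[e[i, 1L]]], annotations[[e[i, 2L]]])) > 0L
  }, TRUE)
  sum(shared)
}

.enrichment <- function(network, stat_fun, statistic_name, n_null,
                        swaps_per_edge, seed) {
  if (n_null < 1L) stop("n_null must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  observed <- stat_fun(network)
  null_stats <- vapply(seq_len(n_null), function(k) {
    stat_fun(rewire_network(network, swaps_per_edge = swaps_per_edge))
  }, 0)
  structure(
    list(statistic_name = statistic_name, observed = observed,
         null_mean = mean(null_stats), null_sd = stats::sd(null_stats),
         empirical_p = (1 + sum(null_stats >= observed)) / (1 + n_null),
         n_rewired_networks = n_null, null_stats = null_stats),
    class = "bfg_enrichment")
}

#' @export
print.bfg_enrichment <- function(x, ...) {
  cat(sprintf(
    "%s: observed %d vs null %.2f +/- %.2f (%d rewired networks), empirical p = %.4g\n",
    x$statistic_name, x$observed, x$null_mean, x$null_sd,
    x$n_rewired_networks, x$empirical_p))
  invisible(x)
}

#' Category-pair edge enrichment against the rewiring null
#'
#' Counts non-homodimer edges with one endpoint in `category_a` and the
#' other in `category_b` (both, when the categories coincide), and compares
#' the observed count against `n_null` degree-preserving rewirings of the
#' network. The empirical p-value uses the `(1 + #null >= observed) /
#' (1 + n_null)` correction, so its smallest attainable value is
#' `1 / (n_null + 1)`.
#'
#' @param network A [interaction_network()] with categories.
#' @param category_a,category_b Category labels.
#' @param n_null Number of rewired networks (default 1000).
#' @param swaps_per_edge Passed to [rewire_network()].
#' @param seed Optional integer seed.
#' @return An object of class `bfg_enrichment`.
#' @export
category_enrichment <- function(network, category_a, category_b,
                                n_null = 1000L, swaps_per_edge = 10L,
                                seed = NULL) {
  labs <- unique(unlist(network$categories))
  if (!category_a %in% labs || !category_b %in% labs) {
    stop("category not present on any node")
  }
  .enrichment(
    network,
    function(net) .count_category_edges(net, category_a, category_b),
    sprintf("%s-%s edge count", category_a, category_b),
    n_null, swaps_per_edge, seed)
}

#' Shared-annotation edge enrichment against the rewiring null
#'
#' Counts non-homodimer edges whose endpoints share at least one annotation
#' (e.g. human protein pairs each targeted by a common viral protein), with
#' the same rewiring null and empirical p as [category_enrichment()].
#'
#' @param network A [interaction_network()].
#' @param annotations Named list: `annotations[[node]]` is a character
#'   vector (e.g. of viral proteins targeting that node).
#' @inheritParams category_enrichment
#' @return An object of class `bfg_enrichment`.
#' @export
shared_target_enrichment <- function(network, annotations, n_null = 1000L,
                                     swaps_per_edge = 10L, seed = NULL) {
  if (length(annotations) == 0L) stop("annotation map is empty")
  .enrichment(
    network,
    function(net) .count_shared_annotation_edges(net, annotations),
    "shared-annotation edge count",
    n_null, swaps_per_edge, seed)
}
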