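# Genomic-species delineation: build the thresholded ANI graph and cluster it
# with a from-scratch Markov Cluster (MCL) implementation.

#' Build an ANI graph from pairwise comparisons
#'
#' Self-comparisons are dropped. An undirected edge between two genomes is
#' kept iff the larger of the (possibly asymmetric) directional ANI values
#' reaches the threshold; its weight is the mean of the available directions.
#' The default threshold of 95% is the classical intra-species boundary for
#' microbial genomes.
#'
#' @param pairs data.frame as returned by [read_ani_pairs()].
#' @param threshold ANI percent in (0, 100]; default 95.
#' @param genomes optional character roster; genomes never mentioned in
#'   `pairs` become isolated nodes. Required if `pairs` is empty.
#' @return object of class `ani_graph`: list with `nodes` (sorted character
#'   vector), `edges` (data.frame `from`, `to`, `weight`) and `threshold`.
#' @export
build_ani_graph <- function(pairs, threshold = 95, genomes = NULL) {
  if (threshold <= 0 || threshold > 100)
    stop_format("threshold must lie in (0, 100], got %s", threshold)
  pairs <- pairs[pairs$query != pairs$reference, , drop = FALSE]
  nodes <- sort(unique(c(pairs$query, pairs$reference, genomes)))
  if (length(nodes) == 0L)
    stop_format("empty ANI pair list and no genome roster supplied")
  if (nrow(pairs)) {
    a <- pmin(pairs$query, pairs$reference)
    b <- pmax(pairs$query, pairs$reference)
    key <- paste(a, b, sep = "\r")
    mx <- tapply(pairs$ani, key, max)
    mn <- tapply(pairs$ani, key, mean)
    keep <- mx >= threshold
    ke <- names(mx)[keep]
    parts <- strsplit(ke, "\r", fixed = TRUE)
    edges <- data.frame(
      from = vapply(parts, `[`, character(1L), 1L),
      to = vapply(parts, `[`, character(1L), 2L),
      weight = unname(mn[keep]),
      stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  } else {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, threshold = threshold),
            class = "ani_graph")
}

#' @export
print.ani_graph <- function(x, ...) {
  cat(sprintf("ANI graph: %d genomes, %d edges at threshold %.6g%%\n",
              length(x$nodes), nrow(x$edges), x$threshold))
  invisible(x)
}

#' Markov clustering of an ANI graph
#'
#' From-scratch MCL (van Dongen): build a column-stochastic transition matrix
#' from the edge weights with per-node self-loops, then iterate expansion
#' (matrix power) and inflation (elementwise power + column renormalization),
#' pruning entries below `prune`, until the maximum column change falls below
#' `tol`. Clusters are read off the attractor structure of the limit matrix;
#' every node is assigned to exactly one cluster (overlaps broken by largest
#' membership weight, then lexicographically). Disconnected components of the
#' graph are never merged.
#'
#' The self-loop weight of a node is its maximum incident edge weight
#' (1 for isolated nodes), which guarantees aperiodicity.
#'
#' @param graph an [build_ani_graph()] result.
#' @param inflation inflation exponent r > 1 (default 2).
#' @param expansion integer matrix power e >= 2 (default 2).
#' @param prune entries below this value are zeroed each iteration.
#' @param tol convergence tolerance on the max column change.
#' @param max_iter iteration cap; non-convergence returns the current
#'   clustering with `converged = FALSE` and a warning.
#' @param binary_edges use unit weights instead of ANI weights.
#' @return object of class `species_clustering`: list with `membership`
#'   (named character vector genome -> cluster label, labels `C1, C2, ...`
#'   ordered by descending size then lexicographic smallest member),
#'   `clusters` (list of member vectors), `converged`, `iterations`.
#' @export
mcl <- function(graph, inflation = 2, expansion = 2L, prune = 1e-6,
                tol = 1e-6, max_iter = 200L, binary_edges = FALSE) {
  if (inflation <= 1) stop_format("inflation must exceed 1")
  expansion <- as.integer(expansion)
  if (expansion < 2L) stop_format("expansion must be an integer >= 2")
  nodes <- sort(graph$nodes)
  n <- length(nodes)
  if (n == 0L) stop_format("empty node set")
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(graph$edges)) {
    w <- if (binary_edges) rep(1, nrow(graph$edges)) else graph$edges$weight
    i <- match(graph$edges$from, nodes)
    j <- match(graph$edges$to, nodes)
    A[cbind(i, j)] <- w
    A[cbind(j, i)] <- w
  }
  loop <- apply(A, 2L, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  M <- sweep(A, 2L, colSums(A), "/")
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    Mx <- M
    for (k in seq_len(expansion - 1L)) Mx <- Mx %*% M
    Mx <- Mx^inflation
    Mx[Mx < prune] <- 0
    cs <- colSums(Mx)
    cs[cs == 0] <- 1
    Mx <- sweep(Mx, 2L, cs, "/")
    delta <- max(abs(Mx - M))
    M <- Mx
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("MCL did not converge in %d iterations", max_iter),
            call. = FALSE)
  # Attractors: nodes that recur on their own random walk. Each column is
  # assigned to its strongest attractor; attractor systems spanning several
  # attractors are merged via their mutual support.
  attract <- which(diag(M) > prune)
  if (length(attract) == 0L) attract <- seq_len(n)  # degenerate fallback
  assign_to <- integer(n)
  for (j in seq_len(n)) {
    w <- M[attract, j]
    if (all(w == 0)) w <- A[attract, j]  # pruned-out column: nearest attractor
    if (all(w == 0)) { assign_to[j] <- if (j %in% attract) j else attract[1L]; next }
    best <- attract[w == max(w)]
    assign_to[j] <- min(best)  # lexicographic tie-break (nodes are sorted)
  }
  # merge attractors that support each other (one attractor system = cluster)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  union_ <- function(x, y) { rx <- find(x); ry <- find(y); if (rx != ry) parent[max(rx, ry)] <<- min(rx, ry) }
  for (a in attract) for (b in attract)
    if (a < b && (M[a, b] > prune || M[b, a] > prune)) union_(a, b)
  for (j in seq_len(n)) union_(j, assign_to[j])
  comp <- vapply(seq_len(n), find, integer(1L))
  groups <- split(nodes, comp)
  sizes <- lengths(groups)
  first_member <- vapply(groups, function(g) min(g), character(1L))
  ord <- order(-sizes, first_member)
  groups <- groups[ord]
  labels <- paste0("C", seq_along(groups))
  membership <- stats::setNames(
    rep(labels, lengths(groups)), unlist(groups, use.names = FALSE))
  membership <- membership[nodes]
  structure(list(membership = membership,
                 clusters = stats::setNames(unname(groups), labels),
                 converged = converged, iterations = iter,
                 inflation = inflation, expansion = expansion),
            class = "species_clustering")
}

#' @export
print.species_clustering <- function(x, ...) {
  cat(sprintf("Species clustering: %d genomes in %d clusters (%s after %d iterations)\n",
              length(x$membership), length(x$clusters),
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Summarize a species clustering
#'
#' @param clustering a [mcl()] result.
#' @return data.frame (`cluster`, `size`, `members`) sorted by descending
#'   size, ties broken by the lexicographically smallest member.
#' @export
cluster_summary <- function(clustering) {
  groups <- clustering$clusters
  if (length(groups) == 0L)
    return(data.frame(cluster = character(), size = integer(),
                      members = character(), stringsAsFactors = FALSE))
  data.frame(
    cluster = names(groups),
    size = unname(lengths(groups)),
    members = vapply(groups, function(g) paste(sort(g), collapse = ","),
                     character(1L)),
    stringsAsFactors = FALSE, row.names = NULL)
}
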