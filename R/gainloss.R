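# Wagner-parsimony reconstruction of ancestral gene content on a fixed
# rooted species tree: per-family Sankoff dynamic programming over the
# binary states {absent, present} with configurable gain/loss penalties,
# vectorized across gene families.

#' Binarize a gene-count matrix
#'
#' @param mat gene-count matrix.
#' @return integer 0/1 matrix of the same shape (1 iff count >= 1).
#' @export
binarize <- function(mat) {
  out <- (mat > 0) * 1L
  dimnames(out) <- dimnames(mat)
  out
}

node_names <- function(tree) {
  c(tree$tip.label, tree$node.label)
}

#' Wagner-parsimony ancestral gene content
#'
#' Per family, a bottom-up Sankoff pass computes
#' `cost(node, s) = sum over children of min_t (cost(child, t) + penalty(s -> t))`
#' with `penalty(0 -> 1) = gain` and `penalty(1 -> 0) = loss`; the root takes
#' the cheaper state (ties resolved by `root_tie`, default absence, which
#' avoids inflating ancestral genome size). A top-down traceback then picks
#' each child's state minimizing `cost + penalty`, resolving ties toward the
#' parent's state (minimizing spurious event pairs on sibling edges).
#' Multifurcations are handled natively by the sum over children.
#'
#' @param tree rooted `ape::phylo` with named internal nodes (see
#'   [read_tree()]); branch lengths are ignored.
#' @param bin binary presence/absence matrix (families x leaves); its column
#'   set must equal the tree's leaf set.
#' @param gain gain penalty (> 0, default 1).
#' @param loss loss penalty (> 0, default 1).
#' @param root_tie `"absence"` (default) or `"presence"`.
#' @return object of class `ancestral_content`: list with `states`
#'   (nodes x families 0/1 matrix, rows named by tip then internal node
#'   labels), `present` (list of family sets per node), `gained`/`lost`
#'   (family sets per non-root node, relative to the parent), `events`
#'   (data.frame `node`, `parent`, `present`, `gained`, `lost`),
#'   `total_cost` (per-family parsimony cost vector), `tree`.
#' @export
wagner_reconstruct <- function(tree, bin, gain = 1, loss = 1,
                               root_tie = c("absence", "presence")) {
  root_tie <- match.arg(root_tie)
  if (gain <= 0 || loss <= 0) stop_format("penalties must be positive")
  if (is.null(tree$node.label)) tree <- name_internal_nodes(tree)
  tips <- tree$tip.label
  sym <- c(setdiff(tips, colnames(bin)), setdiff(colnames(bin), tips))
  if (length(sym))
    stop_format("tree leaves and matrix genomes differ: %s",
                paste(sym, collapse = ", "))
  n <- length(tips)
  m <- tree$Nnode
  nf <- nrow(bin)
  fam <- rownames(bin)
  leaf_states <- t(bin[, tips, drop = FALSE])  # tips x families
  edge <- stats::reorder(tree, "postorder")$edge

  cost0 <- matrix(0, n + m, nf)
  cost1 <- matrix(0, n + m, nf)
  cost0[seq_len(n), ] <- ifelse(leaf_states == 1L, Inf, 0)
  cost1[seq_len(n), ] <- ifelse(leaf_states == 1L, 0, Inf)
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1L]; ch <- edge[e, 2L]
    cost0[p, ] <- cost0[p, ] + pmin(cost0[ch, ], gain + cost1[ch, ])
    cost1[p, ] <- cost1[p, ] + pmin(loss + cost0[ch, ], cost1[ch, ])
  }

  states <- matrix(NA_integer_, n + m, nf,
                   dimnames = list(node_names(tree), fam))
  states[seq_len(n), ] <- leaf_states
  root <- n + 1L
  r0 <- cost0[root, ]; r1 <- cost1[root, ]
  states[root, ] <- ifelse(r0 < r1, 0L,
                    ifelse(r1 < r0, 1L,
                           if (root_tie == "absence") 0L else 1L))
  # preorder traceback (reverse postorder visits parents before children)
  for (e in rev(seq_len(nrow(edge)))) {
    p <- edge[e, 1L]; ch <- edge[e, 2L]
    if (ch <= n) next  # leaves are observed
    s <- states[p, ]
    c0 <- cost0[ch, ] + ifelse(s == 1L, loss, 0)
    c1 <- cost1[ch, ] + ifelse(s == 0L, gain, 0)
    states[ch, ] <- ifelse(c0 < c1, 0L, ifelse(c1 < c0, 1L, s))
  }

  nn <- node_names(tree)
  present <- apply(states, 1L, function(s) fam[s == 1L], simplify = FALSE)
  gained <- vector("list", n + m); lost <- vector("list", n + m)
  names(gained) <- names(lost) <- nn
  parent_of <- rep(NA_integer_, n + m)
  parent_of[edge[, 2L]] <- edge[, 1L]
  for (v in seq_len(n + m)) {
    p <- parent_of[v]
    if (is.na(p)) { gained[[v]] <- character(); lost[[v]] <- character(); next }
    gained[[v]] <- fam[states[v, ] == 1L & states[p, ] == 0L]
    lost[[v]] <- fam[states[v, ] == 0L & states[p, ] == 1L]
  }
  events <- data.frame(
    node = nn,
    parent = ifelse(is.na(parent_of), NA_character_, nn[parent_of]),
    present = vapply(present, length, integer(1L)),
    gained = vapply(gained, length, integer(1L)),
    lost = vapply(lost, length, integer(1L)),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(states = states, present = present, gained = gained,
                 lost = lost, events = events,
                 total_cost = pmin(r0, r1), tree = tree,
                 gain = gain, loss = loss, root_tie = root_tie),
            class = "ancestral_content")
}

#' @export
print.ancestral_content <- function(x, ...) {
  cat(sprintf("Wagner-parsimony ancestral content: %d families on %d nodes (total cost %g)\n",
              ncol(x$states), nrow(x$states), sum(x$total_cost)))
  print(utils::head(x$events, 10L))
  invisible(x)
}

#' Report gene content at one tree node
#'
#' @param content an [wagner_reconstruct()] result.
#' @param node node name (leaf label or internal node label).
#' @return list with `present_count`, `gained_count`, `lost_count`, and
#'   sorted family lists `present`, `gained`, `lost` (gains/losses are
#'   relative to the parent; empty at the root).
#' @export
node_report <- function(content, node) {
  nn <- rownames(content$states)
  if (!node %in% nn) stop_format("unknown node '%s'", node)
  list(node = node,
       present_count = length(content$present[[node]]),
       gained_count = length(content$gained[[node]]),
       lost_count = length(content$lost[[node]]),
       present = sort(content$present[[node]]),
       gained = sort(content$gained[[node]]),
       lost = sort(content$lost[[node]]))
}

#' Compare reconstructed gains/losses to a simulation's true event log
#'
#' Validation harness for the gain/loss stage: reconstructs ancestral content
#' from a [simulate_gene_content()] draw and compares per-edge inferred event
#' counts to the simulation's true log. True counts are restricted to
#' families observable in at least one leaf (families extinct everywhere are
#' unreconstructable in principle).
#'
#' @param sim a [simulate_gene_content()] result.
#' @param gain,loss,root_tie passed to [wagner_reconstruct()].
#' @return list with `per_edge` (data.frame: node, true/inferred gains and
#'   losses) and `spearman` (rank correlation of total per-edge event
#'   counts).
#' @export
simulate_recovery_check <- function(sim, gain = 1, loss = 1,
                                    root_tie = "absence") {
  rec <- wagner_reconstruct(sim$tree, sim$matrix, gain = gain, loss = loss,
                            root_tie = root_tie)
  observable <- rownames(sim$matrix)
  ev <- rec$events[!is.na(rec$events$parent), , drop = FALSE]
  true_g <- vapply(ev$node, function(v)
    length(intersect(sim$events[[v]]$gained, observable)), integer(1L))
  true_l <- vapply(ev$node, function(v)
    length(intersect(sim$events[[v]]$lost, observable)), integer(1L))
  per_edge <- data.frame(node = ev$node,
                         true_gained = true_g, true_lost = true_l,
                         inferred_gained = ev$gained, inferred_lost = ev$lost,
                         stringsAsFactors = FALSE, row.names = NULL)
  tot_true <- true_g + true_l
  tot_inf <- ev$gained + ev$lost
  rho <- if (stats::sd(tot_true) == 0 || stats::sd(tot_inf) == 0) NA_real_
         else stats::cor(tot_true, tot_inf, method = "spearman")
  list(per_edge = per_edge, spearman = rho)
}
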