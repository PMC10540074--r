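# Independent oracles, coded from scratch against the published formulas and
# kept deliberately separate in style from the package implementations.

# -- Tajima (1989) D, second implementation ----------------------------------

oracle_tajima_d <- function(mat) {
  acgt <- c("A", "C", "G", "T")
  keep <- apply(mat, 2, function(col) all(col %in% acgt))
  mat <- mat[, keep, drop = FALSE]
  n <- nrow(mat)
  S <- 0L
  for (j in seq_len(ncol(mat)))
    if (length(unique(mat[, j])) > 1L) S <- S + 1L
  # mean pairwise differences by explicit pair loop
  total <- 0
  np <- 0L
  for (i in seq_len(n - 1L)) for (k in (i + 1L):n) {
    total <- total + sum(mat[i, ] != mat[k, ])
    np <- np + 1L
  }
  pi_hat <- total / np
  if (S == 0L) return(list(S = S, pi = pi_hat, D = NA_real_))
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n * n + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / (a1 * a1)
  e1 <- c1 / a1
  e2 <- c2 / (a1 * a1 + a2)
  D <- (pi_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  list(S = S, pi = pi_hat, D = D)
}

# -- Nei-Gojobori (1986), pathway-enumeration oracle --------------------------

oracle_codon_table <- local({
  tab <- NULL
  function() {
    if (!is.null(tab)) return(tab)
    b <- c("T", "C", "A", "G")
    cods <- character(0)
    for (x in b) for (y in b) for (z in b) cods <- c(cods, paste0(x, y, z))
    aas <- strsplit(paste0("FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRR",
                           "IIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"), "")[[1]]
    tab <<- stats::setNames(aas, cods)
    tab
  }
})

oracle_site_counts <- function(codon) {
  code <- oracle_codon_table()
  stopifnot(code[[codon]] != "*")
  s <- 0; n <- 0
  chars <- strsplit(codon, "")[[1]]
  for (pos in 1:3) {
    for (alt in setdiff(c("T", "C", "A", "G"), chars[pos])) {
      mut <- chars
      mut[pos] <- alt
      mutc <- paste(mut, collapse = "")
      if (code[[mutc]] == "*") next          # stop: no opportunity
      if (code[[mutc]] == code[[codon]]) s <- s + 1 / 3
      else n <- n + 1 / 3
    }
  }
  c(syn = s, nonsyn = n)
}

# Recursive DFS over substitution orders between two codons; averages
# synonymous/nonsynonymous step counts over pathways avoiding stop codons,
# falling back to all pathways (stop steps nonsynonymous) if all are blocked.
oracle_pathways <- function(c1, c2, allow_stop = FALSE) {
  code <- oracle_codon_table()
  a <- strsplit(c1, "")[[1]]
  b <- strsplit(c2, "")[[1]]
  walk <- function(cur, remaining) {
    if (length(remaining) == 0L) return(list(c(0, 0)))
    res <- list()
    for (p in remaining) {
      nxt <- cur
      nxt[p] <- b[p]
      nxtc <- paste(nxt, collapse = "")
      if (code[[nxtc]] == "*" && !allow_stop) next
      step <- if (code[[paste(cur, collapse = "")]] == code[[nxtc]])
        c(1, 0) else c(0, 1)
      for (tail in walk(nxt, setdiff(remaining, p)))
        res[[length(res) + 1L]] <- step + tail
    }
    res
  }
  walk(a, setdiff(which(a != b), integer(0)))
}

oracle_ng86 <- function(seq1, seq2) {
  code <- oracle_codon_table()
  split3 <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  cods1 <- split3(seq1)
  cods2 <- split3(seq2)
  Ss <- Ns <- Sd <- Nd <- 0
  for (k in seq_along(cods1)) {
    ok <- grepl("^[ACGT]{3}$", cods1[k]) && grepl("^[ACGT]{3}$", cods2[k]) &&
      code[[cods1[k]]] != "*" && code[[cods2[k]]] != "*"
    if (!ok) next
    sc1 <- oracle_site_counts(cods1[k])
    sc2 <- oracle_site_counts(cods2[k])
    Ss <- Ss + (sc1["syn"] + sc2["syn"]) / 2
    Ns <- Ns + (sc1["nonsyn"] + sc2["nonsyn"]) / 2
    if (cods1[k] != cods2[k]) {
      paths <- oracle_pathways(cods1[k], cods2[k])
      if (length(paths) == 0L)
        paths <- oracle_pathways(cods1[k], cods2[k], allow_stop = TRUE)
      avg <- Reduce(`+`, paths) / length(paths)
      Sd <- Sd + avg[1]
      Nd <- Nd + avg[2]
    }
  }
  pS <- Sd / Ss
  pN <- Nd / Ns
  corr <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(Sd = unname(Sd), Nd = unname(Nd), Ss = unname(Ss), Ns = unname(Ns),
       dS = corr(pS), dN = corr(pN))
}

# -- brute-force Wagner parsimony --------------------------------------------

# Minimum event cost over all internal labelings, for every binary leaf
# pattern at once. Returns a vector indexed by pattern (2^n patterns, leaf 1
# = least-significant bit).
brute_force_parsimony <- function(tree, gain = 1, loss = 1) {
  n <- length(tree$tip.label)
  m <- tree$Nnode
  edge <- tree$edge
  patterns <- as.matrix(expand.grid(rep(list(0:1), n)))[, n:1, drop = FALSE]
  labelings <- as.matrix(expand.grid(rep(list(0:1), m)))[, m:1, drop = FALSE]
  state_of <- function(node, P, L) {
    if (node <= n) P[, node] else L[, node - n]
  }
  # cost[pattern, labeling]
  cost <- matrix(0, nrow(patterns), nrow(labelings))
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1L]
    ch <- edge[e, 2L]
    ps <- labelings[, p - n]
    cs <- if (ch <= n) patterns[, ch] else labelings[, ch - n]
    if (ch <= n) {
      # outer over (pattern, labeling)
      cost <- cost + outer(cs, ps, function(c, p_) gain * (p_ == 0 & c == 1) +
                             loss * (p_ == 1 & c == 0))
    } else {
      pen <- gain * (ps == 0 & cs == 1) + loss * (ps == 1 & cs == 0)
      cost <- cost + matrix(pen, nrow(patterns), nrow(labelings), byrow = TRUE)
    }
  }
  list(patterns = patterns, min_cost = apply(cost, 1L, min))
}

# Leaf patterns as a binary matrix usable as wagner input (patterns become
# the families).
patterns_as_matrix <- function(tree) {
  n <- length(tree$tip.label)
  patterns <- as.matrix(expand.grid(rep(list(0:1), n)))[, n:1, drop = FALSE]
  mat <- patterns  # families (one per pattern) x leaves
  rownames(mat) <- paste0("P", seq_len(nrow(mat)))
  colnames(mat) <- tree$tip.label
  storage.mode(mat) <- "integer"
  mat
}

# -- connected components (union-find) ---------------------------------------

oracle_components <- function(nodes, edge_from, edge_to) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (k in seq_along(edge_from)) {
    ra <- find(edge_from[k])
    rb <- find(edge_to[k])
    if (ra != rb) parent[[rb]] <- ra
  }
  comps <- vapply(nodes, find, character(1))
  split(nodes, comps)
}

# -- independent pangenome rule coder ----------------------------------------

oracle_partition_class <- function(N, k) {
  if (k <= 0) return(NA_character_)
  if (k == 1) return("unique")
  frac <- k / N
  if (frac == 1) return("core")
  if (frac >= 0.9) return("soft_core")
  if (frac >= 0.15) return("shell")
  "cloud"
}

# -- misc ---------------------------------------------------------------------

random_alignment <- function(n, L, seed) {
  with_seed_local(seed, {
    matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE), n, L,
           dimnames = list(paste0("s", seq_len(n)), NULL))
  })
}

with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# A fixed set of 6-leaf trees (binary and multifurcating) used alongside the
# exhaustive binary enumerations.
fixed_six_leaf_trees <- function() {
  txt <- c(
    "((A,B),((C,D),(E,F)));",
    "(((((A,B),C),D),E),F);",
    "((A,(B,C)),(D,(E,F)));",
    "(A,B,C,D,E,F);",
    "((A,B,C),(D,E,F));",
    "((A,B),(C,D),(E,F));",
    "(((A,B),C,D),(E,F));",
    "((A,(B,C,D)),(E,F));")
  lapply(txt, function(s) {
    tr <- ape::read.tree(text = s)
    pangevo::name_internal_nodes(tr)
  })
}
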