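# Seed-deterministic synthetic-data generators for every input the pipeline
# consumes: gene content evolved along a known tree, neutral coalescent
# samples, codon sequences evolved at a known dN/dS, planted ANI cluster
# structure, and a complete end-to-end miniature study.

# -- codon chain --------------------------------------------------------------

# Neighbor structure of the 61 sense codons under single-nucleotide moves
# (stop codons excluded), parameter-independent, cached.
codon_neighbors <- function() {
  if (!is.null(.ng86_cache$neighbors)) return(.ng86_cache$neighbors)
  tab <- ng86_tables()
  sense <- tab$sense
  ns <- length(sense)
  is_transition <- function(b1, b2)
    (b1 %in% c("A", "G") && b2 %in% c("A", "G")) ||
    (b1 %in% c("C", "T") && b2 %in% c("C", "T"))
  targets <- matrix(0L, ns, 9L)
  ti <- syn <- matrix(FALSE, ns, 9L)
  for (i in seq_len(ns)) {
    sp <- strsplit(sense[i], "")[[1]]
    k <- 0L
    for (p in 1:3) for (b in setdiff(BASES, sp[p])) {
      alt <- sp; alt[p] <- b
      c1 <- paste(alt, collapse = "")
      j <- match(c1, sense)
      if (is.na(j)) next  # stop codon: move forbidden
      k <- k + 1L
      targets[i, k] <- j
      ti[i, k] <- is_transition(sp[p], b)
      syn[i, k] <- tab$aa[sense[i]] == tab$aa[c1]
    }
  }
  .ng86_cache$neighbors <- list(sense = sense, targets = targets,
                                transition = ti, synonymous = syn)
  .ng86_cache$neighbors
}

# Rate structure for given (omega, kappa): per-codon total rate, cumulative
# jump probabilities and per-jump synonymy, normalized so the mean rate over
# the uniform stationary distribution is one substitution per codon per unit
# time.
codon_chain <- function(omega, kappa = 1) {
  nb <- codon_neighbors()
  rates <- matrix(0, nrow(nb$targets), 9L)
  present <- nb$targets > 0L
  rates[present] <- ifelse(nb$transition[present], kappa, 1) *
    ifelse(nb$synonymous[present], 1, omega)
  total <- rowSums(rates)
  scale <- mean(total)
  if (scale > 0) { rates <- rates / scale; total <- total / scale }
  cum <- rates
  for (k in 2:9) cum[, k] <- cum[, k - 1L] + cum[, k]
  cum <- cum / ifelse(total > 0, total, 1)
  cum[, 9L] <- pmax(cum[, 9L], 1)  # guard rounding
  list(nb = nb, total = total, cum = cum,
       omega = omega, kappa = kappa, scale = scale)
}

# Exact stochastic simulation of the codon chain, vectorized over sites.
# `states` are indices into the 61 sense codons; returns new states plus
# realized synonymous/nonsynonymous substitution counts.
evolve_codons <- function(states, t, chain) {
  rem <- rep(t, length(states))
  active <- seq_along(states)
  n_syn <- 0L; n_nonsyn <- 0L
  while (length(active)) {
    active <- active[chain$total[states[active]] > 0]  # absorbing codons
    if (!length(active)) break
    r <- chain$total[states[active]]
    dt <- stats::rexp(length(active), r)
    rem[active] <- rem[active] - dt
    jump <- active[rem[active] > 0]
    if (!length(jump)) break
    u <- stats::runif(length(jump))
    cp <- chain$cum[states[jump], , drop = FALSE]
    col <- rowSums(cp < u) + 1L
    idx <- cbind(states[jump], col)
    syn <- chain$nb$synonymous[idx]
    n_syn <- n_syn + sum(syn)
    n_nonsyn <- n_nonsyn + sum(!syn)
    states[jump] <- chain$nb$targets[idx]
    active <- jump
  }
  list(states = states, n_syn = n_syn, n_nonsyn = n_nonsyn)
}

codon_states_to_string <- function(states) {
  paste(codon_neighbors()$sense[states], collapse = "")
}

#' Simulate a codon-aligned sequence pair with known dN/dS
#'
#' An ancestor of `n_codons` codons is drawn from `frequencies` (uniform
#' over the 61 sense codons by default) and each lineage evolved for
#' `divergence/2` by exact event-by-event stochastic simulation of a
#' GY94-style chain: single-nucleotide codon moves, transitions weighted by
#' `kappa`, nonsynonymous moves by `omega`, stop codons excluded. Rates are
#' normalized to one expected substitution per codon per unit time at
#' stationarity, so `divergence` is the expected pairwise substitutions per
#' codon site.
#'
#' @param n_codons number of codons.
#' @param omega true dN/dS (>= 0).
#' @param kappa transition/transversion rate ratio (> 0, default 1).
#' @param divergence expected substitutions per codon between the two
#'   sequences.
#' @param frequencies optional length-61 ancestor codon weights.
#' @param seed integer seed.
#' @return list with `alignment` (2-row codon [pg_alignment()]), `omega`,
#'   `kappa`, `divergence`, and realized substitution counts `n_syn`,
#'   `n_nonsyn`.
#' @export
simulate_codon_pair <- function(n_codons, omega, kappa = 1, divergence = 0.2,
                                frequencies = NULL, seed = 1L) {
  chain <- codon_chain(omega, kappa)
  ns <- length(chain$nb$sense)
  with_seed(seed, {
    anc <- sample.int(ns, n_codons, replace = TRUE, prob = frequencies)
    e1 <- evolve_codons(anc, divergence / 2, chain)
    e2 <- evolve_codons(anc, divergence / 2, chain)
    aln <- pg_alignment(c(seq1 = codon_states_to_string(e1$states),
                          seq2 = codon_states_to_string(e2$states)),
                        codon = TRUE)
    list(alignment = aln, omega = omega, kappa = kappa,
         divergence = divergence,
         n_syn = e1$n_syn + e2$n_syn, n_nonsyn = e1$n_nonsyn + e2$n_nonsyn)
  })
}

#' Simulate a multi-cluster codon orthogroup against a common outgroup
#'
#' The outgroup sequence is the ancestor; each cluster's founding lineage
#' evolves from it for `t_anc` at the cluster's omega, then every member
#' evolves independently from the founder for `t_tip` at the same omega. A
#' member's path to the outgroup therefore has expected divergence
#' `t_anc + t_tip`, all accumulated at the cluster's omega.
#'
#' @param n_codons number of codons.
#' @param omegas named numeric vector: cluster label -> true omega.
#' @param n_per_cluster sequences per cluster.
#' @param t_anc founder branch length (expected substitutions/codon).
#' @param t_tip member branch length.
#' @param kappa transition/transversion ratio.
#' @param outgroup_label cluster label for the outgroup sequence.
#' @param seed integer seed.
#' @return list with `alignment` (codon [pg_alignment()] with cluster
#'   labels; one outgroup row plus `n_per_cluster` rows per cluster) and
#'   `omegas`.
#' @export
simulate_codon_orthogroup <- function(n_codons, omegas, n_per_cluster = 19L,
                                      t_anc = 0.1, t_tip = 0.1, kappa = 1,
                                      outgroup_label = "OUT", seed = 1L) {
  ns <- length(codon_neighbors()$sense)
  with_seed(seed, {
    anc <- sample.int(ns, n_codons, replace = TRUE)
    seqs <- c(stats::setNames(codon_states_to_string(anc), "outgroup_rep"))
    labels <- outgroup_label
    for (cl in names(omegas)) {
      chain <- codon_chain(omegas[[cl]], kappa)
      founder <- evolve_codons(anc, t_anc, chain)$states
      for (k in seq_len(n_per_cluster)) {
        tip <- evolve_codons(founder, t_tip, chain)$states
        seqs <- c(seqs, stats::setNames(codon_states_to_string(tip),
                                        sprintf("%s_m%02d", cl, k)))
        labels <- c(labels, cl)
      }
    }
    list(alignment = pg_alignment(seqs, cluster = labels, codon = TRUE),
         omegas = omegas)
  })
}

# -- neutral coalescent -------------------------------------------------------

#' Simulate a neutral coalescent sample with infinite-sites mutations
#'
#' Standard n-coalescent in scaled units: while `k` lineages remain, the
#' waiting time is `Exp(k(k-1)/2)` and a uniformly chosen pair merges.
#' Mutations are Poisson with mean `theta/2` times the total branch length,
#' placed uniformly on branches and mapped to distinct sites among `L`
#' (a warning is raised when the expected number of segregating sites
#' exceeds `0.1 * L`, where site exhaustion starts to distort the
#' infinite-sites assumption). Each mutated site gets a random ancestral
#' base and a distinct derived base carried by the subtended leaves.
#'
#' @param n sample size (>= 2).
#' @param theta population-scaled mutation rate (> 0).
#' @param sites alignment length L.
#' @param seed integer seed.
#' @return a [pg_alignment()] of `n` sequences (`s1..sn`) by `sites`
#'   columns, with the realized segregating-site count as attribute
#'   `true_S`.
#' @export
simulate_coalescent <- function(n, theta, sites = 1000L, seed = 1L) {
  if (n < 2L) stop_format("need n >= 2")
  if (theta <= 0) stop_format("theta must be positive")
  exp_S <- theta * sum(1 / seq_len(n - 1L))
  if (exp_S > 0.1 * sites)
    warning(sprintf("expected S (%.1f) exceeds 10%% of %d sites; infinite-sites approximation degrades",
                    exp_S, sites), call. = FALSE)
  with_seed(seed, {
    lineages <- lapply(seq_len(n), identity)  # leaf sets
    seg_leaves <- list()
    seg_len <- numeric()
    while (length(lineages) > 1L) {
      k <- length(lineages)
      tk <- stats::rexp(1L, k * (k - 1) / 2)
      seg_leaves <- c(seg_leaves, lineages)
      seg_len <- c(seg_len, rep(tk, k))
      pick <- sample.int(k, 2L)
      merged <- c(lineages[[pick[1L]]], lineages[[pick[2L]]])
      lineages <- c(lineages[-pick], list(merged))
    }
    total <- sum(seg_len)
    nmut <- stats::rpois(1L, theta / 2 * total)
    if (nmut > sites)
      stop_format("%d mutations exceed %d sites; increase 'sites'", nmut, sites)
    anc <- sample(c("A", "C", "G", "T"), sites, replace = TRUE)
    aln <- matrix(rep(anc, each = n), n, sites,
                  dimnames = list(paste0("s", seq_len(n)), NULL))
    if (nmut > 0L) {
      which_seg <- sample.int(length(seg_len), nmut, replace = TRUE,
                              prob = seg_len)
      pos <- sample.int(sites, nmut)
      for (m in seq_len(nmut)) {
        leaves <- seg_leaves[[which_seg[m]]]
        derived <- sample(setdiff(c("A", "C", "G", "T"), anc[pos[m]]), 1L)
        aln[unlist(leaves), pos[m]] <- derived
      }
    }
    out <- pg_alignment(aln)
    attr(out, "true_S") <- nmut
    out
  })
}

# -- gene content along a tree ------------------------------------------------

#' Simulate gene content evolving along a rooted tree
#'
#' Generative twin of the gain/loss stage: the root carries
#' `Poisson(lambda0)` distinct families; along each edge of length `t` every
#' present family survives with probability `exp(-loss_rate * t)` and
#' `Poisson(gain_rate * t)` new families are born, each once globally
#' (infinitely-many-genes: a family lost on a path never re-appears on it).
#' Every event is logged per edge, so the truth replays exactly to the leaf
#' states.
#'
#' @param tree optional rooted `ape::phylo` with branch lengths; when
#'   `NULL`, a Yule tree with `n_leaves` tips (unit birth rate) is drawn.
#' @param n_leaves tips of the drawn Yule tree (ignored when `tree` given).
#' @param lambda0 Poisson mean of the root family count (> 0).
#' @param gain_rate family births per unit branch length (>= 0).
#' @param loss_rate per-family loss rate per unit branch length (>= 0).
#' @param seed integer seed.
#' @return list with `tree` (internal nodes named), `matrix` (binary
#'   families x leaves, restricted to families present in >= 1 leaf),
#'   `node_content` (family sets per node name), `events` (per non-root
#'   node: list with `gained`, `lost` on the edge above it), and the
#'   configuration.
#' @export
simulate_gene_content <- function(tree = NULL, n_leaves = 10L, lambda0 = 1000,
                                  gain_rate = 0, loss_rate = 0, seed = 1L) {
  if (lambda0 <= 0) stop_format("lambda0 must be positive")
  if (gain_rate < 0 || loss_rate < 0) stop_format("rates must be >= 0")
  with_seed(seed, {
    if (is.null(tree)) tree <- ape::rphylo(n_leaves, birth = 1, death = 0)
    tree <- name_internal_nodes(tree)
    nn <- node_names(tree)
    n <- length(tree$tip.label)
    counter <- 0L
    new_fams <- function(k) {
      if (k == 0L) return(character())
      ids <- sprintf("F%06d", counter + seq_len(k))
      counter <<- counter + k
      ids
    }
    node_content <- stats::setNames(vector("list", length(nn)), nn)
    events <- stats::setNames(vector("list", length(nn)), nn)
    root <- n + 1L
    node_content[[nn[root]]] <- new_fams(stats::rpois(1L, lambda0))
    edge <- stats::reorder(tree, "cladewise")$edge
    elen <- stats::reorder(tree, "cladewise")$edge.length
    if (is.null(elen)) elen <- rep(1, nrow(edge))
    for (e in seq_len(nrow(edge))) {
      p <- nn[edge[e, 1L]]; ch <- nn[edge[e, 2L]]
      t <- elen[e]
      parent_fams <- node_content[[p]]
      keep <- stats::runif(length(parent_fams)) < exp(-loss_rate * t)
      gained <- new_fams(stats::rpois(1L, gain_rate * t))
      node_content[[ch]] <- c(parent_fams[keep], gained)
      events[[ch]] <- list(gained = gained, lost = parent_fams[!keep])
    }
    leaf_fams <- sort(unique(unlist(node_content[tree$tip.label])))
    mat <- matrix(0L, length(leaf_fams), n,
                  dimnames = list(leaf_fams, tree$tip.label))
    for (tip in tree$tip.label)
      mat[node_content[[tip]], tip] <- 1L
    list(tree = tree, matrix = mat, node_content = node_content,
         events = events,
         config = list(lambda0 = lambda0, gain_rate = gain_rate,
                       loss_rate = loss_rate, seed = seed))
  })
}

# -- planted ANI structure ----------------------------------------------------

rtrunc_norm <- function(k, mean, sd, lo, hi) {
  out <- numeric(k)
  need <- seq_len(k)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Simulate a pairwise ANI table with planted cluster structure
#'
#' Within-cluster and between-cluster ANI values are drawn from truncated
#' normals; both directions of every pair are emitted with independent
#' jitter (clamped back into the class truncation bounds, so the planted
#' separation is guaranteed). Self comparisons are emitted at 100%.
#'
#' @param cluster_sizes integer vector of genome counts per planted cluster.
#' @param within_mean,within_sd,within_min within-cluster ANI distribution
#'   (truncated to `[within_min, 100]`).
#' @param between_mean,between_sd,between_max between-cluster distribution
#'   (truncated to `[0, between_max]`).
#' @param jitter_sd s.d. of the independent per-direction jitter.
#' @param seed integer seed.
#' @return list with `pairs` (data.frame in [read_ani_pairs()] shape) and
#'   `truth` (named character vector genome -> planted cluster `C1, C2,
#'   ...`; genomes are named so that MCL's deterministic labelling matches
#'   the planted names when cluster sizes are equal).
#' @export
simulate_ani_table <- function(cluster_sizes = c(5L, 4L, 3L),
                               within_mean = 97.5, within_sd = 0.8,
                               within_min = 95.5,
                               between_mean = 82, between_sd = 3,
                               between_max = 92,
                               jitter_sd = 0.1, seed = 1L) {
  if (within_min <= between_max)
    stop_format("within_min must exceed between_max for a planted structure")
  ids <- unlist(lapply(seq_along(cluster_sizes), function(c)
    sprintf("C%dG%02d", c, seq_len(cluster_sizes[c]))))
  truth <- stats::setNames(rep(paste0("C", seq_along(cluster_sizes)),
                               cluster_sizes), ids)
  with_seed(seed, {
    rows <- list()
    ng <- length(ids)
    for (i in seq_len(ng)) for (j in seq_len(ng)) {
      if (i > j) next
      if (i == j) {
        rows[[length(rows) + 1L]] <- data.frame(
          query = ids[i], reference = ids[i], ani = 100,
          frag_mapped = 1000L, frag_total = 1000L, stringsAsFactors = FALSE)
        next
      }
      same <- truth[[ids[i]]] == truth[[ids[j]]]
      if (same) { mu <- within_mean; sdv <- within_sd; lo <- within_min; hi <- 100 }
      else { mu <- between_mean; sdv <- between_sd; lo <- 0; hi <- between_max }
      base <- rtrunc_norm(1L, mu, sdv, lo, hi)
      d1 <- min(hi, max(lo, base + stats::rnorm(1L, 0, jitter_sd)))
      d2 <- min(hi, max(lo, base + stats::rnorm(1L, 0, jitter_sd)))
      rows[[length(rows) + 1L]] <- data.frame(
        query = c(ids[i], ids[j]), reference = c(ids[j], ids[i]),
        ani = c(d1, d2), frag_mapped = 900L, frag_total = 1000L,
        stringsAsFactors = FALSE)
    }
    list(pairs = do.call(rbind, rows), truth = truth)
  })
}

# -- end-to-end fixture -------------------------------------------------------

#' Write a complete miniature study to a directory
#'
#' One command produces every file the pipeline consumes, in the exact
#' dialects the readers expect, with ground truth alongside: an ANI table
#' with planted clusters, a genome-level gene-count table derived from gene
#' content evolved along a species tree (plus per-genome accessory noise), a
#' gene-to-COG annotation table, within-cluster nucleotide alignments from
#' the neutral coalescent, codon alignments evolved at known per-cluster
#' omegas against a common outgroup, and the species tree. Identical seeds
#' produce byte-identical directories.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @param n_clusters planted species clusters (default 4).
#' @param genomes_per_cluster genomes per cluster (default 5).
#' @param lambda0 root family count for the species-level content.
#' @param n_taj_orthogroups coalescent orthogroup alignments (default 4).
#' @param n_sel_orthogroups codon orthogroup alignments (default 3).
#' @param codons codons per selection orthogroup (default 120).
#' @param theta coalescent mutation parameter (default 5).
#' @return invisibly, the ground-truth list (also written to `truth.json`).
#' @export
make_fixture <- function(dir, seed = 1L, n_clusters = 4L,
                         genomes_per_cluster = 5L, lambda0 = 300,
                         n_taj_orthogroups = 4L, n_sel_orthogroups = 3L,
                         codons = 120L, theta = 5) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(dir, "alignments"), showWarnings = FALSE)
  dir.create(file.path(dir, "cds_alignments"), showWarnings = FALSE)
  cl_names <- paste0("C", seq_len(n_clusters))

  ani <- simulate_ani_table(cluster_sizes = rep(genomes_per_cluster, n_clusters),
                            seed = seed)
  write_ani_pairs(ani$pairs, file.path(dir, "ani.tsv"))
  genomes <- names(ani$truth)

  # species-level gene content on a fixed balanced tree over the clusters
  tree_txt <- if (n_clusters == 4L) "((C1:0.2,C2:0.2):0.2,(C3:0.2,C4:0.2):0.2);"
              else paste0("(", paste(sprintf("%s:0.3", cl_names), collapse = ","), ");")
  tf <- tempfile(fileext = ".nwk"); writeLines(tree_txt, tf)
  sp_tree <- read_tree(tf); unlink(tf)
  content <- simulate_gene_content(tree = sp_tree, lambda0 = lambda0,
                                   gain_rate = 40, loss_rate = 0.3,
                                   seed = seed + 1L)
  write_tree(content$tree, file.path(dir, "tree.nwk"))

  # genome-level counts: species content plus per-genome noise
  fams <- rownames(content$matrix)
  counts <- with_seed(seed + 2L, {
    m <- matrix(0L, length(fams), length(genomes),
                dimnames = list(fams, genomes))
    for (g in genomes) {
      sp <- ani$truth[[g]]
      present <- fams[content$matrix[, sp] == 1L]
      kept <- present[stats::runif(length(present)) > 0.08]
      m[kept, g] <- 1L + stats::rbinom(length(kept), 1L, 0.03)
    }
    m
  })
  uniq <- with_seed(seed + 3L, {
    extra <- lapply(genomes, function(g) sprintf("U_%s_%d", g, 1:3))
    um <- matrix(0L, length(unlist(extra)), length(genomes),
                 dimnames = list(unlist(extra), genomes))
    for (k in seq_along(genomes)) um[extra[[k]], genomes[k]] <- 1L
    um
  })
  counts <- rbind(counts, uniq)
  counts <- counts[rowSums(counts) > 0L, , drop = FALSE]
  write_gene_counts(counts, file.path(dir, "counts.tsv"), total = TRUE)

  # annotations: one representative gene per family, random root-level COG
  ann <- with_seed(seed + 4L, {
    cats <- c("C", "E", "F", "G", "H", "J", "K", "L", "M", "N", "P", "Q",
              "T", "U", "V", "X")
    data.frame(
      gene_id = paste0(rownames(counts), "_g1"),
      orthogroup_id = rownames(counts),
      cog = ifelse(stats::runif(nrow(counts)) < 0.2, "",
                   sample(cats, nrow(counts), replace = TRUE)),
      stringsAsFactors = FALSE)
  })
  write_annotations(ann, file.path(dir, "annotations.tsv"))

  # within-cluster coalescent alignments for the Tajima stage
  taj_thetas <- stats::setNames(
    rep_len(c(theta, theta * 2, theta / 2, theta), n_clusters), cl_names)
  for (k in seq_len(n_taj_orthogroups)) {
    og <- sprintf("OGTAJ%02d", k)
    seqs <- character(); labels <- character()
    for (ci in seq_len(n_clusters)) {
      cl <- cl_names[ci]
      sub <- simulate_coalescent(genomes_per_cluster, taj_thetas[[cl]],
                                 sites = 400L,
                                 seed = seed + 100L + 10L * k + ci)
      members <- genomes[ani$truth == cl]
      s <- apply(unclass(sub), 1L, paste, collapse = "")
      names(s) <- paste0(members, "_", og)
      seqs <- c(seqs, s)
      labels <- c(labels, rep(cl, length(s)))
    }
    write_alignment(pg_alignment(seqs, cluster = labels),
                    file.path(dir, "alignments", paste0(og, ".fasta")))
  }

  # codon orthogroups with known per-cluster omegas, common outgroup
  omega_sets <- lapply(seq_len(n_sel_orthogroups), function(k) {
    if (k == 1L) stats::setNames(c(1.0, 0.2, rep(0.5, n_clusters - 2L)), cl_names)
    else stats::setNames(rep(0.4, n_clusters), cl_names)
  })
  for (k in seq_len(n_sel_orthogroups)) {
    og <- sprintf("OGSEL%02d", k)
    sim <- simulate_codon_orthogroup(
      n_codons = codons, omegas = omega_sets[[k]],
      n_per_cluster = genomes_per_cluster, t_anc = 0.08, t_tip = 0.08,
      outgroup_label = "OUT", seed = seed + 200L + k)
    write_alignment(sim$alignment,
                    file.path(dir, "cds_alignments", paste0(og, ".fasta")))
  }

  truth <- list(seed = seed,
                clusters = as.list(ani$truth),
                species_tree = tree_txt,
                species_content_sizes = lapply(content$node_content, length),
                gainloss_events = lapply(content$events, function(e)
                  if (is.null(e)) NULL
                  else list(gained = length(e$gained), lost = length(e$lost))),
                taj_thetas = as.list(taj_thetas),
                sel_omegas = stats::setNames(
                  lapply(omega_sets, as.list),
                  sprintf("OGSEL%02d", seq_len(n_sel_orthogroups))))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(truth)
}
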