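test_that("gene-content simulation satisfies the per-edge identity exactly", {
  sim <- simulate_gene_content(n_leaves = 8, lambda0 = 200, gain_rate = 20,
                               loss_rate = 0.1, seed = 6)
  tree <- sim$tree
  nn <- c(tree$tip.label, tree$node.label)
  edge <- tree$edge
  for (e in seq_len(nrow(edge))) {
    p <- nn[edge[e, 1]]; ch <- nn[edge[e, 2]]
    ev <- sim$events[[ch]]
    replay <- sort(union(setdiff(sim$node_content[[p]], ev$lost), ev$gained))
    expect_identical(sort(sim$node_content[[ch]]), replay)
    # infinitely-many-genes: gains are globally new
    expect_identical(length(intersect(ev$gained, sim$node_content[[p]])), 0L)
  }
  # leaf matrix equals leaf content
  for (tip in tree$tip.label)
    expect_setequal(rownames(sim$matrix)[sim$matrix[, tip] == 1L],
                    sim$node_content[[tip]])
})

test_that("gene-content simulation hits its limiting regimes", {
  # no events: every leaf equals the root
  s0 <- simulate_gene_content(n_leaves = 5, lambda0 = 100, gain_rate = 0,
                              loss_rate = 0, seed = 2)
  root <- s0$tree$node.label[1]
  for (tip in s0$tree$tip.label)
    expect_setequal(s0$node_content[[tip]], s0$node_content[[root]])

  # catastrophic loss: leaves nearly empty
  s1 <- simulate_gene_content(n_leaves = 5, lambda0 = 100, gain_rate = 0,
                              loss_rate = 50, seed = 2)
  leaf_sizes <- lengths(s1$node_content[s1$tree$tip.label])
  expect_lt(mean(leaf_sizes), 2)

  # survival product: mean leaf content within 3 SD of the closed form
  s2 <- simulate_gene_content(n_leaves = 10, lambda0 = 1000, gain_rate = 0,
                              loss_rate = 0.05, seed = 8)
  depths <- ape::node.depth.edgelength(s2$tree)[seq_along(s2$tree$tip.label)]
  names(depths) <- s2$tree$tip.label
  for (tip in s2$tree$tip.label) {
    p_surv <- exp(-0.05 * depths[[tip]])
    expected <- 1000 * p_surv
    sd3 <- 3 * sqrt(1000 * p_surv * (1 - p_surv) + expected)  # Poisson root + binomial thinning
    expect_lt(abs(length(s2$node_content[[tip]]) - expected), sd3)
  }
})

test_that("coalescent samples obey the standard identities", {
  # theta -> 0: no variation
  a0 <- simulate_coalescent(6, 1e-9, 100, seed = 1)
  expect_identical(segregating_sites(a0), 0L)

  # n = 2: E[pairwise differences] = theta (500 replicates, 5% slack)
  diffs <- vapply(1:500, function(s) {
    a <- simulate_coalescent(2, 5, 600, seed = s)
    sum(unclass(a)[1, ] != unclass(a)[2, ])
  }, numeric(1))
  expect_lt(abs(mean(diffs) / 5 - 1), 0.05)

  # site exhaustion warning
  expect_warning(simulate_coalescent(10, 20, 160, seed = 3), "exceeds 10%")
})

test_that("codon simulation respects its parameters", {
  # zero divergence: identical pair
  p0 <- simulate_codon_pair(50, omega = 1, divergence = 0, seed = 4)
  expect_identical(unclass(p0$alignment)[1, ], unclass(p0$alignment)[2, ])
  expect_identical(p0$n_syn + p0$n_nonsyn, 0L)

  # omega = 0: no nonsynonymous events ever
  p1 <- simulate_codon_pair(200, omega = 0, divergence = 0.5, seed = 5)
  expect_identical(p1$n_nonsyn, 0L)
  expect_gt(p1$n_syn, 0L)
  aa1 <- translate_codons(seq_to_codons(paste(unclass(p1$alignment)[1, ], collapse = "")))
  aa2 <- translate_codons(seq_to_codons(paste(unclass(p1$alignment)[2, ], collapse = "")))
  expect_identical(aa1, aa2)

  # neutral chain: realized N:S ratio approaches the site opportunity ratio
  p2 <- simulate_codon_pair(10000, omega = 1, kappa = 1, divergence = 0.4,
                            seed = 6)
  tab <- ng86_tables()
  opportunity <- sum(tab$nonsyn_sites) / sum(tab$syn_sites)
  realized <- p2$n_nonsyn / p2$n_syn
  expect_lt(abs(realized / opportunity - 1), 0.05)
})

test_that("planted ANI tables respect their truncation contract", {
  # zero jitter: perfectly symmetric directions
  s0 <- simulate_ani_table(cluster_sizes = c(3L, 3L), jitter_sd = 0, seed = 2)
  nonself <- s0$pairs[s0$pairs$query != s0$pairs$reference, ]
  key <- paste(pmin(nonself$query, nonself$reference),
               pmax(nonself$query, nonself$reference))
  spread <- tapply(nonself$ani, key, function(x) diff(range(x)))
  expect_true(all(spread == 0))

  # single cluster: every pair above the species threshold
  s1 <- simulate_ani_table(cluster_sizes = 5L, seed = 3)
  expect_true(all(s1$pairs$ani >= 95.5))

  # 3 planted clusters: all between-cluster values below 95 by construction
  s2 <- simulate_ani_table(cluster_sizes = c(5L, 4L, 3L), seed = 4)
  btw <- s2$pairs[s2$truth[s2$pairs$query] != s2$truth[s2$pairs$reference], ]
  expect_true(all(btw$ani <= 92))
})

test_that("simulators and the fixture are seed-deterministic", {
  a <- simulate_coalescent(6, 3, 200, seed = 12)
  b <- simulate_coalescent(6, 3, 200, seed = 12)
  expect_identical(a, b)
  expect_false(identical(a, simulate_coalescent(6, 3, 200, seed = 13)))

  p <- simulate_codon_pair(30, 0.5, divergence = 0.3, seed = 7)
  q <- simulate_codon_pair(30, 0.5, divergence = 0.3, seed = 7)
  expect_identical(p, q)

  d1 <- file.path(tempfile(), "a"); d2 <- file.path(tempfile(), "b")
  make_fixture(d1, seed = 5, n_taj_orthogroups = 2L, n_sel_orthogroups = 1L,
               codons = 60L)
  make_fixture(d2, seed = 5, n_taj_orthogroups = 2L, n_sel_orthogroups = 1L,
               codons = 60L)
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 5L)
  for (f in files)
    expect_identical(readBin(file.path(d1, f), "raw", n = 1e7),
                     readBin(file.path(d2, f), "raw", n = 1e7))
})

test_that("seeded helpers leave the caller's RNG stream untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_coalescent(5, 2, 100, seed = 1))
  invisible(simulate_codon_pair(10, 1, divergence = 0.1, seed = 1))
  expect_identical(.Random.seed, before)
})
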