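test_that("back-translation expands gaps and validates coding sequences", {
  bt <- backtranslate(c(a = "M-K"), c(a = "ATGAAA"))
  expect_identical(paste(unclass(bt)["a", ], collapse = ""), "ATG---AAA")

  # ungapped alignment: concatenation of the original codons
  bt2 <- backtranslate(c(x = "MEK"), c(x = "ATGGAAAAA"))
  expect_identical(paste(unclass(bt2)["x", ], collapse = ""), "ATGGAAAAA")

  # trailing stop trimmed
  bt3 <- backtranslate(c(x = "MK"), c(x = "ATGAAATAA"))
  expect_identical(ncol(bt3), 6L)

  # internal stop against a protein without one: error naming the position
  expect_error(backtranslate(c(x = "MKK"), c(x = "ATGTAAAAA")),
               "mismatch for 'x' at residue 2")
  # length mismatch
  expect_error(backtranslate(c(x = "MK"), c(x = "ATGTAAAAA")),
               "length mismatch")
  expect_error(backtranslate(c(x = "MKK"), c(x = "ATGAAA")), "length mismatch")
  # bacterial alternative starts are tolerated
  expect_silent(backtranslate(c(x = "MK"), c(x = "GTGAAA")))
})

test_that("translating a back-translation returns the protein alignment", {
  prot <- c(p1 = "MT-KL-", p2 = "M-SKLE")
  cds <- c(p1 = "ATGACCAAACTG", p2 = "ATGAGCAAACTGGAA")
  bt <- backtranslate(prot, cds)
  for (id in names(prot)) {
    cods <- seq_to_codons(paste(unclass(bt)[id, ], collapse = ""))
    aa <- ifelse(cods == "---", "-", translate_codons(cods))
    expect_identical(paste(aa, collapse = ""), prot[[id]])
  }
})

test_that("NG86 classifies single changes and degenerate pairs", {
  ctx <- paste(rep("GGA", 9), collapse = "")  # shared context, 9 codons
  r <- ng86_pair(paste0("TTT", ctx), paste0("TTC", ctx))
  expect_equal(r$Sd, 1)
  expect_equal(r$Nd, 0)
  expect_equal(r$dN, 0)
  expect_gt(r$dS, 0)

  same <- ng86_pair(ctx, ctx)
  expect_equal(same$dN, 0)
  expect_equal(same$dS, 0)
  expect_true(is.na(same$omega))  # undefined at dS = 0
})

test_that("NG86 is exactly symmetric and matches the pathway oracle", {
  set.seed(17)
  for (k in 1:5) {
    p <- simulate_codon_pair(40, omega = 0.7, divergence = 0.5, seed = k)
    s1 <- paste(unclass(p$alignment)[1, ], collapse = "")
    s2 <- paste(unclass(p$alignment)[2, ], collapse = "")
    a <- ng86_pair(s1, s2)
    b <- ng86_pair(s2, s1)
    expect_identical(a[c("Sd", "Nd", "Ss", "Ns", "dN", "dS")],
                     b[c("Sd", "Nd", "Ss", "Ns", "dN", "dS")])
    want <- oracle_ng86(s1, s2)
    expect_equal(a$Sd, want$Sd, tolerance = 1e-12)
    expect_equal(a$Nd, want$Nd, tolerance = 1e-12)
    expect_equal(a$Ss, want$Ss, tolerance = 1e-12)
    expect_equal(a$Ns, want$Ns, tolerance = 1e-12)
  }
})

test_that("two-position codon differences average over valid pathways", {
  ctx <- paste(rep("CTG", 12), collapse = "")
  # TTT -> GTA differs at positions 1 and 3; oracle enumerates both orders
  got <- ng86_pair(paste0("TTT", ctx), paste0("GTA", ctx))
  want <- oracle_ng86(paste0("TTT", ctx), paste0("GTA", ctx))
  expect_equal(got$Sd, want$Sd, tolerance = 1e-12)
  expect_equal(got$Nd, want$Nd, tolerance = 1e-12)
  expect_equal(got$Sd + got$Nd, 2)
})

test_that("Tajima-Nei distance has the right limits", {
  s <- paste(rep("ACGT", 250), collapse = "")
  r0 <- tajima_nei_pair(s, s)
  expect_identical(r0$distance, 0)

  # equal-frequency small-p limit approaches Jukes-Cantor
  set.seed(3)
  x <- sample(c("A", "C", "G", "T"), 4000, replace = TRUE)
  y <- x
  mut <- sample(4000, 80)
  y[mut] <- vapply(x[mut], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  r <- tajima_nei_pair(x, y)
  jc <- -3 / 4 * log(1 - 4 / 3 * r$p)
  expect_lt(abs(r$distance - jc), 1e-3)

  # heavy divergence: the correction expands the raw proportion
  y2 <- x
  mut2 <- sample(4000, 2000)
  y2[mut2] <- vapply(x[mut2], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  r2 <- tajima_nei_pair(x, y2)
  expect_gt(r2$distance, r2$p)

  # non-ACGT sites are excluded
  r3 <- tajima_nei_pair(c("A", "N", "G"), c("A", "C", "G"))
  expect_identical(r3$n_sites, 2L)
})

test_that("the filter policy removes and tallies by rule, idempotently", {
  rec <- data.frame(
    orthogroup = "OG1", seq1 = paste0("s", 1:5), seq2 = "out",
    cluster1 = c("A", "A", "B", "B", "A"), cluster2 = c("O", "O", "O", "O", "A"),
    dN = c(0.1, 0, 0.2, 0.3, 0.1), dS = c(0.2, 0, 0.05, 12, 0.2),
    omega = c(0.5, NA, 6, 0.025, 0.5), tn_distance = c(0.15, 0, 0.18, 5, 0.15),
    usable = c(TRUE, FALSE, TRUE, TRUE, TRUE), reason = "",
    stringsAsFactors = FALSE)
  f <- apply_filters(rec)
  expect_identical(f$records$seq1, "s1")
  expect_identical(f$tally[["unusable"]], 1L)
  expect_identical(f$tally[["omega_above_max"]], 1L)
  expect_identical(f$tally[["ds_above_max"]], 1L)
  expect_identical(f$tally[["same_cluster"]], 1L)

  # idempotent
  f2 <- apply_filters(f$records)
  expect_identical(f2$records, f$records)
  expect_identical(sum(f2$tally), 0L)

  # order-independent: permuting rows permutes nothing but row order
  perm <- rec[c(4, 2, 5, 1, 3), ]
  f3 <- apply_filters(perm)
  expect_identical(sort(f3$records$seq1), sort(f$records$seq1))
  expect_identical(f3$tally[order(names(f3$tally))],
                   f$tally[order(names(f$tally))])
})

test_that("the screen applies the two-fold + significance decision rule", {
  same <- selection_screen(c(0.4, 0.5, 0.6), c(0.4, 0.5, 0.6))
  expect_equal(same$log2_ratio, 0)
  expect_identical(same$flag, "ns")

  r <- selection_screen(c(0.8, 0.9, 1.0), c(0.2, 0.225, 0.25))
  expect_equal(r$log2_ratio, 2)  # log2(0.9 / 0.225)
  # complete separation at n = 3 vs 3: exact two-sided p = 2/20
  expect_equal(r$p, 0.1)
  expect_identical(r$flag, "ns")  # ratio passes, p does not

  expect_error(selection_screen(numeric(), c(1)), "empty")
})

test_that("outgroup-referenced omega sets recover a planted selection contrast", {
  sim <- simulate_codon_orthogroup(200, c(A = 1.0, B = 0.2),
                                   n_per_cluster = 19, t_anc = 0.1,
                                   t_tip = 0.1, seed = 7)
  recs <- selection_pairs(sim$alignment, outgroup = "OUT", orthogroup = "OG")
  expect_identical(nrow(recs), 38L)
  expect_true(all(recs$cluster2 == "OUT"))
  kept <- apply_filters(recs)$records
  sc <- selection_screen(kept$omega[kept$cluster1 == "A"],
                         kept$omega[kept$cluster1 == "B"],
                         cluster_a = "A", cluster_b = "B")
  expect_identical(sc$flag, "higher_in_A")
  expect_gt(sc$log2_ratio, 1)
})

test_that("multi-sequence outgroups pick the closest representative deterministically", {
  sim <- simulate_codon_orthogroup(60, c(A = 0.5), n_per_cluster = 4,
                                   seed = 23)
  aln <- sim$alignment
  # duplicate the outgroup row under two IDs; representative choice is stable
  m <- unclass(aln)
  m2 <- rbind(m, m["outgroup_rep", , drop = FALSE])
  rownames(m2)[nrow(m2)] <- "outgroup_rep2"
  cl <- c(attr(aln, "cluster"), OUT = "OUT")
  names(cl) <- rownames(m2)
  a2 <- pg_alignment(m2, cluster = unname(cl), codon = TRUE)
  r1 <- selection_pairs(a2, outgroup = "OUT")
  r2 <- selection_pairs(a2, outgroup = "OUT")
  expect_identical(r1$seq2, r2$seq2)
  expect_identical(unique(r1$seq2), "outgroup_rep")  # tie broken by ID
})
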