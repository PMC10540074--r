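count_matrix <- function(presence_counts, N) {
  # one orthogroup per requested presence count k: present in the first k
  # genomes
  m <- t(vapply(presence_counts, function(k) c(rep(1L, k), rep(0L, N - k)),
                integer(N)))
  dimnames(m) <- list(paste0("OG_k", presence_counts), paste0("g", seq_len(N)))
  m
}

test_that("partition applies the frequency rules with stated precedence", {
  m <- count_matrix(c(20, 19, 3, 2, 1), 20)
  p <- pangenome_partition(m)
  expect_identical(as.character(p$classes[c("OG_k20", "OG_k19", "OG_k3",
                                            "OG_k2", "OG_k1")]),
                   c("core", "soft_core", "shell", "cloud", "unique"))

  # fraction rule outranks the cloud count rule: N=10, k=2 is shell
  p2 <- pangenome_partition(count_matrix(2, 10))
  expect_identical(as.character(p2$classes), "shell")

  # clonal matrix: everything core
  p3 <- pangenome_partition(matrix(1L, 5, 4, dimnames = list(paste0("OG", 1:5),
                                                             paste0("g", 1:4))))
  expect_true(all(p3$classes == "core"))
  expect_error(pangenome_partition(matrix(1L, 2, 1)), "single genome")
})

test_that("partition rules match an independent coder exhaustively (N <= 30)", {
  for (N in 2:30) {
    ks <- 1:N
    p <- pangenome_partition(count_matrix(ks, N))
    got <- as.character(p$classes[paste0("OG_k", ks)])
    want <- vapply(ks, function(k) oracle_partition_class(N, k), character(1))
    expect_identical(got, want)
    # exhaustive and exclusive: every k classified exactly once
    expect_false(anyNA(got))
  }
  # absent-everywhere orthogroups are excluded
  m <- count_matrix(c(0, 3), 5)
  expect_identical(names(pangenome_partition(m)$classes), "OG_k3")
})

test_that("accumulation curves behave analytically in degenerate regimes", {
  # identical genomes: flat curve
  m <- matrix(1L, 30, 6, dimnames = list(paste0("OG", 1:30), paste0("g", 1:6)))
  cv <- accumulation_curve(m, n_permutations = 50, seed = 1)
  expect_true(all(cv$y_mean == 30))

  # fully disjoint genomes with g families each: y[k] = g*k exactly
  g <- 7L; N <- 5L
  m2 <- matrix(0L, g * N, N,
               dimnames = list(paste0("OG", seq_len(g * N)), paste0("g", 1:N)))
  for (j in seq_len(N)) m2[(j - 1L) * g + seq_len(g), j] <- 1L
  cv2 <- accumulation_curve(m2, n_permutations = 20, seed = 2)
  expect_equal(cv2$y_mean, g * (1:N))

  # seeding contract
  m3 <- matrix(rbinom(200, 1, 0.4), 50, 4,
               dimnames = list(paste0("OG", 1:50), paste0("g", 1:4)))
  a <- accumulation_curve(m3, 25, seed = 10)
  b <- accumulation_curve(m3, 25, seed = 10)
  c <- accumulation_curve(m3, 25, seed = 11)
  expect_identical(a$y_mean, b$y_mean)
  expect_false(identical(a$y_mean, c$y_mean))
})

test_that("every permutation's curve is monotone and ends at the pangenome size", {
  set.seed(3)
  m <- matrix(rbinom(400, 1, 0.3), 100, 4,
              dimnames = list(paste0("OG", 1:100), paste0("g", 1:4)))
  cv <- accumulation_curve(m, 200, seed = 4, keep_permutations = TRUE)
  total <- sum(rowSums(m) > 0)
  for (r in seq_len(nrow(cv$y_perm))) {
    expect_true(all(diff(cv$y_perm[r, ]) >= 0))
    expect_identical(unname(cv$y_perm[r, ncol(cv$y_perm)]), as.numeric(total))
  }
})

test_that("power-law fit recovers noiseless parameters and limiting exponents", {
  mk_curve <- function(x, y) structure(list(x = x, y_mean = y),
                                       class = "accumulation_curve")
  # noiseless model data to >= 4 significant digits
  f <- fit_power_law(mk_curve(1:25, 2000 * (1:25)^0.25))
  expect_equal(f$a, 2000, tolerance = 1e-4)
  expect_equal(f$gamma, 0.25, tolerance = 1e-4)

  # closed pangenome: flat curve
  f2 <- fit_power_law(mk_curve(1:20, rep(1500, 20)))
  expect_lt(abs(f2$gamma), 0.05)
  expect_false(f2$open)

  # fully open: linear curve
  f3 <- fit_power_law(mk_curve(1:20, 7 * (1:20)))
  expect_equal(f3$gamma, 1, tolerance = 0.002)

  expect_error(fit_power_law(mk_curve(1:10, rep(0, 10))), "all-zero")
})

test_that("gamma is invariant to genome reordering and relabeling", {
  set.seed(8)
  m <- matrix(rbinom(1200, 1, 0.35), 200, 6,
              dimnames = list(paste0("OG", 1:200), paste0("g", 1:6)))
  f1 <- fit_power_law(accumulation_curve(m, 200, seed = 5))
  # reordering columns: exactly invariant (canonical column order)
  f2 <- fit_power_law(accumulation_curve(m[, 6:1], 200, seed = 5))
  expect_equal(f1$gamma, f2$gamma, tolerance = 1e-12)
  # renaming genomes: invariant up to permutation-sampling noise
  m3 <- m
  colnames(m3) <- paste0("z", 1:6)
  f3 <- fit_power_law(accumulation_curve(m3, 200, seed = 5))
  expect_equal(f1$gamma, f3$gamma, tolerance = 1e-2)
})

fake_partition <- function(classes) {
  structure(list(classes = factor(classes,
                                  levels = c("core", "soft_core", "shell",
                                             "cloud", "unique")),
                 counts = table(classes), n_genomes = 10L),
            class = "pangenome_partition")
}

test_that("COG enrichment arithmetic, zero rule, and neutral case", {
  # category J: core 10% (1/10), accessory 2.5% (1/40) -> log2 = 2
  cls <- c(rep("core", 10), rep("shell", 40))
  names(cls) <- paste0("OG", 1:50)
  part <- fake_partition(cls)
  ann <- data.frame(gene_id = paste0("gene", 1:50),
                    orthogroup_id = paste0("OG", 1:50),
                    cog = c("J", rep("", 9), "J", rep("", 39)),
                    stringsAsFactors = FALSE)
  e <- cog_enrichment(part, ann)
  j <- e[e$category == "J", ]
  expect_equal(j$core_percent, 10)
  expect_equal(j$accessory_percent, 2.5)
  expect_equal(j$log2_ratio, 2)
  expect_identical(j$call, "core_enriched")
  # unannotated orthogroups carry "@" and are in the denominators
  expect_true("@" %in% e$category)

  # category in the accessory fraction only: undefined
  ann2 <- ann
  ann2$cog[12] <- "X"
  e2 <- cog_enrichment(part, ann2)
  expect_identical(e2[e2$category == "X", "call"], "undefined")
  expect_true(is.na(e2[e2$category == "X", "log2_ratio"]))

  # identical category profiles in both fractions: all log2 = 0, neutral
  cls3 <- c(rep("core", 4), rep("cloud", 4))
  names(cls3) <- paste0("OG", 1:8)
  ann3 <- data.frame(gene_id = paste0("g", 1:8),
                     orthogroup_id = paste0("OG", 1:8),
                     cog = rep(c("J", "K"), 4), stringsAsFactors = FALSE)
  e3 <- cog_enrichment(fake_partition(cls3), ann3)
  expect_true(all(e3$log2_ratio == 0))
  expect_true(all(e3$call == "neutral"))
})

test_that("COG log2 ratios are antisymmetric under swapping fractions", {
  set.seed(21)
  cls <- sample(c("core", "shell"), 60, replace = TRUE, prob = c(0.4, 0.6))
  names(cls) <- paste0("OG", 1:60)
  ann <- data.frame(gene_id = paste0("g", 1:60),
                    orthogroup_id = paste0("OG", 1:60),
                    cog = sample(c("J", "K", "L", ""), 60, replace = TRUE),
                    stringsAsFactors = FALSE)
  swapped <- ifelse(cls == "core", "shell", "core")
  names(swapped) <- names(cls)
  e1 <- cog_enrichment(fake_partition(cls), ann)
  e2 <- cog_enrichment(fake_partition(swapped), ann)
  common <- intersect(e1$category[!is.na(e1$log2_ratio)],
                      e2$category[!is.na(e2$log2_ratio)])
  expect_gt(length(common), 0L)
  expect_equal(e1$log2_ratio[match(common, e1$category)],
               -e2$log2_ratio[match(common, e2$category)])
})

test_that("single-copy core requires exactly one copy everywhere", {
  m <- rbind(OGa = c(1L, 1L, 1L), OGb = c(1L, 2L, 1L), OGc = c(1L, 0L, 1L))
  colnames(m) <- paste0("g", 1:3)
  expect_identical(single_copy_core(m), "OGa")
})
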