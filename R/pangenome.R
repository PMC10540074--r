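# Pangenome partitioning, permutation accumulation curves, Heaps power-law
# openness, COG enrichment, and single-copy-core selection.

PANGENOME_CLASSES <- c("core", "soft_core", "shell", "cloud", "unique")

#' Partition orthogroups into pangenome frequency classes
#'
#' For an orthogroup present in `k` of `N` genomes (fraction `f = k/N`), the
#' first matching rule assigns its class:
#' `k == 1` unique; `f == 1` core; `f >= soft_core_fraction` soft-core;
#' `f >= shell_fraction` shell; `k >= cloud_min_count` cloud. This precedence
#' (unique before the fraction rules) keeps the classes exhaustive for all
#' `N`, including small `N` where a single genome already exceeds the shell
#' fraction. Orthogroups absent from every genome are excluded.
#'
#' @param mat gene-count matrix (orthogroups x genomes), `N >= 2` genomes.
#' @param soft_core_fraction lower bound of the soft-core band (default 0.90).
#' @param shell_fraction lower bound of the shell band (default 0.15).
#' @param cloud_min_count minimum genome count for cloud (default 2).
#' @return object of class `pangenome_partition`: list with `classes`
#'   (named factor orthogroup -> class), `counts` (per-class totals),
#'   `n_genomes`, `thresholds`.
#' @export
pangenome_partition <- function(mat, soft_core_fraction = 0.90,
                                shell_fraction = 0.15, cloud_min_count = 2L) {
  N <- ncol(mat)
  if (N < 2L) stop_format("pangenome partition undefined for a single genome")
  if (!(shell_fraction > 0 && shell_fraction < soft_core_fraction &&
        soft_core_fraction < 1))
    stop_format("need 0 < shell_fraction < soft_core_fraction < 1")
  k <- rowSums(mat > 0)
  present <- k > 0
  k <- k[present]
  f <- k / N
  cls <- ifelse(k == 1L, "unique",
         ifelse(f == 1, "core",
         ifelse(f >= soft_core_fraction, "soft_core",
         ifelse(f >= shell_fraction, "shell", "cloud"))))
  cls <- factor(cls, levels = PANGENOME_CLASSES)
  names(cls) <- rownames(mat)[present]
  structure(list(classes = cls,
                 counts = table(cls),
                 n_genomes = N,
                 thresholds = list(soft_core_fraction = soft_core_fraction,
                                   shell_fraction = shell_fraction,
                                   cloud_min_count = cloud_min_count)),
            class = "pangenome_partition")
}

#' @export
print.pangenome_partition <- function(x, ...) {
  cat(sprintf("Pangenome over %d genomes: %d orthogroups\n",
              x$n_genomes, length(x$classes)))
  print(x$counts)
  invisible(x)
}

#' Permutation accumulation curve of pangenome size
#'
#' For each random permutation of the genome order, the pangenome size after
#' `k` genomes is the number of orthogroups present in at least one of the
#' first `k`. The curve reported is the mean over permutations; every
#' per-permutation curve is non-decreasing and ends at the total pangenome
#' size.
#'
#' @param mat gene-count matrix (orthogroups x genomes).
#' @param n_permutations number of genome-order permutations (default 1000).
#' @param seed integer RNG seed (reproducibility contract: same seed, same
#'   curve).
#' @param keep_permutations retain the per-permutation curve matrix.
#' @return object of class `accumulation_curve`: list with `x` (1..N),
#'   `y_mean`, `n_permutations`, `seed`, and optionally `y_perm`
#'   (permutations x N).
#' @export
accumulation_curve <- function(mat, n_permutations = 1000L, seed = 1L,
                               keep_permutations = FALSE) {
  if (n_permutations < 1L) stop_format("need n_permutations >= 1")
  pres <- mat > 0
  pres <- pres[rowSums(pres) > 0L, , drop = FALSE]
  # canonical column order: the curve depends on the genome set, not on the
  # order columns happen to arrive in
  pres <- pres[, order(colnames(pres)), drop = FALSE]
  N <- ncol(mat)
  curves <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(p) {
      ord <- sample.int(N)
      first <- max.col(pres[, ord, drop = FALSE], ties.method = "first")
      cumsum(tabulate(first, nbins = N))
    }, numeric(N))
  })
  curves <- t(curves)  # permutations x N
  structure(list(x = seq_len(N), y_mean = colMeans(curves),
                 n_permutations = n_permutations, seed = seed,
                 y_perm = if (keep_permutations) curves else NULL),
            class = "accumulation_curve")
}

#' Fit the Heaps power law to an accumulation curve
#'
#' Nonlinear least squares of `y = a * x^gamma` on the mean accumulation
#' curve (Levenberg-Marquardt; start `a = y[1]`, `gamma = 0.3`; tolerance
#' 1e-10). An exponent in (0, 1) is the conventional signature of an open
#' pangenome.
#'
#' @param curve an [accumulation_curve()] result (>= 3 points).
#' @return object of class `heaps_fit`: `a`, `gamma`, `residual_norm`,
#'   `open` (logical: 0 < gamma < 1), plus the input points.
#' @export
fit_power_law <- function(curve) {
  x <- curve$x
  y <- curve$y_mean
  if (length(x) < 3L) stop_format("need at least 3 curve points")
  if (all(y == 0)) stop_format("degenerate all-zero accumulation curve")
  fit <- minpack.lm::nlsLM(
    y ~ a * x^g,
    start = list(a = max(y[1L], .Machine$double.eps), g = 0.3),
    control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                         maxiter = 500L))
  cf <- stats::coef(fit)
  structure(list(a = unname(cf["a"]), gamma = unname(cf["g"]),
                 residual_norm = sqrt(sum(stats::residuals(fit)^2)),
                 open = cf["g"] > 0 && cf["g"] < 1,
                 x = x, y = y),
            class = "heaps_fit")
}

#' @export
print.heaps_fit <- function(x, ...) {
  cat(sprintf("Heaps fit: y = %.4g * x^%.4g  (residual norm %.3g) -> %s pangenome\n",
              x$a, x$gamma, x$residual_norm,
              if (x$open) "open" else "closed/saturating"))
  invisible(x)
}

#' @export
coef.heaps_fit <- function(object, ...) {
  c(a = object$a, gamma = object$gamma)
}

#' @export
predict.heaps_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else newdata$x %||% newdata
  object$a * x^object$gamma
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Core-versus-accessory COG enrichment
#'
#' The accessory fraction pools soft-core, shell, cloud and unique
#' orthogroups. Each orthogroup's category set is the union of its member
#' genes' COG letters (an orthogroup with no annotated letters carries the
#' `@` pseudo-category); a multi-letter orthogroup counts once in each of
#' its categories. Per category: `core_percent` = 100 x (core orthogroups
#' carrying it) / (core orthogroups), likewise for the accessory pool, and
#' `log2_ratio = log2(core_percent / accessory_percent)`. The call is
#' `core_enriched` at log2 >= 1 (two-fold), `core_depleted` at <= -1,
#' `undefined` when either percentage is zero, else `neutral`.
#'
#' @param partition a [pangenome_partition()] result.
#' @param annotations data.frame from [read_annotations()].
#' @param unit `"family"` (default): count each orthogroup once per category;
#'   `"gene"`: count member genes.
#' @return data.frame (`category`, `core_percent`, `accessory_percent`,
#'   `log2_ratio`, `call`) sorted by category.
#' @export
cog_enrichment <- function(partition, annotations, unit = c("family", "gene")) {
  unit <- match.arg(unit)
  cls <- partition$classes
  core_ogs <- names(cls)[cls == "core"]
  acc_ogs <- names(cls)[cls != "core"]
  if (length(core_ogs) == 0L || length(acc_ogs) == 0L)
    stop_format("both core and accessory fractions must be non-empty")
  ann <- annotations[annotations$orthogroup_id %in% names(cls), , drop = FALSE]
  og_cats <- lapply(split(ann$cog, ann$orthogroup_id), function(s) {
    u <- unique(unlist(strsplit(s, "")))
    if (length(u) == 0L) "@" else u
  })
  # orthogroups with no annotated gene at all also carry "@"
  missing <- setdiff(names(cls), names(og_cats))
  og_cats[missing] <- list("@")
  gene_weight <- if (unit == "gene") {
    tab <- table(ann$orthogroup_id)
    w <- stats::setNames(rep(1L, length(og_cats)), names(og_cats))
    w[names(tab)] <- as.integer(tab)
    w
  } else stats::setNames(rep(1L, length(og_cats)), names(og_cats))
  tally <- function(ogs) {
    cats <- og_cats[ogs]
    wt <- rep(gene_weight[ogs], lengths(cats))
    counts <- tapply(wt, unlist(cats), sum)
    denom <- sum(gene_weight[ogs])
    100 * counts / denom
  }
  core_pct <- tally(core_ogs)
  acc_pct <- tally(acc_ogs)
  cats <- sort(unique(c(names(core_pct), names(acc_pct))))
  cp <- ifelse(cats %in% names(core_pct), core_pct[cats], 0)
  ap <- ifelse(cats %in% names(acc_pct), acc_pct[cats], 0)
  ratio <- ifelse(cp > 0 & ap > 0, log2(cp / ap), NA_real_)
  call <- ifelse(cp == 0 | ap == 0, "undefined",
          ifelse(ratio >= 1, "core_enriched",
          ifelse(ratio <= -1, "core_depleted", "neutral")))
  data.frame(category = cats, core_percent = unname(cp),
             accessory_percent = unname(ap), log2_ratio = unname(ratio),
             call = call, stringsAsFactors = FALSE, row.names = NULL)
}

#' Single-copy core orthogroups
#'
#' Orthogroups with exactly one gene in every genome — the selection rule
#' behind concatenated single-copy marker alignments.
#'
#' @param mat gene-count matrix.
#' @return character vector of orthogroup IDs.
#' @export
single_copy_core <- function(mat) {
  rownames(mat)[rowSums(mat == 1L) == ncol(mat)]
}
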