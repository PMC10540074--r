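# Per-orthogroup neutrality statistics from nucleotide alignments, and
# between-cluster distribution comparison with the Mann-Whitney U test and
# the common-language effect size.

# Columns containing any character outside A,C,G,T are excluded entirely
# (complete deletion), identically for S and pi.
retained_columns <- function(aln) {
  ok <- apply(aln, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
  unclass(aln)[, ok, drop = FALSE]
}

#' Number of segregating sites
#'
#' Counts retained alignment columns (complete deletion of any column with a
#' non-ACGT character) carrying at least two distinct bases.
#'
#' @param aln a [pg_alignment()] (or plain character matrix), >= 2 sequences.
#' @return integer S; `NA` when every column is excluded.
#' @export
segregating_sites <- function(aln) {
  if (nrow(aln) < 2L) stop_format("need at least 2 sequences")
  keep <- retained_columns(aln)
  if (ncol(keep) == 0L) return(NA_integer_)
  sum(apply(keep, 2L, function(col) length(unique(col)) > 1L))
}

#' Nucleotide diversity (mean pairwise differences, count units)
#'
#' Mean number of differing retained sites over all `n(n-1)/2` sequence
#' pairs, under the same complete-deletion rule as [segregating_sites()].
#'
#' @param aln a [pg_alignment()], >= 2 sequences.
#' @return numeric pi in difference-count units; `NA` when every column is
#'   excluded.
#' @export
nucleotide_diversity <- function(aln) {
  n <- nrow(aln)
  if (n < 2L) stop_format("need at least 2 sequences")
  keep <- retained_columns(aln)
  if (ncol(keep) == 0L) return(NA_real_)
  npairs <- n * (n - 1) / 2
  # per column: pairwise differences = C(n,2) - sum_b C(count_b, 2)
  diffs <- apply(keep, 2L, function(col) {
    cb <- tabulate(match(col, c("A", "C", "G", "T")), 4L)
    npairs - sum(cb * (cb - 1) / 2)
  })
  sum(diffs) / npairs
}

#' Tajima (1989) constants for sample size n
#'
#' @param n number of sequences (>= 4 for a defined variance).
#' @return named list `a1, a2, b1, b2, c1, c2, e1, e2`.
#' @export
tajima_constants <- function(n) {
  if (n < 2L) stop_format("need n >= 2")
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = e1, e2 = e2)
}

#' Tajima's D
#'
#' `D = (pi - S/a1) / sqrt(e1*S + e2*S*(S-1))` with the constants of
#' [tajima_constants()]. Undefined (flagged, not dropped) when `S = 0` or
#' `n < 4`; undefined results carry `defined = FALSE` and `D = NA`.
#'
#' @param aln a [pg_alignment()].
#' @param orthogroup optional ID carried into the result.
#' @return list (`orthogroup`, `n`, `S`, `pi`, `D`, `defined`).
#' @export
tajimas_d <- function(aln, orthogroup = NA_character_) {
  n <- nrow(aln)
  if (n < 4L)
    return(list(orthogroup = orthogroup, n = n, S = NA_integer_,
                pi = NA_real_, D = NA_real_, defined = FALSE))
  S <- segregating_sites(aln)
  pi <- nucleotide_diversity(aln)
  if (is.na(S) || S == 0L)
    return(list(orthogroup = orthogroup, n = n, S = S, pi = pi,
                D = NA_real_, defined = FALSE))
  k <- tajima_constants(n)
  D <- (pi - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  list(orthogroup = orthogroup, n = n, S = S, pi = pi, D = D,
       defined = TRUE)
}

#' Mann-Whitney U comparison with common-language effect size
#'
#' `U = sum over pairs (a, b) of [1 if a > b, 0.5 if a == b]`;
#' `CLES = U / (n1*n2)` — the probability that a random observation from the
#' first group exceeds one from the second. The two-sided p-value uses the
#' exact tie-free U null distribution when there are no ties and
#' `n1*n2 <= exact_limit`, otherwise the tie-corrected normal approximation
#' with continuity correction.
#'
#' @param a,b numeric vectors (both non-empty).
#' @param exact_limit switch point for the exact path (default 400).
#' @return list (`n1`, `n2`, `U`, `p`, `cles`, `median_a`, `median_b`,
#'   `method`).
#' @export
compare_groups <- function(a, b, exact_limit = 400L) {
  if (length(a) == 0L || length(b) == 0L)
    stop_format("both groups must be non-empty")
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1L)
  if (!has_ties && n1 * n2 <= exact_limit) {
    pl <- stats::pwilcox(U, n1, n2)
    pu <- 1 - stats::pwilcox(U - 1, n1, n2)
    p <- min(1, 2 * min(pl, pu))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    ntot <- n1 + n2
    sigma <- sqrt((n1 * n2 / 12) *
                  ((ntot + 1) - sum(ties^3 - ties) / (ntot * (ntot - 1))))
    z <- U - mu
    cc <- sign(z) * 0.5
    p <- if (sigma == 0) 1 else 2 * stats::pnorm(-abs((z - cc) / sigma))
    p <- min(1, p)
    method <- "normal"
  }
  list(n1 = n1, n2 = n2, U = U, p = p, cles = U / (n1 * n2),
       median_a = stats::median(a), median_b = stats::median(b),
       method = method)
}

#' Per-orthogroup, per-cluster Tajima's D over a directory of alignments
#'
#' Computes within-cluster Tajima's D for every orthogroup alignment: each
#' FASTA in `paths` is split by its cluster labels and D computed per
#' cluster on the within-cluster sequences only.
#'
#' @param paths named character vector of FASTA paths (names = orthogroup
#'   IDs; unnamed paths use the basename).
#' @param min_n minimum sequences per cluster (default 4).
#' @return data.frame (`orthogroup`, `cluster`, `n`, `S`, `pi`, `D`,
#'   `defined`).
#' @export
tajima_scan <- function(paths, min_n = 4L) {
  if (is.null(names(paths)))
    names(paths) <- sub("\\.[^.]*$", "", basename(paths))
  rows <- list()
  for (og in names(paths)) {
    aln <- read_alignment(paths[[og]])
    cl <- attr(aln, "cluster")
    if (is.null(cl)) cl <- stats::setNames(rep("all", nrow(aln)), rownames(aln))
    for (g in sort(unique(cl))) {
      sub <- unclass(aln)[cl == g, , drop = FALSE]
      if (nrow(sub) < min_n) next
      d <- tajimas_d(sub, orthogroup = og)
      rows[[length(rows) + 1L]] <- data.frame(
        orthogroup = og, cluster = g, n = d$n, S = d$S, pi = d$pi,
        D = d$D, defined = d$defined, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(orthogroup = character(), cluster = character(),
                      n = integer(), S = integer(), pi = numeric(),
                      D = numeric(), defined = logical()))
  do.call(rbind, rows)
}
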