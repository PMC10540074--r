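# Codon-aware back-translation, Tajima-Nei distances, the pairwise filter
# policy, and the cross-cluster differential-selection screen.

#' Back-translate a protein alignment to a codon alignment
#'
#' Each amino-acid column is expanded to its source codon; protein gaps
#' become `---`; a trailing stop codon on the CDS is trimmed. Every CDS must
#' translate exactly to its ungapped protein under the standard code, with
#' bacterial (table 11) start-codon tolerance: an initial `GTG`/`TTG` is
#' accepted as methionine.
#'
#' @param protein_aln named character vector of aligned protein strings (or
#'   a character matrix, rows = sequences) with `-` gaps.
#' @param cds named character vector of unaligned CDS nucleotide strings;
#'   names must cover the protein sequence IDs.
#' @return a codon-mode [pg_alignment()].
#' @export
backtranslate <- function(protein_aln, cds) {
  if (is.matrix(protein_aln)) {
    ids <- rownames(protein_aln)
    protein_aln <- stats::setNames(apply(protein_aln, 1L, paste, collapse = ""), ids)
  }
  ids <- names(protein_aln)
  missing <- setdiff(ids, names(cds))
  if (length(missing))
    stop_format("no CDS for: %s", paste(missing, collapse = ", "))
  out <- character(length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    prot <- strsplit(toupper(protein_aln[[id]]), "")[[1]]
    ungapped <- prot[prot != "-"]
    codons <- seq_to_codons(toupper(cds[[id]]))
    aa <- translate_codons(codons)
    if (length(aa) == length(ungapped) + 1L && aa[length(aa)] == "*") {
      codons <- codons[-length(codons)]
      aa <- aa[-length(aa)]
    }
    if (length(aa) != length(ungapped))
      stop_format("CDS length mismatch for '%s': %d codons vs %d residues",
                  id, length(aa), length(ungapped))
    if (length(aa) && aa[1L] != ungapped[1L] &&
        codons[1L] %in% c("GTG", "TTG") && ungapped[1L] == "M")
      aa[1L] <- "M"  # bacterial alternative start
    bad <- which(aa != ungapped)
    if (length(bad))
      stop_format("translation mismatch for '%s' at residue %d: %s vs %s",
                  id, bad[1L], aa[bad[1L]], ungapped[bad[1L]])
    res <- character(length(prot))
    res[prot == "-"] <- "---"
    res[prot != "-"] <- codons
    out[k] <- paste(res, collapse = "")
  }
  pg_alignment(stats::setNames(out, ids), codon = TRUE)
}

#' Tajima-Nei (1984) pairwise distance
#'
#' Distance correcting for unequal base composition:
#' `d = -b log(1 - p/b)` with
#' `b = (1 - sum(g_i^2) + p^2/h) / 2` and
#' `h = sum over base pairs i<j of x_ij^2 / (2 g_i g_j)`, where `p` is the
#' mismatch proportion, `g_i` the base frequencies pooled over both
#' sequences and `x_ij` the proportion of sites showing the unordered base
#' pair `(i, j)`. Sites with a non-ACGT character in either sequence are
#' excluded. Reduces to the Jukes-Cantor distance in the equal-frequency
#' limit.
#'
#' @param seq1,seq2 aligned sequences (strings, base vectors, or alignment
#'   rows) of equal length.
#' @return list (`distance`, `p`, `n_sites`, `usable`, `reason`); identical
#'   sequences give distance 0; `p >= b` (excess divergence) flags the pair
#'   unusable.
#' @export
tajima_nei_pair <- function(seq1, seq2) {
  s1 <- if (length(seq1) > 1L) seq1 else strsplit(toupper(seq1), "")[[1]]
  s2 <- if (length(seq2) > 1L) seq2 else strsplit(toupper(seq2), "")[[1]]
  if (length(s1) != length(s2)) stop_format("sequences differ in length")
  acgt <- c("A", "C", "G", "T")
  ok <- s1 %in% acgt & s2 %in% acgt
  s1 <- s1[ok]; s2 <- s2[ok]
  n <- length(s1)
  out <- list(distance = NA_real_, p = NA_real_, n_sites = n,
              usable = FALSE, reason = "")
  if (n == 0L) { out$reason <- "no_analyzable_sites"; return(out) }
  p <- mean(s1 != s2)
  out$p <- p
  if (p == 0) { out$distance <- 0; out$usable <- TRUE; return(out) }
  g <- (tabulate(match(s1, acgt), 4L) + tabulate(match(s2, acgt), 4L)) / (2 * n)
  diff <- s1 != s2
  lo <- pmin(match(s1[diff], acgt), match(s2[diff], acgt))
  hi <- pmax(match(s1[diff], acgt), match(s2[diff], acgt))
  x <- table(factor(paste(lo, hi), levels = c("1 2", "1 3", "1 4",
                                              "2 3", "2 4", "3 4"))) / n
  pairs_idx <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  gg <- g[pairs_idx[, 1L]] * g[pairs_idx[, 2L]]
  valid <- gg > 0
  h <- sum(as.numeric(x)[valid]^2 / (2 * gg[valid]))
  if (h == 0) { out$reason <- "degenerate_composition"; return(out) }
  b <- (1 - sum(g^2) + p^2 / h) / 2
  if (p >= b) { out$reason <- "excess_divergence"; return(out) }
  out$distance <- -b * log(1 - p / b)
  out$usable <- TRUE
  out
}

#' Apply the pairwise-record filter policy
#'
#' Drops records that are unusable, have zero Tajima-Nei distance, omega
#' above `max_omega`, dS above `max_ds`, or (optionally) compare sequences
#' from the same cluster. Removal reasons are tallied per rule
#' (first-matching rule wins for the tally; the filters themselves are
#' idempotent and order-independent). The zero-distance rule is applied to
#' the Tajima-Nei distance, the quantity the policy is stated for.
#'
#' @param records data.frame with columns `cluster1`, `cluster2`, `dN`,
#'   `dS`, `omega`, `tn_distance`, `usable`.
#' @param max_omega omega cutoff (default 5).
#' @param max_ds dS cutoff (default 10).
#' @param cross_cluster_only drop same-cluster pairs (default `TRUE`).
#' @return list (`records` = surviving rows, `tally` = named integer vector
#'   of removal counts).
#' @export
apply_filters <- function(records, max_omega = 5, max_ds = 10,
                          cross_cluster_only = TRUE) {
  bad_unusable <- !records$usable
  bad_zero <- !bad_unusable & !is.na(records$tn_distance) &
    records$tn_distance == 0
  bad_omega <- !is.na(records$omega) & records$omega > max_omega
  bad_ds <- !is.na(records$dS) & records$dS > max_ds
  bad_same <- if (cross_cluster_only)
    records$cluster1 == records$cluster2 else rep(FALSE, nrow(records))
  drop <- bad_unusable | bad_zero | bad_omega | bad_ds | bad_same
  reason_order <- cbind(unusable = bad_unusable, zero_distance = bad_zero,
                        omega_above_max = bad_omega, ds_above_max = bad_ds,
                        same_cluster = bad_same)
  first <- apply(reason_order, 1L, function(r) which(r)[1L])
  tally <- table(factor(colnames(reason_order)[first[drop]],
                        levels = colnames(reason_order)))
  list(records = records[!drop, , drop = FALSE],
       tally = stats::setNames(as.integer(tally), names(tally)))
}

#' Pairwise selection records for one orthogroup against an outgroup
#'
#' Computes, for every ingroup sequence, its Nei-Gojobori dN/dS and
#' Tajima-Nei distance against one designated outgroup sequence, so that
#' every cluster's omega multiset is measured against the same yardstick.
#' When the outgroup carries several sequences, the one with the smallest
#' median Tajima-Nei distance to the ingroup is chosen (ties broken by ID).
#'
#' @param aln codon [pg_alignment()] with cluster labels.
#' @param outgroup cluster label of the outgroup.
#' @param orthogroup optional ID stamped into the records.
#' @return data.frame, one row per ingroup sequence: `orthogroup`, `seq1`,
#'   `seq2`, `cluster1`, `cluster2`, `dN`, `dS`, `omega`, `tn_distance`,
#'   `usable`, `reason`.
#' @export
selection_pairs <- function(aln, outgroup, orthogroup = NA_character_) {
  cl <- attr(aln, "cluster")
  if (is.null(cl)) stop_format("alignment has no cluster labels")
  out_ids <- rownames(aln)[cl == outgroup]
  in_ids <- rownames(aln)[cl != outgroup]
  if (length(out_ids) == 0L)
    stop_format("no sequences labeled with outgroup '%s'", outgroup)
  if (length(out_ids) > 1L) {
    med <- vapply(sort(out_ids), function(o) {
      stats::median(vapply(in_ids, function(i)
        tajima_nei_pair(unclass(aln)[o, ], unclass(aln)[i, ])$distance,
        numeric(1L)), na.rm = TRUE)
    }, numeric(1L))
    rep_id <- names(med)[order(med, names(med))][1L]
  } else rep_id <- out_ids
  rows <- lapply(in_ids, function(i) {
    ng <- ng86_pair(unclass(aln)[i, ], unclass(aln)[rep_id, ])
    tn <- tajima_nei_pair(unclass(aln)[i, ], unclass(aln)[rep_id, ])
    usable <- ng$usable && tn$usable && !is.na(ng$omega)
    reason <- if (usable) "" else paste(c(ng$reason, tn$reason,
      if (ng$usable && is.na(ng$omega)) "omega_undefined"), collapse = ";")
    data.frame(orthogroup = orthogroup, seq1 = i, seq2 = rep_id,
               cluster1 = cl[[i]], cluster2 = outgroup,
               dN = ng$dN, dS = ng$dS, omega = ng$omega,
               tn_distance = tn$distance, usable = usable,
               reason = reason, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Differential-selection screen between two clusters
#'
#' Compares the per-member omega multisets of two clusters (each member
#' measured against the same outgroup). The orthogroup is flagged
#' `higher_in_A`/`higher_in_B` iff `|log2(median_A / median_B)| >
#' log2_threshold` AND the Mann-Whitney p-value is below `alpha`; otherwise
#' `ns`.
#'
#' @param omega_a,omega_b numeric omega multisets (post-filtering,
#'   non-empty).
#' @param cluster_a,cluster_b labels used in the result.
#' @param orthogroup optional ID.
#' @param log2_threshold absolute log2-ratio cutoff (default 1, i.e.
#'   two-fold).
#' @param alpha significance level (default 0.05).
#' @return one-row data.frame: `orthogroup`, `cluster_a`, `cluster_b`,
#'   `n_a`, `n_b`, `median_a`, `median_b`, `log2_ratio`, `U`, `p`, `cles`,
#'   `flag`.
#' @export
selection_screen <- function(omega_a, omega_b, cluster_a = "A",
                             cluster_b = "B", orthogroup = NA_character_,
                             log2_threshold = 1, alpha = 0.05) {
  if (length(omega_a) == 0L || length(omega_b) == 0L)
    stop_format("empty omega set")
  cmp <- compare_groups(omega_a, omega_b)
  ratio <- log2(cmp$median_a / cmp$median_b)
  hit <- is.finite(ratio) && abs(ratio) > log2_threshold && cmp$p < alpha
  flag <- if (!hit) "ns" else if (ratio > 0) "higher_in_A" else "higher_in_B"
  data.frame(orthogroup = orthogroup, cluster_a = cluster_a,
             cluster_b = cluster_b, n_a = cmp$n1, n_b = cmp$n2,
             median_a = cmp$median_a, median_b = cmp$median_b,
             log2_ratio = ratio, U = cmp$U, p = cmp$p, cles = cmp$cles,
             flag = flag, stringsAsFactors = FALSE)
}
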