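# Nei-Gojobori (1986) pairwise dN/dS with Jukes-Cantor correction.
# Site opportunities and per-codon-pair difference counts are precomputed
# once (pathway enumeration for multi-position differences) and cached.

BASES <- c("T", "C", "A", "G")

# Standard genetic code, codon order TTT, TTC, TTA, TTG, TCT, ... (first
# position slowest). The bacterial code (translation table 11) differs only
# in start codons, which matters for back-translation, not here.
GENETIC_CODE_AA <- strsplit(
  "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG", "")[[1]]

all_codons <- function() {
  g <- expand.grid(b3 = BASES, b2 = BASES, b1 = BASES,
                   stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
}

#' Translate codons to amino acids (standard code)
#'
#' @param codons character vector of 3-letter codons (uppercase ACGT).
#' @return character vector of single-letter amino acids (`*` = stop, `X`
#'   for codons containing non-ACGT characters).
#' @export
translate_codons <- function(codons) {
  tab <- stats::setNames(GENETIC_CODE_AA, all_codons())
  out <- tab[codons]
  out[is.na(out)] <- "X"
  unname(out)
}

# -- precomputed tables -------------------------------------------------------

.ng86_cache <- new.env(parent = emptyenv())

ng86_tables <- function() {
  if (!is.null(.ng86_cache$tables)) return(.ng86_cache$tables)
  codons <- all_codons()
  aa <- stats::setNames(GENETIC_CODE_AA, codons)
  sense <- codons[aa[codons] != "*"]
  ns <- length(sense)

  # Site opportunities: each of the 3 possible changes per position carries
  # weight 1/3; changes to stop codons are excluded from the opportunity
  # (consistent with a codon chain in which stop states are forbidden).
  syn_sites <- nonsyn_sites <- stats::setNames(numeric(ns), sense)
  for (c0 in sense) {
    sp <- strsplit(c0, "")[[1]]
    for (p in 1:3) for (b in setdiff(BASES, sp[p])) {
      alt <- sp; alt[p] <- b
      c1 <- paste(alt, collapse = "")
      if (aa[c1] == "*") next
      if (aa[c1] == aa[c0]) syn_sites[c0] <- syn_sites[c0] + 1 / 3
      else nonsyn_sites[c0] <- nonsyn_sites[c0] + 1 / 3
    }
  }

  # Pairwise difference counts: average syn/nonsyn steps over all
  # single-step pathways, excluding pathways through stop codons (falling
  # back to all pathways, stop steps counted nonsynonymous, when every
  # pathway is blocked).
  syn_diff <- nonsyn_diff <- matrix(0, ns, ns, dimnames = list(sense, sense))
  perms <- list(`1` = matrix(1L, 1, 1),
                `2` = rbind(c(1L, 2L), c(2L, 1L)),
                `3` = rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                            c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  split_codons <- strsplit(sense, "")
  names(split_codons) <- sense
  for (i in seq_len(ns)) for (j in seq_len(ns)) {
    if (i >= j) next
    c1 <- split_codons[[i]]; c2 <- split_codons[[j]]
    pos <- which(c1 != c2)
    d <- length(pos)
    if (d == 0L) next
    P <- perms[[as.character(d)]]
    path_counts <- function(order_idx, allow_stop) {
      cur <- c1; sd <- 0; nd <- 0
      for (p in pos[order_idx]) {
        nxt <- cur; nxt[p] <- c2[p]
        a0 <- aa[paste(cur, collapse = "")]
        a1 <- aa[paste(nxt, collapse = "")]
        if (a1 == "*" && !allow_stop) return(NULL)
        if (a0 == a1) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    }
    res <- lapply(seq_len(nrow(P)), function(r) path_counts(P[r, ], FALSE))
    res <- res[!vapply(res, is.null, logical(1L))]
    if (length(res) == 0L)
      res <- lapply(seq_len(nrow(P)), function(r) path_counts(P[r, ], TRUE))
    avg <- Reduce(`+`, res) / length(res)
    syn_diff[i, j] <- syn_diff[j, i] <- avg[1L]
    nonsyn_diff[i, j] <- nonsyn_diff[j, i] <- avg[2L]
  }
  .ng86_cache$tables <- list(sense = sense, aa = aa,
                             syn_sites = syn_sites,
                             nonsyn_sites = nonsyn_sites,
                             syn_diff = syn_diff, nonsyn_diff = nonsyn_diff)
  .ng86_cache$tables
}

seq_to_codons <- function(s) {
  if (length(s) > 1L) s <- paste(s, collapse = "")
  if (nchar(s) %% 3L != 0L)
    stop_format("sequence length %d not divisible by 3", nchar(s))
  substring(s, seq(1L, nchar(s), 3L), seq(3L, nchar(s), 3L))
}

jc_correct <- function(p) -3 / 4 * log(1 - 4 / 3 * p)

#' Nei-Gojobori (1986) pairwise dN and dS
#'
#' Counting method with fractional site opportunities averaged over the two
#' sequences, pathway-averaged difference counts for multi-position codon
#' differences (pathways through stop codons excluded), and Jukes-Cantor
#' correction `d = -(3/4) ln(1 - (4/3) p)`. Codons containing a gap, `N`, or
#' a stop in either sequence are skipped pairwise. `omega = dN/dS` is
#' defined only when `dS > 0`. A proportion `p >= 3/4` saturates the
#' correction and flags the pair unusable.
#'
#' @param seq1,seq2 codon-aligned sequences (strings, character vectors of
#'   bases, or rows of a codon [pg_alignment()]); equal lengths divisible
#'   by 3.
#' @return list (`dN`, `dS`, `omega`, `Sd`, `Nd`, `Ss`, `Ns`, `n_codons`,
#'   `usable`, `reason`).
#' @export
ng86_pair <- function(seq1, seq2) {
  tab <- ng86_tables()
  cod1 <- seq_to_codons(seq1)
  cod2 <- seq_to_codons(seq2)
  if (length(cod1) != length(cod2))
    stop_format("sequences differ in length")
  ok <- cod1 %in% tab$sense & cod2 %in% tab$sense
  cod1 <- cod1[ok]; cod2 <- cod2[ok]
  out <- list(dN = NA_real_, dS = NA_real_, omega = NA_real_,
              Sd = NA_real_, Nd = NA_real_, Ss = NA_real_, Ns = NA_real_,
              n_codons = length(cod1), usable = FALSE, reason = "")
  if (length(cod1) == 0L) { out$reason <- "no_analyzable_codons"; return(out) }
  Ss <- (sum(tab$syn_sites[cod1]) + sum(tab$syn_sites[cod2])) / 2
  Ns <- (sum(tab$nonsyn_sites[cod1]) + sum(tab$nonsyn_sites[cod2])) / 2
  Sd <- sum(tab$syn_diff[cbind(cod1, cod2)])
  Nd <- sum(tab$nonsyn_diff[cbind(cod1, cod2)])
  out[c("Sd", "Nd", "Ss", "Ns")] <- list(Sd, Nd, Ss, Ns)
  if (Ss == 0 || Ns == 0) { out$reason <- "no_sites"; return(out) }
  pS <- Sd / Ss; pN <- Nd / Ns
  if (pS >= 3 / 4 || pN >= 3 / 4) { out$reason <- "saturated"; return(out) }
  out$dS <- jc_correct(pS)
  out$dN <- jc_correct(pN)
  out$omega <- if (out$dS > 0) out$dN / out$dS else NA_real_
  out$usable <- TRUE
  out
}
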