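# Readers and writers for every external file dialect the pipeline touches.
# All downstream modules operate on the in-memory objects returned here:
# gene-count matrices, ANI pair tables, alignments, rooted trees and
# annotation tables.

COG_ALPHABET <- c(LETTERS, "@")
ALLOWED_BASES <- c("A", "C", "G", "T", "N", "-")

# -- gene-count tables (Orthofinder GeneCount dialect) ------------------------

#' Read an orthogroup-by-genome gene-count table
#'
#' Parses the tab-separated gene-count dialect: first column holds orthogroup
#' identifiers, one column per genome, and an optional trailing `Total` column
#' which is always ignored (it is a derived quantity; a mismatch with the row
#' sums raises a warning, never an error).
#'
#' @param path path to a tab-separated file with a header row.
#' @return integer matrix (orthogroups x genomes) with dimnames.
#' @export
read_gene_counts <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop_format("gene-count table '%s' has no data rows or no genome columns", path)
  og <- as.character(df[[1L]])
  df <- df[, -1L, drop = FALSE]
  has_total <- ncol(df) > 1L && colnames(df)[ncol(df)] == "Total"
  total <- if (has_total) df[[ncol(df)]] else NULL
  if (has_total) df <- df[, -ncol(df), drop = FALSE]
  if (ncol(df) < 1L)
    stop_format("gene-count table '%s' has no genome columns", path)
  if (anyDuplicated(og))
    stop_format("duplicate orthogroup identifiers in '%s': %s", path,
                paste(unique(og[duplicated(og)]), collapse = ", "))
  if (anyDuplicated(colnames(df)))
    stop_format("duplicate genome identifiers in '%s'", path)
  mat <- as.matrix(df)
  if (!is.numeric(mat) || any(is.na(mat)) || any(mat != floor(mat)))
    stop_format("non-integer gene count in '%s'", path)
  if (any(mat < 0))
    stop_format("negative gene count in '%s'", path)
  storage.mode(mat) <- "integer"
  dimnames(mat) <- list(og, colnames(df))
  if (has_total && any(rowSums(mat) != total))
    warning("'Total' column disagrees with row sums; 'Total' ignored",
            call. = FALSE)
  mat
}

#' Write a gene-count table
#'
#' @param mat integer matrix as returned by [read_gene_counts()].
#' @param path output path.
#' @param total append a derived `Total` column (default `FALSE`).
#' @return `path`, invisibly.
#' @export
write_gene_counts <- function(mat, path, total = FALSE) {
  df <- data.frame(Orthogroup = rownames(mat), as.data.frame(mat),
                   check.names = FALSE)
  if (total) df$Total <- unname(rowSums(mat))
  write_tsv_fixed(df, path)
}

# -- ANI pair tables (FastANI 5-column dialect) -------------------------------

strip_fasta_ext <- function(x) {
  x <- basename(x)
  sub("\\.(fa|fna|fasta)(\\.gz)?$", "", x, ignore.case = TRUE)
}

#' Read a pairwise ANI table
#'
#' Parses the headerless 5-column ANI dialect (query path, reference path,
#' ANI percent, fragments mapped, fragments total); columns 4-5 are optional.
#' Genome identifiers are the file basenames with any recognized FASTA
#' extension (`.fa`/`.fna`/`.fasta`, optionally `.gz`) stripped, so that
#' downstream matching works on bare IDs.
#'
#' @param path path to a tab-separated file without header.
#' @return data.frame with columns `query`, `reference`, `ani`,
#'   `frag_mapped`, `frag_total` (the last two `NA` when absent).
#' @export
read_ani_pairs <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    stop_format("ANI table '%s' needs at least 3 columns", path)
  ani <- as.numeric(df[[3L]])
  if (any(is.na(ani)) || any(ani < 0) || any(ani > 100))
    stop_format("ANI value outside [0, 100] in '%s'", path)
  out <- data.frame(
    query = strip_fasta_ext(as.character(df[[1L]])),
    reference = strip_fasta_ext(as.character(df[[2L]])),
    ani = ani,
    frag_mapped = if (ncol(df) >= 4L) as.integer(df[[4L]]) else NA_integer_,
    frag_total = if (ncol(df) >= 5L) as.integer(df[[5L]]) else NA_integer_,
    stringsAsFactors = FALSE)
  out
}

#' Write a pairwise ANI table
#'
#' @param pairs data.frame as returned by [read_ani_pairs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ani_pairs <- function(pairs, path) {
  df <- pairs[, c("query", "reference", "ani", "frag_mapped", "frag_total")]
  if (all(is.na(df$frag_mapped))) df <- df[, 1:3]
  con <- file(path, "w")
  on.exit(close(con))
  lines <- apply(df, 1L, function(r) {
    r[3L] <- sprintf("%.6f", as.numeric(r[3L]))
    paste(r, collapse = "\t")
  })
  writeLines(lines, con)
  invisible(path)
}

# -- alignments (FASTA) -------------------------------------------------------

#' Construct an alignment object
#'
#' Internal container used throughout: a character matrix with one row per
#' sequence (rownames = sequence IDs) and one column per site, uppercase,
#' alphabet restricted to `A,C,G,T,N,-`. Optional per-sequence cluster labels
#' ride along as an attribute.
#'
#' @param seqs named character vector of equal-length sequence strings, or a
#'   character matrix (rows = sequences).
#' @param cluster optional character vector of cluster labels, one per
#'   sequence.
#' @param codon logical; if `TRUE` the length must be divisible by 3.
#' @return object of class `pg_alignment`.
#' @export
pg_alignment <- function(seqs, cluster = NULL, codon = FALSE) {
  if (is.matrix(seqs)) {
    mat <- toupper(seqs)
  } else {
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L)
      stop_format("ragged alignment: sequence lengths %s",
                  paste(unique(lens), collapse = ", "))
    mat <- do.call(rbind, strsplit(toupper(seqs), ""))
    rownames(mat) <- names(seqs)
  }
  bad <- setdiff(unique(as.vector(mat)), ALLOWED_BASES)
  if (length(bad))
    stop_format("alignment contains characters outside A,C,G,T,N,-: %s",
                paste(bad, collapse = ", "))
  if (codon && ncol(mat) %% 3L != 0L)
    stop_format("codon alignment length %d not divisible by 3", ncol(mat))
  if (!is.null(cluster)) {
    if (length(cluster) != nrow(mat))
      stop_format("cluster labels (%d) do not match sequences (%d)",
                  length(cluster), nrow(mat))
    attr(mat, "cluster") <- stats::setNames(as.character(cluster), rownames(mat))
  }
  attr(mat, "codon") <- codon
  class(mat) <- c("pg_alignment", class(mat))
  mat
}

#' Read a FASTA alignment
#'
#' All sequences must have equal length (codon mode additionally requires a
#' length divisible by 3). Sequences are uppercased on read; the alphabet is
#' restricted to `A,C,G,T,N,-`. Cluster labels come either from a sidecar
#' two-column TSV (`sequence<TAB>cluster`) or from the header convention
#' `>cluster|rest_of_id`.
#'
#' @param path FASTA file path.
#' @param codon logical; treat as a codon alignment (default `FALSE`).
#' @param labels optional path to a sidecar label TSV.
#' @return a [pg_alignment()] object.
#' @export
read_alignment <- function(path, codon = FALSE, labels = NULL) {
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop_format("empty FASTA '%s'", path)
  seqs <- vapply(as.character(dna), paste, character(1L), collapse = "")
  ids <- names(dna)
  cluster <- NULL
  if (!is.null(labels)) {
    lab <- utils::read.delim(labels, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
    map <- stats::setNames(as.character(lab[[2L]]), as.character(lab[[1L]]))
    cluster <- unname(map[ids])
  } else if (all(grepl("|", ids, fixed = TRUE))) {
    cluster <- sub("\\|.*$", "", ids)
    ids <- sub("^[^|]*\\|", "", ids)
  }
  names(seqs) <- ids
  pg_alignment(seqs, cluster = cluster, codon = codon)
}

#' Write a FASTA alignment
#'
#' Cluster labels, when present, are written back into the headers as
#' `>cluster|id`, so write-then-read round-trips the object.
#'
#' @param aln a [pg_alignment()] object.
#' @param path output path.
#' @param width line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, width = 60L) {
  ids <- rownames(aln)
  cl <- attr(aln, "cluster")
  headers <- if (!is.null(cl)) paste0(cl, "|", ids) else ids
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(aln))) {
    writeLines(paste0(">", headers[i]), con)
    s <- paste(aln[i, ], collapse = "")
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# -- trees (newick) -----------------------------------------------------------

#' Name internal nodes deterministically
#'
#' Unlabeled internal nodes receive names `N1, N2, ...` in preorder
#' (cladewise) so ancestral-content reports are stable across runs.
#'
#' @param tree an `ape::phylo` object.
#' @return the tree with a complete `node.label`.
#' @export
name_internal_nodes <- function(tree) {
  tree <- stats::reorder(tree, "cladewise")
  m <- tree$Nnode
  n <- length(tree$tip.label)
  preorder <- unique(tree$edge[, 1L])  # internal nodes in order of first visit
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", m)
  lab[is.na(lab)] <- ""
  rank <- match(seq_len(m) + n, preorder)  # preorder rank of node n+i
  lab[lab == ""] <- paste0("N", rank[lab == ""])
  tree$node.label <- lab
  tree
}

#' Read a rooted tree from a newick file
#'
#' Leaf labels must be unique. Unlabeled internal nodes are auto-named
#' deterministically by preorder index (`N1` = root). A multifurcating root
#' (e.g. an unrooted trifurcation written as newick) is accepted but flagged
#' via the `root_multifurcation` attribute.
#'
#' @param path newick file path.
#' @return an `ape::phylo` with complete node labels.
#' @export
read_tree <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop_format("could not parse newick in '%s'", path)
  if (anyDuplicated(tree$tip.label))
    stop_format("duplicate leaf labels: %s",
                paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                      collapse = ", "))
  tree <- name_internal_nodes(tree)
  root <- length(tree$tip.label) + 1L
  attr(tree, "root_multifurcation") <- sum(tree$edge[, 1L] == root) > 2L
  tree
}

#' Write a tree to a newick file
#'
#' @param tree an `ape::phylo`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# -- annotation tables --------------------------------------------------------

#' Read a gene-to-orthogroup COG annotation table
#'
#' Three tab-separated columns with header: `gene_id`, `orthogroup_id`,
#' `cog` (a string of root-level COG category letters, possibly empty;
#' `@` marks genes without any COG). A gene maps to at most one orthogroup.
#'
#' @param path TSV path.
#' @return data.frame with columns `gene_id`, `orthogroup_id`, `cog`.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("gene_id", "orthogroup_id", "cog") %in% colnames(df)))
    stop_format("annotation table '%s' must have columns gene_id, orthogroup_id, cog", path)
  df[is.na(df$cog), "cog"] <- ""
  if (anyDuplicated(df$gene_id))
    stop_format("gene mapped to more than one orthogroup in '%s'", path)
  letters_used <- unique(unlist(strsplit(df$cog, "")))
  bad <- setdiff(letters_used, COG_ALPHABET)
  if (length(bad))
    stop_format("unknown COG category letters in '%s': %s", path,
                paste(bad, collapse = ", "))
  df[, c("gene_id", "orthogroup_id", "cog")]
}

#' Write an annotation table
#'
#' @param annotations data.frame as returned by [read_annotations()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  write_tsv_fixed(annotations[, c("gene_id", "orthogroup_id", "cog")], path)
}
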