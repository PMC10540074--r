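# Single-command orchestration of the full study: cluster -> pangenome ->
# gainloss -> tajima -> dnds -> screen, with a run manifest recording every
# parameter, seed and filter tally. Outputs are deterministic: a rerun with
# the same configuration is byte-identical.

default_config <- function() {
  list(ani_threshold = 95, inflation = 2, expansion = 2L,
       binary_edges = FALSE,
       soft_core_fraction = 0.90, shell_fraction = 0.15,
       permutations = 200L, seed = 1L,
       aggregate_fraction = 0.90,
       max_omega = 5, max_ds = 10,
       log2_threshold = 1, alpha = 0.05,
       outgroup = "OUT", min_cluster_genomes = 3L)
}

#' Run the complete pipeline on a directory of inputs
#'
#' Executes all stages in dependency order on the file dialects the readers
#' understand, writing one TSV/JSON per stage plus a manifest that records
#' every threshold, seed, engine choice, per-stage record count and filter
#' tally. Any missing input aborts with the input named. No timestamps are
#' written, so identical configurations produce byte-identical outputs.
#'
#' @param config named list, or path to a YAML file with the same keys:
#'   `ani`, `counts`, `tree`, `annotations`, `alignments_dir`, `cds_dir`,
#'   `out_dir` (paths), plus any of the tuning keys of the stage functions
#'   (`ani_threshold`, `inflation`, `soft_core_fraction`, `shell_fraction`,
#'   `permutations`, `seed`, `aggregate_fraction`, `max_omega`, `max_ds`,
#'   `log2_threshold`, `alpha`, `outgroup`, `min_cluster_genomes`). Unknown
#'   keys are rejected.
#' @return invisibly, the manifest list (also written to `manifest.json`).
#' @export
run_all <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  defaults <- default_config()
  path_keys <- c("ani", "counts", "tree", "annotations", "alignments_dir",
                 "cds_dir", "out_dir")
  unknown <- setdiff(names(config), c(path_keys, names(defaults)))
  if (length(unknown))
    stop_format("unknown config keys: %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  for (key in path_keys) {
    if (is.null(cfg[[key]]))
      stop_format("missing required config key '%s'", key)
    if (key != "out_dir" && !file.exists(cfg[[key]]))
      stop_format("input for '%s' not found: %s", key, cfg[[key]])
  }
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "pangevo",
                   engines = list(dnds = "NG86+JC", clustering = "MCL",
                                  reconstruction = "Wagner parsimony",
                                  tie_breaks = list(root = "absence",
                                                    traceback = "parent")),
                   config = cfg[order(names(cfg))], stages = list())

  # stage 1: species clusters
  pairs <- read_ani_pairs(cfg$ani)
  graph <- build_ani_graph(pairs, threshold = cfg$ani_threshold)
  clustering <- mcl(graph, inflation = cfg$inflation,
                    expansion = cfg$expansion,
                    binary_edges = cfg$binary_edges)
  members <- clustering$membership
  write_tsv_fixed(data.frame(genome = names(members),
                             cluster = unname(members),
                             stringsAsFactors = FALSE),
                  file.path(out, "clusters.tsv"))
  manifest$stages$cluster <- list(
    genomes = length(members), clusters = length(clustering$clusters),
    converged = clustering$converged, iterations = clustering$iterations)

  # stage 2: pangenome per sufficiently large cluster
  counts <- read_gene_counts(cfg$counts)
  missing_genomes <- setdiff(colnames(counts), names(members))
  if (length(missing_genomes))
    stop_format("genomes in counts but not in ANI table: %s",
                paste(missing_genomes, collapse = ", "))
  annotations <- read_annotations(cfg$annotations)
  pg_stage <- list()
  for (cl in names(clustering$clusters)) {
    gs <- intersect(colnames(counts), clustering$clusters[[cl]])
    if (length(gs) < cfg$min_cluster_genomes) next
    sub <- counts[, gs, drop = FALSE]
    part <- pangenome_partition(sub,
                                soft_core_fraction = cfg$soft_core_fraction,
                                shell_fraction = cfg$shell_fraction)
    curve <- accumulation_curve(sub, n_permutations = cfg$permutations,
                                seed = cfg$seed)
    fit <- fit_power_law(curve)
    enr <- cog_enrichment(part, annotations)
    write_tsv_fixed(data.frame(orthogroup = names(part$classes),
                               class = as.character(part$classes),
                               stringsAsFactors = FALSE),
                    file.path(out, sprintf("pangenome_%s_partition.tsv", cl)))
    write_tsv_fixed(data.frame(genomes = curve$x, mean_size = curve$y_mean),
                    file.path(out, sprintf("pangenome_%s_curve.tsv", cl)))
    jsonlite::write_json(list(a = fit$a, gamma = fit$gamma,
                              residual_norm = fit$residual_norm,
                              open = fit$open),
                         file.path(out, sprintf("pangenome_%s_fit.json", cl)),
                         auto_unbox = TRUE, digits = NA)
    write_tsv_fixed(enr, file.path(out, sprintf("pangenome_%s_enrichment.tsv", cl)))
    pg_stage[[cl]] <- list(genomes = length(gs),
                           orthogroups = length(part$classes),
                           counts = as.list(as.integer(part$counts)),
                           gamma = fit$gamma)
  }
  manifest$stages$pangenome <- pg_stage

  # stage 3: gain/loss on the species tree
  tree <- read_tree(cfg$tree)
  missing_leaves <- setdiff(tree$tip.label, names(clustering$clusters))
  if (length(missing_leaves))
    stop_format("tree leaves with no matching cluster: %s",
                paste(missing_leaves, collapse = ", "))
  sp_mat <- vapply(tree$tip.label, function(cl) {
    gs <- intersect(colnames(counts), clustering$clusters[[cl]])
    if (length(gs) == 1L) as.integer(counts[, gs] > 0)
    else as.integer(rowMeans(counts[, gs, drop = FALSE] > 0) >=
                    cfg$aggregate_fraction)
  }, integer(nrow(counts)))
  rownames(sp_mat) <- rownames(counts)
  rec <- wagner_reconstruct(tree, binarize(sp_mat))
  write_tsv_fixed(rec$events, file.path(out, "gainloss_nodes.tsv"))
  manifest$stages$gainloss <- list(
    families = nrow(sp_mat), nodes = nrow(rec$events),
    total_cost = sum(rec$total_cost),
    root_present = rec$events$present[rec$events$node ==
                                      tree$node.label[1L]])

  # stage 4: Tajima's D per orthogroup per cluster
  taj_files <- sort(list.files(cfg$alignments_dir, pattern = "\\.fasta$",
                               full.names = TRUE))
  if (length(taj_files) == 0L)
    stop_format("no FASTA alignments found in '%s'", cfg$alignments_dir)
  taj <- tajima_scan(stats::setNames(taj_files,
                                     sub("\\.fasta$", "", basename(taj_files))))
  write_tsv_fixed(taj, file.path(out, "tajima.tsv"))
  defined <- taj[taj$defined, , drop = FALSE]
  cls <- sort(unique(defined$cluster))
  cmp_rows <- list()
  if (length(cls) >= 2L) {
    for (i in seq_along(cls)) for (j in seq_along(cls)) {
      if (i >= j) next
      da <- defined$D[defined$cluster == cls[i]]
      db <- defined$D[defined$cluster == cls[j]]
      if (length(da) == 0L || length(db) == 0L) next
      cmp <- compare_groups(da, db)
      cmp_rows[[length(cmp_rows) + 1L]] <- data.frame(
        cluster_a = cls[i], cluster_b = cls[j], n_a = cmp$n1, n_b = cmp$n2,
        U = cmp$U, p = cmp$p, cles = cmp$cles,
        median_a = cmp$median_a, median_b = cmp$median_b,
        stringsAsFactors = FALSE)
    }
  }
  cmp_df <- if (length(cmp_rows)) do.call(rbind, cmp_rows) else
    data.frame(cluster_a = character(), cluster_b = character(),
               n_a = integer(), n_b = integer(), U = numeric(),
               p = numeric(), cles = numeric(), median_a = numeric(),
               median_b = numeric())
  write_tsv_fixed(cmp_df, file.path(out, "tajima_comparisons.tsv"))
  manifest$stages$tajima <- list(orthogroups = length(unique(taj$orthogroup)),
                                 records = nrow(taj),
                                 defined = sum(taj$defined),
                                 comparisons = nrow(cmp_df))

  # stage 5+6: pairwise dN/dS against the outgroup, filters, screen
  cds_files <- sort(list.files(cfg$cds_dir, pattern = "\\.fasta$",
                               full.names = TRUE))
  if (length(cds_files) == 0L)
    stop_format("no codon alignments found in '%s'", cfg$cds_dir)
  all_records <- list(); screen_rows <- list()
  tally_total <- NULL
  for (f in cds_files) {
    og <- sub("\\.fasta$", "", basename(f))
    aln <- read_alignment(f, codon = TRUE)
    recs <- selection_pairs(aln, outgroup = cfg$outgroup, orthogroup = og)
    filt <- apply_filters(recs, max_omega = cfg$max_omega,
                          max_ds = cfg$max_ds, cross_cluster_only = TRUE)
    all_records[[og]] <- recs
    tally_total <- if (is.null(tally_total)) filt$tally
                   else tally_total + filt$tally
    kept <- filt$records
    in_cls <- sort(unique(kept$cluster1))
    for (i in seq_along(in_cls)) for (j in seq_along(in_cls)) {
      if (i >= j) next
      oa <- kept$omega[kept$cluster1 == in_cls[i]]
      ob <- kept$omega[kept$cluster1 == in_cls[j]]
      if (length(oa) == 0L || length(ob) == 0L) next
      screen_rows[[length(screen_rows) + 1L]] <- selection_screen(
        oa, ob, cluster_a = in_cls[i], cluster_b = in_cls[j],
        orthogroup = og, log2_threshold = cfg$log2_threshold,
        alpha = cfg$alpha)
    }
  }
  pair_df <- do.call(rbind, all_records)
  rownames(pair_df) <- NULL
  write_tsv_fixed(pair_df, file.path(out, "dnds_pairs.tsv"))
  screen_df <- if (length(screen_rows)) do.call(rbind, screen_rows) else
    data.frame()
  write_tsv_fixed(screen_df, file.path(out, "screen.tsv"))
  manifest$stages$dnds <- list(orthogroups = length(cds_files),
                               records = nrow(pair_df),
                               filter_tally = as.list(tally_total))
  manifest$stages$screen <- list(comparisons = nrow(screen_df),
                                 flagged = if (nrow(screen_df))
                                   sum(screen_df$flag != "ns") else 0L)

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
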