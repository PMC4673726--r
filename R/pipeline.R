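#' Run the full FEM analysis on a cohort
#'
#' Orchestrates all stages — gene-level statistics, module discovery,
#' deviation scoring and coordination testing, integrative subtype
#' centroids, and (when a copy-number statistic is present) the
#' shortest-path contrast — and writes every result table plus a JSON run
#' manifest to `out_dir`. Re-running with the same inputs, configuration and
#' seed reproduces the outputs exactly.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()], or a list
#'   with the same elements (`beta`, `annotation`, `expression`,
#'   `phenotype`, `network`, optional `cnv_stats`) built from files read via
#'   [read_matrix_tsv()] and friends.
#' @param out_dir Output directory for the run (created if needed); `NULL`
#'   skips writing.
#' @param n_seeds,max_size,tau,n_perm,overlap_threshold Module search
#'   parameters, see [find_fem_modules()].
#' @param sig_threshold Gene eligibility threshold for deviation scoring.
#' @param p_threshold Per-sample deviation threshold for the binary matrix.
#' @param k Number of integrative clusters.
#' @param n_top Genes per list in the shortest-path contrast.
#' @param expression_is_raw Preprocess the expression matrix (zero
#'   substitution, log2, quantile normalization) before analysis.
#' @param seed Master RNG seed for all stochastic stages.
#' @return List with `stats` (per-type gene statistics), `network`,
#'   `modules`, `module_table`, `deviation` (Z matrices, alpha, scores,
#'   binary matrices, coordination tests), `centroids` (partition,
#'   centroids, training classification, ARI vs subtype when available),
#'   `distances` (when CNV supplied), and `manifest`.
#' @export
run_fem_pipeline <- function(cohort, out_dir = NULL,
                             n_seeds = 10, max_size = 100, tau = 0.5,
                             n_perm = 1000, overlap_threshold = 0.5,
                             sig_threshold = 0.05, p_threshold = 0.1,
                             k = 2, n_top = 100,
                             expression_is_raw = FALSE, seed = NULL) {
  phen <- check_phenotype(cohort$phenotype)
  if (is.null(seed)) seed <- 1L  # deterministic default, recorded in manifest
  seeds <- child_seeds(seed, 6)

  ## stage 1: gene-level statistics -------------------------------------
  expr <- cohort$expression
  if (expression_is_raw) expr <- preprocess_expression(expr)
  beta <- cohort$beta
  if (anyNA(beta)) beta <- filter_and_impute(beta)
  dnam <- summarize_gene_methylation(beta, cohort$annotation)
  stats_D <- moderated_t(dnam, phen)
  stats_R <- moderated_t(expr, phen)
  stats_Rs <- scale_statistics(stats_D, stats_R)

  ## stage 2: module discovery ------------------------------------------
  net <- build_weighted_network(stats_D, stats_Rs, cohort$network)
  modules <- find_fem_modules(net, n_seeds = n_seeds, max_size = max_size,
                              tau = tau, n_perm = n_perm,
                              overlap_threshold = overlap_threshold,
                              seed = seeds[[1]])
  mod_tab <- module_table(modules)

  ## stage 3: deviation scores and coordination -------------------------
  common_samples <- intersect(colnames(dnam), colnames(expr))
  tum <- intersect(common_samples, phen$sample_id[phen$group == "tumour"])
  ref_D <- fit_normal_reference(dnam[, common_samples, drop = FALSE], phen)
  ref_R <- fit_normal_reference(expr[, common_samples, drop = FALSE], phen)
  Z_D <- z_statistics(dnam[, tum, drop = FALSE], ref_D)
  Z_R <- z_statistics(expr[, tum, drop = FALSE], ref_R)
  shared_genes <- intersect(rownames(Z_D), rownames(Z_R))
  Z_D <- Z_D[shared_genes, , drop = FALSE]
  Z_R <- Z_R[shared_genes, , drop = FALSE]
  alpha <- scaling_factor(Z_D, Z_R)
  coord_seeds <- child_seeds(seeds[[2]], max(1L, length(modules)))
  scores <- list(); binmats <- list(); coord <- list()
  for (i in seq_along(modules)) {
    m <- modules[[i]]
    sc <- suppressWarnings(
      fem_score(m, stats_D, stats_Rs, Z_D, Z_R, alpha, sig_threshold))
    if (is.null(sc)) next
    bm <- binary_deviation_matrix(m, Z_D, Z_R, stats_D, stats_Rs,
                                  p_threshold, sig_threshold)
    scores[[m$seed]] <- sc
    binmats[[m$seed]] <- bm
    coord[[m$seed]] <- if (!is.null(bm) && nrow(bm) >= 2L)
      coordination_test(bm, n_perm = n_perm, seed = coord_seeds[[i]])
  }
  score_mat <- if (length(scores)) do.call(rbind, scores) else NULL

  ## stage 4: integrative subtype centroids -----------------------------
  elig_all <- unique(unlist(lapply(modules, eligible_genes, stats_D,
                                   stats_Rs, sig_threshold)))
  elig_all <- intersect(elig_all, shared_genes)
  centroid_res <- NULL
  if (length(elig_all) >= 3L && length(tum) >= k) {
    d_sub <- dnam[elig_all, tum, drop = FALSE]
    r_sub <- expr[elig_all, tum, drop = FALSE]
    part <- joint_cluster_standin(d_sub, r_sub, k = k, seed = seeds[[3]])
    cents <- build_centroids(d_sub, r_sub, part, elig_all)
    train_call <- classify_nearest_centroid(d_sub, cents, "dnam")
    ari_subtype <- NA_real_
    sub_lab <- setNames(phen$subtype, phen$sample_id)[tum]
    if (length(unique(sub_lab)) > 1L)
      ari_subtype <- adjusted_rand_index(part, sub_lab)
    centroid_res <- list(partition = part, centroids = cents,
                         training_labels = train_call,
                         ari_vs_subtype = ari_subtype,
                         genes = elig_all)
  }

  ## stage 5: shortest-path contrast (optional) -------------------------
  dist_res <- NULL
  if (!is.null(cohort$cnv_stats)) {
    n_top <- min(n_top, igraph::vcount(cohort$network))
    dm_top <- top_ranked(setNames(stats_D$t, stats_D$gene), n_top,
                         cohort$network)
    cnv_top <- top_ranked(cohort$cnv_stats, n_top, cohort$network)
    d_dm <- pairwise_shortest_paths(dm_top, cohort$network)
    d_cnv <- pairwise_shortest_paths(cnv_top, cohort$network)
    cmp <- compare_distance_sets(d_dm, d_cnv)
    dist_res <- list(dnam = d_dm, cnv = d_cnv, comparison = cmp)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("femnet")),
    seed = seed,
    config = list(n_seeds = n_seeds, max_size = max_size, tau = tau,
                  n_perm = n_perm, overlap_threshold = overlap_threshold,
                  sig_threshold = sig_threshold, p_threshold = p_threshold,
                  k = k, n_top = n_top),
    counts = list(
      probes = nrow(beta), genes_methylation = nrow(dnam),
      genes_expression = nrow(expr),
      network_genes = igraph::vcount(net),
      modules_found = length(modules),
      modules_scored = length(scores),
      eligible_genes = length(elig_all)))

  res <- list(stats = list(dnam = stats_D, expr = stats_R,
                           expr_scaled = stats_Rs),
              gene_dnam = dnam, gene_expr = expr,
              network = net, modules = modules, module_table = mod_tab,
              deviation = list(Z_D = Z_D, Z_R = Z_R, alpha = alpha,
                               scores = score_mat, binary = binmats,
                               coordination = coord),
              centroids = centroid_res, distances = dist_res,
              manifest = manifest)

  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  invisible(res)
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(res$module_table))
    write_module_table(res$module_table, file.path(out_dir, "modules.tsv"))
  if (!is.null(res$deviation$scores))
    write_matrix_tsv(res$deviation$scores,
                     file.path(out_dir, "fem_scores.tsv"), "module")
  for (nm in names(res$deviation$binary)) {
    bm <- res$deviation$binary[[nm]]
    if (!is.null(bm))
      write_matrix_tsv(bm + 0,
                       file.path(out_dir, paste0("binary_", nm, ".tsv")),
                       "gene")
  }
  cr <- Filter(Negate(is.null), res$deviation$coordination)
  if (length(cr)) {
    df <- data.frame(module = names(cr),
                     observed_mhd = vapply(cr, `[[`, 0, "observed"),
                     null_mean = vapply(cr, `[[`, 0, "null_mean"),
                     p = vapply(cr, `[[`, 0, "p"))
    write.table(df, file.path(out_dir, "coordination.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$centroids)) {
    part <- res$centroids$partition
    write.table(data.frame(sample_id = names(part), cluster = part),
                file.path(out_dir, "partition.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    ce <- res$centroids$centroids
    long <- rbind(
      data.frame(gene = rep(ce$genes, length(ce$clusters)),
                 data_type = "dnam",
                 cluster = rep(ce$clusters, each = length(ce$genes)),
                 value = as.vector(ce$dnam)),
      data.frame(gene = rep(ce$genes, length(ce$clusters)),
                 data_type = "expr",
                 cluster = rep(ce$clusters, each = length(ce$genes)),
                 value = as.vector(ce$expr)))
    write.table(long, file.path(out_dir, "centroids.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$distances)) {
    df <- data.frame(
      source = c("DNAm", "CNV"),
      n_genes = c(res$distances$dnam$n_genes, res$distances$cnv$n_genes),
      mean_distance = c(res$distances$dnam$mean, res$distances$cnv$mean),
      n_pairs = c(res$distances$dnam$n_pairs, res$distances$cnv$n_pairs),
      n_disconnected = c(res$distances$dnam$n_disconnected,
                         res$distances$cnv$n_disconnected))
    write.table(df, file.path(out_dir, "distances.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
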