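#' Specify a synthetic matched cohort
#'
#' Describes a simulated study with normal, luminal-A-like and
#' luminal-B-like samples, probe-level promoter methylation, gene-level
#' expression, an interactome with planted dense modules, and an optional
#' gene-level copy-number statistic. Planted module genes are
#' hypermethylated and underexpressed (or vice versa) in affected tumours,
#' with luminal-B shifts scaled by `lumB_multiplier` to emulate the larger
#' epigenetic deviation of the more proliferative subtype.
#'
#' @param n_normal,n_lumA,n_lumB Samples per group.
#' @param n_genes Number of genes (network nodes).
#' @param probes_per_gene Promoter probes per gene (each gene also gets one
#'   decoy gene-body probe, which the summarizer must ignore).
#' @param network List: `model` (`"smallworld"` or `"scalefree"`), `nei`
#'   (neighbourhood size / attachment edges), `p_rewire` (small-world
#'   rewiring probability).
#' @param modules List of planted modules, each a list with `size`,
#'   `delta_D` (logit-scale methylation shift), `delta_R` (log2-scale
#'   expression shift, opposite sign), `mode` (`"coordinated"`,
#'   `"exclusive"` or `"independent"`), `affected_fraction` in `(0, 1]`.
#' @param module_density Internal edge density of planted modules.
#' @param module_bridges Edges anchoring each planted module to the
#'   background graph.
#' @param lumB_multiplier Multiplier (>= 1) on planted shifts in luminal-B
#'   samples.
#' @param noise_sd_D,noise_sd_R Noise standard deviations (logit scale for
#'   methylation, log2 scale for expression).
#' @param promoter_baseline,body_baseline Baseline beta levels of promoter
#'   and gene-body probes.
#' @param expr_baseline_mean,expr_baseline_sd Log2 expression baseline
#'   distribution across genes.
#' @param n_cnv,cnv_effect Number of genes given a large copy-number
#'   statistic (placed uniformly over the network, i.e. not clustered) and
#'   its magnitude.
#' @param expression_scale `"log2"` (already preprocessed) or `"raw"`
#'   (positive scale with occasional zeros, to exercise
#'   [preprocess_expression()]).
#' @param seed RNG seed; the whole cohort is deterministic given the spec.
#' @return A validated list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_normal = 50, n_lumA = 50, n_lumB = 50,
                        n_genes = 500, probes_per_gene = 3,
                        network = list(model = "smallworld", nei = 4,
                                       p_rewire = 0.1),
                        modules = list(list(size = 15, delta_D = 1,
                                            delta_R = -1,
                                            mode = "coordinated",
                                            affected_fraction = 1)),
                        module_density = 0.8, module_bridges = 3,
                        lumB_multiplier = 2,
                        noise_sd_D = 0.5, noise_sd_R = 1,
                        promoter_baseline = 0.15, body_baseline = 0.7,
                        expr_baseline_mean = 7, expr_baseline_sd = 1,
                        n_cnv = 15, cnv_effect = 3,
                        expression_scale = c("log2", "raw"),
                        seed = NULL) {
  expression_scale <- match.arg(expression_scale)
  spec <- as.list(environment())
  n_tumour <- n_lumA + n_lumB
  stopifnot(n_normal >= 3, n_lumA >= 2, n_lumB >= 0, n_genes >= 10,
            probes_per_gene >= 1, lumB_multiplier >= 1,
            module_density > 0, module_density <= 1,
            network$model %in% c("smallworld", "scalefree"))
  total_planted <- 0
  for (m in spec$modules) {
    stopifnot(m$size >= 2, m$size <= n_genes,
              m$affected_fraction > 0, m$affected_fraction <= 1,
              m$mode %in% c("coordinated", "exclusive", "independent"))
    if (sign(m$delta_D) == sign(m$delta_R) || m$delta_D == 0)
      stop_femnet("planted deltas must be non-zero with opposite signs")
    if (m$mode == "exclusive" &&
        m$size * max(1, round(m$affected_fraction * n_tumour)) > n_tumour)
      stop_femnet("exclusive mode needs size * affected count <= tumours")
    total_planted <- total_planted + m$size
  }
  if (total_planted > n_genes)
    stop_femnet("planted modules exceed the gene count")
  structure(spec, class = "cohort_spec")
}

#' Generate the synthetic interactome with planted modules
#'
#' A connected small-world or scale-free background graph in which each
#' planted module is wired as a dense connected subgraph attached to the
#' background by a small number of bridge edges. Deterministic under the
#' spec's seed.
#'
#' @param spec A [cohort_spec()].
#' @return List with `graph` (igraph, vertex names `G0001`, ...) and
#'   `planted` (list of member vectors, one per planted module).
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, generate_network_impl(spec))
}

generate_network_impl <- function(spec) {
  n <- spec$n_genes
  gnames <- sprintf("G%04d", seq_len(n))
  g <- switch(spec$network$model,
    smallworld = igraph::sample_smallworld(1, n, nei = spec$network$nei,
                                           p = spec$network$p_rewire),
    scalefree = igraph::sample_pa(n, m = spec$network$nei,
                                  directed = FALSE))
  igraph::V(g)$name <- gnames

  pool <- seq_len(n)
  planted <- list()
  effect_D <- list(); effect_R <- list()
  for (ms in spec$modules) {
    mem <- sort(sample(pool, ms$size))
    pool <- setdiff(pool, mem)
    planted[[length(planted) + 1L]] <- gnames[mem]
    # heterogeneous per-gene effect sizes, fixed with the planted wiring so
    # that independent cohorts drawn over this network share the same
    # module biology
    effect_D[[length(effect_D) + 1L]] <- runif(ms$size, 0.6, 1.4)
    effect_R[[length(effect_R) + 1L]] <- runif(ms$size, 0.6, 1.4)
    # detach members from the background, then wire densely
    g <- igraph::delete_edges(g, igraph::E(g)[.inc(mem)])
    pairs <- t(combn(mem, 2))
    keep <- runif(nrow(pairs)) < spec$module_density
    ring <- cbind(mem, mem[c(seq_along(mem)[-1], 1L)])
    g <- igraph::add_edges(g, t(rbind(pairs[keep, , drop = FALSE], ring)))
    bg <- setdiff(seq_len(n), mem)
    for (b in seq_len(spec$module_bridges))
      g <- igraph::add_edges(g, c(sample(mem, 1), sample(bg, 1)))
    g <- igraph::simplify(g)
  }
  # connect any stray components to the largest one
  comp <- igraph::components(g)
  if (comp$no > 1L) {
    main <- which.max(comp$csize)
    anchor <- which(comp$membership == main)[1]
    for (cc in setdiff(seq_len(comp$no), main)) {
      v <- which(comp$membership == cc)[1]
      g <- igraph::add_edges(g, c(anchor, v))
    }
  }
  list(graph = g, planted = planted, effect_D = effect_D,
       effect_R = effect_R)
}

#' Generate a synthetic matched cohort
#'
#' Draws probe-level beta values (logit-normal around region-specific
#' baselines), gene-level expression, a phenotype table, the planted-module
#' interactome, and a gene-level copy-number statistic. Planted module genes
#' are shifted by `delta_D` on the logit-methylation scale and `delta_R` on
#' the log2-expression scale in affected tumours (luminal-B shifts times
#' `lumB_multiplier`); the `mode` of each module controls *which* tumours
#' deviate per gene (a shared sample set, disjoint sets, or independent
#' sets). The `truth` element records everything needed to score recovery.
#'
#' @param spec A [cohort_spec()].
#' @param network Optional [generate_network()] result to reuse a fixed
#'   interactome with its planted wiring — e.g. to draw an independent
#'   validation cohort over the same genes and module structure.
#' @return An object of class `synthetic_cohort`: `beta`, `annotation`,
#'   `expression`, `phenotype`, `network` (igraph), `cnv_stats` (named
#'   vector), `truth` (planted members, affected samples per gene, CNV
#'   genes), `spec`.
#' @export
generate_cohort <- function(spec, network = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(network)) {
    stopifnot(is.list(network), igraph::is_igraph(network$graph),
              igraph::vcount(network$graph) == spec$n_genes,
              length(network$planted) == length(spec$modules))
  }
  with_seed(spec$seed, {
    net <- if (is.null(network)) generate_network_impl(spec) else network
    n <- spec$n_genes
    genes <- igraph::V(net$graph)$name

    samples <- c(sprintf("N%03d", seq_len(spec$n_normal)),
                 sprintf("A%03d", seq_len(spec$n_lumA)),
                 if (spec$n_lumB > 0) sprintf("B%03d", seq_len(spec$n_lumB)))
    group <- c(rep("normal", spec$n_normal),
               rep("tumour", spec$n_lumA + spec$n_lumB))
    subtype <- c(rep("none", spec$n_normal), rep("lumA", spec$n_lumA),
                 rep("lumB", spec$n_lumB))
    phen <- data.frame(sample_id = samples, group = group,
                       subtype = subtype, stringsAsFactors = FALSE)
    tumours <- samples[group == "tumour"]
    n_tum <- length(tumours)
    mult <- setNames(rep(0, length(samples)), samples)
    mult[subtype == "lumA"] <- 1
    mult[subtype == "lumB"] <- spec$lumB_multiplier

    # per-gene planted shifts and affected tumour sets
    delta_D <- setNames(rep(0, n), genes)
    delta_R <- setNames(rep(0, n), genes)
    affected <- list()
    for (mi in seq_along(spec$modules)) {
      ms <- spec$modules[[mi]]
      mem <- net$planted[[mi]]
      delta_D[mem] <- ms$delta_D * net$effect_D[[mi]]
      delta_R[mem] <- ms$delta_R * net$effect_R[[mi]]
      cnt <- max(1L, round(ms$affected_fraction * n_tum))
      sets <- switch(ms$mode,
        coordinated = {
          shared <- sample(tumours, cnt)
          rep(list(shared), length(mem))
        },
        exclusive = {
          pick <- sample(tumours, cnt * length(mem))
          split(pick, rep(seq_along(mem), each = cnt))
        },
        independent = lapply(mem, function(g) sample(tumours, cnt)))
      names(sets) <- mem
      affected <- c(affected, sets)
    }

    # affected indicator, genes x samples
    aff <- matrix(0, n, length(samples), dimnames = list(genes, samples))
    for (g in names(affected)) aff[g, affected[[g]]] <- 1
    shift_mat_D <- (delta_D * aff) * rep(mult, each = n)
    shift_mat_R <- (delta_R * aff) * rep(mult, each = n)

    # methylation: promoter probes per gene plus one decoy body probe
    base_logit <- qlogis(spec$promoter_baseline) + rnorm(n, 0, 0.3)
    body_logit <- qlogis(spec$body_baseline) + rnorm(n, 0, 0.3)
    region_choice <- sample(c("TSS200", "FirstExon", "TSS1500"), n,
                            replace = TRUE, prob = c(0.7, 0.2, 0.1))
    npp <- spec$probes_per_gene
    probe_gene <- rep(seq_len(n), each = npp)
    probe_ids <- sprintf("cg%06d", seq_len(n * npp))
    offsets <- rnorm(n * npp, 0, 0.2)
    L <- matrix(base_logit[probe_gene] + offsets, n * npp, length(samples)) +
      matrix(rnorm(n * npp * length(samples), 0, spec$noise_sd_D),
             n * npp) +
      shift_mat_D[probe_gene, , drop = FALSE]
    body_ids <- sprintf("cg9%05d", seq_len(n))
    Lb <- matrix(body_logit, n, length(samples)) +
      matrix(rnorm(n * length(samples), 0, spec$noise_sd_D), n)
    beta <- plogis(rbind(L, Lb))
    rownames(beta) <- c(probe_ids, body_ids)
    colnames(beta) <- samples
    annot <- data.frame(
      probe_id = c(probe_ids, body_ids),
      gene = c(genes[probe_gene], genes),
      region = c(region_choice[probe_gene], rep("Body", n)),
      stringsAsFactors = FALSE)

    # expression on the log2 scale
    b_g <- rnorm(n, spec$expr_baseline_mean, spec$expr_baseline_sd)
    X <- matrix(b_g, n, length(samples)) +
      matrix(rnorm(n * length(samples), 0, spec$noise_sd_R), n) +
      shift_mat_R
    dimnames(X) <- list(genes, samples)
    if (spec$expression_scale == "raw") {
      X <- 2^X
      zero_idx <- sample(length(X), max(1L, round(0.005 * length(X))))
      X[zero_idx] <- 0
    }

    # copy-number statistic: large effects placed uniformly (not clustered)
    cnv <- setNames(rnorm(n), genes)
    cnv_genes <- sample(genes, min(spec$n_cnv, n))
    cnv[cnv_genes] <- sample(c(-1, 1), length(cnv_genes), replace = TRUE) *
      spec$cnv_effect + rnorm(length(cnv_genes))

    structure(list(beta = beta, annotation = annot, expression = X,
                   phenotype = phen, network = net$graph,
                   cnv_stats = cnv,
                   truth = list(modules = net$planted, affected = affected,
                                cnv_genes = cnv_genes),
                   spec = spec),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(paste0("Synthetic cohort: %d probes x %d samples, %d genes, ",
                     "%d planted module(s)\n"),
              nrow(x$beta), ncol(x$beta), nrow(x$expression),
              length(x$truth$modules)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Emits the TSV dialects consumed by the analysis functions (beta matrix,
#' probe annotation, expression matrix, phenotype, PPI edge list, CNV
#' statistics) plus a JSON truth record.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(cohort$beta, file.path(dir, "beta.tsv"), "probe_id")
  write_matrix_tsv(cohort$expression, file.path(dir, "expression.tsv"),
                   "gene")
  write.table(cohort$annotation, file.path(dir, "annotation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$phenotype, file.path(dir, "phenotype.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  el <- igraph::as_edgelist(cohort$network)
  write.table(data.frame(gene1 = el[, 1], gene2 = el[, 2]),
              file.path(dir, "ppi.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(gene = names(cohort$cnv_stats),
                         statistic = unname(cohort$cnv_stats)),
              file.path(dir, "cnv.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                       auto_unbox = FALSE)
  invisible(dir)
}
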