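#' Fit a normal-tissue reference for one data type
#'
#' Per-gene mean and standard deviation estimated over the samples labeled
#' `normal` only. Genes with zero standard deviation are floored at the
#' smallest positive standard deviation observed and flagged.
#'
#' @param x Genes x samples matrix (one data type, gene level).
#' @param phen Phenotype table covering the columns of `x`.
#' @return List with `mu`, `sigma` (named vectors) and `flagged` (gene
#'   symbols whose sigma was floored).
#' @export
fit_normal_reference <- function(x, phen) {
  check_matrix(x)
  phen <- check_phenotype(phen)
  normals <- intersect(colnames(x), phen$sample_id[phen$group == "normal"])
  if (length(normals) < 3L) stop_femnet("need >= 3 normal samples")
  xn <- x[, normals, drop = FALSE]
  mu <- rowMeans(xn)
  sigma <- apply(xn, 1L, sd)
  flagged <- names(sigma)[sigma == 0]
  if (length(flagged)) {
    if (all(sigma == 0)) stop_femnet("all genes have zero normal variance")
    sigma[sigma == 0] <- min(sigma[sigma > 0])
  }
  list(mu = mu, sigma = sigma, flagged = flagged)
}

#' Per-sample Z-statistics against the normal reference
#'
#' `Z_gs = (X_gs - mu_g) / sigma_g` elementwise. Genes absent from the
#' reference are dropped with a warning.
#'
#' @param x Genes x samples matrix.
#' @param ref Reference from [fit_normal_reference()].
#' @return Z matrix over the covered genes.
#' @export
z_statistics <- function(x, ref) {
  check_matrix(x)
  covered <- intersect(rownames(x), names(ref$mu))
  if (length(covered) < nrow(x))
    warning(nrow(x) - length(covered), " genes lack a reference; dropped")
  if (!length(covered)) stop_femnet("no genes covered by the reference")
  x <- x[covered, , drop = FALSE]
  (x - ref$mu[covered]) / ref$sigma[covered]
}

#' Data-type scaling factor for deviation scores
#'
#' `alpha = sd(Z_D) / sd(Z_R)` over all entries of the two Z matrices (all
#' genes, not only module genes, and all scored samples), making the two data
#' types comparable inside the deviation score.
#'
#' @param Z_D,Z_R Z-statistic matrices from [z_statistics()].
#' @return Positive scalar `alpha`.
#' @export
scaling_factor <- function(Z_D, Z_R) {
  s_d <- sd(as.vector(Z_D))
  s_r <- sd(as.vector(Z_R))
  if (!is.finite(s_r) || s_r == 0) stop_femnet("sd of Z_R is zero")
  s_d / s_r
}

#' Genes driving a module's significance
#'
#' The module genes significant at both the differential DNAm and the
#' differential expression level and whose statistics are anti-correlated
#' (strictly opposite signs): hypermethylated-and-underexpressed or
#' hypomethylated-and-overexpressed.
#'
#' @param module A [fem_module] or character vector of genes.
#' @param stats_D,stats_R Gene statistics of the discovery cohort.
#' @param sig_threshold Significance threshold on both P values
#'   (default 0.05).
#' @return Character vector of eligible genes (possibly empty).
#' @export
eligible_genes <- function(module, stats_D, stats_R, sig_threshold = 0.05) {
  members <- if (inherits(module, "fem_module")) module$members else module
  shared <- Reduce(intersect, list(members, stats_D$gene, stats_R$gene))
  td <- stats_D$t[match(shared, stats_D$gene)]
  pd <- stats_D$p[match(shared, stats_D$gene)]
  tr <- stats_R$t[match(shared, stats_R$gene)]
  pr <- stats_R$p[match(shared, stats_R$gene)]
  keep <- pd < sig_threshold & pr < sig_threshold &
    ((td > 0 & tr < 0) | (td < 0 & tr > 0))
  shared[keep]
}

#' Per-sample FEM deviation score
#'
#' For the module's eligible genes (see [eligible_genes()]),
#' `score_s = mean_g |Z_D(g, s) - alpha * Z_R(g, s)|`: the average absolute
#' mismatch between a sample's methylation deviation and its (scaled)
#' expression deviation from normal tissue.
#'
#' @param module A [fem_module] or gene vector.
#' @param stats_D,stats_R Gene statistics defining eligibility.
#' @param Z_D,Z_R Z matrices over a common sample set.
#' @param alpha Scaling factor from [scaling_factor()].
#' @param sig_threshold Eligibility threshold (default 0.05).
#' @return Named non-negative score vector over samples, or `NULL` (with a
#'   warning) when no gene is eligible.
#' @export
fem_score <- function(module, stats_D, stats_R, Z_D, Z_R, alpha,
                      sig_threshold = 0.05) {
  stopifnot(identical(colnames(Z_D), colnames(Z_R)))
  elig <- eligible_genes(module, stats_D, stats_R, sig_threshold)
  elig <- Reduce(intersect, list(elig, rownames(Z_D), rownames(Z_R)))
  if (!length(elig)) {
    warning("no eligible genes; module skipped")
    return(NULL)
  }
  diffs <- abs(Z_D[elig, , drop = FALSE] - alpha * Z_R[elig, , drop = FALSE])
  colMeans(diffs)
}

#' Binary deviation matrix of a module
#'
#' Entry `(g, s)` is 1 when both two-sided Gaussian P values of the sample's
#' Z deviations are below `p_threshold` *and* the deviation directions match
#' the gene's population-level anti-correlative pattern (the signs of its
#' cohort t-statistics); otherwise 0. Rows are the module's eligible genes.
#'
#' @param module A [fem_module] or gene vector.
#' @param Z_D,Z_R Z matrices over tumour samples.
#' @param stats_D,stats_R Gene statistics (direction reference and
#'   eligibility).
#' @param p_threshold Per-sample deviation threshold (default 0.1).
#' @param sig_threshold Gene eligibility threshold (default 0.05).
#' @return Binary matrix, eligible genes x samples.
#' @export
binary_deviation_matrix <- function(module, Z_D, Z_R, stats_D, stats_R,
                                    p_threshold = 0.1, sig_threshold = 0.05) {
  stopifnot(p_threshold > 0, p_threshold < 1,
            identical(colnames(Z_D), colnames(Z_R)))
  elig <- eligible_genes(module, stats_D, stats_R, sig_threshold)
  elig <- Reduce(intersect, list(elig, rownames(Z_D), rownames(Z_R)))
  if (!length(elig)) {
    warning("no eligible genes; module skipped")
    return(NULL)
  }
  zd <- Z_D[elig, , drop = FALSE]
  zr <- Z_R[elig, , drop = FALSE]
  pd <- 2 * pnorm(-abs(zd))
  pr <- 2 * pnorm(-abs(zr))
  sd_ref <- sign(stats_D$t[match(elig, stats_D$gene)])
  sr_ref <- sign(stats_R$t[match(elig, stats_R$gene)])
  dir_ok <- (sign(zd) == sd_ref) & (sign(zr) == sr_ref)
  out <- (pd < p_threshold) & (pr < p_threshold) & dir_ok
  storage.mode(out) <- "integer"
  out
}

#' Mean Manhattan distance between binary matrix rows
#'
#' Mean over all unordered row pairs of the Hamming distance
#' `sum_s |a_s - b_s|`. Small values mean different genes flag the same
#' samples (coordination).
#'
#' @param binmat Binary genes x samples matrix with >= 2 rows.
#' @return Mean pairwise Manhattan distance.
#' @export
mean_manhattan <- function(binmat) {
  if (is.null(binmat) || nrow(binmat) < 2L)
    stop_femnet("need >= 2 rows")
  mean(dist(binmat, method = "manhattan"))
}

#' Coordination vs mutual-exclusivity permutation test
#'
#' Compares the observed mean Manhattan distance between the rows of a
#' module's binary deviation matrix to a null distribution obtained by
#' independently permuting the samples within each row (preserving each
#' gene's number of flagged samples exactly). Coordinated deviation makes
#' rows agree on which samples deviate, giving a *smaller* distance than the
#' null, so the default alternative is lower-tail; `"exclusive"` tests the
#' upper tail (disjoint flagged samples).
#'
#' @param binmat Binary genes x samples matrix.
#' @param n_perm Number of within-row permutations (>= 100).
#' @param seed Optional RNG seed.
#' @param alternative `"coordinated"` (lower tail, default) or
#'   `"exclusive"` (upper tail).
#' @return List with `p`, `observed`, `null_mean`, `alternative`, and
#'   `degenerate` (`TRUE` when every row is constant, in which case `p = 1`).
#' @export
coordination_test <- function(binmat, n_perm = 1000, seed = NULL,
                              alternative = c("coordinated", "exclusive")) {
  alternative <- match.arg(alternative)
  stopifnot(n_perm >= 100)
  if (is.null(binmat) || nrow(binmat) < 2L) stop_femnet("need >= 2 rows")
  G <- nrow(binmat); S <- ncol(binmat)
  rs <- rowSums(binmat)
  npairs <- choose(G, 2)
  obs <- mean_manhattan(binmat)
  if (all(rs == 0L | rs == S)) {
    return(list(p = 1, observed = obs, null_mean = obs,
                alternative = alternative, degenerate = TRUE))
  }
  # mean pairwise Manhattan distance via column counts:
  # sum_s k_s (G - k_s) / choose(G, 2), with k_s ones in column s
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      idx <- unlist(lapply(rs, function(r) sample.int(S, r)),
                    use.names = FALSE)
      k <- tabulate(idx, nbins = S)
      sum(k * (G - k)) / npairs
    }, numeric(1))
  })
  cnt <- if (alternative == "coordinated") sum(null <= obs + 1e-12)
         else sum(null >= obs - 1e-12)
  list(p = (1 + cnt) / (1 + n_perm), observed = obs,
       null_mean = mean(null), alternative = alternative,
       degenerate = FALSE)
}
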