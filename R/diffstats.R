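#' Moderated two-group t-statistics (empirical Bayes)
#'
#' Per-gene tumour-vs-normal t-statistics with the gene-wise pooled variance
#' shrunk towards a prior variance. The prior variance and its degrees of
#' freedom are estimated by the method of moments on the log sample
#' variances (matching the classic limma squeeze); the t-statistic uses the
#' posterior variance and augmented degrees of freedom, with two-sided P
#' values. The statistic is oriented as tumour minus normal.
#'
#' Genes whose pooled variance is exactly zero are floored at the smallest
#' positive pooled variance observed and flagged in the `flagged` column.
#'
#' @param x Genes x samples numeric matrix (methylation or expression).
#' @param phen Phenotype table with `sample_id` and `group`
#'   (`normal`/`tumour`) covering the columns of `x`.
#' @param prior_df Optional fixed prior degrees of freedom; `0` gives the
#'   ordinary pooled two-sample t-statistic, `NULL` (default) estimates it.
#' @return A data.frame with columns `gene`, `t`, `p`, `flagged`; attributes
#'   `prior_df` and `prior_var` record the fitted prior.
#' @export
moderated_t <- function(x, phen, prior_df = NULL) {
  check_matrix(x)
  phen <- check_phenotype(phen)
  phen <- phen[match(colnames(x), phen$sample_id), , drop = FALSE]
  if (anyNA(phen$sample_id))
    stop_femnet("phenotype table does not cover all matrix columns")
  grp <- phen$group
  n1 <- sum(grp == "normal"); n2 <- sum(grp == "tumour")
  if (n1 < 2L || n2 < 2L) stop_femnet("need >= 2 samples per group")
  if (!all(is.finite(x))) stop_femnet("matrix must be finite")

  xn <- x[, grp == "normal", drop = FALSE]
  xt <- x[, grp == "tumour", drop = FALSE]
  m1 <- rowMeans(xn); m2 <- rowMeans(xt)
  v1 <- apply(xn, 1L, var); v2 <- apply(xt, 1L, var)
  df_res <- n1 + n2 - 2
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df_res

  flagged <- s2 <= 0
  if (all(flagged)) stop_femnet("all genes have zero pooled variance")
  if (any(flagged)) s2[flagged] <- min(s2[s2 > 0])

  if (is.null(prior_df)) {
    fit <- fit_f_dist(s2, df_res)
    d0 <- fit$df_prior; s0 <- fit$var_prior
  } else {
    stopifnot(prior_df >= 0)
    d0 <- prior_df
    s0 <- if (prior_df > 0) fit_f_dist(s2, df_res)$var_prior else NA_real_
  }

  if (is.finite(d0) && d0 > 0) {
    var_post <- (d0 * s0 + df_res * s2) / (d0 + df_res)
  } else if (is.infinite(d0)) {
    var_post <- rep(s0, length(s2))
  } else {
    var_post <- s2
  }
  df_total <- min(df_res + d0, length(s2) * df_res)
  tstat <- (m2 - m1) / sqrt(var_post * (1 / n1 + 1 / n2))
  pval <- 2 * pt(-abs(tstat), df = df_total)

  out <- data.frame(gene = rownames(x), t = unname(tstat), p = unname(pval),
                    flagged = unname(flagged), stringsAsFactors = FALSE)
  attr(out, "prior_df") <- d0
  attr(out, "prior_var") <- s0
  attr(out, "df_total") <- df_total
  out
}

# Method-of-moments fit of a scaled F prior to sample variances on the log
# scale: E[log s^2] and Var[log s^2] identify the prior df and scale through
# the digamma/trigamma moments of log chi-square variables.
fit_f_dist <- function(s2, df) {
  z <- log(s2)
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- var(e) - trigamma(df / 2)
  if (is.finite(evar) && evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s0 <- mean(s2)
  }
  list(df_prior = d0, var_prior = s0)
}

# Newton solve of trigamma(y) = x.
trigamma_inverse <- function(x) {
  stopifnot(length(x) == 1L, is.finite(x), x > 0)
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Rescale mRNA statistics to the variance of the DNAm statistics
#'
#' Multiplies the expression t-statistics by `sd(t_D)/sd(t_R)` computed over
#' the genes present in both statistic vectors, so that both data types
#' contribute on an equal-variance scale to the edge weights.
#'
#' @param stats_D Gene statistics for DNA methylation (from [moderated_t()]).
#' @param stats_R Gene statistics for expression.
#' @return `stats_R` with rescaled `t`; attribute `scale_factor` records the
#'   multiplier.
#' @export
scale_statistics <- function(stats_D, stats_R) {
  stats_D <- check_gene_stats(stats_D, "stats_D")
  stats_R <- check_gene_stats(stats_R, "stats_R")
  common <- intersect(stats_D$gene, stats_R$gene)
  if (length(common) < 2L) stop_femnet("need >= 2 common genes to scale")
  sd_d <- sd(stats_D$t[match(common, stats_D$gene)])
  sd_r <- sd(stats_R$t[match(common, stats_R$gene)])
  if (sd_r == 0) stop_femnet("sd of expression statistics is zero")
  fac <- sd_d / sd_r
  stats_R$t <- stats_R$t * fac
  attr(stats_R, "scale_factor") <- fac
  stats_R
}
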