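#' Preprocess a raw expression matrix
#'
#' Replaces zero counts by the global minimum positive value, applies a log2
#' transform, and quantile-normalizes columns so that every sample shares the
#' identical sorted value multiset.
#'
#' @param raw Non-negative numeric genes x samples matrix.
#' @param log2_transform Apply log2 after zero substitution (default `TRUE`;
#'   set `FALSE` for data already on log scale).
#' @return Preprocessed matrix of the same dimensions.
#' @export
preprocess_expression <- function(raw, log2_transform = TRUE) {
  check_matrix(raw)
  if (anyNA(raw)) stop_femnet("expression matrix must not contain NA")
  if (any(raw < 0)) stop_femnet("expression matrix must be non-negative")
  pos <- raw[raw > 0]
  if (!length(pos)) stop_femnet("expression matrix is all zero")
  raw[raw == 0] <- min(pos)
  if (log2_transform) raw <- log2(raw)
  quantile_normalize(raw)
}

#' Quantile-normalize matrix columns
#'
#' After normalization every column carries the same sorted values (the
#' per-rank row means of the input); ties share the average of their tied-rank
#' reference values.
#'
#' @param x Numeric matrix.
#' @return Quantile-normalized matrix.
#' @export
quantile_normalize <- function(x) {
  check_matrix(x)
  out <- limma::normalizeQuantiles(x, ties = TRUE)
  dimnames(out) <- dimnames(x)
  out
}

#' Filter high-missingness probes and impute the rest
#'
#' Probes missing in strictly more than `max_missing_frac` of samples are
#' removed; remaining missing entries are filled by averaging the `k`
#' nearest probes (Euclidean distance over shared non-missing samples) that
#' carry a value in the affected sample.
#'
#' @param beta Probes x samples beta-value matrix in `[0, 1]`, `NA` allowed.
#' @param max_missing_frac Maximum tolerated missing fraction per probe,
#'   in `(0, 1]`.
#' @param k Number of nearest probes used for imputation.
#' @return A complete beta matrix (no `NA`), values in `[0, 1]`.
#' @export
filter_and_impute <- function(beta, max_missing_frac = 0.5, k = 5) {
  check_matrix(beta)
  if (max_missing_frac <= 0 || max_missing_frac > 1)
    stop_femnet("max_missing_frac must be in (0, 1]")
  if (any(!is.na(beta))) {
    rng <- range(beta, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1)
      stop_femnet("beta values must lie in [0, 1]")
  }
  miss_frac <- rowMeans(is.na(beta))
  keep <- miss_frac <= max_missing_frac
  if (!any(keep)) stop_femnet("all probes removed by missingness filter")
  beta <- beta[keep, , drop = FALSE]
  if (!anyNA(beta)) return(beta)
  if (k < 1 || k >= nrow(beta))
    stop_femnet("k must be >= 1 and < number of retained probes")

  bad <- which(rowSums(is.na(beta)) > 0)
  complete_vals <- beta
  for (i in bad) {
    target <- beta[i, ]
    obs <- !is.na(target)
    # distance to every other probe over samples observed in both
    d <- vapply(seq_len(nrow(beta)), function(j) {
      if (j == i) return(Inf)
      other <- beta[j, ]
      shared <- obs & !is.na(other)
      if (!any(shared)) return(Inf)
      sqrt(mean((target[shared] - other[shared])^2))
    }, numeric(1))
    ord <- order(d)
    for (s in which(!obs)) {
      donors <- ord[!is.na(beta[ord, s]) & is.finite(d[ord])]
      if (length(donors)) {
        complete_vals[i, s] <- mean(beta[donors[seq_len(min(k, length(donors)))], s])
      } else {
        # no informative neighbour: fall back to the probe's own mean,
        # then to the sample mean
        fb <- mean(target, na.rm = TRUE)
        if (is.nan(fb)) fb <- mean(beta[, s], na.rm = TRUE)
        complete_vals[i, s] <- fb
      }
    }
  }
  stopifnot(!anyNA(complete_vals))
  complete_vals
}

#' Collapse probe-level methylation to gene level
#'
#' A gene's methylation is the mean beta of its TSS200 probes; genes without
#' TSS200 probes use first-exon probes, then TSS1500 probes. Gene-body probes
#' never contribute, and genes represented only by body probes are absent
#' from the output.
#'
#' @param beta Probes x samples beta matrix (complete).
#' @param annot Probe annotation with columns `probe_id`, `gene`, `region`.
#' @return Genes x samples matrix of promoter methylation.
#' @export
summarize_gene_methylation <- function(beta, annot) {
  check_matrix(beta)
  annot <- validate_probe_annotation(annot)
  annot <- annot[annot$probe_id %in% rownames(beta), , drop = FALSE]
  if (!nrow(annot)) stop_femnet("annotation covers none of the probes")
  priority <- c("TSS200", "FirstExon", "TSS1500")
  annot <- annot[annot$region %in% priority, , drop = FALSE]
  if (!nrow(annot)) stop_femnet("no promoter-region probes in annotation")
  annot$rank <- match(annot$region, priority)
  best <- tapply(annot$rank, annot$gene, min)
  use <- annot[annot$rank == best[annot$gene], , drop = FALSE]
  sub <- beta[use$probe_id, , drop = FALSE]
  num <- rowsum(sub, group = use$gene)
  cnt <- as.vector(table(use$gene)[rownames(num)])
  out <- num / cnt
  out[order(rownames(out)), , drop = FALSE]
}
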