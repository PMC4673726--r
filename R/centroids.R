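#' Joint two-data-type clustering (k-means stand-in)
#'
#' A deliberately simple integrative clustering over matched methylation and
#' expression matrices: each gene row of each data type is standardized, the
#' two matrices are stacked row-wise and samples are clustered by k-means
#' with multiple restarts under a fixed seed. This stands in for latent
#' variable joint-clustering models; any externally produced partition can be
#' supplied to [build_centroids()] instead.
#'
#' @param d_mat,r_mat Genes x samples matrices over the same samples
#'   (matched column names, any order).
#' @param k Number of clusters (>= 2).
#' @param nstart k-means restarts (default 25).
#' @param seed Optional RNG seed.
#' @return Named integer vector: sample -> cluster label in `1..k`.
#' @export
joint_cluster_standin <- function(d_mat, r_mat, k = 2, nstart = 25,
                                  seed = NULL) {
  check_matrix(d_mat); check_matrix(r_mat)
  stopifnot(k >= 2)
  samples <- colnames(d_mat)
  if (!setequal(samples, colnames(r_mat)))
    stop_femnet("matrices must cover the same samples")
  r_mat <- r_mat[, samples, drop = FALSE]
  if (k > length(samples)) stop_femnet("k exceeds number of samples")
  std <- function(m) {
    mu <- rowMeans(m)
    s <- apply(m, 1L, sd)
    s[s == 0] <- 1
    (m - mu) / s
  }
  x <- rbind(std(d_mat), std(r_mat))
  km <- with_seed(seed, kmeans(t(x), centers = k, nstart = nstart))
  setNames(km$cluster, samples)
}

#' Build gene-centred cluster centroids
#'
#' For each data type, every gene is first centred to mean zero across the
#' training samples, then centred values are averaged within each cluster.
#'
#' @param d_mat,r_mat Matched genes x samples matrices.
#' @param partition Named sample -> cluster vector (any labels).
#' @param genes Centroid gene set; must be present in both matrices.
#' @return List of class `cluster_centroids`: `dnam` and `expr` (genes x
#'   clusters matrices), `genes`, `clusters`.
#' @export
build_centroids <- function(d_mat, r_mat, partition, genes) {
  check_matrix(d_mat); check_matrix(r_mat)
  if (!all(genes %in% rownames(d_mat)) || !all(genes %in% rownames(r_mat)))
    stop_femnet("all centroid genes must be present in both matrices")
  samples <- names(partition)
  if (!all(samples %in% colnames(d_mat)) ||
      !all(samples %in% colnames(r_mat)))
    stop_femnet("partition samples missing from matrices")
  labs <- sort(unique(as.character(partition)))
  cent_one <- function(m) {
    m <- m[genes, samples, drop = FALSE]
    m <- m - rowMeans(m)
    out <- vapply(labs, function(l) {
      mem <- samples[as.character(partition) == l]
      if (!length(mem)) stop_femnet("empty cluster: ", l)
      rowMeans(m[, mem, drop = FALSE])
    }, numeric(length(genes)))
    dimnames(out) <- list(genes, labs)
    out
  }
  structure(list(dnam = cent_one(d_mat), expr = cent_one(r_mat),
                 genes = genes, clusters = labs),
            class = "cluster_centroids")
}

#' Nearest-centroid classification by Spearman correlation
#'
#' Genes of the new data set are first centred to mean zero within that set
#' (using that set's own means; disable with `centre = FALSE` when the input
#' is already centred); each sample is then assigned to the centroid with
#' which it has the highest Spearman rank correlation (ties broken by the
#' first cluster label and flagged; constant sample vectors are
#' unclassifiable and returned as `NA`). The classification step proper is
#' exactly invariant to strictly monotone per-sample transformations of its
#' (centred) input, and the centring step absorbs per-gene additive offsets.
#'
#' @param x Genes x samples matrix of one data type.
#' @param centroids A `cluster_centroids` object.
#' @param type Which data type's centroids to use, `"dnam"` or `"expr"`.
#' @param centre Centre genes of `x` to mean zero first (default `TRUE`).
#' @return Named character vector of cluster labels (attribute `flagged`
#'   lists tied or unclassifiable samples).
#' @export
classify_nearest_centroid <- function(x, centroids,
                                      type = c("dnam", "expr"),
                                      centre = TRUE) {
  type <- match.arg(type)
  check_matrix(x)
  cen <- centroids[[type]]
  genes <- intersect(rownames(cen), rownames(x))
  if (length(genes) < 3L)
    stop_femnet("need >= 3 centroid genes present in the sample matrix")
  xs <- x[genes, , drop = FALSE]
  if (centre) xs <- xs - rowMeans(xs)
  cen <- cen[genes, , drop = FALSE]
  flagged <- character(0)
  labels <- vapply(colnames(xs), function(s) {
    v <- xs[, s]
    if (sd(v) == 0) { flagged <<- c(flagged, s); return(NA_character_) }
    r <- apply(cen, 2L, function(cc) cor(v, cc, method = "spearman"))
    best <- which(r == max(r))
    if (length(best) > 1L) flagged <<- c(flagged, s)
    colnames(cen)[best[1]]
  }, character(1))
  attr(labels, "flagged") <- flagged
  labels
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement under the permutation model; 1 for identical
#' partitions (up to relabeling), about 0 for independent ones.
#'
#' @param p1,p2 Named sample -> label vectors over the same samples.
#' @return ARI in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(p1, p2) {
  common <- intersect(names(p1), names(p2))
  if (!length(common)) stop_femnet("partitions share no samples")
  tab <- table(as.character(p1[common]), as.character(p2[common]))
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expected <- a * b / choose(n, 2)
  max_idx <- (a + b) / 2
  if (max_idx == expected) return(if (sum_ij == expected) 1 else 0)
  (sum_ij - expected) / (max_idx - expected)
}
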