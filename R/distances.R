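#' Top-ranked genes by absolute statistic
#'
#' The `n` network genes with the largest `|statistic|`; ties at the cutoff
#' are broken lexicographically by gene symbol.
#'
#' @param stats Named numeric vector of per-gene statistics, or a gene
#'   statistics data.frame (columns `gene`, `t`).
#' @param n Number of genes requested (>= 2).
#' @param net Interactome; ranking is restricted to its nodes.
#' @return data.frame with columns `gene`, `statistic`, in rank order.
#' @export
top_ranked <- function(stats, n, net) {
  stopifnot(n >= 2, igraph::is_igraph(net))
  if (is.data.frame(stats)) stats <- setNames(stats$t, stats$gene)
  stats <- stats[names(stats) %in% igraph::V(net)$name]
  if (!length(stats)) stop_femnet("no statistics on network genes")
  if (n > length(stats)) {
    warning("n exceeds available genes; truncating")
    n <- length(stats)
  }
  ord <- order(-abs(stats), names(stats))[seq_len(n)]
  data.frame(gene = names(stats)[ord], statistic = unname(stats[ord]),
             stringsAsFactors = FALSE)
}

#' All-pairs shortest-path distances within a gene list
#'
#' Unweighted (hop-count) shortest paths on the undirected interactome for
#' every unordered pair of the listed genes. Pairs falling in different
#' components are excluded from the distance multiset and counted
#' separately.
#'
#' @param genes Character vector or a [top_ranked()] data.frame.
#' @param net Interactome.
#' @return List with `distances` (finite pair distances), `mean`,
#'   `n_pairs` (finite pairs), `n_disconnected`, `n_genes` (genes found in
#'   the network).
#' @export
pairwise_shortest_paths <- function(genes, net) {
  if (is.data.frame(genes)) genes <- genes$gene
  genes <- intersect(unique(genes), igraph::V(net)$name)
  if (length(genes) < 2L) stop_femnet("need >= 2 genes in the network")
  d <- igraph::distances(net, v = genes, to = genes, weights = NA)
  up <- d[upper.tri(d)]
  finite <- up[is.finite(up)]
  list(distances = finite,
       mean = if (length(finite)) mean(finite) else NA_real_,
       n_pairs = length(finite),
       n_disconnected = sum(!is.finite(up)),
       n_genes = length(genes))
}

#' Compare two shortest-path distance multisets
#'
#' Difference of means and two-sided Wilcoxon rank-sum P between two distance
#' distributions (e.g. top differentially methylated genes vs top copy-number
#' altered genes). With all pooled values tied the P value is 1.
#'
#' @param d1,d2 Numeric distance multisets (or outputs of
#'   [pairwise_shortest_paths()]).
#' @return List with `mean_diff` (`mean(d1) - mean(d2)`) and `p`.
#' @export
compare_distance_sets <- function(d1, d2) {
  if (is.list(d1)) d1 <- d1$distances
  if (is.list(d2)) d2 <- d2$distances
  if (!length(d1) || !length(d2)) stop_femnet("both multisets must be non-empty")
  md <- mean(d1) - mean(d2)
  pooled <- c(d1, d2)
  p <- if (length(unique(pooled)) == 1L) 1
       else suppressWarnings(wilcox.test(d1, d2, exact = FALSE)$p.value)
  list(mean_diff = md, p = p)
}
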