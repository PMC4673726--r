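#' Anti-correlation gated integrated statistic
#'
#' Combines the differential methylation and differential expression
#' statistics of one gene into
#' `t_I = [H(t_D) H(-t_R) + H(-t_D) H(t_R)] * |t_D - t_R|`,
#' where `H` is the Heaviside step with `H(0) = 0`: only genes whose two
#' statistics have strictly opposite signs carry evidence, so hypermethylated
#' and overexpressed (or hypomethylated and underexpressed) genes contribute
#' nothing.
#'
#' @param t_D Numeric vector of DNAm statistics.
#' @param t_R Numeric vector of (rescaled) expression statistics.
#' @return Non-negative numeric vector `t_I`.
#' @export
integrated_statistic <- function(t_D, t_R) {
  stopifnot(length(t_D) == length(t_R), all(is.finite(t_D)),
            all(is.finite(t_R)))
  gate <- (t_D > 0 & t_R < 0) | (t_D < 0 & t_R > 0)
  as.numeric(gate) * abs(t_D - t_R)
}

#' Weight an interactome with integrated statistics
#'
#' Restricts the network to genes carrying both statistics, assigns each edge
#' the weight `w_gh = (t_I(g) + t_I(h)) / 2`, and keeps the maximally
#' connected component (ties between equally sized components broken by the
#' component containing the lexicographically smallest gene symbol). The
#' per-gene statistics are stored as vertex attributes `tI`, `tD`, `tR`.
#'
#' @param stats_D Gene statistics for DNA methylation.
#' @param stats_R Gene statistics for expression, already rescaled with
#'   [scale_statistics()].
#' @param ppi Undirected simple [igraph::graph] with gene-symbol vertex names.
#' @return A weighted `igraph` object (the module-search substrate).
#' @export
build_weighted_network <- function(stats_D, stats_R, ppi) {
  stats_D <- check_gene_stats(stats_D, "stats_D")
  stats_R <- check_gene_stats(stats_R, "stats_R")
  stopifnot(igraph::is_igraph(ppi))
  genes <- intersect(intersect(stats_D$gene, stats_R$gene),
                     igraph::V(ppi)$name)
  if (!length(genes))
    stop_femnet("no genes shared between statistics and network")
  g <- igraph::induced_subgraph(ppi, genes)
  tD <- stats_D$t[match(igraph::V(g)$name, stats_D$gene)]
  tR <- stats_R$t[match(igraph::V(g)$name, stats_R$gene)]
  tI <- integrated_statistic(tD, tR)
  igraph::V(g)$tD <- tD
  igraph::V(g)$tR <- tR
  igraph::V(g)$tI <- tI
  el <- igraph::as_edgelist(g, names = FALSE)
  igraph::E(g)$weight <- (tI[el[, 1]] + tI[el[, 2]]) / 2

  comp <- igraph::components(g)
  big <- which(comp$csize == max(comp$csize))
  if (length(big) > 1L) {
    # tie: keep the component containing the lexicographically smallest gene
    firsts <- vapply(big, function(cc)
      min(igraph::V(g)$name[comp$membership == cc]), character(1))
    big <- big[order(firsts)[1]]
  }
  igraph::induced_subgraph(g, which(comp$membership == big))
}

#' Select seed genes for module search
#'
#' The `n_seeds` network genes with the largest integrated statistic; ties
#' broken lexicographically by gene symbol.
#'
#' @param net Weighted network from [build_weighted_network()].
#' @param n_seeds Number of seeds requested.
#' @return Character vector of seed gene symbols.
#' @export
select_seeds <- function(net, n_seeds) {
  stopifnot(igraph::is_igraph(net), n_seeds >= 1)
  nm <- igraph::V(net)$name
  ti <- igraph::V(net)$tI
  if (n_seeds > length(nm)) {
    warning("n_seeds exceeds network size; truncating")
    n_seeds <- length(nm)
  }
  nm[order(-ti, nm)][seq_len(n_seeds)]
}
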