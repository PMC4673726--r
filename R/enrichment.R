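#' Gene-set overlap enrichment (hypergeometric test)
#'
#' Upper-tail hypergeometric P value of the overlap between a module's
#' members and each gene set, within a stated gene universe, with
#' Benjamini-Hochberg adjustment across sets.
#'
#' @param members Character vector of module genes (a subset of `universe`).
#' @param gene_sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param universe Character vector: the gene universe (e.g. network genes).
#' @return data.frame with one row per set: `set`, `n_set` (set size within
#'   the universe), `n_overlap`, `p`, `p_adj`, `overlap_genes`
#'   (semicolon-separated).
#' @export
overlap_enrichment <- function(members, gene_sets, universe) {
  if (!length(universe)) stop_femnet("empty universe")
  universe <- unique(universe)
  if (!all(members %in% universe))
    stop_femnet("members must be a subset of the universe")
  members <- unique(members)
  n_u <- length(universe)
  n_m <- length(members)
  rows <- lapply(names(gene_sets), function(nm) {
    set_u <- intersect(gene_sets[[nm]], universe)
    ov <- intersect(members, set_u)
    k <- length(ov)
    p <- phyper(k - 1, length(set_u), n_u - length(set_u), n_m,
                lower.tail = FALSE)
    data.frame(set = nm, n_set = length(set_u), n_overlap = k, p = p,
               overlap_genes = paste(sort(ov), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out[order(out$p), c("set", "n_set", "n_overlap", "p", "p_adj",
                      "overlap_genes")]
}
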