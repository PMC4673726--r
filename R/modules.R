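#' Construct a FEM module object
#'
#' @param seed Seed gene symbol.
#' @param members Character vector of member genes (includes the seed).
#' @param modularity Mean induced edge weight of the member set.
#' @param p_value Permutation P value (may be `NA` before testing).
#' @return An object of class `fem_module`.
#' @export
fem_module <- function(seed, members, modularity = NA_real_,
                       p_value = NA_real_) {
  stopifnot(is.character(seed), length(seed) == 1L, seed %in% members)
  structure(list(seed = seed, members = sort(unique(members)),
                 modularity = modularity, p_value = p_value,
                 size = length(unique(members))),
            class = "fem_module")
}

#' @export
print.fem_module <- function(x, ...) {
  cat(sprintf("FEM module seeded at %s: %d genes, modularity %.3f, p = %s\n",
              x$seed, x$size, x$modularity,
              format.pval(x$p_value, digits = 3)))
  invisible(x)
}

#' Modularity of a gene set on a weighted network
#'
#' The module's modularity is the arithmetic mean of the edge weights of its
#' induced subgraph (not the Newman-Girvan global modularity).
#'
#' @param members Character vector of gene symbols.
#' @param net Weighted network.
#' @return Mean induced edge weight.
#' @export
module_modularity <- function(members, net) {
  stopifnot(igraph::is_igraph(net))
  members <- intersect(members, igraph::V(net)$name)
  sub <- igraph::induced_subgraph(net, members)
  if (igraph::ecount(sub) == 0L)
    stop_femnet("member set induces no edges")
  mean(igraph::E(sub)$weight)
}

#' Grow a module around a seed gene
#'
#' Seeded local greedy search in the spirit of the spin-glass module
#' detection family: at each step the adjacent gene whose connecting edges
#' have the highest mean weight is considered, and accepted while that mean
#' exceeds `tau` times the current modularity. With `tau = 1` additions are
#' accepted only when they strictly increase the modularity (the mean
#' induced edge weight rises if and only if the new edges beat the current
#' mean); the default `tau = 0.5` lets the search traverse plateaus of
#' comparable edge weight instead of stopping at the single heaviest edge,
#' which is what recovers extended hotspots.
#'
#' An isolated seed yields a degenerate single-gene module with `p = 1`,
#' which downstream steps exclude.
#'
#' @param seed Seed gene symbol (must be in the network).
#' @param net Weighted network from [build_weighted_network()].
#' @param max_size Maximum module size (default 100).
#' @param tau Relative acceptance threshold in `(0, 1]` (default 0.5).
#' @return A [fem_module] (with `p_value` still `NA` unless degenerate).
#' @export
grow_module <- function(seed, net, max_size = 100, tau = 0.5) {
  stopifnot(igraph::is_igraph(net), max_size >= 2, tau > 0, tau <= 1)
  nm <- igraph::V(net)$name
  if (!seed %in% nm) stop_femnet("seed gene not in network")
  sid <- match(seed, nm)
  if (igraph::degree(net, sid) == 0L)
    return(fem_module(seed, seed, modularity = NA_real_, p_value = 1))

  adj <- igraph::adjacent_vertices(net, igraph::V(net))
  adj <- lapply(adj, as.integer)
  el <- igraph::as_edgelist(net, names = FALSE)
  w <- igraph::E(net)$weight
  # incident edge lookup: for node i, edges and opposite endpoints
  inc_e <- igraph::incident_edges(net, igraph::V(net))

  in_mod <- logical(length(nm))
  in_mod[sid] <- TRUE
  members <- sid
  sum_w <- 0; n_e <- 0L

  repeat {
    if (length(members) >= max_size) break
    cand <- setdiff(unique(unlist(adj[members])), members)
    if (!length(cand)) break
    best <- NA_integer_; best_avg <- -Inf; best_sum <- 0; best_k <- 0L
    for (u in cand) {
      es <- as.integer(inc_e[[u]])
      opp <- el[es, 1L] + el[es, 2L] - u
      sel <- in_mod[opp]
      su <- sum(w[es[sel]]); ku <- sum(sel)
      avg <- su / ku
      if (avg > best_avg ||
          (avg == best_avg && !is.na(best) && nm[u] < nm[best])) {
        best <- u; best_avg <- avg; best_sum <- su; best_k <- ku
      }
    }
    cur_mod <- if (n_e > 0L) sum_w / n_e else 0
    accept <- if (n_e == 0L) best_avg > 0 else best_avg > tau * cur_mod
    if (!accept) break
    in_mod[best] <- TRUE
    members <- c(members, best)
    sum_w <- sum_w + best_sum; n_e <- n_e + best_k
  }
  if (length(members) < 2L)
    return(fem_module(seed, seed, modularity = NA_real_, p_value = 1))
  fem_module(seed, nm[members], modularity = sum_w / n_e)
}

#' Permutation significance of a module
#'
#' Node-level statistic pairs are randomly reassigned over the network's
#' genes, edge weights recomputed, and the module's modularity re-evaluated
#' on the same member set, `n_perm` times. Because an edge weight is the mean
#' of its endpoints' integrated statistics, the permuted modularity of a
#' fixed member set depends only on which integrated statistics land on the
#' member genes, so each permutation draws `|members|` values from the vector
#' of network integrated statistics without replacement (equivalent to, and
#' much faster than, rebuilding the weighted network).
#'
#' `p = (1 + #\{permuted modularity >= observed\}) / (1 + n_perm)`.
#'
#' @param module A [fem_module] (or character vector of member genes).
#' @param net Weighted network carrying vertex attribute `tI`.
#' @param n_perm Number of permutations (>= 100).
#' @param seed Optional RNG seed for reproducibility.
#' @return The module with `modularity` and `p_value` filled in; the null
#'   modularities are attached as attribute `null`.
#' @export
module_significance <- function(module, net, n_perm = 1000, seed = NULL) {
  stopifnot(n_perm >= 100)
  members <- if (inherits(module, "fem_module")) module$members else module
  members <- intersect(members, igraph::V(net)$name)
  if (length(members) < 2L) {
    out <- fem_module(members[1] %||% "NA", members[1] %||% "NA",
                      p_value = 1)
    return(out)
  }
  sub <- igraph::induced_subgraph(net, members)
  if (igraph::ecount(sub) == 0L) stop_femnet("module induces no edges")
  deg_in <- igraph::degree(sub)
  n_e <- igraph::ecount(sub)
  ti_all <- igraph::V(net)$tI
  ti_mem <- igraph::V(sub)$tI
  obs <- sum(deg_in * ti_mem) / (2 * n_e)
  m <- length(members)
  null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      v <- ti_all[sample.int(length(ti_all), m)]
      sum(deg_in * v) / (2 * n_e)
    }, numeric(1))
  })
  p <- (1 + sum(null >= obs - 1e-12)) / (1 + n_perm)
  out <- if (inherits(module, "fem_module")) module
         else fem_module(members[1], members)
  out$modularity <- obs
  out$p_value <- p
  attr(out, "null") <- null
  out
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

#' Remove redundant overlapping modules
#'
#' Modules are ranked by modularity (descending; ties by seed symbol) and a
#' module is dropped when its overlap coefficient
#' `|A & B| / min(|A|, |B|)` with any already retained module exceeds
#' `overlap_threshold`.
#'
#' @param modules List of [fem_module] objects.
#' @param overlap_threshold Overlap coefficient threshold in `(0, 1]`.
#' @return Pruned list, in modularity order.
#' @export
prune_redundant <- function(modules, overlap_threshold = 0.5) {
  stopifnot(overlap_threshold > 0, overlap_threshold <= 1)
  if (!length(modules)) return(modules)
  mods <- vapply(modules, function(m) m$modularity, numeric(1))
  seeds <- vapply(modules, function(m) m$seed, character(1))
  ord <- order(-mods, seeds)
  kept <- list()
  for (i in ord) {
    mi <- modules[[i]]
    overlap <- vapply(kept, function(kj)
      length(intersect(mi$members, kj$members)) /
        min(mi$size, kj$size), numeric(1))
    if (!length(overlap) || all(overlap <= overlap_threshold))
      kept[[length(kept) + 1L]] <- mi
  }
  kept
}

#' Re-score modules in an independent cohort
#'
#' The network is re-weighted with the validation cohort's statistics and
#' each module's modularity and permutation P are recomputed on its (surviving)
#' member set. Members without validation statistics are dropped and counted;
#' modules with fewer than two surviving connected members are flagged as not
#' validated.
#'
#' @param modules List of [fem_module] objects from discovery.
#' @param stats_D,stats_R Validation-cohort gene statistics (expression
#'   already rescaled).
#' @param ppi The interactome.
#' @param n_perm Permutations for the validation P.
#' @param seed Optional RNG seed.
#' @return data.frame with one row per module: `seed`, `size`,
#'   `n_validated` (surviving members), `modularity`, `p_value`,
#'   `validated` (logical; `NA` when untestable).
#' @export
validate_modules <- function(modules, stats_D, stats_R, ppi,
                             n_perm = 1000, seed = NULL) {
  net <- build_weighted_network(stats_D, stats_R, ppi)
  seeds <- child_seeds(seed, length(modules))
  rows <- lapply(seq_along(modules), function(i) {
    m <- modules[[i]]
    surv <- intersect(m$members, igraph::V(net)$name)
    if (length(surv) < 2L ||
        igraph::ecount(igraph::induced_subgraph(net, surv)) == 0L) {
      return(data.frame(seed = m$seed, size = m$size,
                        n_validated = length(surv),
                        modularity = NA_real_, p_value = NA_real_,
                        validated = NA))
    }
    vs <- module_significance(surv, net, n_perm = n_perm,
                              seed = seeds[[i]])
    data.frame(seed = m$seed, size = m$size, n_validated = length(surv),
               modularity = vs$modularity, p_value = vs$p_value,
               validated = vs$p_value < 0.05)
  })
  do.call(rbind, rows)
}

#' Cross-cohort consistency of module statistics
#'
#' Pearson correlation (with two-sided P) between discovery and validation
#' t-statistics over a module's genes, separately for DNA methylation and
#' expression. A significant positive correlation indicates directionally
#' consistent differential patterns.
#'
#' @param disc_D,disc_R Discovery gene statistics.
#' @param val_D,val_R Validation gene statistics.
#' @param module A [fem_module] or character vector of genes.
#' @return List with `r_D`, `p_D`, `r_R`, `p_R` and the gene count `n`.
#' @export
consistency_correlation <- function(disc_D, disc_R, val_D, val_R, module) {
  members <- if (inherits(module, "fem_module")) module$members else module
  one <- function(d, v) {
    shared <- Reduce(intersect, list(members, d$gene, v$gene))
    if (length(shared) < 3L) stop_femnet("need >= 3 shared genes")
    ct <- cor.test(d$t[match(shared, d$gene)], v$t[match(shared, v$gene)])
    list(r = unname(ct$estimate), p = ct$p.value, n = length(shared))
  }
  dn <- one(disc_D, val_D)
  ex <- one(disc_R, val_R)
  list(r_D = dn$r, p_D = dn$p, r_R = ex$r, p_R = ex$p,
       n = min(dn$n, ex$n))
}

#' Discover FEM modules end to end
#'
#' Selects the top-`n_seeds` genes by integrated statistic, grows a module
#' around each, evaluates permutation significance, and prunes redundant
#' overlaps. Degenerate single-gene modules are excluded.
#'
#' @param net Weighted network from [build_weighted_network()].
#' @param n_seeds Number of seed genes.
#' @param max_size,tau Growth parameters, see [grow_module()].
#' @param n_perm Permutations per module.
#' @param overlap_threshold Redundancy threshold, see [prune_redundant()].
#' @param seed Optional RNG seed.
#' @return List of [fem_module] objects sorted by modularity.
#' @export
find_fem_modules <- function(net, n_seeds = 10, max_size = 100, tau = 0.5,
                             n_perm = 1000, overlap_threshold = 0.5,
                             seed = NULL) {
  seeds_g <- select_seeds(net, n_seeds)
  rng <- child_seeds(seed, length(seeds_g))
  mods <- lapply(seq_along(seeds_g), function(i) {
    m <- grow_module(seeds_g[i], net, max_size = max_size, tau = tau)
    if (m$size < 2L) return(NULL)
    module_significance(m, net, n_perm = n_perm, seed = rng[[i]])
  })
  mods <- Filter(Negate(is.null), mods)
  prune_redundant(mods, overlap_threshold = overlap_threshold)
}

#' Tabulate a module list
#'
#' @param modules List of [fem_module] objects.
#' @return data.frame with columns seed, size, modularity, p_value, members.
#' @export
module_table <- function(modules) {
  do.call(rbind, lapply(modules, function(m)
    data.frame(seed = m$seed, size = m$size, modularity = m$modularity,
               p_value = m$p_value,
               members = paste(m$members, collapse = ";"),
               stringsAsFactors = FALSE)))
}
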