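# Shared fixtures and independent oracles for the test suite.

# data.frame wrapper for per-gene statistics
stats_df <- function(genes, t, p = rep(0.01, length(genes))) {
  data.frame(gene = genes, t = t, p = p, stringsAsFactors = FALSE)
}

# Assign integrated statistics and edge weights to a graph directly
# (same weighting contract as build_weighted_network, without the
# statistics plumbing); used to build null fixtures quickly.
set_stats_on_graph <- function(g, tD, tR) {
  H <- function(x) as.numeric(x > 0)
  tI <- (H(tD) * H(-tR) + H(-tD) * H(tR)) * abs(tD - tR)
  igraph::V(g)$tD <- tD
  igraph::V(g)$tR <- tR
  igraph::V(g)$tI <- tI
  el <- igraph::as_edgelist(g, names = FALSE)
  igraph::E(g)$weight <- (tI[el[, 1]] + tI[el[, 2]]) / 2
  g
}

# Random named Erdos-Renyi graph
rand_graph <- function(n, p = 0.3) {
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("g%03d", seq_len(n))
  g
}

# Exhaustive-enumeration modularity oracle: loop over all unordered vertex
# pairs of the member set and average the weights of existing edges.
brute_modularity <- function(members, g) {
  nm <- igraph::V(g)$name
  el <- igraph::as_edgelist(g)
  w <- igraph::E(g)$weight
  key <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
  names(w) <- key
  vals <- c()
  for (i in seq_along(members)) for (j in seq_len(i - 1L)) {
    a <- members[i]; b <- members[j]
    k <- paste(min(a, b), max(a, b))
    if (k %in% key) vals <- c(vals, w[[k]])
  }
  mean(vals)
}

# Hand breadth-first-search distances from one vertex (hop counts)
bfs_dist <- function(g, from) {
  nm <- igraph::V(g)$name
  adj <- lapply(igraph::adjacent_vertices(g, igraph::V(g)), as.integer)
  d <- rep(Inf, length(nm))
  s <- match(from, nm)
  d[s] <- 0
  frontier <- s
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) for (u in adj[[v]]) if (is.infinite(d[u])) {
      d[u] <- d[v] + 1
      nxt <- c(nxt, u)
    }
    frontier <- unique(nxt)
  }
  setNames(d, nm)
}

# Random connected vertex subset found by truncated BFS
random_connected_set <- function(g, size) {
  start <- sample(igraph::vcount(g), 1)
  ord <- as.integer(igraph::bfs(g, start, unreachable = FALSE)$order)
  ord <- ord[!is.na(ord)]
  igraph::V(g)$name[ord[seq_len(min(size, length(ord)))]]
}

# Matched D and R matrices with two well-separated sample groups
two_blob_cohort <- function(n_per = 15, genes = 20, sep = 3, seed = NULL) {
  gen <- function() {
    s <- c(paste0("x", seq_len(n_per)), paste0("y", seq_len(n_per)))
    m <- matrix(rnorm(genes * 2 * n_per), genes,
                dimnames = list(paste0("g", seq_len(genes)), s))
    shift_genes <- seq_len(genes / 2)
    m[shift_genes, seq_len(n_per)] <- m[shift_genes, seq_len(n_per)] + sep
    m
  }
  if (!is.null(seed)) set.seed(seed)
  list(d = gen(), r = gen(),
       truth = setNames(rep(1:2, each = n_per),
                        c(paste0("x", seq_len(n_per)),
                          paste0("y", seq_len(n_per)))))
}

# Tiny matched cohort for fast end-to-end tests
small_spec <- function(seed = 1, ...) {
  defaults <- list(n_normal = 12, n_lumA = 10, n_lumB = 10, n_genes = 60,
                   probes_per_gene = 2,
                   modules = list(list(size = 8, delta_D = 1.5,
                                       delta_R = -1.5, mode = "coordinated",
                                       affected_fraction = 1)),
                   seed = seed)
  dots <- list(...)
  defaults[names(dots)] <- dots   # outright replacement, no list merging
  do.call(cohort_spec, defaults)
}
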