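test_that("integrated statistic gates on anti-correlated signs", {
  expect_equal(integrated_statistic(2, -3), 5)
  expect_equal(integrated_statistic(-2, 3), 5)
  expect_equal(integrated_statistic(2, 3), 0)
  expect_equal(integrated_statistic(-2, -3), 0)
  expect_equal(integrated_statistic(0, 5), 0)   # H(0) = 0 convention
  expect_equal(integrated_statistic(5, 0), 0)
})

test_that("edge weights average the endpoint integrated statistics", {
  g <- igraph::make_graph(~ a - b, b - c)
  # a: tI = 5 (t: 2/-3); b: tI = 2 (1/-1); c: concordant -> 0
  d <- stats_df(c("a", "b", "c"), c(2, 1, 2))
  r <- stats_df(c("a", "b", "c"), c(-3, -1, 3))
  net <- build_weighted_network(d, r, g)
  w <- igraph::E(net)$weight
  names(w) <- apply(igraph::as_edgelist(net), 1, paste, collapse = "-")
  expect_equal(unname(w["a-b"]), 3.5)
  expect_equal(unname(w["b-c"]), 1)   # (2 + 0)/2; zero-tI edge retained
  expect_equal(igraph::V(net)$tI[match("c", igraph::V(net)$name)], 0)
})

test_that("network restriction keeps the maximally connected component", {
  g <- igraph::make_graph(~ a - b, b - c, a - c, x - y, y - z, x - z, w - x)
  genes <- c("a", "b", "c", "x", "y", "z", "w")
  d <- stats_df(genes, rep(1, 7))
  r <- stats_df(genes, rep(-1, 7))
  net <- build_weighted_network(d, r, g)
  expect_setequal(igraph::V(net)$name, c("x", "y", "z", "w"))

  # equal component sizes: tie broken by lexicographically smallest gene
  g2 <- igraph::make_graph(~ m - n, n - o, d - e, e - f)
  genes2 <- c("m", "n", "o", "d", "e", "f")
  net2 <- build_weighted_network(stats_df(genes2, rep(1, 6)),
                                 stats_df(genes2, rep(-1, 6)), g2)
  expect_setequal(igraph::V(net2)$name, c("d", "e", "f"))

  expect_error(build_weighted_network(stats_df("q", 1), stats_df("q", -1), g),
               "no genes shared")
})

test_that("seed selection ranks by integrated statistic with lexicographic ties", {
  g <- igraph::make_ring(4)
  igraph::V(g)$name <- c("d", "c", "b", "a")
  d <- stats_df(c("d", "c", "b", "a"), c(5, 3, 1, 1))
  r <- stats_df(c("d", "c", "b", "a"), c(-5, -3, -1, -1))
  net <- build_weighted_network(d, r, g)
  expect_equal(select_seeds(net, 2), c("d", "c"))
  # all equal -> lexicographic
  net2 <- build_weighted_network(stats_df(letters[1:4], rep(2, 4)),
                                 stats_df(letters[1:4], rep(-2, 4)),
                                 igraph::make_full_graph(4) |>
                                   igraph::set_vertex_attr("name",
                                     value = c("c", "a", "d", "b")))
  expect_equal(select_seeds(net2, 3), c("a", "b", "c"))
  expect_warning(out <- select_seeds(net, 10), "truncating")
  expect_length(out, 4)
})

test_that("greedy growth takes the heavy edge of a star and stops on plateaus", {
  # star: hub h (tI 0) with one heavy spoke s1 (tI 20 -> w = 10), others 0
  g <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(g)$name <- c("h", "s1", "s2", "s3", "s4")
  g <- set_stats_on_graph(g, tD = c(-1, 10, -1, -1, -1),
                          tR = c(-1, -10, -1, -1, -1))
  m <- grow_module("h", g, tau = 1)
  expect_setequal(m$members, c("h", "s1"))
  expect_equal(m$modularity, 10)
  m2 <- grow_module("h", g)           # default tau keeps the same answer here
  expect_setequal(m2$members, c("h", "s1"))

  # equal weights everywhere: strict rule (tau = 1) stops at the first
  # non-increase, i.e. a single-edge module
  gc <- set_stats_on_graph(igraph::make_full_graph(5) |>
                             igraph::set_vertex_attr("name",
                               value = letters[1:5]),
                           tD = rep(2, 5), tR = rep(-2, 5))
  me <- grow_module("a", gc, tau = 1)
  expect_equal(me$size, 2)

  # isolated seed degenerates to size 1 with p = 1
  gi <- igraph::make_graph(~ a - b) + igraph::vertex("z")
  gi <- set_stats_on_graph(gi, tD = c(1, 1, 1), tR = c(-1, -1, -1))
  mz <- grow_module("z", gi)
  expect_equal(mz$size, 1)
  expect_equal(mz$p_value, 1)
})

test_that("relaxed growth recovers a planted clique the strict rule cannot", {
  # 8-clique of weight 3 inside a weight-0.1 background path
  set.seed(41)
  g <- igraph::make_full_graph(8)
  g <- igraph::add_vertices(g, 4)
  g <- igraph::add_edges(g, c(8, 9, 9, 10, 10, 11, 11, 12))
  igraph::V(g)$name <- sprintf("v%02d", 1:12)
  tD <- c(rep(3, 8), rep(0.1, 4)); tR <- -tD
  g <- set_stats_on_graph(g, tD, tR)
  m <- grow_module("v01", g, tau = 0.5)
  expect_gte(length(intersect(m$members, sprintf("v%02d", 1:8))) /
               length(union(m$members, sprintf("v%02d", 1:8))), 0.7)
})

test_that("module modularity equals the exhaustive enumeration oracle", {
  # induced weights {1, 2, 3} -> 2
  g <- igraph::make_graph(~ a - b, b - c, c - a)
  igraph::E(g)$weight <- c(1, 2, 3)
  igraph::V(g)$tI <- 0
  expect_equal(module_modularity(c("a", "b", "c"), g), 2)
  expect_equal(module_modularity(c("a", "b"), g), 1)  # single edge

  set.seed(42)
  for (i in 1:5) {
    gr <- rand_graph(12, 0.4)
    gr <- set_stats_on_graph(gr, rnorm(12), rnorm(12))
    mem <- random_connected_set(gr, 8)
    expect_equal(module_modularity(mem, gr), brute_modularity(mem, gr))
  }
  gsolo <- igraph::make_graph(~ a - b) + igraph::vertex("z")
  igraph::E(gsolo)$weight <- 1
  expect_error(module_modularity(c("a", "z"), gsolo), "no edges")
})

test_that("fast permutation statistic equals a full network re-weighting", {
  set.seed(43)
  g <- rand_graph(15, 0.3)
  tD <- rnorm(15); tR <- rnorm(15)
  g <- set_stats_on_graph(g, tD, tR)
  mem <- random_connected_set(g, 6)
  sub <- igraph::induced_subgraph(g, mem)
  deg_in <- igraph::degree(sub)
  for (i in 1:10) {
    perm <- sample(15)
    gp <- set_stats_on_graph(g, tD[perm], tR[perm])   # full re-weighting
    full <- module_modularity(mem, gp)
    ti_perm <- igraph::V(gp)$tI[match(igraph::V(sub)$name,
                                      igraph::V(gp)$name)]
    fast <- sum(deg_in * ti_perm) / (2 * igraph::ecount(sub))
    expect_equal(fast, full, tolerance = 1e-12)
  }
})

test_that("permutation significance is exact at the extremes", {
  # the two members hold the unique maximal statistics: no permutation of
  # node statistics can exceed the observed modularity, and only the
  # re-landing of that same pair can tie it
  g <- igraph::make_graph(~ a - b, b - c, c - d, d - e)
  g <- set_stats_on_graph(g, tD = c(9, 8, 0.1, 0.1, 0.1),
                          tR = c(-9, -8, -0.1, -0.1, -0.1))
  ms <- module_significance(c("a", "b"), g, n_perm = 200, seed = 5)
  null <- attr(ms, "null")
  expect_true(all(null <= ms$modularity + 1e-12))
  expect_equal(ms$p_value, (1 + sum(null >= ms$modularity - 1e-12)) / 201)
  # ties occur only when the maximal pair is resampled (prob 1/10 per draw)
  expect_lt(ms$p_value, 0.2)

  # module spanning a regular network: every permutation yields the same
  # modularity, so p = 1 by symmetry
  ring <- igraph::make_ring(5)
  igraph::V(ring)$name <- letters[1:5]
  ring <- set_stats_on_graph(ring, tD = c(5, 4, 3, 2, 1),
                             tR = -c(5, 4, 3, 2, 1))
  ms2 <- module_significance(letters[1:5], ring, n_perm = 100, seed = 5)
  expect_equal(ms2$p_value, 1)
})

test_that("redundant module pruning uses the overlap coefficient", {
  mk <- function(seed, members, mod)
    fem_module(seed, members, modularity = mod, p_value = 0.01)
  a <- mk("a", letters[1:5], 5)
  a2 <- mk("b", letters[1:5], 4)       # identical member set
  expect_length(prune_redundant(list(a, a2)), 1)

  dis <- mk("x", c("x", "y"), 3)
  expect_length(prune_redundant(list(a, dis)), 2)

  # A subset of B: overlap coefficient 1 > 0.5 -> lower-modularity dropped
  big <- mk("a", letters[1:10], 2)
  small <- mk("b", letters[1:5], 6)
  kept <- prune_redundant(list(big, small), 0.5)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$seed, "b")
})

test_that("validation re-scores modules with independent statistics", {
  set.seed(44)
  g <- rand_graph(20, 0.3)
  genes <- igraph::V(g)$name
  tD <- rnorm(20, 2); tR <- rnorm(20, -2)
  d <- stats_df(genes, tD); r <- stats_df(genes, tR)
  net <- build_weighted_network(d, r, g)
  mod <- grow_module(select_seeds(net, 1), net)
  val <- validate_modules(list(mod), d, r, g, n_perm = 100, seed = 9)
  expect_equal(val$modularity, mod$modularity, tolerance = 1e-12)

  # all-zero validation statistics: modularity 0, p = 1
  z <- stats_df(genes, rep(0, 20))
  val0 <- validate_modules(list(mod), z, z, g, n_perm = 100, seed = 9)
  expect_equal(val0$modularity, 0)
  expect_equal(val0$p_value, 1)

  # members missing from validation statistics are dropped and counted
  d2 <- d[d$gene %in% mod$members[1:2] == FALSE, ]
  val2 <- validate_modules(list(mod), d2, r, g, n_perm = 100, seed = 9)
  expect_equal(val2$n_validated, mod$size - 2)
})

test_that("cross-cohort consistency correlation behaves at its extremes", {
  genes <- sprintf("g%02d", 1:10)
  d <- stats_df(genes, rnorm(10)); r <- stats_df(genes, rnorm(10))
  cc <- consistency_correlation(d, r, d, r, genes)
  expect_equal(cc$r_D, 1)
  expect_equal(cc$r_R, 1)
  neg_d <- d; neg_d$t <- -neg_d$t
  neg_r <- r; neg_r$t <- -neg_r$t
  cc2 <- consistency_correlation(d, r, neg_d, neg_r, genes)
  expect_equal(cc2$r_D, -1)
  expect_error(consistency_correlation(d, r, d, r, genes[1:2]),
               ">= 3 shared genes")
})

test_that("overlap enrichment reproduces hypergeometric tail probabilities", {
  universe <- sprintf("u%02d", 1:10)
  sets <- list(S = universe[1:5])
  members <- universe[c(1:4)]
  res <- overlap_enrichment(members, sets, universe)
  expect_equal(res$p, 5 / 210, tolerance = 1e-12)  # P(X >= 4), hand enumeration
  expect_equal(res$n_overlap, 4)

  # module = set = universe: overlap certain, p = 1
  res2 <- overlap_enrichment(universe, list(S = universe), universe)
  expect_equal(res2$p, 1)

  # monotone in overlap
  p_by_overlap <- vapply(2:4, function(k)
    overlap_enrichment(c(universe[1:k], universe[6:(9 - k + 2)])[1:4],
                       sets, universe)$p, numeric(1))
  expect_true(all(diff(p_by_overlap) < 0))
  expect_error(overlap_enrichment(members, sets, character(0)), "universe")
})
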