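ref_phen <- function(n_norm, n_tum) {
  data.frame(sample_id = c(sprintf("N%02d", seq_len(n_norm)),
                           sprintf("T%02d", seq_len(n_tum))),
             group = rep(c("normal", "tumour"), c(n_norm, n_tum)),
             stringsAsFactors = FALSE)
}

test_that("normal reference uses normals only and floors degenerate variance", {
  phen <- ref_phen(5, 3)
  x <- matrix(rnorm(2 * 8), 2, 8,
              dimnames = list(c("gA", "gB"), phen$sample_id))
  x["gA", 1:5] <- 0.5                         # constant across normals
  ref <- fit_normal_reference(x, phen)
  expect_equal(unname(ref$mu["gA"]), 0.5)
  expect_equal(ref$flagged, "gA")
  expect_equal(unname(ref$sigma["gA"]), unname(ref$sigma["gB"]))  # floored

  expect_error(fit_normal_reference(x[, c(1, 2, 6, 7, 8)], ref_phen(2, 3)),
               ">= 3 normal")

  # estimator consistency on a larger draw
  set.seed(51)
  ok <- replicate(50, {
    p2 <- ref_phen(100, 3)
    m <- matrix(rnorm(103, 10, 2), 1, 103,
                dimnames = list("g", p2$sample_id))
    abs(fit_normal_reference(m, p2)$mu - 10) < 3 * 2 / sqrt(100)
  })
  expect_gte(mean(ok), 0.95)
})

test_that("Z statistics standardize elementwise against the reference", {
  phen <- ref_phen(4, 2)
  set.seed(52)
  x <- matrix(runif(3 * 6), 3, dimnames = list(paste0("g", 1:3),
                                               phen$sample_id))
  ref <- fit_normal_reference(x, phen)
  tum <- x[, 5:6]
  z <- z_statistics(tum, ref)
  # independent elementwise recomputation
  for (g in rownames(tum)) for (s in colnames(tum))
    expect_equal(z[g, s], (tum[g, s] - ref$mu[[g]]) / ref$sigma[[g]])
  # X = mu -> 0 ; X = mu + sigma -> 1
  at_mu <- matrix(ref$mu, 3, 1, dimnames = list(names(ref$mu), "s"))
  expect_equal(unname(z_statistics(at_mu, ref)), matrix(0, 3, 1))
  at_sd <- at_mu + ref$sigma
  expect_equal(unname(z_statistics(at_sd, ref)), matrix(1, 3, 1))
})

test_that("the scaling factor is the ratio of Z standard deviations", {
  set.seed(53)
  zd <- matrix(rnorm(200, sd = 2), 10, dimnames = list(paste0("g", 1:10),
                                                       paste0("s", 1:20)))
  zr <- matrix(rnorm(200, sd = 4), 10, dimnames = dimnames(zd))
  a <- scaling_factor(zd, zr)
  expect_equal(a, sd(as.vector(zd)) / sd(as.vector(zr)))
  # homogeneity: scaling Z_R by c scales alpha by 1/c
  expect_equal(scaling_factor(zd, 3 * zr), a / 3, tolerance = 1e-12)
  # identically distributed matrices -> alpha 1
  expect_equal(scaling_factor(zd, zd), 1)
  expect_error(scaling_factor(zd, zr * 0), "zero")
})

test_that("FEM score averages the absolute scaled deviation mismatch", {
  genes <- c("g1", "g2", "g3")
  d <- stats_df(genes, c(3, 3, 3), p = c(0.01, 0.01, 0.5))
  r <- stats_df(genes, c(-3, 3, -3), p = c(0.01, 0.01, 0.01))
  # eligible: g1 only (g2 concordant, g3 not significant at DNAm level)
  expect_equal(eligible_genes(genes, d, r), "g1")

  zd <- matrix(c(2, 0, 0, 0, 0, 0), 3, 2,
               dimnames = list(genes, c("s1", "s2")))
  zr <- matrix(c(-1, 0, 0, 0, 0, 0), 3, 2,
               dimnames = list(genes, c("s1", "s2")))
  sc <- fem_score(genes, d, r, zd, zr, alpha = 1)
  expect_equal(unname(sc["s1"]), 3)   # |2 - 1*(-1)|
  expect_equal(unname(sc["s2"]), 0)   # at the normal mean in both types

  r_all_conc <- stats_df(genes, c(3, 3, 3))
  expect_warning(out <- fem_score(genes, d, r_all_conc, zd, zr, 1),
                 "no eligible genes")
  expect_null(out)
})

test_that("FEM scores are invariant to affine rescaling when the reference is refit", {
  set.seed(54)
  phen <- ref_phen(10, 8)
  genes <- paste0("g", 1:4)
  x <- matrix(rnorm(4 * 18, 5, 1), 4, dimnames = list(genes, phen$sample_id))
  y <- matrix(rnorm(4 * 18, 8, 2), 4, dimnames = list(genes, phen$sample_id))
  d <- stats_df(genes, rep(3, 4)); r <- stats_df(genes, rep(-3, 4))
  score_of <- function(xx, yy) {
    rd <- fit_normal_reference(xx, phen); rr <- fit_normal_reference(yy, phen)
    zd <- z_statistics(xx[, 11:18], rd); zr <- z_statistics(yy[, 11:18], rr)
    fem_score(genes, d, r, zd, zr, scaling_factor(zd, zr))
  }
  s1 <- score_of(x, y)
  s2 <- score_of(3 * x + 2, 0.5 * y - 7)
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("binary deviation entries require joint significance and the gene's pattern", {
  genes <- "g1"
  d <- stats_df(genes, 3)          # hypermethylated
  r <- stats_df(genes, -3)         # underexpressed
  mk <- function(zd, zr) {
    bm <- binary_deviation_matrix(genes,
      matrix(zd, 1, 1, dimnames = list(genes, "s1")),
      matrix(zr, 1, 1, dimnames = list(genes, "s1")), d, r,
      p_threshold = 0.1)
    bm[1, 1]
  }
  expect_equal(mk(3, -3), 1L)       # both P < 0.1, anti-correlated direction
  expect_equal(mk(0, -3), 0L)       # P(Z_D) = 1
  expect_equal(mk(3, 3), 0L)        # wrong direction for this gene
  expect_equal(mk(-3, 3), 0L)       # deviates against the cohort pattern
  expect_equal(mk(1, -3), 0L)       # P(|Z| >= 1) = 0.32 > 0.1
})

test_that("mean Manhattan distance equals exhaustive pair enumeration", {
  m <- rbind(a = c(1, 1, 0, 0), b = c(0, 0, 1, 1))
  expect_equal(mean_manhattan(m), 4)
  expect_equal(mean_manhattan(rbind(m[1, ], m[1, ])), 0)

  set.seed(55)
  bm <- matrix(rbinom(40, 1, 0.4), 5, 8,
               dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  pairs <- combn(5, 2)
  oracle <- mean(apply(pairs, 2, function(ij)
    sum(abs(bm[ij[1], ] - bm[ij[2], ]))))
  expect_equal(mean_manhattan(bm), oracle)
  expect_error(mean_manhattan(bm[1, , drop = FALSE]), ">= 2 rows")
})

test_that("coordination test separates shared from disjoint deviation patterns", {
  # ten genes flagging the same half of 40 samples: observed MHD = 0 is the
  # null minimum -> minimal p
  shared <- matrix(0L, 10, 40, dimnames = list(paste0("g", 1:10),
                                               paste0("s", 1:40)))
  shared[, 1:20] <- 1L
  ct <- coordination_test(shared, n_perm = 1000, seed = 6)
  expect_equal(ct$p, 1 / 1001)

  # perfectly mutually exclusive rows: lower-tail p near 1, upper tail small
  excl <- matrix(0L, 8, 40, dimnames = list(paste0("g", 1:8),
                                            paste0("s", 1:40)))
  for (i in 1:8) excl[i, ((i - 1) * 5 + 1):(i * 5)] <- 1L
  ct_lo <- coordination_test(excl, n_perm = 500, seed = 6)
  expect_gte(ct_lo$p, 0.9)
  ct_hi <- coordination_test(excl, n_perm = 500, seed = 6,
                             alternative = "exclusive")
  expect_lte(ct_hi$p, 0.05)

  # constant matrix: degenerate null
  const <- matrix(1L, 3, 10, dimnames = list(paste0("g", 1:3),
                                             paste0("s", 1:10)))
  ctc <- coordination_test(const, n_perm = 100)
  expect_true(ctc$degenerate)
  expect_equal(ctc$p, 1)
})

test_that("planted coordination monotonically lowers the median p", {
  set.seed(57)
  med_p <- vapply(c(0, 0.3, 0.6), function(rho) {
    ps <- replicate(30, {
      m <- matrix(0L, 8, 60)
      core <- sample(60, 15)
      for (i in 1:8) {
        own <- sample(60, 15)
        take <- rbinom(15, 1, rho) == 1
        m[i, ifelse(take, core, own)] <- 1L
      }
      dimnames(m) <- list(paste0("g", 1:8), paste0("s", 1:60))
      coordination_test(m, n_perm = 300, seed = NULL)$p
    })
    median(ps)
  }, numeric(1))
  expect_true(all(diff(med_p) < 0))
})
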