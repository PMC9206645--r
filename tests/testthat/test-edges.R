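make_group_assoc <- function(n_sub, atlas, seed, Sigma = NULL) {
  set.seed(seed)
  p <- nrow(atlas)
  X <- if (is.null(Sigma)) matrix(rnorm(n_sub * p), n_sub, p)
       else MASS::mvrnorm(n_sub, rep(0, p), Sigma)
  colnames(X) <- atlas$roi
  build_mcn(X)
}

test_that("edge Z follows the independent-samples Fisher r-to-z formula", {
  a <- toy_atlas(c(2, 2))
  zlo <- matrix(0, 4, 4, dimnames = list(a$roi, a$roi))
  zhi <- zlo
  zlo["a1", "a2"] <- atanh(0.3); zhi["a1", "a2"] <- atanh(0.6)
  zlo["a1", "b1"] <- atanh(0.4); zhi["a1", "b1"] <- atanh(0.4)
  mlo <- fake_assoc(zlo, n = 90); mhi <- fake_assoc(zhi, n = 90)
  res <- compare_edge_correlations(mlo, mhi, a, r_min = 0.10)

  row1 <- res[res$roi_i == "a1" & res$roi_j == "a2", ]
  expect_equal(row1$Z, (atanh(0.6) - atanh(0.3)) / sqrt(2 / 87),
               tolerance = 1e-10)
  expect_equal(row1$Z, 2.530, tolerance = 5e-4)
  expect_equal(row1$p, 2 * pnorm(-abs(row1$Z)), tolerance = 1e-12)

  row2 <- res[res$roi_i == "a1" & res$roi_j == "b1", ]   # equal correlations
  expect_equal(row2$Z, 0)
  expect_equal(row2$p, 1)

  # r = 0 in both groups -> excluded by the spurious-correlation filter
  row3 <- res[res$roi_i == "a2" & res$roi_j == "b2", ]
  expect_true(row3$excluded)
  expect_match(row3$reason, "both groups")
  expect_true(is.na(row3$Z) && is.na(row3$p) && is.na(row3$q))
})

test_that("the filter excludes only edges weak in both groups by default", {
  a <- toy_atlas(c(2, 2))
  zlo <- matrix(0, 4, 4, dimnames = list(a$roi, a$roi))
  zhi <- zlo
  zlo["a1", "a2"] <- atanh(0.08); zhi["a1", "a2"] <- atanh(0.05)  # both weak
  zlo["a1", "b1"] <- atanh(0.05); zhi["a1", "b1"] <- atanh(0.65)  # decoupling
  zlo["b1", "b2"] <- atanh(-0.5); zhi["b1", "b2"] <- atanh(-0.4)  # negative
  res <- compare_edge_correlations(fake_assoc(zlo, 60), fake_assoc(zhi, 60), a)
  expect_true(res$excluded[res$roi_i == "a1" & res$roi_j == "a2"])
  expect_false(res$excluded[res$roi_i == "a1" & res$roi_j == "b1"])
  expect_false(res$excluded[res$roi_i == "b1" & res$roi_j == "b2"])  # |r| filter

  either <- compare_edge_correlations(fake_assoc(zlo, 60), fake_assoc(zhi, 60),
                                      a, filter = "either")
  expect_true(either$excluded[either$roi_i == "a1" & either$roi_j == "b1"])
})

test_that("swapping the groups negates every included Z", {
  a <- toy_atlas(c(3, 3))
  Sigma <- build_block_correlation(a, c(A = 0.5, B = 0.3), c("A-B" = 0.2))
  mlo <- make_group_assoc(40, a, 1, Sigma)
  mhi <- make_group_assoc(40, a, 2, Sigma)
  r1 <- compare_edge_correlations(mlo, mhi, a)
  r2 <- compare_edge_correlations(mhi, mlo, a)
  expect_equal(r2$Z, -r1$Z, tolerance = 1e-12)
  expect_true(all(r1$q >= r1$p - 1e-12, na.rm = TRUE))
})

test_that("Z increases with the z-difference at equal group sizes", {
  set.seed(44)
  a <- toy_atlas(c(2, 2))
  diffs <- numeric(0); zs <- numeric(0)
  for (i in 1:25) {
    rl <- runif(1, -0.8, 0.8); rh <- runif(1, -0.8, 0.8)
    zlo <- matrix(0, 4, 4, dimnames = list(a$roi, a$roi))
    zhi <- zlo
    zlo["a1", "a2"] <- atanh(rl); zhi["a1", "a2"] <- atanh(rh)
    res <- compare_edge_correlations(fake_assoc(zlo, 50), fake_assoc(zhi, 50),
                                     a, r_min = 0)
    row <- res[res$roi_i == "a1" & res$roi_j == "a2", ]
    diffs <- c(diffs, atanh(rh) - atanh(rl)); zs <- c(zs, row$Z)
  }
  ord <- order(diffs)
  expect_true(all(diff(zs[ord]) > 0))
})

test_that("under a shared covariance the edge test is calibrated", {
  a <- default_atlas()
  Sigma <- build_block_correlation(
    a, c(SN = 0.35, DMN = 0.35, ECN = 0.35),
    c("SN-DMN" = 0.15, "SN-ECN" = 0.15, "DMN-ECN" = 0.15))
  hits <- 0L; total <- 0L
  for (rep in 1:20) {
    mlo <- make_group_assoc(90, a, 100 + rep, Sigma)
    mhi <- make_group_assoc(90, a, 200 + rep, Sigma)
    res <- compare_edge_correlations(mlo, mhi, a)
    inc <- !res$excluded
    hits <- hits + sum(res$p[inc] < 0.05)
    total <- total + sum(inc)
  }
  rate <- hits / total
  expect_gt(rate, 0.03); expect_lt(rate, 0.07)
})

test_that("mismatched inputs are rejected", {
  a <- toy_atlas(c(2, 2)); b <- toy_atlas(c(3, 3))
  m1 <- make_group_assoc(20, a, 1); m2 <- make_group_assoc(20, b, 2)
  expect_error(compare_edge_correlations(m1, m2, a), "do not match")
  m3 <- make_group_assoc(20, a, 3); m3$n <- 3L
  expect_error(compare_edge_correlations(m3, m1, a), "3 subjects")
})
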