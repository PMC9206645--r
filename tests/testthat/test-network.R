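test_that("fisher_z is atanh with the documented domain", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.549306144334055, tolerance = 1e-12)
  expect_equal(fisher_z(-0.9), -1.47221948958322, tolerance = 1e-12)
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(fisher_z(-r), -fisher_z(r))           # odd
  expect_true(all(diff(fisher_z(r)) > 0))            # strictly increasing
  expect_error(fisher_z(1), "\\|r\\| < 1")
})

test_that("build_mcn matches brute-force pairwise Pearson correlation", {
  set.seed(17)
  rates <- matrix(rnorm(20 * 6), 20, 6,
                  dimnames = list(NULL, paste0("roi", 1:6)))
  mcn <- build_mcn(rates)
  brute <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) if (i != j)
    brute[i, j] <- sum(scale(rates[, i]) * scale(rates[, j])) / 19
  expect_lt(max(abs(mcn$r - brute)), 1e-12)
  expect_equal(diag(mcn$r), rep(0, 6), ignore_attr = TRUE)
  expect_equal(diag(mcn$z), rep(0, 6), ignore_attr = TRUE)
  expect_equal(mcn$z[1, 2], atanh(mcn$r[1, 2]))
  expect_equal(mcn$r, t(mcn$r))
  expect_equal(mcn$n, 20L)
})

test_that("build_mcn is invariant to subject order and guards its domain", {
  set.seed(18)
  rates <- matrix(rnorm(12 * 5), 12, 5, dimnames = list(NULL, paste0("r", 1:5)))
  m1 <- build_mcn(rates)
  m2 <- build_mcn(rates[sample(12), ])
  expect_equal(m1$r, m2$r, tolerance = 1e-12)
  expect_true(all(abs(m1$r[upper.tri(m1$r)]) <= 1))

  expect_error(build_mcn(rates[1:3, ]), "at least 4")
  ratesz <- rates; ratesz[, 3] <- 2
  expect_error(build_mcn(ratesz), "r3")

  # duplicated column -> perfect correlation, clipped with a warning for z
  ratesd <- cbind(rates, r5b = rates[, 5])
  expect_warning(md <- build_mcn(ratesd), "clipped")
  expect_equal(md$r["r5", "r5b"], 1)
  expect_equal(md$z["r5", "r5b"], atanh(1 - 1e-7))
})

test_that("thresholding retains exactly the strongest m edges", {
  a4 <- toy_atlas(c(2, 2))  # rois a1 a2 b1 b2
  z <- matrix(0, 4, 4, dimnames = list(a4$roi, a4$roi))
  z["a1", "a2"] <- 0.9; z["a1", "b1"] <- 0.7; z["b1", "b2"] <- 0.5
  z["a2", "b2"] <- 0.3; z["a1", "b2"] <- 0.2; z["a2", "b1"] <- 0.1
  mcn <- fake_assoc(z)
  net <- threshold_binarize(mcn, 3 / 6, a4)
  expect_equal(net$m, 3L)
  expect_equal(net$adjacency["a1", "a2"], 1L)
  expect_equal(net$adjacency["a1", "b1"], 1L)
  expect_equal(net$adjacency["b1", "b2"], 1L)
  expect_equal(sum(net$adjacency), 2L * 3L)
  expect_equal(diag(net$adjacency), rep(0L, 4), ignore_attr = TRUE)

  counts <- count_connections(net, a4)
  expect_equal(counts, c("within-A" = 1L, "within-B" = 1L, "A-B" = 1L))

  # complete graph at K = 1
  full <- threshold_binarize(mcn, 1, a4)
  expect_equal(full$m, 6L)
  expect_equal(count_connections(full, a4),
               c("within-A" = 1L, "within-B" = 1L, "A-B" = 4L))
  expect_error(threshold_binarize(mcn, 0, a4), "K")
})

test_that("K = 0.20 on the default atlas retains 99 edges and counts partition", {
  set.seed(5)
  a <- default_atlas()
  rates <- matrix(rnorm(40 * 32), 40, 32, dimnames = list(NULL, a$roi))
  mcn <- build_mcn(rates)
  net <- threshold_binarize(mcn, 0.20, a)
  expect_equal(net$m, 99L)
  counts <- count_connections(net, a)
  expect_equal(sum(counts), 99L)
  expect_true(all(counts <= block_sizes(a)))
  # complete graph recovers the block sizes themselves
  expect_equal(count_connections(threshold_binarize(mcn, 1, a), a),
               block_sizes(a))
})

test_that("tie-break on equal weights is lexicographic and deterministic", {
  a4 <- toy_atlas(c(2, 2))
  z <- matrix(0.4, 4, 4, dimnames = list(a4$roi, a4$roi))  # all tied
  net <- threshold_binarize(fake_assoc(z), 2 / 6, a4)
  eu <- edge_universe(a4)
  expect_equal(paste(eu$roi_i[net$retained], eu$roi_j[net$retained]),
               c("a1 a2", "a1 b1"))  # first two pairs lexicographically
})

test_that("coupling_delta is zero for identical groups and antisymmetric", {
  set.seed(23)
  a <- toy_atlas(c(3, 3))
  X <- matrix(rnorm(10 * 6), 10, 6, dimnames = list(NULL, a$roi))
  rates <- rbind(X, X)
  labels <- rep(c("low", "high"), each = 10)
  d0 <- coupling_delta(rates, labels, 0.3, a)
  expect_true(all(d0 == 0L))

  rates2 <- matrix(rnorm(20 * 6), 20, 6, dimnames = list(NULL, a$roi))
  d1 <- coupling_delta(rates2, labels, 0.3, a)
  d2 <- coupling_delta(rates2, rev(labels), 0.3, a)
  expect_equal(d2, -d1)
  expect_equal(sum(d1), 0L)
})

test_that("planted within-block correlation difference shows up in the delta sign", {
  cfg <- sim_config(n_per_group = 200, seed = 41,
                    covariate_effects = c(gestational_age = 0))
  sim <- simulate_cohort(cfg)
  rt <- growth_rates(sim$cohort)
  d <- coupling_delta(rt, sim$group, 0.20, cfg$atlas)
  expect_gt(d[["within-SN"]], 0)
  expect_lt(d[["within-DMN"]], 0)
  expect_lt(d[["SN-DMN"]], 0)
})
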