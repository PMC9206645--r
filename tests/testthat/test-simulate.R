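test_that("block correlation matrix fills blocks exactly", {
  a <- toy_atlas(c(2, 2))
  # independence case
  C0 <- build_block_correlation(a, c(A = 0, B = 0), c("A-B" = 0))
  expect_equal(unname(C0[, ]), diag(4), ignore_attr = TRUE)
  # direct block fill
  C <- build_block_correlation(a, c(A = 0.5, B = 0.5), c("A-B" = 0.2))
  # atlas order is a1, a2 (net A), b1, b2 (net B)
  want <- rbind(c(1, .5, .2, .2), c(.5, 1, .2, .2),
                c(.2, .2, 1, .5), c(.2, .2, .5, 1))
  expect_equal(unname(C[, ]), want, ignore_attr = TRUE)
  expect_false(attr(C, "psd_repaired"))
  expect_error(build_block_correlation(a, c(A = 1.2, B = 0), c("A-B" = 0)),
               "targets")
})

test_that("PSD repair yields a valid correlation matrix (eigen oracle)", {
  set.seed(31)
  a <- default_atlas()
  nets <- unique(a$network)
  for (i in 1:8) {
    rw <- stats::setNames(runif(3, -0.5, 0.9), nets)
    rb <- stats::setNames(runif(3, -0.8, 0.9),
                          c("SN-DMN", "SN-ECN", "DMN-ECN"))
    C <- build_block_correlation(a, rw, rb)
    ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
    expect_true(min(ev) >= -1e-10)
    expect_equal(unname(diag(C)), rep(1, 32))
    expect_true(max(abs(C - t(C))) < 1e-12)
  }
})

test_that("PSD repair agrees with an independent nearest-PSD routine", {
  a <- toy_atlas(c(3, 3))
  # targets that are jointly infeasible -> repair must engage
  rw <- c(A = 0.1, B = 0.1); rb <- c("A-B" = 0.9)
  C <- build_block_correlation(a, rw, rb)
  expect_true(attr(C, "psd_repaired"))
  # raw (pre-repair) block fill, assembled independently of the package
  eu <- edge_universe(a)
  raw <- diag(nrow(a))
  blk <- as.character(eu$block)
  tgt <- ifelse(startsWith(blk, "within-"), rw[sub("^within-", "", blk)],
                rb[blk])
  raw[cbind(eu$idx_i, eu$idx_j)] <- tgt
  raw[cbind(eu$idx_j, eu$idx_i)] <- tgt
  np <- Matrix::nearPD(raw, corr = TRUE)
  expect_true(min(eigen(C, only.values = TRUE)$values) >= -1e-10)
  # both repairs stay close to each other entrywise
  expect_lt(max(abs(C - as.matrix(np$mat))), 0.15)
})

test_that("simulation is reproducible and constructs volumes from rates", {
  cfg <- sim_config(n_per_group = 10, seed = 99)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$cohort$volumes, s2$cohort$volumes)
  expect_identical(s1$stress, s2$stress)

  # v_t2 = v_t1 * (1 + rate * delta_weeks) exactly: growth_rates inverts it
  rt <- growth_rates(s1$cohort)
  v <- s1$cohort$volumes
  dt <- v$age_scan2_weeks - v$age_scan1_weeks
  roi <- "cerebellum_left"
  expect_equal(v[[paste0(roi, "_t2")]],
               v[[paste0(roi, "_t1")]] * (1 + rt[, roi] * dt),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("empirical rate correlations hit the block targets at large n", {
  cfg <- sim_config(n_per_group = 2000, seed = 64,
                    rho_within = list(SN = c(0.5, 0.5), DMN = c(0.3, 0.3),
                                      ECN = c(0.3, 0.3)),
                    rho_between = list("SN-DMN" = c(0.1, 0.1),
                                       "SN-ECN" = c(0.1, 0.1),
                                       "DMN-ECN" = c(0.1, 0.1)),
                    covariate_effects = c(gestational_age = 0))
  sim <- simulate_cohort(cfg)
  rt <- growth_rates(sim$cohort)
  eu <- edge_universe(cfg$atlas)
  r <- stats::cor(rt[sim$group == "low", ])
  within_sn <- eu$block == "within-SN"
  mean_r <- mean(r[cbind(eu$idx_i[within_sn], eu$idx_j[within_sn])])
  expect_lt(abs(mean_r - 0.5), 0.03)
})

test_that("high-stress group scores dominate and invariants hold", {
  sim <- simulate_cohort(sim_config(n_per_group = 60, seed = 7))
  sc <- compute_stress_scores(sim$stress$subject_id, sim$stress$procedures,
                              sim$stress$nicu_days)
  expect_gt(mean(sc$score[sim$group == "high"]),
            mean(sc$score[sim$group == "low"]) + 1)
  for (g in c("low", "high"))
    expect_true(min(eigen(sim$corr[[g]], only.values = TRUE)$values) >= -1e-10)
  # recovered groups from the stress path match the truth closely
  g <- assign_groups(sc, "median")
  expect_gt(mean(g == sim$group), 0.95)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_per_group = 2), "at least 4")
  expect_error(sim_config(rho_within = list(SN = c(0.2, 0.2))), "missing")
  expect_error(simulate_cohort(sim_config(
    covariate_effects = c(not_a_covariate = 1), seed = 1)), "schema")
})
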