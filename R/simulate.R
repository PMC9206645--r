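#' Simulation configuration for synthetic cohorts
#'
#' Bundles the parameters of the synthetic-cohort generator.  The generator
#' emulates a two-timepoint extremely-preterm cohort: per-subject covariates
#' on the scales of a typical NICU sample (birth gestational age ~ 26.6 +/-
#' 1.0 weeks truncated to [24, 28), scans near 30 and 41 post-menstrual
#' weeks), per-ROI weekly fractional growth rates drawn from a group-specific
#' multivariate normal whose correlation matrix has network-block structure,
#' linear covariate effects added to the rates, and invasive-procedure
#' counts whose per-day rate differs by group so that the standardized
#' stress score of the high group stochastically dominates the low group.
#'
#' Correlation targets are given per block as `c(low, high)` pairs — the
#' value for the low- and the high-stress group.  The defaults encode a
#' high-stress group with stronger within-SN coupling (+0.3), weaker
#' within-DMN coupling (-0.3) and weaker SN-DMN cross-coupling (-0.2),
#' i.e. a salience-over-default-mode reprioritization pattern.
#'
#' @param n_per_group subjects per group (>= 4); default 90.
#' @param atlas an [mcn_atlas()]; default the 32-node [default_atlas()].
#' @param rho_within named list, per network, of `c(low, high)` within-block
#'   rate-correlation targets in (-1, 1).
#' @param rho_between named list, per network pair (`"A-B"`, networks in
#'   atlas order), of `c(low, high)` cross-block targets.
#' @param covariate_effects named numeric vector of linear coefficients of
#'   covariates on the growth rate (per covariate unit, per week); names
#'   from the cohort covariate schema.  Unnamed covariates get 0.
#' @param rate_mean mean weekly fractional growth rate; default 0.06/week.
#' @param rate_noise_sd SD of the correlated rate noise; default 0.015.
#' @param baseline_volume_mean,baseline_volume_sd scalar or per-ROI vector
#'   of first-scan volume mean/SD (mm^3).
#' @param stress_rate_per_day expected invasive procedures per NICU day,
#'   `c(low, high)`.
#' @param seed integer RNG seed (or `NULL` to use the current RNG state).
#' @return List of class `mcn_sim_config`.
#' @export
sim_config <- function(n_per_group = 90L,
                       atlas = default_atlas(),
                       rho_within = list(SN  = c(0.25, 0.55),
                                         DMN = c(0.55, 0.25),
                                         ECN = c(0.40, 0.40)),
                       rho_between = list("SN-DMN"  = c(0.35, 0.15),
                                          "SN-ECN"  = c(0.20, 0.20),
                                          "DMN-ECN" = c(0.20, 0.20)),
                       covariate_effects = c(gestational_age = 0.002,
                                             gender = 0.002,
                                             morphine_days = -0.0003),
                       rate_mean = 0.06,
                       rate_noise_sd = 0.015,
                       baseline_volume_mean = 3000,
                       baseline_volume_sd = 450,
                       stress_rate_per_day = c(low = 2, high = 4),
                       seed = NULL) {
  stopifnot(inherits(atlas, "mcn_atlas"))
  if (n_per_group < 4L)
    stop("n_per_group must be at least 4", call. = FALSE)
  nets <- atlas_networks(atlas)
  miss <- setdiff(nets, names(rho_within))
  if (length(miss))
    stop("rho_within missing network(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  pairs <- if (length(nets) > 1L)
    utils::combn(nets, 2L, FUN = function(p) paste(p, collapse = "-")) else character(0)
  miss <- setdiff(pairs, names(rho_between))
  if (length(miss))
    stop("rho_between missing pair(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  all_rho <- c(unlist(rho_within), unlist(rho_between))
  if (any(abs(all_rho) >= 1))
    stop("correlation targets must lie in (-1, 1)", call. = FALSE)
  structure(list(n_per_group = as.integer(n_per_group), atlas = atlas,
                 rho_within = rho_within, rho_between = rho_between,
                 covariate_effects = covariate_effects,
                 rate_mean = rate_mean, rate_noise_sd = rate_noise_sd,
                 baseline_volume_mean = baseline_volume_mean,
                 baseline_volume_sd = baseline_volume_sd,
                 stress_rate_per_day = stress_rate_per_day,
                 seed = seed),
            class = "mcn_sim_config")
}

#' Build a block-structured correlation matrix
#'
#' Fills a ROIs x ROIs correlation matrix with per-block constants: one
#' target per within-network block and one per between-network block, unit
#' diagonal.  Arbitrary block targets need not be jointly positive
#' semi-definite; if the filled matrix is not PSD it is repaired by
#' eigenvalue clipping (negative eigenvalues raised to a small positive
#' floor, the matrix reconstructed and re-standardized to unit diagonal).
#' The repair is reported via attributes.
#'
#' @param atlas an [mcn_atlas()].
#' @param rho_within named numeric vector/list: one target per network.
#' @param rho_between named numeric vector/list: one target per network pair
#'   (`"A-B"`, atlas network order).
#' @return Correlation matrix with attributes `psd_repaired` (logical) and
#'   `max_target_shift` (largest absolute change any entry underwent in the
#'   repair).
#' @export
build_block_correlation <- function(atlas, rho_within, rho_between) {
  stopifnot(inherits(atlas, "mcn_atlas"))
  rho_within <- unlist(rho_within); rho_between <- unlist(rho_between)
  if (any(abs(c(rho_within, rho_between)) >= 1))
    stop("correlation targets must lie in (-1, 1)", call. = FALSE)
  nets <- atlas_networks(atlas)
  p <- nrow(atlas)
  C <- matrix(0, p, p, dimnames = list(atlas$roi, atlas$roi))
  edges <- edge_universe(atlas)
  blk <- as.character(edges$block)
  tgt <- numeric(nrow(edges))
  within <- startsWith(blk, "within-")
  tgt[within] <- rho_within[sub("^within-", "", blk[within])]
  tgt[!within] <- rho_between[blk[!within]]
  if (anyNA(tgt))
    stop("missing correlation target for block(s): ",
         paste(unique(blk[is.na(tgt)]), collapse = ", "), call. = FALSE)
  C[cbind(edges$idx_i, edges$idx_j)] <- tgt
  C[cbind(edges$idx_j, edges$idx_i)] <- tgt
  diag(C) <- 1
  ev <- eigen(C, symmetric = TRUE)
  repaired <- FALSE; shift <- 0
  if (min(ev$values) < 1e-8) {
    lam <- pmax(ev$values, 1e-8)
    C2 <- ev$vectors %*% (lam * t(ev$vectors))
    C2 <- stats::cov2cor(C2)
    C2 <- (C2 + t(C2)) / 2
    dimnames(C2) <- dimnames(C)
    shift <- max(abs(C2 - C))
    C <- C2; diag(C) <- 1
    repaired <- TRUE
  }
  attr(C, "psd_repaired") <- repaired
  attr(C, "max_target_shift") <- shift
  C
}

# truncated-normal draws by rejection
rtnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lower | out >= upper)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower | out[bad] >= upper]
  }
  out
}

#' Simulate a synthetic two-timepoint cohort
#'
#' Draws a full cohort under an [sim_config()]: covariates, group-specific
#' block-correlated growth rates, two-timepoint volumes constructed as
#' `v_t2 = v_t1 * (1 + rate * delta_weeks)`, and stress exposure
#' (invasive-procedure counts over the NICU stay) consistent with the group
#' labels.  Fully reproducible from the config seed.
#'
#' @param config an [sim_config()].
#' @return List of class `mcn_sim` with elements `cohort` (an
#'   `mcn_cohort`), `group` (true labels, factor low/high), `stress`
#'   (subject_id, procedures, nicu_days), `corr` (the group-wise
#'   correlation matrices actually used, after any PSD repair) and
#'   `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "mcn_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  atlas <- config$atlas
  p <- nrow(atlas)
  ng <- config$n_per_group
  n <- 2L * ng
  id <- sprintf("S%03d", seq_len(n))
  group <- factor(rep(c("low", "high"), each = ng), levels = c("low", "high"))

  # covariates on Table-1-like scales
  ga <- rtnorm(n, 26.64, 0.99, lower = 24, upper = 28)
  age1 <- rtnorm(n, 30.00, 0.97, lower = 28)
  age2 <- rtnorm(n, 41.00, 0.90, lower = 38)
  bad <- which(age2 <= age1 + 4)
  while (length(bad)) {          # scans ~30 and ~41 weeks, ordered
    age2[bad] <- rtnorm(length(bad), 41.00, 0.90, lower = 38)
    bad <- bad[age2[bad] <= age1[bad] + 4]
  }
  covariates <- data.frame(
    subject_id = id,
    gender = stats::rbinom(n, 1L, 0.433),
    total_brain_volume = rtnorm(n, 180000, 20000, lower = 1),
    gestational_age = ga,
    age_scan1_weeks = age1,
    age_scan2_weeks = age2,
    ivh = stats::rbinom(n, 1L, 59 / 180),
    surgeries = stats::rpois(n, 0.5),
    prenatal_steroids = stats::rbinom(n, 1L, 164 / 180),
    postnatal_steroids = stats::rbinom(n, 1L, 54 / 180),
    morphine_days = stats::rbinom(n, 1L, 0.6) *
      round(stats::rgamma(n, shape = 1, scale = 5)),
    stringsAsFactors = FALSE)

  # group-wise block correlation matrices (PSD-repaired if needed)
  pick <- function(lst, k) lapply(lst, `[`, k)
  corr <- list(low  = build_block_correlation(atlas, pick(config$rho_within, 1L),
                                              pick(config$rho_between, 1L)),
               high = build_block_correlation(atlas, pick(config$rho_within, 2L),
                                              pick(config$rho_between, 2L)))
  for (g in names(corr))
    if (attr(corr[[g]], "max_target_shift") > 0.05)
      warning("PSD repair moved ", g, "-group correlation targets by up to ",
              round(attr(corr[[g]], "max_target_shift"), 3), call. = FALSE)

  # correlated rate noise + linear covariate effects
  beta <- stats::setNames(numeric(length(covariate_columns())),
                          covariate_columns())
  ce <- unlist(config$covariate_effects)
  unknown <- setdiff(names(ce), names(beta))
  if (length(unknown))
    stop("covariate_effects names not in schema: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  beta[names(ce)] <- ce
  X <- covariate_design(covariates)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  shift <- as.vector(Xc %*% beta)

  rates <- matrix(NA_real_, n, p, dimnames = list(id, atlas$roi))
  for (g in levels(group)) {
    rows <- group == g
    noise <- MASS::mvrnorm(sum(rows), mu = rep(0, p),
                           Sigma = corr[[g]]) * config$rate_noise_sd
    rates[rows, ] <- config$rate_mean + noise + shift[rows]
  }

  v1 <- matrix(rtnorm(n * p,
                      mean = rep(config$baseline_volume_mean, each = n),
                      sd = rep(config$baseline_volume_sd, each = n),
                      lower = 1),
               n, p, dimnames = list(id, atlas$roi))
  dt <- age2 - age1
  v2 <- v1 * (1 + rates * dt)
  if (any(v2 <= 0))
    stop("simulated second-scan volume non-positive; ",
         "rate_mean/rate_noise_sd imply shrinkage beyond -100%",
         call. = FALSE)

  volumes <- data.frame(subject_id = id, age_scan1_weeks = age1,
                        age_scan2_weeks = age2, stringsAsFactors = FALSE)
  for (k in seq_len(p)) {
    volumes[[paste0(atlas$roi[k], "_t1")]] <- v1[, k]
    volumes[[paste0(atlas$roi[k], "_t2")]] <- v2[, k]
  }

  # stress exposure consistent with group labels: per-day procedure rate
  # higher in the high group, counts accumulated over the NICU stay up to
  # the first scan
  nicu_days <- pmax(1L, round((age1 - ga) * 7))
  lam <- config$stress_rate_per_day[as.character(group)] * nicu_days
  procedures <- stats::rpois(n, lam)
  stress <- data.frame(subject_id = id, procedures = procedures,
                       nicu_days = nicu_days, stringsAsFactors = FALSE)

  structure(list(cohort = as_cohort(volumes, covariates, atlas),
                 group = group, stress = stress, corr = corr,
                 config = config),
            class = "mcn_sim")
}

#' @export
print.mcn_sim <- function(x, ...) {
  cat("Synthetic MCN cohort:", length(x$group), "subjects (",
      paste(table(x$group), collapse = " low / "), "high ),",
      nrow(x$config$atlas), "ROIs; seed =",
      if (is.null(x$config$seed)) "unset" else x$config$seed, "\n")
  invisible(x)
}
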