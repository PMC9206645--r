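#' Annualized fractional growth rate between two scans
#'
#' The growth trajectory of a region is summarized by the volume change
#' between the two scans, normalized on the first-scan volume and divided by
#' the inter-scan interval in weeks:
#' `rate = ((v2 - v1) / v1) / (age2 - age1)`, in units of fractional change
#' per week.
#'
#' @param v1,v2 volumes (mm^3) at the first and second scan; `v1 > 0`.
#' @param age1,age2 scan ages in weeks; `age2 > age1`.
#' @return Numeric growth rate(s), per week.  Vectorized.
#' @export
annualized_rate <- function(v1, v2, age1, age2) {
  if (any(v1 <= 0))
    stop("baseline volume must be positive", call. = FALSE)
  if (any(age2 <= age1))
    stop("age2 must exceed age1", call. = FALSE)
  ((v2 - v1) / v1) / (age2 - age1)
}

#' Growth-rate matrix of a cohort
#'
#' Applies [annualized_rate()] ROI-wise to every subject, producing the raw
#' subjects x ROIs rate matrix that feeds covariate adjustment and network
#' construction.
#'
#' @param cohort an `mcn_cohort` from [load_cohort()] / [as_cohort()].
#' @return Numeric matrix (subjects x ROIs), rownames `subject_id`,
#'   colnames atlas ROI names, with attribute `kind = "raw"`.
#' @export
growth_rates <- function(cohort) {
  stopifnot(inherits(cohort, "mcn_cohort"))
  vol <- cohort$volumes
  dt <- vol$age_scan2_weeks - vol$age_scan1_weeks
  rois <- cohort$atlas$roi
  v1 <- as.matrix(vol[, paste0(rois, "_t1")])
  v2 <- as.matrix(vol[, paste0(rois, "_t2")])
  rates <- ((v2 - v1) / v1) / dt
  dimnames(rates) <- list(vol$subject_id, rois)
  attr(rates, "kind") <- "raw"
  rates
}

#' Design matrix for covariate adjustment
#'
#' Intercept plus the ten covariate columns of the cohort model (gender,
#' total brain volume, gestational age at birth, both scan ages, IVH,
#' surgeries, pre-/postnatal corticosteroids, days of morphine).
#' @noRd
covariate_design <- function(covariates) {
  X <- as.matrix(covariates[, covariate_columns(), drop = FALSE])
  storage.mode(X) <- "double"
  X
}

#' Remove covariate effects via studentized residuals
#'
#' For each column of `mat` (typically a ROI's growth rates), fits an
#' ordinary least-squares regression on the covariates and returns the
#' studentized residuals.  The default is *externally* studentized
#' residuals, `t_i = e_i / (s_(-i) * sqrt(1 - h_ii))`, where `e_i` is the
#' raw residual, `h_ii` the leverage and `s_(-i)` the residual SD of the
#' model refitted without observation i (computed via the standard
#' leave-one-out identity, [stats::rstudent()]).  `type = "internal"` gives
#' internally standardized residuals ([stats::rstandard()]).
#'
#' @param mat numeric subjects x variables matrix (e.g. from
#'   [growth_rates()]); rownames must be subject ids matching the
#'   covariate table.
#' @param covariates covariate data frame in the cohort schema (see
#'   [cohort-model]), one row per subject in `mat` order.
#' @param type `"external"` (default) or `"internal"` studentization.
#' @return Matrix of the same shape as `mat` with attribute
#'   `kind = "studentized"`.
#' @export
residualize <- function(mat, covariates, type = c("external", "internal")) {
  type <- match.arg(type)
  stopifnot(is.matrix(mat))
  X <- covariate_design(covariates)
  if (nrow(X) != nrow(mat))
    stop("covariates and rate matrix disagree on subject count",
         call. = FALSE)
  n <- nrow(X)
  if (n < ncol(X) + 3L)
    stop("too few subjects (", n, ") for ", ncol(X), " covariates",
         call. = FALSE)
  df <- data.frame(X)
  fit0 <- stats::lm(mat[, 1L] ~ ., data = df)
  if (fit0$rank < ncol(X) + 1L) {
    aliased <- names(which(is.na(stats::coef(fit0))))
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  h <- stats::lm.influence(fit0, do.coef = FALSE)$hat
  if (any(h > 1 - 1e-10)) {
    bad <- rownames(mat)[h > 1 - 1e-10]
    stop("leverage of 1 (self-fitting observation) for subject(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out <- apply(mat, 2L, function(y) {
    fit <- stats::lm(y ~ ., data = df)
    if (type == "external") stats::rstudent(fit) else stats::rstandard(fit)
  })
  dimnames(out) <- dimnames(mat)
  attr(out, "kind") <- "studentized"
  out
}

#' Studentized growth rates of a cohort
#'
#' Convenience wrapper: [growth_rates()] then [residualize()].  With
#' `adjust = "volumes"` the covariate adjustment is instead applied to the
#' t1 and t2 volume matrices before rates are computed from the
#' studentized volumes' implied trajectories; the default adjusts the rates
#' themselves (the annualization already absorbs inter-scan-interval
#' differences, and the trajectory is the quantity whose covariance defines
#' the network).
#'
#' @inheritParams residualize
#' @param cohort an `mcn_cohort`.
#' @param adjust `"rates"` (default) or `"volumes"`: which quantity is
#'   residualized.
#' @return Subjects x ROIs matrix of studentized trajectories.
#' @export
studentized_rates <- function(cohort, type = c("external", "internal"),
                              adjust = c("rates", "volumes")) {
  type <- match.arg(type); adjust <- match.arg(adjust)
  if (adjust == "rates")
    return(residualize(growth_rates(cohort), cohort$covariates, type = type))
  # volumes-first variant: studentize each timepoint's volumes, then take
  # the per-week difference of the studentized values
  vol <- cohort$volumes
  rois <- cohort$atlas$roi
  v1 <- as.matrix(vol[, paste0(rois, "_t1")])
  v2 <- as.matrix(vol[, paste0(rois, "_t2")])
  dimnames(v1) <- dimnames(v2) <- list(vol$subject_id, rois)
  r1 <- residualize(v1, cohort$covariates, type = type)
  r2 <- residualize(v2, cohort$covariates, type = type)
  dt <- vol$age_scan2_weeks - vol$age_scan1_weeks
  out <- (r2 - r1) / dt
  attr(out, "kind") <- "studentized"
  out
}
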