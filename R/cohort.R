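#' @title Cohort data model and I/O
#'
#' @description
#' A cohort couples two tables keyed by `subject_id`:
#'
#' * **volumes** — two-timepoint regional volumes, wide format:
#'   `subject_id`, `age_scan1_weeks`, `age_scan2_weeks`, then `{roi}_t1` and
#'   `{roi}_t2` (mm^3) for every atlas ROI.
#' * **covariates** — `subject_id`, `gender` (0/1), `total_brain_volume`
#'   (mm^3), `gestational_age` (weeks at birth), `age_scan1_weeks`,
#'   `age_scan2_weeks`, `ivh` (0/1 intraventricular hemorrhage),
#'   `surgeries` (count), `prenatal_steroids` (0/1), `postnatal_steroids`
#'   (0/1), `morphine_days` (days).
#'
#' Scan ages appear in both files; [load_cohort()] checks they agree.
#' @name cohort-model
NULL

covariate_columns <- function() {
  c("gender", "total_brain_volume", "gestational_age",
    "age_scan1_weeks", "age_scan2_weeks", "ivh", "surgeries",
    "prenatal_steroids", "postnatal_steroids", "morphine_days")
}

#' Assemble a validated cohort from in-memory tables
#'
#' @param volumes data frame in the wide volumes schema (see
#'   [cohort-model]).
#' @param covariates data frame in the covariates schema.
#' @param atlas an [mcn_atlas()]; its ROI names must match the volume
#'   columns.
#' @return A list of class `mcn_cohort` with elements `volumes`,
#'   `covariates` (rows aligned by `subject_id`, atlas column order) and
#'   `atlas`.
#' @export
as_cohort <- function(volumes, covariates, atlas) {
  stopifnot(inherits(atlas, "mcn_atlas"))
  vol_need <- c("subject_id", "age_scan1_weeks", "age_scan2_weeks",
                paste0(rep(atlas$roi, each = 2L), c("_t1", "_t2")))
  miss <- setdiff(vol_need, names(volumes))
  if (length(miss))
    stop("volumes table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  cov_need <- c("subject_id", covariate_columns())
  miss <- setdiff(cov_need, names(covariates))
  if (length(miss))
    stop("covariates table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)

  volumes$subject_id <- as.character(volumes$subject_id)
  covariates$subject_id <- as.character(covariates$subject_id)
  if (anyDuplicated(volumes$subject_id))
    stop("duplicated subject_id in volumes table", call. = FALSE)
  if (anyDuplicated(covariates$subject_id))
    stop("duplicated subject_id in covariates table", call. = FALSE)

  only_v <- setdiff(volumes$subject_id, covariates$subject_id)
  only_c <- setdiff(covariates$subject_id, volumes$subject_id)
  if (length(only_v) || length(only_c))
    stop("subject alignment error; present in volumes only: [",
         paste(only_v, collapse = ", "), "], in covariates only: [",
         paste(only_c, collapse = ", "), "]", call. = FALSE)

  # align covariates to the volumes row order; order itself is irrelevant
  covariates <- covariates[match(volumes$subject_id, covariates$subject_id),
                           cov_need, drop = FALSE]
  volumes <- volumes[, vol_need, drop = FALSE]
  rownames(volumes) <- rownames(covariates) <- NULL

  if (anyNA(volumes) || anyNA(covariates))
    stop("missing values are not allowed after validation", call. = FALSE)

  vol_cols <- paste0(rep(atlas$roi, each = 2L), c("_t1", "_t2"))
  vmat <- as.matrix(volumes[, vol_cols])
  if (any(vmat <= 0)) {
    bad <- volumes$subject_id[apply(vmat <= 0, 1L, any)]
    stop("non-positive volume for subject(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad_age <- volumes$age_scan2_weeks <= volumes$age_scan1_weeks
  if (any(bad_age))
    stop("age at scan 2 must exceed age at scan 1; offending subject(s): ",
         paste(volumes$subject_id[bad_age], collapse = ", "), call. = FALSE)
  if (max(abs(volumes$age_scan1_weeks - covariates$age_scan1_weeks),
          abs(volumes$age_scan2_weeks - covariates$age_scan2_weeks)) > 1e-6)
    stop("scan ages disagree between volumes and covariates tables",
         call. = FALSE)

  structure(list(volumes = volumes, covariates = covariates, atlas = atlas),
            class = "mcn_cohort")
}

#' Load a cohort from delimited files
#'
#' Reads, validates and aligns the volumes and covariates CSVs (schema in
#' [cohort-model]).  Validation failures are errors naming the offending
#' column or subject.
#'
#' @param volumes_path,covariates_path CSV paths.
#' @param atlas an [mcn_atlas()] (default: [default_atlas()]).
#' @return An `mcn_cohort`; see [as_cohort()].
#' @export
load_cohort <- function(volumes_path, covariates_path,
                        atlas = default_atlas()) {
  for (p in c(volumes_path, covariates_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  vol <- utils::read.csv(volumes_path, stringsAsFactors = FALSE)
  cov <- utils::read.csv(covariates_path, stringsAsFactors = FALSE)
  as_cohort(vol, cov, atlas)
}

#' Write a cohort to delimited files
#'
#' Inverse of [load_cohort()]: writes the documented CSV schema so that
#' load -> write -> load round-trips.
#'
#' @param cohort an `mcn_cohort`.
#' @param volumes_path,covariates_path output CSV paths.
#' @param atlas_path optional path; if given the atlas is written too.
#' @return Invisibly, the cohort.
#' @export
write_cohort <- function(cohort, volumes_path, covariates_path,
                         atlas_path = NULL) {
  stopifnot(inherits(cohort, "mcn_cohort"))
  utils::write.csv(cohort$volumes, volumes_path, row.names = FALSE)
  utils::write.csv(cohort$covariates, covariates_path, row.names = FALSE)
  if (!is.null(atlas_path))
    utils::write.csv(as.data.frame(unclass(cohort$atlas))[
      c("roi", "hemisphere", "network")], atlas_path, row.names = FALSE)
  invisible(cohort)
}

#' @export
print.mcn_cohort <- function(x, ...) {
  cat("MCN cohort:", nrow(x$volumes), "subjects,", nrow(x$atlas),
      "ROIs, scans at mean",
      sprintf("%.1f and %.1f weeks\n", mean(x$volumes$age_scan1_weeks),
              mean(x$volumes$age_scan2_weeks)))
  invisible(x)
}
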