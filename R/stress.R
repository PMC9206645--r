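#' Standardized early-life-stress exposure scores
#'
#' Operationalizes early-life stress in a NICU cohort as the cumulative
#' number of invasive procedures (skin-breaking procedures, days of
#' ventilation and cerebral monitoring, suctioning, ...) accrued up to the
#' first scan, weighted by the duration of the NICU stay.  The weighted
#' score is the per-day procedure rate `count / days`; it is then
#' standardized to zero mean and unit SD over the cohort so that group
#' splits can be expressed on a common z-scale.
#'
#' @param subject_id character vector of subject identifiers.
#' @param procedures non-negative invasive-procedure counts, one per
#'   subject.
#' @param nicu_days positive NICU-stay durations (days) up to the first
#'   scan.
#' @param sd_type `"population"` (divisor n, the default) or `"sample"`
#'   (divisor n - 1) for the standardization SD.
#' @return A data frame of class `mcn_stress` with columns `subject_id`,
#'   `procedures`, `nicu_days`, `weighted` (procedures per day) and `score`
#'   (standardized weighted score, mean 0 / SD 1 over the cohort).
#' @export
compute_stress_scores <- function(subject_id, procedures, nicu_days,
                                  sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  subject_id <- as.character(subject_id)
  n <- length(subject_id)
  if (length(procedures) != n || length(nicu_days) != n)
    stop("subject_id, procedures and nicu_days must have equal length",
         call. = FALSE)
  if (any(procedures < 0))
    stop("negative procedure count for subject(s): ",
         paste(subject_id[procedures < 0], collapse = ", "), call. = FALSE)
  bad <- nicu_days <= 0
  if (any(bad))
    stop("NICU days must be positive; offending subject(s): ",
         paste(subject_id[bad], collapse = ", "), call. = FALSE)
  w <- procedures / nicu_days
  s <- if (sd_type == "population")
    sqrt(mean((w - mean(w))^2)) else stats::sd(w)
  if (!is.finite(s) || s == 0)
    stop("weighted stress scores are constant; standardization undefined",
         call. = FALSE)
  out <- data.frame(subject_id = subject_id, procedures = procedures,
                    nicu_days = nicu_days, weighted = w,
                    score = (w - mean(w)) / s, stringsAsFactors = FALSE)
  class(out) <- c("mcn_stress", "data.frame")
  out
}

#' Assign stress-exposure groups
#'
#' Splits a cohort into stress-exposure groups by one of three schemes:
#'
#' * `"median"` — lowest 50% of scores -> `low`, highest 50% -> `high`
#'   (with odd n the extra subject goes to `high`);
#' * `"zero_mean"` — standardized score < 0 -> `low`, >= 0 -> `high`;
#' * `"tertile"` — thirds by rank -> `low` / `mild` / `high`.
#'
#' Rank-based schemes order subjects by `(score, subject_id)`; at a tied
#' boundary the lower-sorting subject goes to the lower group, so group
#' sizes are reproducible for any input.
#'
#' @param scores an `mcn_stress` table from [compute_stress_scores()], or
#'   any data frame with `subject_id` and `score` columns.
#' @param scheme `"median"`, `"zero_mean"` or `"tertile"`.
#' @return Factor of group labels aligned with `scores` rows (levels
#'   `low`/`high`, or `low`/`mild`/`high` for tertile).
#' @export
assign_groups <- function(scores, scheme = c("median", "zero_mean", "tertile")) {
  scheme <- match.arg(scheme)
  stopifnot(is.data.frame(scores), all(c("subject_id", "score") %in% names(scores)))
  n <- nrow(scores)
  ord <- order(scores$score, scores$subject_id, method = "radix")
  rank <- integer(n); rank[ord] <- seq_len(n)
  g <- switch(scheme,
    median = {
      n_low <- n %/% 2L
      factor(ifelse(rank <= n_low, "low", "high"), levels = c("low", "high"))
    },
    zero_mean = factor(ifelse(scores$score < 0, "low", "high"),
                       levels = c("low", "high")),
    tertile = {
      b1 <- round(n / 3); b2 <- round(2 * n / 3)
      factor(ifelse(rank <= b1, "low", ifelse(rank <= b2, "mild", "high")),
             levels = c("low", "mild", "high"))
    })
  tab <- table(g)
  if (any(tab < 2L))
    stop("group(s) with fewer than 2 subjects: ",
         paste(names(tab)[tab < 2L], collapse = ", "), call. = FALSE)
  g
}
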