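#' Compare maturational covariance networks between stress-exposure groups
#'
#' End-to-end analysis: early-life-stress scoring and group assignment,
#' annualized growth rates, covariate adjustment via studentized residuals,
#' group-level association matrices, equal-density thresholding over a
#' density sweep, label-permutation inference on within/between-network
#' connection counts with FDR correction, and the secondary edge-wise
#' Fisher r-to-z comparison.
#'
#' @param cohort an `mcn_cohort` from [load_cohort()], [as_cohort()] or
#'   [simulate_cohort()]`$cohort`.
#' @param stress optional data frame `subject_id`, `procedures`,
#'   `nicu_days` used to score stress and split groups (see
#'   [compute_stress_scores()]).  Exactly one of `stress` or `groups` must
#'   be supplied.
#' @param groups optional two-level group labels per cohort subject,
#'   bypassing stress scoring.
#' @param scheme group-splitting scheme for `stress` input
#'   (see [assign_groups()]); must yield two groups, so `"median"` or
#'   `"zero_mean"`.
#' @param densities density sweep (default 0.10 to 0.30 in 0.01 steps).
#' @param report_K reporting density (default 0.20).
#' @param n_perm number of label permutations (default 5000).
#' @param seed RNG seed for the permutation draw.
#' @param type,adjust studentization options, see [studentized_rates()].
#' @param rank_by,tail thresholding/p-value options, see
#'   [permutation_test()].
#' @param r_min,edge_filter edge-level filter options, see
#'   [compare_edge_correlations()].
#' @return Object of class `mcn_comparison`: a list with `atlas`, `groups`,
#'   `scores` (or NULL), `rates` (studentized), `assoc` (per-group
#'   `mcn_association`s), `deltas` (the [density_sweep_report()] table),
#'   `edges` (the [compare_edge_correlations()] table), `report_K`,
#'   `n_perm`, `seed`, `call`.
#' @seealso [print.mcn_comparison()], [summary.mcn_comparison()],
#'   [coef.mcn_comparison()], [plot.mcn_comparison()]
#' @examples
#' sim <- simulate_cohort(sim_config(n_per_group = 30, seed = 7))
#' fit <- mcn_compare(sim$cohort, stress = sim$stress,
#'                    densities = 0.20, n_perm = 200, seed = 7)
#' fit
#' coef(fit)
#' @export
mcn_compare <- function(cohort, stress = NULL, groups = NULL,
                        scheme = c("median", "zero_mean"),
                        densities = seq(0.10, 0.30, by = 0.01),
                        report_K = 0.20, n_perm = 5000L, seed = 1L,
                        type = c("external", "internal"),
                        adjust = c("rates", "volumes"),
                        rank_by = c("signed", "absolute"),
                        tail = c("absolute", "doubled"),
                        r_min = 0.10, edge_filter = c("both", "either")) {
  stopifnot(inherits(cohort, "mcn_cohort"))
  scheme <- match.arg(scheme)
  if (is.null(stress) == is.null(groups))
    stop("supply exactly one of 'stress' or 'groups'", call. = FALSE)

  scores <- NULL
  if (!is.null(stress)) {
    stress <- stress[match(cohort$volumes$subject_id, stress$subject_id), ]
    if (anyNA(stress$subject_id))
      stop("stress table does not cover every cohort subject", call. = FALSE)
    scores <- compute_stress_scores(stress$subject_id, stress$procedures,
                                    stress$nicu_days)
    groups <- assign_groups(scores, scheme)
  }
  groups <- group_factor(groups)

  rates <- studentized_rates(cohort, type = match.arg(type),
                             adjust = match.arg(adjust))
  if (!any(abs(densities - report_K) < 1e-9))
    densities <- sort(c(densities, report_K))
  res <- permutation_test(rates, groups, K_values = densities,
                          n_perm = n_perm, seed = seed, atlas = cohort$atlas,
                          rank_by = match.arg(rank_by),
                          tail = match.arg(tail))
  deltas <- density_sweep_report(res, report_K)

  lo <- levels(groups)[1L]; hi <- levels(groups)[2L]
  assoc <- list(low = build_mcn(rates, groups == lo, group = lo),
                high = build_mcn(rates, groups == hi, group = hi))
  edges <- compare_edge_correlations(assoc$low, assoc$high, cohort$atlas,
                                     r_min = r_min,
                                     filter = match.arg(edge_filter))

  structure(list(atlas = cohort$atlas, groups = groups, scores = scores,
                 rates = rates, assoc = assoc, deltas = deltas,
                 edges = edges, report_K = report_K, n_perm = n_perm,
                 seed = seed, call = match.call()),
            class = "mcn_comparison")
}

report_rows <- function(x) x$deltas[x$deltas$is_report, , drop = FALSE]

#' @describeIn mcn_compare Print the block-level differences at the
#'   reporting density.
#' @param x,object an `mcn_comparison`.
#' @param ... unused.
#' @export
print.mcn_comparison <- function(x, ...) {
  tab <- report_rows(x)
  cat("Maturational covariance network comparison\n")
  cat(sprintf("  groups: %s (n = %d) vs %s (n = %d); %d permutations\n",
              levels(x$groups)[1L], sum(x$groups == levels(x$groups)[1L]),
              levels(x$groups)[2L], sum(x$groups == levels(x$groups)[2L]),
              x$n_perm))
  cat(sprintf("  coupling differences (high - low) at density K = %.2f:\n",
              x$report_K))
  out <- data.frame(block = as.character(tab$block), delta = tab$delta,
                    p = signif(tab$p, 3), q = signif(tab$q, 3))
  print(out, row.names = FALSE)
  invisible(x)
}

#' @describeIn mcn_compare Block-level table plus sweep-robustness and
#'   edge-level significance summaries.
#' @export
summary.mcn_comparison <- function(object, ...) {
  tab <- report_rows(object)
  sig_edges <- sum(object$edges$q < 0.05, na.rm = TRUE)
  out <- list(report = tab,
              n_densities = length(unique(object$deltas$K)),
              sig_edges = sig_edges,
              n_included_edges = sum(!object$edges$excluded))
  class(out) <- "summary.mcn_comparison"
  out
}

#' @export
print.summary.mcn_comparison <- function(x, ...) {
  cat("Block-level coupling differences at the reporting density:\n")
  tab <- x$report
  print(data.frame(block = as.character(tab$block), delta = tab$delta,
                   p = signif(tab$p, 3), q = signif(tab$q, 3),
                   sign_consistency = round(tab$sign_consistency, 2),
                   sig_consistency = round(tab$sig_consistency, 2)),
        row.names = FALSE)
  cat(sprintf("Density sweep: %d densities; edge-level: %d of %d included edges with q < 0.05\n",
              x$n_densities, x$sig_edges, x$n_included_edges))
  invisible(x)
}

#' @describeIn mcn_compare Named vector of block Deltas at the reporting
#'   density.
#' @export
coef.mcn_comparison <- function(object, ...) {
  tab <- report_rows(object)
  stats::setNames(tab$delta, as.character(tab$block))
}

#' @describeIn mcn_compare Delta across the density sweep per block, with
#'   the permutation 95% band and the reporting density marked.
#' @export
plot.mcn_comparison <- function(x, ...) {
  d <- x$deltas
  blocks <- levels(d$block)
  old <- graphics::par(mfrow = c(2, ceiling(length(blocks) / 2)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (b in blocks) {
    db <- d[d$block == b, ]
    ylim <- range(db$delta, db$perm_lo95, db$perm_hi95)
    graphics::plot(db$K, db$delta, type = "b", pch = 19,
                   xlab = "density K", ylab = expression(Delta),
                   main = b, ylim = ylim, ...)
    graphics::polygon(c(db$K, rev(db$K)),
                      c(db$perm_lo95, rev(db$perm_hi95)),
                      col = grDevices::adjustcolor("gray", 0.4), border = NA)
    graphics::lines(db$K, db$perm_mean, lty = 2, col = "gray40")
    graphics::abline(v = x$report_K, lty = 3)
    graphics::abline(h = 0, col = "gray70")
  }
  invisible(x)
}
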