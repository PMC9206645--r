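#' Edge-wise comparison of two groups' correlation matrices
#'
#' Secondary, region-level analysis: for every ROI pair, the two groups'
#' correlations are compared with the independent-samples Fisher r-to-z
#' statistic
#' `Z = (atanh(r_high) - atanh(r_low)) / sqrt(1/(n_high - 3) + 1/(n_low - 3))`,
#' with a two-sided normal p-value and BH-FDR across the included edges.
#' Spurious correlations are filtered before transformation: by default an
#' edge is excluded when `|r| < r_min` in *both* groups (excluding an edge
#' that is strong in one group only would hide exactly the
#' coupling/decoupling effects of interest; `filter = "either"` drops an
#' edge as soon as one group is below threshold).  The filter is on |r|, so
#' strong negative correlations are never silently discarded.
#'
#' @param mcn_low,mcn_high `mcn_association` objects (see [build_mcn()])
#'   over the same atlas, for the low- and high-exposure group.
#' @param atlas the common [mcn_atlas()].
#' @param r_min spurious-correlation threshold (default 0.10).
#' @param filter `"both"` (default) or `"either"`: which groups must be
#'   below `r_min` for an edge to be excluded.
#' @return Data frame of class `mcn_edges`, one row per ROI pair: `roi_i`,
#'   `roi_j`, `block`, `r_low`, `r_high`, `n_low`, `n_high`, `excluded`,
#'   `reason`, `Z`, `p`, `q` (Z/p/q are `NA` for excluded edges).
#' @export
compare_edge_correlations <- function(mcn_low, mcn_high, atlas,
                                      r_min = 0.10,
                                      filter = c("both", "either")) {
  filter <- match.arg(filter)
  stopifnot(inherits(mcn_low, "mcn_association"),
            inherits(mcn_high, "mcn_association"),
            inherits(atlas, "mcn_atlas"))
  if (!identical(dim(mcn_low$r), dim(mcn_high$r)) ||
      nrow(mcn_low$r) != nrow(atlas) ||
      !identical(colnames(mcn_low$r), atlas$roi) ||
      !identical(colnames(mcn_high$r), atlas$roi))
    stop("association matrices and atlas do not match", call. = FALSE)
  if (mcn_low$n <= 3L || mcn_high$n <= 3L)
    stop("Fisher r-to-z comparison needs more than 3 subjects per group",
         call. = FALSE)

  edges <- edge_universe(atlas)
  cells <- cbind(edges$idx_i, edges$idx_j)
  r_lo <- mcn_low$r[cells]
  r_hi <- mcn_high$r[cells]
  below_lo <- abs(r_lo) < r_min
  below_hi <- abs(r_hi) < r_min
  excluded <- if (filter == "both") below_lo & below_hi else below_lo | below_hi
  reason <- ifelse(excluded,
                   paste0("|r| < ", format(r_min), " in ",
                          ifelse(below_lo & below_hi, "both groups",
                                 ifelse(below_lo, "low group", "high group"))),
                   NA_character_)

  se <- sqrt(1 / (mcn_high$n - 3) + 1 / (mcn_low$n - 3))
  Z <- (atanh(clip_r(r_hi)) - atanh(clip_r(r_lo))) / se
  p <- 2 * stats::pnorm(-abs(Z))
  Z[excluded] <- NA_real_
  p[excluded] <- NA_real_
  q <- rep(NA_real_, length(p))
  if (any(!excluded))
    q[!excluded] <- fdr_adjust(pmax(p[!excluded], .Machine$double.xmin))

  out <- data.frame(roi_i = edges$roi_i, roi_j = edges$roi_j,
                    block = edges$block,
                    r_low = r_lo, r_high = r_hi,
                    n_low = mcn_low$n, n_high = mcn_high$n,
                    excluded = excluded, reason = reason,
                    Z = Z, p = p, q = q, stringsAsFactors = FALSE)
  class(out) <- c("mcn_edges", "data.frame")
  out
}
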