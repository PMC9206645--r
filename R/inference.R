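#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values (q-values) with enforced monotonicity, capped
#' at 1, computed via [stats::p.adjust()] with `method = "BH"` after input
#' validation.
#'
#' @param p numeric vector of p-values in (0, 1].
#' @return q-values, same length and order as `p`.
#' @export
fdr_adjust <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0 | p > 1))
    stop("p-values must be finite and in (0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}

# Precomputed edge bookkeeping for the fast permutation path.
edge_info <- function(atlas) {
  edges <- edge_universe(atlas)
  n <- nrow(atlas)
  list(cells = cbind(edges$idx_i, edges$idx_j),
       block = as.integer(edges$block),
       nblocks = nlevels(edges$block),
       block_names = levels(edges$block),
       n_edges = nrow(edges))
}

# Per-block retained-edge counts for one group at each density.  Ranking is
# on r, which is monotone-equivalent to ranking on Fisher z; edges are in
# lexicographic order, so the tie-break index reproduces threshold_binarize.
block_counts_fast <- function(rates_sub, info, mvec, absolute = FALSE) {
  r <- suppressWarnings(stats::cor(rates_sub))
  w <- r[info$cells]
  if (absolute) w <- abs(w)
  ord <- order(-w, seq_len(info$n_edges), na.last = TRUE)
  vapply(mvec, function(m)
    tabulate(info$block[ord[seq_len(m)]], nbins = info$nblocks),
    integer(info$nblocks))
}

#' Permutation test of within/between-network coupling differences
#'
#' The headline analysis: for the observed group labels and for `n_perm`
#' random relabelings (shuffles preserving group sizes), the full pipeline —
#' per-group association matrix, equal-density thresholding at each K,
#' block counting, high-minus-low difference Delta — is recomputed.  The
#' two-tailed p-value of each block x density cell is the add-one smoothed
#' percentile position of the observed |Delta| in the permutation
#' distribution, `p = (1 + #{|Delta_perm| >= |Delta_obs|}) / (1 + n_perm)`,
#' and the six block p-values within each density are FDR-adjusted
#' (Benjamini-Hochberg).
#'
#' @param rates subjects x ROIs matrix of studentized trajectories.
#' @param labels two-level group labels per subject (see [coupling_delta()]).
#' @param K_values numeric vector of densities, each in (0, 1].
#' @param n_perm number of permutations, `>= 100`.
#' @param seed integer RNG seed; identical seeds give identical results.
#' @param atlas an [mcn_atlas()].
#' @param rank_by `"signed"` (default) or `"absolute"` edge ranking.
#' @param tail `"absolute"` (default; two-tailed via |Delta|) or `"doubled"`
#'   (twice the smaller one-sided percentile p, capped at 1).
#' @return Data frame of class `mcn_delta`, one row per block x density:
#'   `block`, `K`, `delta`, `perm_mean`, `perm_lo95`, `perm_hi95`
#'   (permutation-distribution mean and central 95% band), `p`, `q`,
#'   `n_perm`, `seed`.
#' @export
permutation_test <- function(rates, labels, K_values = seq(0.10, 0.30, by = 0.01),
                             n_perm = 5000L, seed = 1L,
                             atlas = default_atlas(),
                             rank_by = c("signed", "absolute"),
                             tail = c("absolute", "doubled")) {
  rank_by <- match.arg(rank_by); tail <- match.arg(tail)
  stopifnot(is.matrix(rates))
  if (nrow(rates) != length(labels))
    stop("labels length must match subject count", call. = FALSE)
  if (n_perm < 100L)
    stop("n_perm must be at least 100", call. = FALSE)
  if (any(K_values <= 0 | K_values > 1))
    stop("densities must lie in (0, 1]", call. = FALSE)
  labels <- group_factor(labels)
  if (nrow(rates) != ncol(rates) && ncol(rates) != nrow(atlas))
    stop("rate matrix has ", ncol(rates), " ROIs but atlas has ",
         nrow(atlas), call. = FALSE)

  info <- edge_info(atlas)
  mvec <- floor(K_values * info$n_edges + 0.5)
  absolute <- rank_by == "absolute"
  lo <- levels(labels)[1L]

  delta_for <- function(lab) {
    block_counts_fast(rates[lab != lo, , drop = FALSE], info, mvec, absolute) -
      block_counts_fast(rates[lab == lo, , drop = FALSE], info, mvec, absolute)
  }

  obs <- delta_for(labels)                       # nblocks x nK
  set.seed(seed)
  perm <- array(NA_real_, dim = c(info$nblocks, length(K_values), n_perm))
  for (b in seq_len(n_perm)) perm[, , b] <- delta_for(sample(labels))

  if (tail == "absolute") {
    exceed <- apply(abs(perm) >= rep(abs(obs), n_perm), c(1L, 2L), sum)
    p <- (1 + exceed) / (1 + n_perm)
  } else {
    ge <- apply(perm >= rep(obs, n_perm), c(1L, 2L), sum)
    le <- apply(perm <= rep(obs, n_perm), c(1L, 2L), sum)
    p <- array(pmin(1, 2 * pmin((1 + ge) / (1 + n_perm),
                                 (1 + le) / (1 + n_perm))), dim = dim(ge))
  }
  q <- apply(p, 2L, fdr_adjust)

  out <- data.frame(
    block = factor(rep(info$block_names, times = length(K_values)),
                   levels = info$block_names),
    K = rep(K_values, each = info$nblocks),
    delta = as.integer(obs),
    perm_mean = as.vector(apply(perm, c(1L, 2L), mean)),
    perm_lo95 = as.vector(apply(perm, c(1L, 2L), stats::quantile, 0.025)),
    perm_hi95 = as.vector(apply(perm, c(1L, 2L), stats::quantile, 0.975)),
    p = as.vector(p), q = as.vector(q),
    n_perm = n_perm, seed = seed)
  class(out) <- c("mcn_delta", "data.frame")
  out
}

#' Summarize a density sweep around a reporting density
#'
#' Organizes [permutation_test()] results into a per-block, per-density
#' table and flags the reporting density.  For each block, two robustness
#' summaries are attached: `sign_consistency`, the fraction of densities
#' whose Delta sign matches the sign at the reporting density, and
#' `sig_consistency`, the fraction of densities where that sign matches
#' *and* q < 0.05.
#'
#' @param results an `mcn_delta` data frame from [permutation_test()].
#' @param report_K the density highlighted in reporting (must be present in
#'   `results`).
#' @return The `results` table with added columns `is_report`,
#'   `sign_consistency`, `sig_consistency`.
#' @export
density_sweep_report <- function(results, report_K = 0.20) {
  stopifnot(inherits(results, "mcn_delta") || is.data.frame(results))
  hit <- abs(results$K - report_K) < 1e-9
  if (!any(hit))
    stop("reporting density ", report_K, " not present in results",
         call. = FALSE)
  ref <- results[hit, c("block", "delta")]
  ref_sign <- stats::setNames(sign(ref$delta), as.character(ref$block))
  sgn_match <- sign(results$delta) == ref_sign[as.character(results$block)]
  out <- results
  out$is_report <- hit
  agg <- function(v) stats::ave(v, as.character(results$block), FUN = mean)
  out$sign_consistency <- agg(as.numeric(sgn_match))
  out$sig_consistency <- agg(as.numeric(sgn_match & results$q < 0.05))
  out
}
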