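#' Fisher's r-to-z transformation
#'
#' `z = atanh(r) = 0.5 * log((1 + r) / (1 - r))`, the variance-stabilizing
#' transform under which correlation differences between independent
#' samples are approximately normal with variance `1/(n-3)`.
#'
#' @param r correlation value(s), `|r| < 1`.
#' @return z value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1))
    stop("fisher_z requires |r| < 1", call. = FALSE)
  atanh(r)
}

# correlations from degenerate draws are clipped before atanh so that
# permutation loops survive perfect correlations in tiny samples
clip_r <- function(r, eps = 1e-7) {
  hit <- abs(r) >= 1 - eps
  if (any(hit, na.rm = TRUE)) {
    warning("clipped ", sum(hit, na.rm = TRUE),
            " near-perfect correlation(s) to +/-(1 - 1e-7) before atanh",
            call. = FALSE)
    r[which(hit)] <- sign(r[which(hit)]) * (1 - eps)
  }
  r
}

#' Build a maturational covariance network (association matrix)
#'
#' The group-level MCN is the ROIs x ROIs matrix of across-subject Pearson
#' correlations of studentized growth trajectories: entry `r_ij` is the
#' correlation between the trajectory of region i and region j over the
#' selected subjects.  The diagonal is set to zero.  A companion Fisher-z
#' matrix (`atanh` entrywise off-diagonal, after clipping near-perfect
#' correlations to +/-(1 - 1e-7)) is stored alongside.
#'
#' @param rates subjects x ROIs matrix (typically [studentized_rates()]).
#' @param subjects optional subset selector (logical, integer or rowname
#'   character vector); default all rows.
#' @param group optional group label stored on the result.
#' @return List of class `mcn_association` with elements `r` (correlations,
#'   zero diagonal), `z` (Fisher z, zero diagonal), `n` (subjects used) and
#'   `group`.
#' @export
build_mcn <- function(rates, subjects = NULL, group = NA_character_) {
  stopifnot(is.matrix(rates))
  sub <- if (is.null(subjects)) rates else rates[subjects, , drop = FALSE]
  if (nrow(sub) < 4L)
    stop("at least 4 subjects are required (got ", nrow(sub), ")",
         call. = FALSE)
  sds <- apply(sub, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance trajectory for ROI(s): ",
         paste(colnames(sub)[sds == 0], collapse = ", "), call. = FALSE)
  r <- stats::cor(sub)
  diag(r) <- 0
  z <- atanh(clip_r(r))
  diag(z) <- 0
  structure(list(r = r, z = z, n = nrow(sub), group = group),
            class = "mcn_association")
}

#' @export
print.mcn_association <- function(x, ...) {
  off <- x$r[upper.tri(x$r)]
  cat(sprintf(
    "MCN association matrix: %d ROIs, n = %d subjects%s; off-diagonal r in [%.3f, %.3f]\n",
    nrow(x$r), x$n,
    if (is.na(x$group)) "" else paste0(" (group ", x$group, ")"),
    min(off), max(off)))
  invisible(x)
}

#' Threshold and binarize an association matrix at a fixed density
#'
#' Ranks the off-diagonal edge weights by signed Fisher z, descending
#' (strongest positive covariance first), and retains the top
#' `m = round(K * n_edges)` edges (half-up rounding) as 1, all others 0 —
#' i.e. equal network density K for every matrix thresholded at the same K.
#' Ties are broken by lexicographic `(roi_i, roi_j)` order so the retained
#' set is deterministic.  `rank_by = "absolute"` ranks on `|z|` instead.
#'
#' @param mcn an `mcn_association` from [build_mcn()].
#' @param K density, fraction of edges retained, `0 < K <= 1`.
#' @param atlas the [mcn_atlas()] the matrix was built over.
#' @param rank_by `"signed"` (default) or `"absolute"` edge ranking.
#' @return List of class `mcn_binary_network`: `adjacency` (0/1 symmetric,
#'   zero diagonal), `K`, `m` (retained edge count), `retained` (logical
#'   over the [edge_universe()] rows), `edges` (the edge universe).
#' @export
threshold_binarize <- function(mcn, K, atlas,
                               rank_by = c("signed", "absolute")) {
  rank_by <- match.arg(rank_by)
  stopifnot(inherits(mcn, "mcn_association"), inherits(atlas, "mcn_atlas"))
  if (!is.numeric(K) || length(K) != 1L || K <= 0 || K > 1)
    stop("density K must be a single value in (0, 1]", call. = FALSE)
  if (nrow(mcn$r) != nrow(atlas))
    stop("matrix dimension does not match atlas", call. = FALSE)
  edges <- edge_universe(atlas)
  w <- mcn$z[cbind(edges$idx_i, edges$idx_j)]
  if (rank_by == "absolute") w <- abs(w)
  m <- floor(K * nrow(edges) + 0.5)
  ord <- order(-w, seq_len(nrow(edges)))  # edges are lexicographic already
  retained <- logical(nrow(edges))
  retained[ord[seq_len(m)]] <- TRUE
  adj <- matrix(0L, nrow(atlas), nrow(atlas),
                dimnames = list(atlas$roi, atlas$roi))
  adj[cbind(edges$idx_i[retained], edges$idx_j[retained])] <- 1L
  adj[cbind(edges$idx_j[retained], edges$idx_i[retained])] <- 1L
  structure(list(adjacency = adj, K = K, m = m, retained = retained,
                 edges = edges),
            class = "mcn_binary_network")
}

#' Count retained connections per network block
#'
#' Each retained edge falls in exactly one block — within-SN, within-DMN,
#' within-ECN, or one of the between-network blocks — so the counts
#' partition the retained edge set and always sum to `m`.
#'
#' @param net an `mcn_binary_network` from [threshold_binarize()].
#' @param atlas the matching [mcn_atlas()].
#' @return Named integer vector of counts per block (in [edge_universe()]
#'   block-level order).
#' @export
count_connections <- function(net, atlas) {
  stopifnot(inherits(net, "mcn_binary_network"), inherits(atlas, "mcn_atlas"))
  if (nrow(net$adjacency) != nrow(atlas))
    stop("network dimension does not match atlas", call. = FALSE)
  edges <- net$edges
  counts <- tabulate(as.integer(edges$block[net$retained]),
                     nbins = nlevels(edges$block))
  names(counts) <- levels(edges$block)
  stopifnot(sum(counts) == net$m)  # partition invariant
  counts
}

#' Observed between-group coupling difference per block
#'
#' Builds one association matrix per group from the same rate matrix,
#' thresholds both at the same density K, counts within/between-network
#' connections and returns `count_high - count_low` per block.  Positive
#' values mean higher coupling in the `high` group.  Because both networks
#' retain exactly m edges, the six differences always sum to zero.
#'
#' @param rates subjects x ROIs matrix of studentized trajectories.
#' @param labels factor/character of group labels per subject with exactly
#'   two levels; the *second* level (or `"high"` if present) is the
#'   high-exposure group.
#' @param K density fraction.
#' @param atlas an [mcn_atlas()].
#' @param rank_by edge ranking rule, see [threshold_binarize()].
#' @return Named integer vector of per-block count differences.
#' @export
coupling_delta <- function(rates, labels, K, atlas,
                           rank_by = c("signed", "absolute")) {
  rank_by <- match.arg(rank_by)
  labels <- group_factor(labels)
  lo <- levels(labels)[1L]; hi <- levels(labels)[2L]
  counts <- lapply(c(lo, hi), function(g) {
    mcn <- build_mcn(rates, subjects = labels == g, group = g)
    count_connections(threshold_binarize(mcn, K, atlas, rank_by), atlas)
  })
  delta <- counts[[2L]] - counts[[1L]]
  stopifnot(sum(delta) == 0L)  # equal-density invariant
  delta
}

# normalize labels to a two-level factor, low level first
group_factor <- function(labels) {
  f <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  if (nlevels(f) != 2L)
    stop("exactly two groups are required (got levels: ",
         paste(levels(f), collapse = ", "), ")", call. = FALSE)
  if (all(c("low", "high") %in% levels(f)))
    f <- factor(f, levels = c("low", "high"))
  if (any(table(f) < 4L))
    stop("each group needs at least 4 subjects", call. = FALSE)
  f
}
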