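#' Construct a network atlas
#'
#' An atlas maps regions of interest (ROIs) to a hemisphere and to one of a
#' set of large-scale brain networks.  The association matrices, edge
#' universe and all within/between-network counts of the pipeline are
#' defined relative to an atlas.
#'
#' @param roi character vector of unique ROI identifiers.
#' @param hemisphere character vector, `"left"` or `"right"`, one per ROI.
#' @param network character vector, network membership per ROI (e.g. `"SN"`,
#'   `"DMN"`, `"ECN"`).  Each ROI belongs to exactly one network.
#'
#' @return A data frame of class `mcn_atlas` with columns `roi`,
#'   `hemisphere`, `network`.  Row order is the canonical node order used by
#'   every matrix in the pipeline.
#'
#' @seealso [default_atlas()], [edge_universe()], [read_atlas()]
#' @export
mcn_atlas <- function(roi, hemisphere, network) {
  roi <- as.character(roi)
  hemisphere <- as.character(hemisphere)
  network <- as.character(network)
  if (length(roi) < 2L)
    stop("an atlas needs at least 2 ROIs", call. = FALSE)
  if (length(hemisphere) != length(roi) || length(network) != length(roi))
    stop("roi, hemisphere and network must have equal length", call. = FALSE)
  if (anyDuplicated(roi))
    stop("duplicated ROI identifiers: ",
         paste(unique(roi[duplicated(roi)]), collapse = ", "), call. = FALSE)
  bad <- !hemisphere %in% c("left", "right")
  if (any(bad))
    stop("hemisphere must be 'left' or 'right' (offending ROI: ",
         paste(roi[bad], collapse = ", "), ")", call. = FALSE)
  if (any(is.na(network)) || any(!nzchar(network)))
    stop("every ROI must have a non-empty network label", call. = FALSE)
  out <- data.frame(roi = roi, hemisphere = hemisphere, network = network,
                    stringsAsFactors = FALSE)
  class(out) <- c("mcn_atlas", "data.frame")
  out
}

#' The default 32-node SN/DMN/ECN atlas
#'
#' Thirty-two regional gray-matter volume measurements, 16 per hemisphere,
#' covering key nodes of three canonical large-scale networks: the salience
#' network (SN: amygdala, anterior cingulate cortex, insula, thalamus,
#' subthalamic nucleus, lentiform nucleus), the default mode network (DMN:
#' posterior cingulate gyrus, hippocampus, anterior/posterior
#' parahippocampal gyrus, anterior/posterior fusiform) and the executive
#' control network (ECN: frontal lobe, parietal lobe, cerebellum, caudate
#' nucleus).  Node counts are 12 (SN), 12 (DMN) and 8 (ECN), giving an edge
#' universe of choose(32, 2) = 496 unordered pairs.
#'
#' @return An `mcn_atlas` with 32 rows.
#' @export
default_atlas <- function() {
  regions <- list(
    SN  = c("amygdala", "anterior_cingulate", "insula", "thalamus",
            "subthalamic_nucleus", "lentiform_nucleus"),
    DMN = c("posterior_cingulate", "hippocampus",
            "parahippocampal_anterior", "parahippocampal_posterior",
            "fusiform_anterior", "fusiform_posterior"),
    ECN = c("frontal_lobe", "parietal_lobe", "cerebellum", "caudate_nucleus")
  )
  roi <- character(0); hemi <- character(0); net <- character(0)
  for (nw in names(regions)) {
    for (rg in regions[[nw]]) {
      roi <- c(roi, paste0(rg, "_left"), paste0(rg, "_right"))
      hemi <- c(hemi, "left", "right")
      net <- c(net, nw, nw)
    }
  }
  mcn_atlas(roi, hemi, net)
}

#' Read an atlas from a CSV file
#'
#' The file must have columns `roi`, `hemisphere`, `network`.
#'
#' @param path path to a CSV file.
#' @return An `mcn_atlas`.
#' @export
read_atlas <- function(path) {
  if (!file.exists(path)) stop("atlas file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("roi", "hemisphere", "network")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("atlas file missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  mcn_atlas(df$roi, df$hemisphere, df$network)
}

#' @export
print.mcn_atlas <- function(x, ...) {
  cat("MCN atlas:", nrow(x), "ROIs,",
      length(unique(x$network)), "networks (",
      paste(sprintf("%s=%d", names(table(x$network)), table(x$network)),
            collapse = ", "), ")\n")
  invisible(x)
}

# Canonical network order for block labels: the order in which networks
# first appear in the atlas.
atlas_networks <- function(atlas) unique(atlas$network)

#' Block label for a pair of networks
#'
#' Within-network blocks are labelled `within-<net>`; between-network blocks
#' `<netA>-<netB>` with networks in atlas order.
#' @noRd
block_label <- function(net_i, net_j, net_order) {
  ifelse(net_i == net_j, paste0("within-", net_i),
         ifelse(match(net_i, net_order) < match(net_j, net_order),
                paste(net_i, net_j, sep = "-"),
                paste(net_j, net_i, sep = "-")))
}

#' Enumerate the edge universe of an atlas
#'
#' All unordered distinct ROI pairs, each labelled by the block its
#' endpoints define (within-network for same-network pairs, a
#' network-pair label otherwise).  For the default atlas this yields 496
#' pairs in blocks of size 66 (within-SN), 66 (within-DMN), 28 (within-ECN),
#' 144 (SN-DMN), 96 (SN-ECN) and 96 (DMN-ECN).
#'
#' @param atlas an [mcn_atlas()].
#' @return A data frame with one row per unordered pair, lexicographically
#'   ordered by (`roi_i`, `roi_j`) with `roi_i < roi_j` as strings; columns
#'   `roi_i`, `roi_j`, `idx_i`, `idx_j` (row indices into the atlas) and
#'   `block` (factor whose levels list within-network blocks first, in atlas
#'   network order, then between-network blocks).
#' @export
edge_universe <- function(atlas) {
  stopifnot(inherits(atlas, "mcn_atlas"))
  n <- nrow(atlas)
  idx <- utils::combn(n, 2L)
  a <- atlas$roi[idx[1L, ]]
  b <- atlas$roi[idx[2L, ]]
  swap <- a > b
  roi_i <- ifelse(swap, b, a)
  roi_j <- ifelse(swap, a, b)
  ii <- ifelse(swap, idx[2L, ], idx[1L, ])
  jj <- ifelse(swap, idx[1L, ], idx[2L, ])
  nets <- atlas_networks(atlas)
  lab <- block_label(atlas$network[ii], atlas$network[jj], nets)
  levels <- c(paste0("within-", nets),
              if (length(nets) > 1L)
                utils::combn(nets, 2L, FUN = function(p) paste(p, collapse = "-")))
  ord <- order(roi_i, roi_j, method = "radix")
  out <- data.frame(roi_i = roi_i[ord], roi_j = roi_j[ord],
                    idx_i = ii[ord], idx_j = jj[ord],
                    block = factor(lab[ord], levels = levels),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Block sizes of an atlas
#'
#' Number of unordered ROI pairs in each within- and between-network block.
#' @param atlas an [mcn_atlas()].
#' @return Named integer vector over blocks; sums to choose(n_roi, 2).
#' @export
block_sizes <- function(atlas) {
  tab <- table(edge_universe(atlas)$block)
  stats::setNames(as.integer(tab), names(tab))
}
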