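# Connectome construction: band-pass filtering, motion-based exclusion,
# Fisher-z correlation matrices, and density-thresholded binary graph stacks.

#' Zero-phase band-pass filter for ROI time series
#'
#' Removes column means and applies a forward-backward (zero-phase)
#' Butterworth band-pass, the conventional temporal filter for resting-state
#' BOLD signals. The default band of 0.008-0.09 Hz retains the low-frequency
#' fluctuations that drive resting-state connectivity while discarding scanner
#' drift and respiratory/cardiac aliasing.
#'
#' @param timeseries Numeric matrix, time points in rows, ROIs in columns.
#' @param tr_seconds Sampling interval (repetition time) in seconds.
#' @param low_hz,high_hz Pass-band edges in Hz. Must satisfy
#'   `0 < low_hz < high_hz < 1/(2 * tr_seconds)` (the Nyquist frequency).
#' @param order Butterworth prototype order (default 2).
#' @return A matrix with the same dimensions and column names as the input.
#' @examples
#' ts <- matrix(rnorm(400), 100, 4)
#' filt <- bandpass_filter(ts, tr_seconds = 3)
#' @export
bandpass_filter <- function(timeseries, tr_seconds, low_hz = 0.008,
                            high_hz = 0.09, order = 2) {
  timeseries <- as.matrix(timeseries)
  if (!is.numeric(timeseries)) abort_validation("`timeseries` must be numeric.")
  nyquist <- 1 / (2 * tr_seconds)
  if (!(low_hz > 0 && low_hz < high_hz))
    abort_config("need 0 < low_hz < high_hz", field = "low_hz")
  if (high_hz >= nyquist)
    abort_config(sprintf("high_hz (%.4g Hz) must be below the Nyquist frequency (%.4g Hz)",
                         high_hz, nyquist), field = "high_hz")
  centred <- scale(timeseries, center = TRUE, scale = FALSE)
  bf <- signal::butter(order, c(low_hz, high_hz) / nyquist, type = "pass")
  out <- apply(centred, 2L, function(x) signal::filtfilt(bf, x))
  dimnames(out) <- dimnames(timeseries)
  out
}

#' Exclude high-motion subjects and censor flagged volumes
#'
#' Applies the motion quality-control rule: a subject is excluded when the
#' fraction of outlier-flagged volumes strictly exceeds `max_outlier_fraction`
#' (default 1/2, i.e. a subject with exactly half flagged is retained).
#' Flagged volumes of retained subjects are dropped from their time series.
#'
#' @param cohort A [generate_cohort()] / [read_cohort()] cohort object.
#' @param max_outlier_fraction Exclusion threshold on the flagged fraction.
#' @return A list with `kept` (the filtered cohort) and `excluded`
#'   (character vector of excluded subject ids).
#' @export
exclude_high_motion <- function(cohort, max_outlier_fraction = 0.5) {
  stopifnot(inherits(cohort, "redunet_cohort"))
  frac <- vapply(cohort$outlier_flags, mean, numeric(1))
  drop <- names(frac)[frac > max_outlier_fraction]
  keep <- setdiff(cohort$subjects$subject_id, drop)
  kept <- cohort
  kept$subjects <- dplyr::filter(cohort$subjects, !.data$subject_id %in% drop)
  kept$timeseries <- lapply(
    setNames(keep, keep),
    function(id) cohort$timeseries[[id]][!cohort$outlier_flags[[id]], , drop = FALSE]
  )
  kept$outlier_flags <- lapply(
    setNames(keep, keep),
    function(id) cohort$outlier_flags[[id]][!cohort$outlier_flags[[id]]]
  )
  rlang::inform(sprintf(
    "Motion QC: %d of %d subjects retained (%d excluded at >%.0f%% flagged volumes).",
    length(keep), length(frac), length(drop), 100 * max_outlier_fraction))
  list(kept = kept, excluded = drop)
}

new_connectivity <- function(values, node_ids, subject_id = NULL) {
  dimnames(values) <- list(node_ids, node_ids)
  structure(list(values = values, node_ids = node_ids, subject_id = subject_id),
            class = "redunet_connectivity")
}

#' @export
print.redunet_connectivity <- function(x, ...) {
  cat(sprintf("<redunet_connectivity> %d nodes%s\n", length(x$node_ids),
              if (is.null(x$subject_id)) "" else paste0(", subject ", x$subject_id)))
  invisible(x)
}

#' Fisher-z connectivity matrix from ROI time series
#'
#' Computes all pairwise Pearson correlations between ROI columns and applies
#' the Fisher z transform (`atanh`), the variance-stabilizing scale on which
#' edges are ranked for density thresholding. Perfect correlations are clipped
#' to `1 - clip_eps` before `atanh` so the matrix stays finite; any clipping
#' is reported as a warning.
#'
#' @param timeseries Numeric matrix, time points in rows, ROIs in columns
#'   (at least 3 rows; no constant columns).
#' @param node_ids Node labels; defaults to the column names, or `ROI###`.
#' @param subject_id Optional subject label carried along for bookkeeping.
#' @param clip_eps Clipping margin for |r| = 1 (default 1e-7).
#' @return A `redunet_connectivity` object: symmetric Fisher-z matrix with a
#'   zero diagonal plus node ids.
#' @examples
#' ts <- matrix(rnorm(300), 100, 3)
#' cm <- correlation_matrix(ts)
#' @export
correlation_matrix <- function(timeseries, node_ids = NULL, subject_id = NULL,
                               clip_eps = 1e-7) {
  timeseries <- as.matrix(timeseries)
  if (nrow(timeseries) < 3)
    abort_validation("`timeseries` needs at least 3 time points for a correlation.")
  n <- ncol(timeseries)
  ids <- node_ids %||% colnames(timeseries) %||% default_node_ids(n)
  sds <- apply(timeseries, 2L, sd)
  if (any(sds == 0))
    abort_validation(sprintf("Constant time series (undefined correlation) at node(s): %s",
                             paste(ids[sds == 0], collapse = ", ")))
  r <- cor(timeseries)
  hi <- abs(r) >= 1 - clip_eps
  diag(hi) <- FALSE
  if (any(hi)) {
    rlang::warn(sprintf("%d correlation(s) at |r| ~ 1 clipped before Fisher z.",
                        sum(hi) / 2))
    r[hi] <- sign(r[hi]) * (1 - clip_eps)
  }
  z <- atanh(r)
  diag(z) <- 0
  new_connectivity(z, ids, subject_id)
}

conn_values <- function(conn) {
  if (inherits(conn, "redunet_connectivity")) return(conn$values)
  if (is.matrix(conn) && nrow(conn) == ncol(conn)) return(conn)
  abort_validation("expected a `redunet_connectivity` object or a square matrix.")
}

# Upper-triangle edge order used everywhere: strongest signed z first, ties
# broken by ascending (i, j) node-index pairs so binarization is reproducible
# and nested across densities.
edge_order <- function(z) {
  ij <- which(upper.tri(z), arr.ind = TRUE)
  vals <- z[ij]
  ord <- order(-vals, ij[, 1L], ij[, 2L])
  ij[ord, , drop = FALSE]
}

#' Binarize a connectivity matrix at a fixed edge density
#'
#' Retains exactly `round(density * n * (n - 1) / 2)` edges — the strongest
#' signed Fisher-z values — so every subject's graph has an identical edge
#' count at a given density. Ties are broken by ascending (i, j) node order.
#'
#' @param conn A `redunet_connectivity` object or symmetric numeric matrix.
#' @param density Fraction of possible edges to retain, in (0, 1].
#' @return A symmetric 0/1 adjacency matrix with zero diagonal.
#' @examples
#' cm <- correlation_matrix(matrix(rnorm(500), 100, 5))
#' A <- binarize_at_density(cm, 0.2)
#' sum(A) / 2  # exactly round(0.2 * 10) edges
#' @export
binarize_at_density <- function(conn, density) {
  z <- conn_values(conn)
  n <- nrow(z)
  if (!(density > 0 && density <= 1))
    abort_config("density must lie in (0, 1]", field = "density")
  k <- round(density * n * (n - 1) / 2)
  if (k < 1)
    abort_config(sprintf("density %.4g retains zero edges for n = %d", density, n),
                 field = "density")
  keep <- edge_order(z)[seq_len(k), , drop = FALSE]
  A <- matrix(0, n, n, dimnames = dimnames(z))
  A[keep] <- 1
  A[keep[, c(2L, 1L), drop = FALSE]] <- 1
  A
}

#' Density-thresholded binary graph stack
#'
#' Binarizes one connectivity matrix at every density on a grid (default
#' 2.5% to 25% in 2.5% steps, ten levels). Because edges are ranked once,
#' the graphs are nested: the adjacency at a lower density is a subgraph of
#' every higher-density adjacency.
#'
#' @inheritParams binarize_at_density
#' @param grid Strictly increasing density grid within (0, 1].
#' @return A `redunet_graph_stack`: list with `densities`, `adjacencies`
#'   (one 0/1 matrix per density), `node_ids`, `subject_id`.
#' @export
density_stack <- function(conn, grid = density_grid()) {
  if (length(grid) < 1 || any(diff(grid) <= 0) || any(grid <= 0) || any(grid > 1))
    abort_config("grid must be strictly increasing within (0, 1]", field = "grid")
  z <- conn_values(conn)
  adjs <- lapply(grid, function(d) binarize_at_density(z, d))
  structure(
    list(densities = grid, adjacencies = adjs,
         node_ids = if (inherits(conn, "redunet_connectivity")) conn$node_ids
                    else colnames(z) %||% default_node_ids(nrow(z)),
         subject_id = if (inherits(conn, "redunet_connectivity")) conn$subject_id else NULL),
    class = "redunet_graph_stack")
}

#' Default density grid (2.5% to 25% in 2.5% steps)
#' @return Numeric vector of ten densities.
#' @export
density_grid <- function() seq(0.025, 0.25, by = 0.025)

#' @export
print.redunet_graph_stack <- function(x, ...) {
  cat(sprintf("<redunet_graph_stack> %d nodes, %d densities (%.3g-%.3g)\n",
              length(x$node_ids), length(x$densities),
              min(x$densities), max(x$densities)))
  invisible(x)
}

#' Overall functional connectivity of one ROI
#'
#' Mean Fisher-z connectivity of an ROI to all other nodes, used as a control
#' analysis: group effects on graph metrics should not be explained by crude
#' differences in underlying connectivity strength. Two variants are offered:
#' `positive_only` averages only positive edges (0, with a warning, if none),
#' `absolute` averages absolute values.
#'
#' @inheritParams binarize_at_density
#' @param roi Node id (character) or index of the ROI.
#' @param mode `"positive_only"` or `"absolute"`.
#' @return A single numeric value.
#' @export
overall_connectivity <- function(conn, roi, mode = c("positive_only", "absolute")) {
  mode <- match.arg(mode)
  z <- conn_values(conn)
  idx <- if (is.character(roi)) match(roi, rownames(z)) else as.integer(roi)
  if (is.na(idx) || idx < 1 || idx > nrow(z))
    abort_validation(sprintf("roi '%s' not found in the connectivity matrix.", roi))
  row <- z[idx, -idx]
  if (mode == "absolute") return(mean(abs(row)))
  pos <- row[row > 0]
  if (length(pos) == 0) {
    rlang::warn(sprintf("ROI %s has no positive edges; positive-only connectivity set to 0.",
                        rownames(z)[idx] %||% idx))
    return(0)
  }
  mean(pos)
}
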