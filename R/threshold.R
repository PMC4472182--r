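#' Histogram of a connectivity scene
#'
#' Bins the positive connectivity values over `(0, 1]` into `bins` equal
#' bins, half-open on the left so the seed's value 1 falls in the last bin.
#' Voxels with `CS == 0` (never reached) are excluded: on a liver CT they
#' are the untouched background mass, which carries no information about
#' where to cut the vessel tree.
#'
#' @param cs a `connectivity_scene` from [compute_connectivity()].
#' @param bins number of bins (default 1000).
#' @return An object of class `cs_histogram`: list with `bin_edges`
#'   (length `bins + 1`, from 0 to 1), `counts` and `voxel_volume_ml`.
#' @export
cs_histogram <- function(cs, bins = 1000) {
  stopifnot(inherits(cs, "connectivity_scene"))
  bins <- as.integer(bins)
  if (bins < 2L) stop("bins must be >= 2", call. = FALSE)
  edges <- seq(0, 1, length.out = bins + 1L)
  pos <- cs$values[cs$values > 0]
  # bin i covers (edges[i], edges[i+1]]
  idx <- pmin(pmax(ceiling(pos * bins), 1L), bins)
  structure(list(bin_edges = edges,
                 counts = tabulate(idx, nbins = bins),
                 voxel_volume_ml = prod(cs$spacing) / 1000),
            class = "cs_histogram")
}

#' Build a histogram object from explicit counts
#'
#' Mainly for tests and for replaying a histogram dumped with
#' [histogram_as_data_frame()].
#'
#' @param counts non-negative integer vector, one entry per bin over
#'   `(0, 1]`.
#' @param voxel_volume_ml volume of one voxel in ml.
#' @return A `cs_histogram`.
#' @export
cs_histogram_from_counts <- function(counts, voxel_volume_ml) {
  bins <- length(counts)
  if (bins < 2L) stop("need at least 2 bins", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  structure(list(bin_edges = seq(0, 1, length.out = bins + 1L),
                 counts = as.numeric(counts),
                 voxel_volume_ml = voxel_volume_ml),
            class = "cs_histogram")
}

#' @export
print.cs_histogram <- function(x, ...) {
  cat(sprintf("<cs_histogram> %d bins over (0, 1], %g voxels, voxel %.4g ml\n",
              length(x$counts), sum(x$counts), x$voxel_volume_ml))
  invisible(x)
}

#' Histogram as a data frame
#'
#' @param hist a `cs_histogram`.
#' @return Data frame with columns `bin_left`, `bin_right`, `count`.
#' @export
histogram_as_data_frame <- function(hist) {
  stopifnot(inherits(hist, "cs_histogram"))
  b <- length(hist$counts)
  data.frame(bin_left = hist$bin_edges[1:b],
             bin_right = hist$bin_edges[2:(b + 1)],
             count = hist$counts)
}

#' Segmented volume above a connectivity threshold
#'
#' The volume (ml) of all voxels with connectivity `>= h`, evaluated at bin
#' resolution: `h` is snapped down to the nearest bin edge and the counts of
#' all bins above that edge are summed. Non-increasing in `h`.
#'
#' @param h threshold in `[0, 1]`.
#' @param hist a `cs_histogram`.
#' @return Volume in ml.
#' @export
volume_above <- function(h, hist) {
  stopifnot(inherits(hist, "cs_histogram"))
  b <- length(hist$counts)
  lefts <- hist$bin_edges[1:b]
  # snap h down to a bin edge, capped at the last bin's left edge so
  # h = 1 still counts the bin holding CS == 1
  k <- min(max(findInterval(h, hist$bin_edges), 1L), b)
  snapped <- lefts[k]
  hist$voxel_volume_ml * sum(hist$counts[lefts >= snapped - 1e-12])
}

#' Peak bins of a smoothed histogram
#'
#' Counts are smoothed by a centred moving average of odd width
#' `smooth_window` (shortened one-sidedly at the ends), then bin `i` is a
#' peak iff `smoothed[i] > smoothed[i-1]` and `smoothed[i] >= smoothed[i+1]`
#' (one-sided at the boundary bins). A plateau therefore resolves to its
#' left edge, and a histogram that climbs to the last bin has its peak
#' there.
#'
#' @param hist a `cs_histogram`.
#' @param smooth_window odd positive integer (1 = no smoothing).
#' @return Ascending integer vector of peak bin indices (1-based).
#' @export
find_peaks <- function(hist, smooth_window = 5) {
  stopifnot(inherits(hist, "cs_histogram"))
  w <- as.integer(smooth_window)
  if (w < 1L || w %% 2L == 0L)
    stop("smooth_window must be odd and >= 1", call. = FALSE)
  x <- smooth_counts(hist$counts, w)
  b <- length(x)
  if (b == 1L) return(1L)
  left_ok <- c(TRUE, x[-1] > x[-b])         # one-sided at bin 1
  right_ok <- c(x[-b] >= x[-1], TRUE)       # one-sided at bin B
  which(left_ok & right_ok)
}

smooth_counts <- function(counts, w) {
  if (w == 1L) return(as.numeric(counts))
  half <- (w - 1L) %/% 2L
  b <- length(counts)
  csum <- cumsum(c(0, counts))
  lo <- pmax(seq_len(b) - half, 1L)
  hi <- pmin(seq_len(b) + half, b)
  (csum[hi + 1L] - csum[lo]) / (hi - lo + 1L)
}

#' Watershed-like threshold suggestion from the connectivity histogram
#'
#' Implements the endpoint-then-peak search: the endpoint `EP` is the
#' largest positive bin edge `h` whose cumulative volume
#' [volume_above()]`(h)` still reaches `max_volume_ml` (the physiological
#' cap on total hepatic vessel volume); if no positive edge reaches the cap
#' (small scenes or phantoms), `EP` falls back to the left edge of the
#' histogram's first bin above zero. If the bin at `EP` is itself a peak,
#' the threshold `T` is `EP`; otherwise `T` is the left edge of the first
#' peak bin strictly above `EP` — the first connectivity level at which
#' voxels pile up again on the seed's side of the cut, i.e. the vessel
#' mode. When no peak exists above `EP`, `T` falls back to `EP` with a
#' warning.
#'
#' @param hist a `cs_histogram`.
#' @param max_volume_ml volume cap in ml (default 50, the physiological
#'   upper bound used for total hepatic vessel volume; scale it down for
#'   phantoms smaller than a liver).
#' @param smooth_window passed to [find_peaks()].
#' @return An object of class `threshold_result`: list with `T`, `EP`,
#'   `ep_is_peak`, `volume_at_T_ml`.
#' @export
suggest_threshold <- function(hist, max_volume_ml = 50, smooth_window = 5) {
  stopifnot(inherits(hist, "cs_histogram"))
  if (sum(hist$counts) == 0) stop("histogram is empty", call. = FALSE)
  b <- length(hist$counts)
  pos_edges <- hist$bin_edges[-1]   # positive edges, one per bin (right edges)
  lefts <- hist$bin_edges[1:b]

  vols <- vapply(pos_edges, volume_above, 0, hist = hist)
  ok <- which(vols >= max_volume_ml)
  if (length(ok) > 0) {
    ep <- pos_edges[max(ok)]
  } else {
    # cap never reached: start from the lowest positive edge bounding mass,
    # i.e. the right edge of the first non-empty bin
    ep <- pos_edges[min(which(hist$counts > 0))]
  }
  # bin whose left edge is EP (EP = right edge of bin k -> bin k + 1),
  # capped at the last bin for EP = 1
  ep_bin <- min(match(TRUE, abs(pos_edges - ep) < 1e-12) + 1L, b)

  peaks <- find_peaks(hist, smooth_window)
  ep_is_peak <- ep_bin %in% peaks
  if (ep_is_peak) {
    t_val <- ep
  } else {
    above <- peaks[peaks > ep_bin]
    if (length(above) > 0) {
      t_val <- lefts[above[1]]
    } else {
      warning("no peak above EP; falling back to T = EP", call. = FALSE)
      t_val <- ep
    }
  }
  structure(list(T = t_val, EP = ep, ep_is_peak = ep_is_peak,
                 volume_at_T_ml = volume_above(t_val, hist)),
            class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("<threshold_result> T = %.4g (EP = %.4g%s), volume at T = %.3f ml\n",
              x$T, x$EP, if (x$ep_is_peak) ", EP is a peak" else "",
              x$volume_at_T_ml))
  invisible(x)
}

#' Threshold a connectivity scene into a segmentation mask
#'
#' `mask = (CS >= T)`; the seed (CS = 1) is always included.
#'
#' @param cs a `connectivity_scene`.
#' @param threshold value in `(0, 1]`.
#' @return A logical-valued [scene] (mask) with the same spacing.
#' @export
apply_threshold <- function(cs, threshold) {
  stopifnot(inherits(cs, "connectivity_scene"))
  if (!is.finite(threshold) || threshold <= 0 || threshold > 1)
    stop("threshold must lie in (0, 1]", call. = FALSE)
  scene(array(cs$values >= threshold, dim = cs$dim), spacing = cs$spacing)
}
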