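#' Refined region growing: descending-threshold trace
#'
#' The comparator method: starting at `theta_beg = f(seed)`, repeatedly
#' lowers an intensity threshold by 1 and flood-fills all 26-connected
#' voxels with intensity `>= theta`, recording the cumulative region size
#' `N(theta)` at every step down to `theta_end`. The region at any `theta`
#' is nested inside the region at any lower threshold.
#'
#' @param sc a [scene] with integer intensities in 0..255.
#' @param seed `(x, y, z)` voxel index, 1-based.
#' @param theta_end lowest threshold to descend to; must not exceed the
#'   seed's intensity.
#' @param max_voxels safety cap: growth stops (with a warning) once the
#'   region exceeds this many voxels, truncating the trace. Default
#'   unlimited.
#' @return An object of class `rrg_trace`: list with `thetas` (descending),
#'   `sizes` (`N(theta)`, non-decreasing), `join_theta` (3D array: the
#'   threshold at which each voxel joined, `NA` if never), `truncated`.
#' @export
rrg_grow <- function(sc, seed, theta_end, max_voxels = Inf) {
  stopifnot(is_scene(sc))
  seed <- check_index(sc, seed)
  v <- sc$values
  if (any(v < 0) || any(v > 255) || any(v != round(v)))
    stop("scene intensities must be integers in 0..255; apply ",
         "window_to_byte() first", call. = FALSE)
  theta_end <- as.integer(theta_end)
  f_seed <- v[seed[1], seed[2], seed[3]]
  if (theta_end > f_seed)
    stop("theta_end (", theta_end, ") exceeds the seed intensity (",
         f_seed, ")", call. = FALSE)
  seed0 <- (seed[1] - 1L) + sc$dim[1] * (seed[2] - 1L) +
    sc$dim[1] * sc$dim[2] * (seed[3] - 1L)
  res <- rrg_grow_cpp(as.integer(v), as.integer(sc$dim), as.integer(seed0),
                      theta_end, max_voxels)
  if (res$truncated)
    warning("region growth truncated at theta = ",
            res$thetas[length(res$thetas)], ": region exceeded ",
            max_voxels, " voxels", call. = FALSE)
  jt <- res$join_theta
  jt[jt < 0] <- NA_integer_
  structure(list(thetas = res$thetas, sizes = res$sizes,
                 join_theta = array(jt, dim = sc$dim),
                 truncated = res$truncated,
                 spacing = sc$spacing, seed = seed),
            class = "rrg_trace")
}

#' @export
print.rrg_trace <- function(x, ...) {
  cat(sprintf("<rrg_trace> theta %d ... %d, N(theta) %d ... %d%s\n",
              x$thetas[1], x$thetas[length(x$thetas)],
              x$sizes[1], x$sizes[length(x$sizes)],
              if (x$truncated) " (truncated)" else ""))
  invisible(x)
}

#' Trace as a data frame
#' @param trace an `rrg_trace`.
#' @return Data frame with columns `theta`, `n_voxels`.
#' @export
rrg_trace_as_data_frame <- function(trace) {
  stopifnot(inherits(trace, "rrg_trace"))
  data.frame(theta = trace$thetas, n_voxels = trace$sizes)
}

#' Select the optimal region-growing threshold from a trace
#'
#' `theta_opt` is the threshold just above the largest relative explosion
#' of the region: the `theta` maximizing `N(theta - 1) / N(theta)`, ties
#' resolved toward larger `theta`. The rationale is that once the threshold
#' drops below the vessel/parenchyma boundary the region floods into liver
#' tissue and its size jumps by a large factor; the threshold right above
#' that jump is the last "vessel-only" level. A trace with no distinguished
#' jump (constant or strictly linear growth) returns `theta_end` with a
#' warning.
#'
#' @param trace an `rrg_trace` with at least two thresholds.
#' @param strategy `"relative"` (ratio of consecutive sizes, default) or
#'   `"absolute"` (first difference) jump measure.
#' @return Integer threshold.
#' @export
select_theta_opt <- function(trace, strategy = c("relative", "absolute")) {
  stopifnot(inherits(trace, "rrg_trace"))
  strategy <- match.arg(strategy)
  k <- length(trace$thetas)
  if (k < 2L) stop("trace needs at least 2 thresholds", call. = FALSE)
  diffs <- diff(trace$sizes)
  # no distinguished jump: constant or strictly linear growth
  if (all(diffs == diffs[1])) {
    warning("region size shows no distinguished jump; falling back to ",
            "theta_opt = theta_end", call. = FALSE)
    return(trace$thetas[k])
  }
  jump <- switch(strategy,
    relative = trace$sizes[-1] / trace$sizes[-k],
    absolute = diffs)
  # jump[i] is the growth from thetas[i] to thetas[i+1]; pick the larger
  # theta of the steepest pair, earliest (largest theta) on ties
  trace$thetas[which.max(jump)]
}

#' Segment by refined region growing
#'
#' Runs [rrg_grow()], selects `theta_opt` with [select_theta_opt()], and
#' returns the region grown down to `theta_opt` (read back from the trace,
#' no second growth pass).
#'
#' @inheritParams rrg_grow
#' @param strategy passed to [select_theta_opt()].
#' @return A logical-valued [scene] (mask) with attributes `theta_opt` and
#'   `trace`.
#' @export
rrg_segment <- function(sc, seed, theta_end, max_voxels = Inf,
                        strategy = "relative") {
  trace <- rrg_grow(sc, seed, theta_end, max_voxels)
  theta_opt <- select_theta_opt(trace, strategy)
  mask <- rrg_mask_at(trace, theta_opt)
  attr(mask, "theta_opt") <- theta_opt
  attr(mask, "trace") <- trace
  mask
}

#' Region mask at a given threshold of a trace
#'
#' @param trace an `rrg_trace`.
#' @param theta threshold within the traced range.
#' @return A logical-valued [scene].
#' @export
rrg_mask_at <- function(trace, theta) {
  stopifnot(inherits(trace, "rrg_trace"))
  jt <- trace$join_theta
  m <- !is.na(jt) & jt >= theta
  scene(array(m, dim = dim(jt)), spacing = trace$spacing)
}
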