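#' Seeded fuzzy-connectedness vessel segmentation
#'
#' The package's main entry point: runs the full adaptive-threshold
#' fuzzy-connectedness pipeline on a windowed 8-bit scene and returns a
#' fitted-model-style object. Stages, in order: estimate the vessel
#' intensity statistics `(m, s)` from a cube around the seed (Otsu split,
#' brighter class), replace the seed's intensity with `m`, build the
#' 256 x 256 affinity lookup table, propagate max-min connectivity from
#' the seed, histogram the connectivity scene, choose the threshold by the
#' watershed-like endpoint-then-peak search (unless `threshold` overrides
#' it), and cut the mask.
#'
#' @param sc a [scene] with integer intensities in 0..255 (apply
#'   [window_to_byte()] to HU volumes first).
#' @param seed `(x, y, z)` voxel index, 1-based, inside a vessel.
#' @param cube_edge edge of the parameter-estimation cube, voxels.
#' @param s_floor lower bound on the estimated `s`.
#' @param bins connectivity histogram bins.
#' @param smooth_window histogram smoothing window (odd).
#' @param max_volume_ml vessel volume cap for the endpoint search; the
#'   default 50 ml suits a whole liver — scale it down for phantoms.
#' @param threshold optional manual threshold in `(0, 1]`, bypassing the
#'   adaptive search.
#' @param use_lut if `FALSE`, evaluate the affinity per link instead of
#'   using the lookup table (identical output; for benchmarking).
#' @param aff_floor optional link-affinity pruning floor (default 0, off).
#' @return An object of class `fuzzycon`: list with `params`
#'   ([affinity_params]), `cs` (`connectivity_scene`), `hist`,
#'   `threshold` (`threshold_result`, or a manual stand-in), `mask`
#'   (logical-valued [scene]), `volume` (`volume_report`), `seed`, `call`.
#' @examples
#' ph <- default_phantom(rng_seed = 42)
#' seed <- seed_in_trunk(ph)
#' fit <- fuzzycon(ph$scene, seed, max_volume_ml = 2)
#' fit
#' dice(fit$mask, ph$truth)
#' @seealso [rrg()] for the region-growing comparator.
#' @export
fuzzycon <- function(sc, seed, cube_edge = 20, s_floor = 0.5, bins = 1000,
                     smooth_window = 5, max_volume_ml = 50, threshold = NULL,
                     use_lut = TRUE, aff_floor = 0) {
  stopifnot(is_scene(sc))
  seed <- check_index(sc, seed)
  params <- estimate_params(sc, seed, cube_edge = cube_edge,
                            s_floor = s_floor)
  sc2 <- replace_seed_value(sc, seed, params)
  lut <- affinity_lut(params)
  cs <- if (use_lut)
    compute_connectivity(sc2, seed, lut = lut, aff_floor = aff_floor)
  else
    compute_connectivity(sc2, seed, params = params, aff_floor = aff_floor)
  h <- cs_histogram(cs, bins = bins)
  thr <- if (is.null(threshold)) {
    suggest_threshold(h, max_volume_ml = max_volume_ml,
                      smooth_window = smooth_window)
  } else {
    structure(list(T = threshold, EP = threshold, ep_is_peak = NA,
                   volume_at_T_ml = volume_above(threshold, h),
                   manual = TRUE),
              class = "threshold_result")
  }
  mask <- apply_threshold(cs, thr$T)
  structure(list(params = params, cs = cs, hist = h, threshold = thr,
                 mask = mask, volume = mask_volume(mask), seed = seed,
                 call = match.call()),
            class = "fuzzycon")
}

#' @export
print.fuzzycon <- function(x, ...) {
  cat("Fuzzy-connectedness vessel segmentation\n")
  cat(sprintf("  seed (%d, %d, %d); vessel class m = %.2f, s = %.2f\n",
              x$seed[1], x$seed[2], x$seed[3], x$params$m, x$params$s))
  cat(sprintf("  threshold T = %.4g (EP = %.4g)%s\n", x$threshold$T,
              x$threshold$EP,
              if (isTRUE(x$threshold$manual)) " [manual]" else ""))
  cat(sprintf("  segmented: %d voxels, %.3f ml\n",
              x$volume$voxel_count, x$volume$volume_ml))
  invisible(x)
}

#' @export
summary.fuzzycon <- function(object, ...) {
  x <- object
  reached <- sum(x$cs$values > 0)
  out <- list(
    seed = x$seed, m = x$params$m, s = x$params$s,
    otsu_threshold = attr(x$params, "threshold"),
    T = x$threshold$T, EP = x$threshold$EP,
    ep_is_peak = x$threshold$ep_is_peak,
    voxels = x$volume$voxel_count, volume_ml = x$volume$volume_ml,
    reached_voxels = reached,
    reached_fraction = reached / prod(x$cs$dim))
  class(out) <- "summary.fuzzycon"
  out
}

#' @export
print.summary.fuzzycon <- function(x, ...) {
  cat("Fuzzy-connectedness segmentation summary\n")
  cat(sprintf("  seed:            (%d, %d, %d)\n", x$seed[1], x$seed[2],
              x$seed[3]))
  cat(sprintf("  vessel class:    m = %.3f, s = %.3f (Otsu cut %d)\n",
              x$m, x$s, x$otsu_threshold))
  cat(sprintf("  threshold:       T = %.4g, EP = %.4g, EP %s a peak\n",
              x$T, x$EP,
              if (isTRUE(x$ep_is_peak)) "is" else "is not"))
  cat(sprintf("  reached voxels:  %d (%.1f%% of scene)\n",
              x$reached_voxels, 100 * x$reached_fraction))
  cat(sprintf("  segmentation:    %d voxels, %.3f ml\n", x$voxels,
              x$volume_ml))
  invisible(x)
}

#' @export
coef.fuzzycon <- function(object, ...) {
  c(m = object$params$m, s = object$params$s,
    T = object$threshold$T, EP = object$threshold$EP)
}

#' Plot the connectivity histogram of a fit
#'
#' Log-count histogram of the connectivity scene with the endpoint `EP`
#' and chosen threshold `T` marked — the plot on which the watershed-like
#' search operates.
#'
#' @param x a `fuzzycon` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fuzzycon <- function(x, ...) {
  df <- histogram_as_data_frame(x$hist)
  mids <- (df$bin_left + df$bin_right) / 2
  graphics::plot(mids, log10(df$count + 1), type = "h", col = "grey40",
                 xlab = "connectivity", ylab = "log10(count + 1)",
                 main = "Connectivity-scene histogram", ...)
  graphics::abline(v = x$threshold$EP, col = "orange", lty = 2)
  graphics::abline(v = x$threshold$T, col = "red")
  graphics::legend("topright", bty = "n", lty = c(2, 1),
                   col = c("orange", "red"),
                   legend = c(sprintf("EP = %.3g", x$threshold$EP),
                              sprintf("T = %.3g", x$threshold$T)))
  invisible(x)
}

#' Refined region-growing segmentation (comparator)
#'
#' Fitted-model-style wrapper over [rrg_grow()], [select_theta_opt()] and
#' the mask readback: descending-threshold 26-adjacent growth from the
#' seed, stopping at `theta_end`, with the operating threshold chosen at
#' the largest relative jump of the region size.
#'
#' @inheritParams rrg_grow
#' @param strategy jump measure for [select_theta_opt()].
#' @return An object of class `rrg`: list with `trace`, `theta_opt`,
#'   `mask`, `volume`, `seed`, `call`.
#' @export
rrg <- function(sc, seed, theta_end, max_voxels = Inf,
                strategy = "relative") {
  stopifnot(is_scene(sc))
  seed <- check_index(sc, seed)
  trace <- rrg_grow(sc, seed, theta_end, max_voxels)
  theta_opt <- select_theta_opt(trace, strategy)
  mask <- rrg_mask_at(trace, theta_opt)
  structure(list(trace = trace, theta_opt = theta_opt, mask = mask,
                 volume = mask_volume(mask), seed = seed,
                 call = match.call()),
            class = "rrg")
}

#' @export
print.rrg <- function(x, ...) {
  cat("Refined region-growing segmentation\n")
  cat(sprintf("  seed (%d, %d, %d); theta %d ... %d, theta_opt = %d\n",
              x$seed[1], x$seed[2], x$seed[3], x$trace$thetas[1],
              x$trace$thetas[length(x$trace$thetas)], x$theta_opt))
  cat(sprintf("  segmented: %d voxels, %.3f ml\n",
              x$volume$voxel_count, x$volume$volume_ml))
  invisible(x)
}

#' Plot the region-size trace of an RRG fit
#'
#' @param x an `rrg` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.rrg <- function(x, ...) {
  graphics::plot(x$trace$thetas, log10(x$trace$sizes), type = "s",
                 xlab = "theta", ylab = "log10 N(theta)",
                 xlim = rev(range(x$trace$thetas)),
                 main = "Region growth vs descending threshold", ...)
  graphics::abline(v = x$theta_opt, col = "red")
  invisible(x)
}

#' Pick a seed voxel inside the phantom trunk
#'
#' Returns the truth voxel closest to the first tube segment's midpoint —
#' a reproducible stand-in for the interactive seed click.
#'
#' @param ph a `phantom`.
#' @return `(x, y, z)` integer index.
#' @export
seed_in_trunk <- function(ph) {
  stopifnot(inherits(ph, "phantom"))
  seg <- ph$spec$tree[[1]]
  mid <- (as.numeric(seg$from) + as.numeric(seg$to)) / 2
  idx <- which(ph$truth$values, arr.ind = TRUE)
  mm <- sweep(idx - 1, 2, ph$spec$spacing, `*`)
  d2 <- rowSums(sweep(mm, 2, mid, `-`)^2)
  as.integer(idx[which.min(d2), ])
}
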