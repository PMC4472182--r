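#' Extract the intensities of a cube centred on the seed
#'
#' Returns all intensities of the axis-aligned cube of edge `edge` voxels
#' "centred" on the seed, truncated at the scene borders. An even edge
#' cannot be centred exactly; the cube spans `edge/2` voxels below to
#' `edge/2 - 1` above the seed plane on each axis (half-open convention),
#' so the default edge 20 takes 10 below and 9 above plus the seed plane.
#'
#' @param sc a [scene].
#' @param seed `(x, y, z)` voxel index, 1-based, inside the scene.
#' @param edge cube edge in voxels (default 20).
#' @return Numeric vector of cube intensities.
#' @export
seed_cube <- function(sc, seed, edge = 20) {
  stopifnot(is_scene(sc))
  seed <- check_index(sc, seed)
  edge <- as.integer(edge)
  if (edge < 1L) stop("cube edge must be >= 1", call. = FALSE)
  lo <- seed - edge %/% 2L
  hi <- lo + edge - 1L
  lo <- pmax(lo, 1L)
  hi <- pmin(hi, sc$dim)
  as.vector(sc$values[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]])
}

#' Otsu threshold of an intensity sample
#'
#' The integer threshold `t` in 0..255 maximizing the between-class variance
#' of the split `{v <= t}` vs `{v > t}`; ties resolve to the smallest
#' maximizer. Computed from the 256-bin histogram by the cumulative-moment
#' recurrence. Inputs are rounded to integers and clamped to 0..255 (the
#' method operates on 8-bit scenes).
#'
#' @param values numeric vector with at least two distinct intensities.
#' @return Integer threshold in 0..254.
#' @export
otsu_threshold <- function(values) {
  v <- pmin(pmax(floor(values + 0.5), 0), 255)
  if (length(unique(v)) < 2L)
    stop("degenerate cube: single intensity", call. = FALSE)
  h <- tabulate(v + 1L, nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)              # P(v <= t), t = 0..255
  mu <- cumsum(p * (0:255))       # sum of v*p up to t
  mu_t <- mu[256]
  # between-class variance for t = 0..254; undefined where a class is empty
  om <- omega[1:255]
  sigma_b <- (mu_t * om - mu[1:255])^2 / (om * (1 - om))
  sigma_b[om == 0 | om == 1] <- -Inf
  which.max(sigma_b) - 1L         # which.max takes the first (smallest) tie
}

#' Estimate vessel affinity parameters from the seed neighbourhood
#'
#' Splits the intensities of a cube around the seed into two classes by
#' [otsu_threshold()] and takes the brighter class as the vessel class
#' (contrast-enhanced vessels are brighter than parenchyma). `m` and `s`
#' are the mean and population standard deviation (divisor N) of that
#' class; `s` is floored at `s_floor` so a noiseless cube cannot produce a
#' singular Gaussian. The seed's own intensity must fall in the vessel
#' class; otherwise the seed was placed outside a vessel and an error is
#' raised. Estimating from the whole cube rather than the seed voxel alone
#' makes the parameters insensitive to where inside the vessel the seed
#' was clicked.
#'
#' @param sc a [scene] with intensities on the 8-bit scale.
#' @param seed `(x, y, z)` voxel index, 1-based.
#' @param cube_edge cube edge in voxels (default 20).
#' @param s_floor lower bound on `s` (default 0.5 intensity units).
#' @return An [affinity_params] with attributes `threshold` (the Otsu cut)
#'   and `n_vessel` (vessel-class voxel count).
#' @export
estimate_params <- function(sc, seed, cube_edge = 20, s_floor = 0.5) {
  stopifnot(is_scene(sc))
  seed <- check_index(sc, seed)
  vals <- seed_cube(sc, seed, cube_edge)
  t <- otsu_threshold(vals)
  upper <- vals[vals > t]
  if (length(upper) == 0L)
    stop("degenerate cube: vessel class empty", call. = FALSE)
  f_seed <- sc$values[seed[1], seed[2], seed[3]]
  if (!(f_seed > t))
    stop("seed not in vessel class (seed intensity ", f_seed,
         " <= Otsu threshold ", t, "); place the seed inside a vessel",
         call. = FALSE)
  m <- mean(upper)
  s <- sqrt(mean((upper - m)^2))   # population sd, divisor N
  p <- affinity_params(m = m, s = max(s, s_floor))
  attr(p, "threshold") <- t
  attr(p, "n_vessel") <- length(upper)
  p
}

#' Replace the seed's intensity with the vessel mean
#'
#' Returns a copy of the scene with the seed voxel set to `round(m)`
#' (half-up); every other voxel is untouched. Together with cube-based
#' parameter estimation this removes the dependence of the propagation on
#' the exact intensity of the clicked voxel (e.g. a seed on the blurred
#' vessel edge).
#'
#' @param sc a [scene].
#' @param seed `(x, y, z)` voxel index, 1-based.
#' @param params an [affinity_params] providing `m`.
#' @return A [scene].
#' @export
replace_seed_value <- function(sc, seed, params) {
  stopifnot(is_scene(sc), inherits(params, "affinity_params"))
  seed <- check_index(sc, seed)
  out <- sc
  out$values[seed[1], seed[2], seed[3]] <- floor(params$m + 0.5)
  out
}
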