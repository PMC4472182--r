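#' Affinity parameters of the vessel class
#'
#' Bundles the mean `m` and standard deviation `s` of the vessel intensity
#' class (on the 8-bit scale) that parameterize the Gaussian pair-mean
#' affinity between adjacent voxels, together with the mixture weights of
#' the general affinity form. The intensity component used here is the
#' Gaussian of the pair mean, with weight `w1`; a second component is
#' admitted by the general form but carries weight `w2 = 0` and is not
#' evaluated, so `w1 + w2 = 1` is required and the default `w1 = 1` is the
#' operating setting.
#'
#' @param m mean vessel intensity, 8-bit scale.
#' @param s standard deviation of vessel intensity; must be > 0.
#' @param w1,w2 mixture weights, `w1 + w2 = 1`; only `w1 = 1, w2 = 0` is
#'   evaluated.
#' @return An object of class `affinity_params`.
#' @export
affinity_params <- function(m, s, w1 = 1, w2 = 0) {
  if (!is.finite(s) || s <= 0) stop("s must be > 0", call. = FALSE)
  if (abs(w1 + w2 - 1) > 1e-12)
    stop("weights must satisfy w1 + w2 = 1", call. = FALSE)
  if (w2 != 0)
    stop("only w1 = 1, w2 = 0 is supported (the second affinity component ",
         "is not defined)", call. = FALSE)
  structure(list(m = as.numeric(m), s = as.numeric(s), w1 = w1, w2 = w2),
            class = "affinity_params")
}

#' @export
print.affinity_params <- function(x, ...) {
  cat(sprintf("<affinity_params> m = %.4g, s = %.4g (w1 = %g, w2 = %g)\n",
              x$m, x$s, x$w1, x$w2))
  invisible(x)
}

#' Fuzzy adjacency between two voxel indices
#'
#' The 6-adjacency relation: 1 when the Euclidean distance between the index
#' triples is at most 1 (the same voxel or a face neighbour), 0 otherwise.
#'
#' @param c,d integer `(x, y, z)` voxel index triples.
#' @return 1 or 0.
#' @examples
#' voxel_adjacency(c(1, 1, 1), c(1, 1, 2))  # 1
#' voxel_adjacency(c(1, 1, 1), c(2, 2, 1))  # 0
#' @export
voxel_adjacency <- function(c, d) {
  as.numeric(sum((as.numeric(c) - as.numeric(d))^2) <= 1)
}

#' Fuzzy affinity between two voxel intensities
#'
#' For adjacent voxels, a Gaussian of the pair-mean intensity around the
#' vessel mean: `exp(-0.5 * (((fc + fd)/2 - m)/s)^2)`; zero for
#' non-adjacent pairs. The pair mean is computed in floating point. The
#' function is vectorized over `fc`/`fd`.
#'
#' @param fc,fd voxel intensities.
#' @param params an [affinity_params].
#' @param adjacent adjacency value in `{0, 1}` (default 1).
#' @return Affinity values in `[0, 1]`.
#' @examples
#' p <- affinity_params(m = 160, s = 15)
#' fuzzy_affinity(160, 160, p)           # 1
#' fuzzy_affinity(160, 190, p)           # exp(-0.5)
#' @export
fuzzy_affinity <- function(fc, fd, params, adjacent = 1) {
  stopifnot(inherits(params, "affinity_params"))
  z <- ((fc + fd) / 2 - params$m) / params$s
  adjacent * exp(-0.5 * z^2)
}

#' Build the 256 x 256 affinity lookup table
#'
#' Tabulates the affinity of every ordered pair of 8-bit intensities
#' (adjacency factor 1), so that propagation over an 8-bit scene never
#' re-evaluates the Gaussian. Entries are double precision, making a
#' LUT-backed run bit-identical to direct evaluation. Row/column `i`
#' corresponds to intensity `i - 1` (0-based intensities 0..255).
#'
#' @param params an [affinity_params].
#' @return An object of class `affinity_lut`: list with `table`
#'   (256 x 256 numeric matrix) and `params`.
#' @export
affinity_lut <- function(params) {
  stopifnot(inherits(params, "affinity_params"))
  v <- 0:255
  pair_mean <- outer(v, v, `+`) / 2
  z <- (pair_mean - params$m) / params$s
  structure(list(table = exp(-0.5 * z^2), params = params),
            class = "affinity_lut")
}

#' @export
print.affinity_lut <- function(x, ...) {
  cat(sprintf("<affinity_lut> 256 x 256, m = %.4g, s = %.4g\n",
              x$params$m, x$params$s))
  invisible(x)
}

#' Look up an affinity in the table
#'
#' Intensities outside 0..255 are clamped into range, making the lookup
#' total. Vectorized over `fc`/`fd`.
#'
#' @param lut an [affinity_lut].
#' @param fc,fd intensities.
#' @return Affinity values in `[0, 1]`.
#' @export
lut_lookup <- function(lut, fc, fd) {
  stopifnot(inherits(lut, "affinity_lut"))
  a <- pmin(pmax(round(fc), 0), 255)
  b <- pmin(pmax(round(fd), 0), 255)
  lut$table[cbind(a + 1, b + 1)]
}

#' Dump an affinity LUT as a data frame
#'
#' Long-format `(fc, fd, affinity)` table for inspection or plotting.
#'
#' @param lut an [affinity_lut].
#' @return A data frame with 65,536 rows.
#' @export
lut_as_data_frame <- function(lut) {
  stopifnot(inherits(lut, "affinity_lut"))
  data.frame(fc = rep(0:255, times = 256),
             fd = rep(0:255, each = 256),
             affinity = as.vector(lut$table))
}
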