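#' Strength of a path through the scene
#'
#' A path is a sequence of 6-adjacent voxel indices; its strength is the
#' weakest pairwise affinity along it (min over links). A single-voxel path
#' has strength 1 by the empty-min convention.
#'
#' @param path integer matrix with one `(x, y, z)` row per voxel, or a list
#'   of index triples; consecutive rows must be 6-adjacent.
#' @param sc a [scene].
#' @param params an [affinity_params].
#' @return Path strength in `[0, 1]`.
#' @export
path_strength <- function(path, sc, params) {
  stopifnot(is_scene(sc))
  if (is.list(path)) path <- do.call(rbind, path)
  path <- matrix(as.integer(path), ncol = 3)
  if (nrow(path) < 1L) stop("path must contain at least one voxel", call. = FALSE)
  apply(path, 1, function(p) check_index(sc, p, "path voxel"))
  if (nrow(path) == 1L) return(1.0)
  strength <- 1.0
  for (i in seq_len(nrow(path) - 1L)) {
    a <- path[i, ]; b <- path[i + 1L, ]
    if (voxel_adjacency(a, b) != 1)
      stop("path voxels ", i, " and ", i + 1L, " are not 6-adjacent",
           call. = FALSE)
    aff <- fuzzy_affinity(sc$values[a[1], a[2], a[3]],
                          sc$values[b[1], b[2], b[3]], params)
    strength <- min(strength, aff)
  }
  strength
}

cs_scene <- function(values, sc, seed) {
  structure(list(values = values, spacing = sc$spacing, dim = sc$dim,
                 seed = seed),
            class = c("connectivity_scene", "scene"))
}

#' @export
print.connectivity_scene <- function(x, ...) {
  cat(sprintf(paste0("<connectivity_scene> %d x %d x %d voxels, seed (%d, ",
                     "%d, %d)\n"),
              x$dim[1], x$dim[2], x$dim[3], x$seed[1], x$seed[2], x$seed[3]))
  cat(sprintf("  reached voxels (CS > 0): %d of %d\n",
              sum(x$values > 0), prod(x$dim)))
  invisible(x)
}

#' Fuzzy connectedness of every voxel to the seed
#'
#' Computes the connectivity scene: for each voxel, the strength of the
#' strongest 6-connected path from the seed, where a path's strength is its
#' weakest link affinity. Implemented as a Dijkstra-style propagation with
#' a max-priority queue (lazy re-insertion; stale entries are skipped): the
#' voxel with maximal current connectivity is popped, each of its 6
#' neighbours `e` is relaxed to `min(CS(c), affinity(c, e))` when that
#' improves `CS(e)`. Max-min propagation is exact and independent of how
#' ties in the queue are broken.
#'
#' @param sc a [scene] with integer intensities in 0..255 (see
#'   [window_to_byte()]).
#' @param seed `(x, y, z)` voxel index, 1-based.
#' @param params an [affinity_params]; ignored when `lut` is given.
#' @param lut an [affinity_lut] built from the same parameters; when
#'   supplied, link affinities are read from the table instead of being
#'   re-evaluated (identical output, roughly half the runtime on CT-sized
#'   scenes).
#' @param aff_floor optional pruning floor: links with affinity `<=`
#'   this value are skipped. Default 0 (off); the Gaussian never reaches
#'   exactly 0 in floating point, so by default every in-bounds link is
#'   considered.
#' @param tie_break processing order among equal-priority queue entries,
#'   `"fifo"` or `"lifo"`; the result is provably identical either way and
#'   the flag exists so tests can demonstrate that.
#' @return A `connectivity_scene` (a [scene] whose values are the
#'   connectedness in `[0, 1]`, plus the seed), with `CS(seed) == 1`.
#' @seealso [connectivity_oracle()] for the brute-force reference,
#'   [suggest_threshold()] and [apply_threshold()] for the segmentation
#'   step.
#' @export
compute_connectivity <- function(sc, seed, params = NULL, lut = NULL,
                                 aff_floor = 0, tie_break = c("fifo", "lifo")) {
  stopifnot(is_scene(sc))
  seed <- check_index(sc, seed)
  tie_break <- match.arg(tie_break)
  v <- sc$values
  if (any(v < 0) || any(v > 255) || any(v != round(v)))
    stop("scene intensities must be integers in 0..255; apply ",
         "window_to_byte() first", call. = FALSE)
  use_lut <- !is.null(lut)
  if (use_lut) {
    stopifnot(inherits(lut, "affinity_lut"))
    tab <- lut$table
    m <- lut$params$m; s <- lut$params$s
  } else {
    if (is.null(params))
      stop("supply either params or lut", call. = FALSE)
    stopifnot(inherits(params, "affinity_params"))
    tab <- matrix(0, 1, 1)  # placeholder, not consulted
    m <- params$m; s <- params$s
  }
  seed0 <- (seed[1] - 1L) + sc$dim[1] * (seed[2] - 1L) +
    sc$dim[1] * sc$dim[2] * (seed[3] - 1L)
  cs <- fc_propagate(as.integer(v), as.integer(sc$dim), as.integer(seed0),
                     tab, use_lut, m, s, aff_floor,
                     if (tie_break == "fifo") 0L else 1L)
  cs_scene(array(cs, dim = sc$dim), sc, seed)
}

#' Brute-force connectivity reference (small scenes)
#'
#' Iterated Bellman-Ford-style relaxation to the fixpoint of
#' `CS(v) = max(CS(v), max over neighbours n of min(CS(n), affinity(n, v)))`,
#' which for max-min path strength is exact. Runtime grows with scene size
#' times path length, so this is intended as an independent test reference
#' for scenes of up to a few hundred voxels, not for segmentation.
#'
#' @inheritParams compute_connectivity
#' @param params an [affinity_params].
#' @return A `connectivity_scene`.
#' @export
connectivity_oracle <- function(sc, seed, params) {
  stopifnot(is_scene(sc), inherits(params, "affinity_params"))
  seed <- check_index(sc, seed)
  d <- sc$dim
  v <- sc$values
  cs <- array(0, dim = d)
  cs[seed[1], seed[2], seed[3]] <- 1

  # logical selector for given positions along one axis (column-major
  # order aligns the lo/hi selections link by link)
  sel <- function(axis, positions) {
    slice.index(array(0, dim = d), axis) %in% positions
  }
  link <- lapply(1:3, function(axis) {
    n <- d[axis]
    if (n < 2L) return(NULL)
    lo <- sel(axis, 1:(n - 1)); hi <- sel(axis, 2:n)
    list(lo = lo, hi = hi, aff = fuzzy_affinity(v[lo], v[hi], params))
  })

  repeat {
    new <- cs
    for (lk in link) {
      if (is.null(lk)) next
      new[lk$hi] <- pmax(new[lk$hi], pmin(new[lk$lo], lk$aff))
      new[lk$lo] <- pmax(new[lk$lo], pmin(new[lk$hi], lk$aff))
    }
    if (identical(new, cs)) break
    cs <- new
  }
  cs_scene(cs, sc, seed)
}
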