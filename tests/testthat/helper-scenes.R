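# Fixtures built in code: clean two-level tube scenes and small random
# scenes used across the module tests.

# Straight z-axis tube of given radius (voxels) at `vessel` intensity over a
# flat background; no blur, no noise. Returns list(scene, mask, axis).
tube_scene <- function(shape = c(24, 24, 24), axis_xy = c(12, 12),
                       radius = 2.5, vessel = 180, background = 80,
                       spacing = c(1, 1, 1)) {
  d <- as.integer(shape)
  vals <- array(background, dim = d)
  mask <- array(FALSE, dim = d)
  for (x in 1:d[1]) for (y in 1:d[2]) {
    if ((x - axis_xy[1])^2 + (y - axis_xy[2])^2 <= radius^2) {
      mask[x, y, ] <- TRUE
      vals[x, y, ] <- vessel
    }
  }
  list(scene = vesselfc::scene(vals, spacing),
       mask = vesselfc::scene(mask, spacing),
       axis = axis_xy)
}

random_scene <- function(shape = c(4, 4, 3)) {
  vesselfc::scene(array(sample(0:255, prod(shape), replace = TRUE),
                        dim = shape))
}

random_params <- function() {
  vesselfc::affinity_params(m = stats::runif(1, 30, 220),
                            s = stats::runif(1, 3, 50))
}

random_seed_index <- function(shape) {
  vapply(shape, function(n) sample.int(n, 1), 1L)
}

# independent brute-force Otsu: scan all 256 thresholds, maximizing
# w1*w2*(mu1-mu2)^2 (an algebraically different route than the package's
# cumulative-moment recurrence)
otsu_brute <- function(v) {
  v <- pmin(pmax(floor(v + 0.5), 0), 255)
  best <- -Inf
  bt <- NA_integer_
  for (t in 0:254) {
    lo <- v[v <= t]
    hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w1 <- length(lo) / length(v)
    sb <- w1 * (1 - w1) * (mean(lo) - mean(hi))^2
    if (sb > best + 1e-9) {
      best <- sb
      bt <- t
    }
  }
  bt
}

# mask of a logical scene as voxel count
n_true <- function(mask) sum(mask$values != 0)
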