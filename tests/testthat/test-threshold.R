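make_cs <- function(values, spacing = c(1, 1, 1), seed = c(1, 1, 1)) {
  structure(list(values = values, spacing = spacing, dim = dim(values),
                 seed = seed),
            class = c("connectivity_scene", "scene"))
}

test_that("histogram puts the seed in the last bin and conserves counts", {
  v <- array(0, dim = c(4, 4, 2))
  v[1, 1, 1] <- 1
  h <- cs_histogram(make_cs(v), bins = 10)
  expect_equal(h$counts, c(rep(0, 9), 1))

  v2 <- array(1, dim = c(3, 3, 3))
  h2 <- cs_histogram(make_cs(v2), bins = 10)
  expect_equal(h2$counts[10], 27)

  set.seed(41)
  v3 <- array(runif(200) * rbinom(200, 1, 0.7), dim = c(10, 5, 4))
  h3 <- cs_histogram(make_cs(v3), bins = 50)
  expect_equal(sum(h3$counts), sum(v3 > 0))
  expect_equal(h3$voxel_volume_ml, 1e-3)
})

test_that("volume above a threshold integrates the upper histogram", {
  # all mass in the last bin: Table-1-style arithmetic
  h <- cs_histogram_from_counts(c(rep(0, 9), 24904),
                                voxel_volume_ml = 0.671 * 0.671 * 1 / 1000)
  expect_equal(volume_above(1.0, h), 11.213, tolerance = 5e-5)
  expect_equal(volume_above(0.95, h), volume_above(1.0, h))
  expect_equal(volume_above(0, h), volume_above(1.0, h))

  # monotone non-increasing in h on random histograms
  set.seed(43)
  for (i in 1:20) {
    hr <- cs_histogram_from_counts(rpois(40, 5), voxel_volume_ml = 0.002)
    hs <- sort(runif(25))
    vols <- vapply(hs, volume_above, 0, hist = hr)
    expect_true(all(diff(vols) <= 1e-12))
  }
})

test_that("peaks follow the strict-left / non-strict-right rule", {
  vv <- 1e-3
  expect_equal(find_peaks(cs_histogram_from_counts(c(1, 5, 1), vv),
                          smooth_window = 1), 2L)
  expect_equal(find_peaks(cs_histogram_from_counts(1:6, vv),
                          smooth_window = 1), 6L)
  expect_equal(find_peaks(cs_histogram_from_counts(c(1, 5, 5, 1), vv),
                          smooth_window = 1), 2L)   # plateau -> left edge
  expect_equal(find_peaks(cs_histogram_from_counts(c(6, 1, 1, 1), vv),
                          smooth_window = 1), 1L)   # boundary peak
  expect_error(find_peaks(cs_histogram_from_counts(c(1, 2, 1), vv),
                          smooth_window = 2), "odd")
})

test_that("smoothing averages over the in-range window", {
  h <- cs_histogram_from_counts(c(0, 0, 9, 0, 0, 0), 1e-3)
  # window 3: counts become (0, 3, 3, 3, 0, 0); single peak at its left edge
  expect_equal(find_peaks(h, smooth_window = 3), 2L)
})

test_that("endpoint-then-peak search finds the vessel mode", {
  # background mass of 104 ml over bins 5..30, silence, then an 8 ml
  # vessel peak around 0.9; cap 50 ml. Hand trace: volume_above(h) counts
  # bins with left edge >= h, so descending from 1.0 the cumulative volume
  # first reaches 50 at the left edge of bin 20 (4*11 + 8 = 52 >= 50,
  # whereas from bin 21 it is 4*10 + 8 = 48): EP = 0.19. Bin 20 is flat,
  # not a peak; the first peak strictly above is bin 90 (counts 2,4,2
  # around it), so T = 0.89.
  counts <- rep(0, 100)
  counts[5:30] <- 4
  counts[89:91] <- c(2, 4, 2)
  h <- cs_histogram_from_counts(counts, voxel_volume_ml = 1)
  res <- suggest_threshold(h, max_volume_ml = 50, smooth_window = 1)
  expect_equal(res$EP, 0.19)
  expect_false(res$ep_is_peak)
  expect_equal(res$T, 0.89)
  expect_equal(res$volume_at_T_ml, 6)
  expect_gte(res$T, res$EP)
})

test_that("small scenes fall back to the lowest occupied edge", {
  # total volume below the cap: EP starts at the first non-empty bin's
  # right edge and the search climbs to the only peak
  counts <- rep(0, 20)
  counts[3] <- 2          # faint low mass
  counts[15] <- 6         # vessel mode
  h <- cs_histogram_from_counts(counts, voxel_volume_ml = 0.001)
  res <- suggest_threshold(h, max_volume_ml = 50, smooth_window = 1)
  expect_equal(res$EP, 3 / 20)
  expect_equal(res$T, 14 / 20)   # left edge of peak bin 15
})

test_that("degenerate single-mode histograms resolve sensibly", {
  # everything in the last bin with volume over the cap
  h <- cs_histogram_from_counts(c(rep(0, 9), 60000), voxel_volume_ml = 0.001)
  res <- suggest_threshold(h, max_volume_ml = 50, smooth_window = 1)
  expect_equal(res$EP, 1.0)
  expect_true(res$ep_is_peak)
  expect_equal(res$T, 1.0)

  # no peak above EP: falls back to EP with a warning
  h2 <- cs_histogram_from_counts(c(100, 90, 80, 70, 60, 50, 0, 0, 0, 0),
                                 voxel_volume_ml = 1)
  expect_warning(res2 <- suggest_threshold(h2, max_volume_ml = 50,
                                           smooth_window = 1), "no peak")
  expect_equal(res2$T, res2$EP)

  expect_error(suggest_threshold(cs_histogram_from_counts(rep(0, 5), 1), 50),
               "empty")
})

test_that("thresholding keeps the seed and is monotone in T", {
  v <- array(runif(125, 0, 0.9), dim = c(5, 5, 5))
  v[3, 3, 3] <- 1
  cs <- make_cs(v, seed = c(3, 3, 3))
  expect_equal(sum(apply_threshold(cs, 1.0)$values), 1)
  expect_true(apply_threshold(cs, 1.0)$values[3, 3, 3])
  sizes <- vapply(c(0.05, 0.2, 0.5, 0.8, 1), function(t)
    sum(apply_threshold(cs, t)$values), 0)
  expect_true(all(diff(sizes) <= 0))
  expect_error(apply_threshold(cs, 0), "0, 1")
  expect_error(apply_threshold(cs, 1.2), "0, 1")
})
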