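test_that("tube rasterization matches brute-force voxel-centre distances", {
  spec <- phantom_spec(shape = c(20, 20, 16), blur_sigma_mm = 0, noise_sd = 0,
                       tree = list(list(from = c(9, 9, 2), to = c(9, 9, 13),
                                        radius = 2)))
  ph <- generate_phantom(spec)
  # independent enumeration over every voxel centre
  expected <- array(FALSE, dim = spec$shape)
  for (x in 1:20) for (y in 1:20) for (z in 1:16) {
    p <- c(x - 1, y - 1, z - 1)
    tz <- min(max(p[3], 2), 13)
    d2 <- (p[1] - 9)^2 + (p[2] - 9)^2 + (p[3] - tz)^2
    expected[x, y, z] <- d2 <= 4
  }
  expect_identical(ph$truth$values, expected)
  # two-level image with vessel/background values only
  expect_setequal(unique(as.vector(ph$scene$values)), c(80, 160))
  expect_true(all(ph$scene$values[ph$truth$values] == 160))
})

test_that("phantom generation is deterministic in its seed", {
  a <- default_phantom(rng_seed = 7)
  b <- default_phantom(rng_seed = 7)
  c <- default_phantom(rng_seed = 8)
  expect_identical(a$scene$values, b$scene$values)
  expect_identical(a$truth$values, b$truth$values)
  expect_false(identical(a$scene$values, c$scene$values))
  # generation does not disturb the global RNG stream
  set.seed(1); before <- rnorm(3)
  set.seed(1); invisible(default_phantom(rng_seed = 9)); after <- rnorm(3)
  expect_identical(before, after)
})

test_that("branching trees have the promised geometry", {
  t1 <- branching_tree(levels = 1, rng_seed = 2)
  expect_length(t1, 1)
  t3 <- branching_tree(levels = 3, decay = 0.7, radius0 = 3, rng_seed = 2)
  expect_length(t3, 7)
  radii <- sort(unique(vapply(t3, `[[`, 0, "radius")), decreasing = TRUE)
  expect_equal(radii, c(3, 2.1, 1.47))
  expect_identical(t3, branching_tree(levels = 3, decay = 0.7, radius0 = 3,
                                      rng_seed = 2))
})

test_that("phantom rejects out-of-volume tubes and empty trees", {
  expect_error(generate_phantom(phantom_spec(tree = NULL)), "no tube")
  bad <- phantom_spec(shape = c(10, 10, 10),
                      tree = list(list(from = c(5, 5, 0), to = c(5, 5, 40),
                                       radius = 1)))
  expect_error(generate_phantom(bad), "outside the volume")
  expect_error(phantom_spec(vessel_mean = 80, background_mean = 90),
               "exceed")
})

test_that("phantom specs round-trip through YAML", {
  spec <- phantom_spec(shape = c(12, 12, 12), noise_sd = 4,
                       tree = list(list(from = c(5, 5, 2), to = c(5, 5, 9),
                                        radius = 1.5)))
  p <- file.path(tempdir(), "spec.yaml")
  write_phantom_spec(spec, p)
  back <- read_phantom_spec(p)
  expect_equal(back$shape, spec$shape)
  expect_equal(back$noise_sd, spec$noise_sd)
  expect_identical(generate_phantom(back)$scene$values,
                   generate_phantom(spec)$scene$values)
})

test_that("affinity parameters are recoverable from the default phantom", {
  ph <- default_phantom(rng_seed = 3)
  seed <- seed_in_trunk(ph)
  p <- estimate_params(ph$scene, seed)
  expect_gt(p$m, 150)
  expect_lt(p$m, 170)
})

test_that("the weak bridge carries connectivity between vessel systems", {
  # bridge at full vessel intensity: the second tree is strongly reached
  ph <- two_system_phantom(phantom_spec(shape = c(40, 40, 40),
                                        blur_sigma_mm = 0, noise_sd = 0),
                           bridge_intensity = 160)
  t1 <- attr(ph, "tree1"); t2 <- attr(ph, "tree2")
  expect_true(any(t1$values) && any(t2$values))
  expect_false(any(t1$values & t2$values))
  expect_identical(ph$truth$values, t1$values | t2$values)

  idx <- which(t1$values, arr.ind = TRUE)
  seed <- as.integer(idx[1, ])
  p <- estimate_params(ph$scene, seed)
  cs <- compute_connectivity(replace_seed_value(ph$scene, seed, p), seed,
                             params = p)
  expect_gt(max(cs$values[t2$values]), 0.5)

  # without the bridge the second system stays at background-level
  ph0 <- two_system_phantom(phantom_spec(shape = c(40, 40, 40),
                                         blur_sigma_mm = 0, noise_sd = 0),
                            bridge_intensity = NA)
  cs0 <- compute_connectivity(replace_seed_value(ph0$scene, seed, p), seed,
                              params = p)
  expect_lt(max(cs0$values[t2$values]), 1e-6)
  expect_identical(ph0$truth$values, ph$truth$values)
})
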