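fake_trace <- function(thetas, sizes) {
  structure(list(thetas = thetas, sizes = sizes,
                 join_theta = array(NA_integer_, dim = c(1, 1, 1)),
                 truncated = FALSE, spacing = c(1, 1, 1), seed = c(1, 1, 1)),
            class = "rrg_trace")
}

test_that("uniform scenes flood entirely at the seed intensity", {
  sc <- scene(array(120L, dim = c(6, 6, 4)))
  tr <- rrg_grow(sc, c(3, 3, 2), theta_end = 120)
  expect_equal(tr$thetas, 120)
  expect_equal(tr$sizes, prod(sc$dim))
})

test_that("two-level tube: flat trace, jump into background, exact mask", {
  tp <- tube_scene(shape = c(20, 20, 12), axis_xy = c(10, 10), radius = 2.5,
                   vessel = 180, background = 80)
  seed <- c(10, 10, 6)
  tr <- rrg_grow(tp$scene, seed, theta_end = 70)
  tube_n <- n_true(tp$mask)
  sizes <- tr$sizes
  thetas <- tr$thetas
  expect_true(all(sizes[thetas > 80] == tube_n))
  expect_equal(sizes[thetas == 80], prod(dim(tp$scene$values)))
  expect_true(all(diff(sizes) >= 0))       # nesting as theta descends

  expect_equal(select_theta_opt(tr), 81)
  mask <- rrg_segment(tp$scene, seed, theta_end = 70)
  expect_equal(attr(mask, "theta_opt"), 81)
  expect_identical(mask$values, tp$mask$values)
  expect_equal(sum(mask$values), sizes[thetas == 81])
  expect_true(mask$values[seed[1], seed[2], seed[3]])
})

test_that("theta_opt sits just above the largest relative jump", {
  tr <- fake_trace(thetas = c(150, 149, 148, 147),
                   sizes = c(10, 11, 12, 5000))
  expect_equal(select_theta_opt(tr), 148)
  expect_equal(select_theta_opt(tr, strategy = "absolute"), 148)
  # ties resolve toward the larger theta
  tr2 <- fake_trace(thetas = 110:101, sizes = c(5, 10, 10, 20, 20, 40, 40,
                                                80, 80, 160))
  expect_equal(select_theta_opt(tr2), 110)
})

test_that("traces without a distinguished jump fall back with a warning", {
  expect_warning(t1 <- select_theta_opt(fake_trace(100:96, rep(7, 5))),
                 "no distinguished jump")
  expect_equal(t1, 96)
  expect_warning(t2 <- select_theta_opt(fake_trace(100:96, seq(10, 50, 10))),
                 "no distinguished jump")
  expect_equal(t2, 96)
  expect_error(select_theta_opt(fake_trace(100, 5)), "at least 2")
})

test_that("seed membership, nesting and the growth guard", {
  set.seed(51)
  v <- array(sample(60:200, 14 * 12 * 10, TRUE), dim = c(14, 12, 10))
  sc <- scene(v)
  seed <- c(7, 6, 5)
  tr <- rrg_grow(sc, seed, theta_end = 60)
  expect_true(all(diff(tr$sizes) >= 0))
  # region at theta is a superset of the region at theta + 1
  for (th in tr$thetas[-1]) {
    a <- rrg_mask_at(tr, th)$values
    b <- rrg_mask_at(tr, th + 1L)$values
    expect_true(all(a[b]))
  }
  expect_true(rrg_mask_at(tr, tr$thetas[1])$values[7, 6, 5])

  expect_warning(trc <- rrg_grow(sc, seed, theta_end = 60, max_voxels = 200),
                 "truncated")
  expect_true(trc$truncated)
  expect_lt(length(trc$thetas), length(tr$thetas))

  expect_error(rrg_grow(sc, seed, theta_end = 250), "exceeds the seed")
})

test_that("the rrg() front end wraps trace, selection and mask", {
  tp <- tube_scene(shape = c(18, 18, 10), axis_xy = c(9, 9), radius = 2)
  fit <- rrg(tp$scene, c(9, 9, 5), theta_end = 70)
  expect_s3_class(fit, "rrg")
  expect_equal(fit$theta_opt, 81)
  expect_identical(fit$mask$values, tp$mask$values)
  expect_equal(fit$volume$voxel_count, n_true(tp$mask))
  expect_output(print(fit), "theta_opt = 81")
})
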