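test_that("path strength is the weakest link, 1 for a trivial path", {
  p <- affinity_params(m = 150, s = 20)
  sc <- scene(array(c(150, 150, 110, 150), dim = c(1, 1, 4)))
  expect_equal(path_strength(rbind(c(1, 1, 2)), sc, p), 1.0)
  path <- rbind(c(1, 1, 1), c(1, 1, 2), c(1, 1, 3), c(1, 1, 4))
  links <- fuzzy_affinity(sc$values[1, 1, 1:3], sc$values[1, 1, 2:4], p)
  expect_equal(path_strength(path, sc, p), min(links))
  expect_equal(path_strength(path[4:1, ], sc, p),
               path_strength(path, sc, p))
  bad <- rbind(c(1, 1, 1), c(1, 1, 3))
  expect_error(path_strength(bad, sc, p), "adjacent")
})

test_that("chain connectivity is the running minimum of link affinities", {
  p <- affinity_params(m = 150, s = 12)
  sc <- scene(array(c(150, 148, 120, 135, 150, 90), dim = c(1, 1, 6)))
  links <- fuzzy_affinity(sc$values[1, 1, 1:5], sc$values[1, 1, 2:6], p)
  cs <- compute_connectivity(sc, c(1, 1, 1), params = p)
  expect_equal(as.vector(cs$values), c(1, cummin(links)))
})

test_that("connectivity takes the stronger of two loop paths", {
  # 2x2x1 loop: seed at (1,1); the direct link to (2,1) is weak, the
  # two-hop path via (1,2)/(2,2) is strong
  p <- affinity_params(m = 100, s = 10)
  v <- array(0, dim = c(2, 2, 1))
  v[1, 1, 1] <- 100; v[1, 2, 1] <- 100; v[2, 2, 1] <- 100
  v[2, 1, 1] <- 70   # direct link (1,1)-(2,1) has pair mean 85
  sc <- scene(v)
  aff <- function(a, b) fuzzy_affinity(a, b, p)
  direct <- aff(100, 70)
  around <- min(aff(100, 100), aff(100, 100), aff(100, 70))
  cs <- compute_connectivity(sc, c(1, 1, 1), params = p)
  expect_equal(cs$values[2, 1, 1], max(direct, around))
  expect_equal(cs$values[2, 2, 1], 1.0)
})

test_that("propagation matches the Bellman-Ford oracle on random scenes", {
  set.seed(17)
  for (i in 1:40) {
    sc <- random_scene(c(4, 4, 3))
    p <- random_params()
    seed <- random_seed_index(c(4, 4, 3))
    fast <- compute_connectivity(sc, seed, params = p)
    slow <- connectivity_oracle(sc, seed, p)
    expect_identical(fast$values, slow$values)
  }
})

test_that("uniform scene at m has connectivity 1 everywhere", {
  p <- affinity_params(m = 140, s = 9)
  sc <- scene(array(140, dim = c(6, 5, 4)))
  cs <- compute_connectivity(sc, c(3, 3, 2), params = p)
  expect_true(all(cs$values == 1))
})

test_that("an underflow slab cuts the scene into exact zeros", {
  # slab at intensity 0 with m = 200, s = 2: link Gaussian underflows to
  # exactly 0 in double precision, so nothing beyond the slab is reached
  p <- affinity_params(m = 200, s = 2)
  v <- array(200, dim = c(3, 3, 7))
  v[, , 4] <- 0
  cs <- compute_connectivity(scene(v), c(2, 2, 1), params = p)
  expect_true(all(cs$values[, , 1:3] == 1))
  expect_true(all(cs$values[, , 4:7] == 0))
})

test_that("queue tie-breaking does not affect the result", {
  set.seed(23)
  for (i in 1:10) {
    sc <- random_scene(c(5, 4, 3))
    p <- random_params()
    seed <- random_seed_index(c(5, 4, 3))
    a <- compute_connectivity(sc, seed, params = p, tie_break = "fifo")
    b <- compute_connectivity(sc, seed, params = p, tie_break = "lifo")
    expect_identical(a$values, b$values)
  }
})

test_that("no voxel exceeds the strongest first link from the seed", {
  set.seed(29)
  for (i in 1:10) {
    sc <- random_scene(c(4, 4, 4))
    p <- random_params()
    seed <- random_seed_index(c(4, 4, 4))
    cs <- compute_connectivity(sc, seed, params = p)
    f <- sc$values
    nb <- c()
    for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1))) {
      q <- seed + d
      if (all(q >= 1) && all(q <= sc$dim))
        nb <- c(nb, fuzzy_affinity(f[seed[1], seed[2], seed[3]],
                                   f[q[1], q[2], q[3]], p))
    }
    others <- cs$values
    others[seed[1], seed[2], seed[3]] <- 0
    expect_lte(max(others), max(nb))
    expect_equal(cs$values[seed[1], seed[2], seed[3]], 1.0)
  }
})

test_that("connectivity scenes survive a float round-trip on disk", {
  sc <- tube_scene(shape = c(12, 12, 8))$scene
  p <- estimate_params(sc, c(12, 12, 4), cube_edge = 8)
  cs <- compute_connectivity(sc, c(12, 12, 4), params = p)
  path <- file.path(tempdir(), "cs.nii.gz")
  write_scene(cs, path)
  expect_equal(read_scene(path)$values, cs$values, tolerance = 1e-15)
})
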