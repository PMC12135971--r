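test_that("hexagonal spacing follows the close-packing geometry", {
  phimax <- pi / (2 * sqrt(3))
  expect_equal(hexagonal_spacing(phimax), 2)           # disks touch
  expect_equal(hexagonal_spacing(0.6), sqrt(2 * pi / (sqrt(3) * 0.6)))
  expect_equal(hexagonal_spacing(0.6), 2.4589, tolerance = 1e-4)
  # a scales as phi^(-1/2)
  expect_equal(hexagonal_spacing(0.15), 2 * hexagonal_spacing(0.6))
  expect_error(hexagonal_spacing(0.95), "close-packing")
  expect_error(packing_spec(phimax + 0.001, 100), "close-packing")
  expect_error(packing_spec(0.3, l = 3), "exceed 4")
})

test_that("hexagonal initialization fills the box just below target", {
  p <- hexagonal_init(packing_spec(0.6, l = 500))
  expect_identical(p$n_x, 203L)
  expect_identical(p$n_y, 234L)
  expect_equal(p$phi_actual, 203 * 234 * pi / 500^2)
  expect_equal(p$phi_actual, 0.5969, tolerance = 1e-4)
  expect_lte(p$phi_actual, 0.6)

  # small dense and dilute lattices are overlap-free under brute force
  for (spec in list(packing_spec(0.05, 20), packing_spec(0.71, 30),
                    packing_spec(0.85, 40))) {
    q <- hexagonal_init(spec)
    expect_identical(nrow(q$positions), q$n_x * q$n_y)
    expect_true(all(q$positions >= 0 & q$positions[, 1] < q$l))
    expect_gte(r_brute_min_dist(q$positions, q$l), 2)
  }
  expect_error(hexagonal_init(packing_spec(0.05, 10)), "too small")
})

test_that("minimum-image distance uses the nearest periodic copy", {
  expect_equal(min_image_distance(c(0.5, 0.5), c(499.5, 0.5), 500), 1)
  expect_equal(min_image_distance(c(3, 4), c(3, 4), 500), 0)
  expect_equal(min_image_distance(c(0, 0), c(3, 4), 500), 5)
  # agrees with the plain-R oracle on random pairs
  set.seed(4)
  for (i in 1:50) {
    a <- runif(2, 0, 77); b <- runif(2, 0, 77)
    expect_equal(min_image_distance(a, b, 77), r_min_image_dist(a, b, 77))
  }
})

test_that("tile grid holds one disk per tile and tracks moves", {
  p <- hexagonal_init(packing_spec(0.6, l = 500))
  g <- build_tile_grid(p)
  expect_identical(attr(g, "n_tiles"), 354)
  expect_equal(attr(g, "tile_side"), 500 / 354)
  expect_lte(attr(g, "tile_side"), sqrt(2))
  expect_identical(sum(g > 0), nrow(p$positions))

  # empty configuration: all tiles empty
  empty <- p; empty$positions <- p$positions[0, , drop = FALSE]
  expect_true(all(build_tile_grid(empty) == -1L))

  # overlapping disks betray themselves as a double-occupied tile
  bad <- p; bad$positions[2, ] <- bad$positions[1, ] + 0.01
  expect_error(build_tile_grid(bad), "one tile")

  # incremental update equals rebuild from scratch across accepted moves
  set.seed(8)
  q <- hexagonal_init(packing_spec(0.3, l = 25))
  g <- build_tile_grid(q)
  for (i in 1:200) {
    st <- attempt_move(q, g, sample(nrow(q$positions), 1), sigma = 0.4)
    q <- st$packing; g <- st$grid
  }
  expect_identical(unclass(g)[, ], unclass(build_tile_grid(q))[, ])
})

test_that("tile-based collision check matches brute force", {
  # strict inequality at contact: 1.99 collides, 2.00 does not
  p <- hexagonal_init(packing_spec(0.1, l = 40))
  p$positions <- rbind(c(10, 10), c(20, 20))
  g <- build_tile_grid(p)
  expect_true(collision_check(g, p, 1, c(20 - 1.99, 20)))
  expect_false(collision_check(g, p, 1, c(20 - 2.0, 20)))

  # random probes against the plain-R all-pairs oracle
  run <- run_packing(packing_spec(0.4, l = 40, seed = 2), n_sweeps = 60,
                     burn_in = 20, sample_interval = 20)
  for (pk in run$samples) {
    gg <- build_tile_grid(pk)
    set.seed(12)
    for (i in 1:2500) {
      id <- sample(nrow(pk$positions), 1)
      prop <- runif(2, 0, pk$l)
      expect_identical(collision_check(gg, pk, id, prop),
                       r_brute_collision(pk$positions, pk$l, id, prop))
    }
  }
})

test_that("attempted moves preserve the hard core and reject atomically", {
  # single disk: nothing to collide with
  p <- hexagonal_init(packing_spec(0.05, l = 30))
  p$positions <- p$positions[1, , drop = FALSE]
  g <- build_tile_grid(p)
  set.seed(3)
  acc <- vapply(1:50, function(i) {
    st <- attempt_move(p, g, 1, sigma = 1)
    p <<- st$packing; g <<- st$grid
    st$accepted
  }, logical(1))
  expect_true(all(acc))

  # dense box: state unchanged on rejection, invariant held throughout
  set.seed(5)
  q <- hexagonal_init(packing_spec(0.71, l = 16))
  g <- build_tile_grid(q)
  for (i in 1:400) {
    before <- q$positions
    st <- attempt_move(q, g, sample(nrow(q$positions), 1))
    if (!st$accepted) expect_identical(st$packing$positions, before)
    q <- st$packing; g <- st$grid
    if (i %% 20 == 0) expect_gte(r_brute_min_dist(q$positions, q$l), 2)
  }
  expect_gte(r_brute_min_dist(q$positions, q$l), 2)
})

test_that("step-size tuning shrinks sigma only under crowding", {
  set.seed(6)
  dil <- hexagonal_init(packing_spec(0.05, l = 60))
  t1 <- tune_step_size(dil)
  expect_equal(t1$sigma, dil$sigma)          # dilute: first window passes
  expect_lte(t1$rejection_rate, 0.5)

  # an oversized step at high density must be shrunk by powers of 0.8
  dense <- hexagonal_init(packing_spec(0.71, l = 60))
  t2 <- tune_step_size(dense, step_policy(sigma = 1))
  expect_lt(t2$sigma, 1)
  expect_lte(t2$rejection_rate, 0.5)
  k <- log(t2$sigma) / log(0.8)
  expect_equal(k, round(k), tolerance = 1e-9)
})

test_that("simulation runs count sweeps, sample on schedule and stay valid", {
  spec <- packing_spec(0.3, l = 40, seed = 14)
  r0 <- run_packing(spec, n_sweeps = 30, burn_in = 30, sample_interval = 10)
  expect_length(r0$samples, 0)
  r2 <- run_packing(spec, n_sweeps = 50, burn_in = 30, sample_interval = 10)
  expect_length(r2$samples, 2)

  run <- run_packing(packing_spec(0.3, l = 60, seed = 1), n_sweeps = 500,
                     burn_in = 100, sample_interval = 100)
  expect_gt(run$acceptance_rate, 0.5)
  for (pk in run$samples)
    expect_gte(r_brute_min_dist(pk$positions, pk$l), 2)

  # determinism: same spec and seed give the identical trajectory
  a <- run_packing(packing_spec(0.4, l = 30, seed = 99), n_sweeps = 40,
                   burn_in = 20, sample_interval = 10)
  b <- run_packing(packing_spec(0.4, l = 30, seed = 99), n_sweeps = 40,
                   burn_in = 20, sample_interval = 10)
  expect_identical(a$packing$positions, b$packing$positions)
  expect_identical(a$samples[[2]]$positions, b$samples[[2]]$positions)
})

test_that("snapshots round-trip bit-identically", {
  run <- run_packing(packing_spec(0.5, l = 30, seed = 4), n_sweeps = 20,
                     burn_in = 10, sample_interval = 10)
  p <- run$samples[[1]]
  f <- tempfile(fileext = ".txt")
  write_snapshot(p, f)
  q <- read_snapshot(f)
  expect_identical(q$positions[, ], p$positions[, ])
  expect_identical(q$l, p$l)
  expect_identical(q$phi0, p$phi0)
  expect_identical(q$phi_actual, p$phi_actual)
  expect_identical(q$seed, p$seed)
  unlink(f)
})
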