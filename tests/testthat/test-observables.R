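test_that("tilt angle follows the folded arccos definition", {
  expect_equal(compute_theta(c(0, 0, 1), c(0, 0, 1)), 0)
  expect_equal(compute_theta(c(0, 0, -1), c(0, 0, 1)), 0)  # fore-aft fold
  expect_equal(compute_theta(c(1, 0, 0), c(0, 0, 1)), 90)
  expect_equal(compute_theta(c(1, 0, 1), c(0, 0, 1)), 45)
  expect_error(compute_theta(c(0, 0, 0), c(0, 0, 1)), "zero")
})

test_that("depth is positive inside the undistorted sphere", {
  ctr <- c(1, 2, 3)
  expect_equal(compute_depth(ctr + c(5, 0, 0), ctr, 5), 0)
  expect_equal(compute_depth(ctr + c(3, 0, 0), ctr, 5), 2)
  expect_equal(compute_depth(ctr + c(7, 0, 0), ctr, 5), -2)
})

test_that("theta and d are invariant under global rotation and translation", {
  set.seed(21)
  for (k in 1:5) {
    axis <- random_unit()
    com <- stats::rnorm(3) * 3
    ctr <- stats::rnorm(3)
    R <- 8
    Q <- random_rotation()
    shift <- stats::rnorm(3) * 10
    th1 <- compute_theta(axis, com - ctr)
    d1 <- compute_depth(com, ctr, R)
    com2 <- as.numeric(Q %*% com + shift)
    ctr2 <- as.numeric(Q %*% ctr + shift)
    axis2 <- as.numeric(Q %*% axis)
    expect_equal(compute_theta(axis2, com2 - ctr2), th1, tolerance = 1e-10)
    expect_equal(compute_depth(com2, ctr2, R), d1, tolerance = 1e-10)
  }
})

test_that("equatorial band filter keeps exactly -0.8R < z < 0.8R", {
  fr <- data.frame(z = c(0, 0.79, 0.8, 0.9, -0.79, -0.85), R = 1)
  kept <- filter_equatorial_band(fr)
  expect_equal(kept$z, c(0, 0.79, -0.79))
  # uniform z on [-R, R]: kept fraction tends to 0.8
  z <- seq(-1, 1, length.out = 200001)
  frac <- nrow(filter_equatorial_band(data.frame(z = z, R = 1))) / length(z)
  expect_equal(frac, 0.8, tolerance = 1e-3)
})

test_that("wrapped fractions resolve empty, single-lobe and full coverage", {
  a <- 2
  ctr <- c(0, 0, 0); ax <- c(0, 0, 1)
  expect_equal(unname(wrapped_fraction(matrix(0, 0, 3), ctr, ax, a, 1.0)),
               c(0, 0))
  # beads far away
  far <- matrix(rnorm(30) + 50, 10, 3)
  expect_equal(unname(wrapped_fraction(far, ctr, ax, a, 1.0)), c(0, 0))
  # beads tiling exactly lobe 1 (centre +a*axis) at contact distance
  mesh <- vesiwrap:::fibonacci_sphere(2000) * (a + 0.5)
  lobe1 <- sweep(mesh, 2, ctr + a * ax, `+`)
  f <- wrapped_fraction(lobe1, ctr, ax, a, contact_cutoff = 0.8)
  expect_gt(f[1], 0.98)
  expect_lt(f[2], 0.02)
  # both lobes tiled
  lobe2 <- sweep(mesh, 2, ctr - a * ax, `+`)
  f2 <- wrapped_fraction(rbind(lobe1, lobe2), ctr, ax, a, 0.8)
  expect_gt(f2[1], 0.98)
  expect_gt(f2[2], 0.98)
})

test_that("relabelling the lobes swaps the fractions", {
  a <- 2
  mesh <- vesiwrap:::fibonacci_sphere(800) * (a + 0.5)
  lobe1 <- sweep(mesh, 2, c(0, 0, a), `+`)
  f <- wrapped_fraction(lobe1, c(0, 0, 0), c(0, 0, 1), a, 0.8)
  fswap <- wrapped_fraction(lobe1, c(0, 0, 0), c(0, 0, -1), a, 0.8)
  expect_equal(unname(f), unname(rev(fswap)), tolerance = 1e-12)
})

test_that("state classifier matches an independent decision table", {
  grid <- seq(0, 1, by = 0.01)
  thetas <- c(NA, 10, 50)
  for (contact2 in c(FALSE, TRUE)) {
    for (att in c(FALSE, TRUE)) {
      for (th in thetas) {
        for (f1 in grid) {
          f2s <- grid[grid <= f1]
          got <- vapply(f2s, function(f2) {
            classify_wrap_state(f1, f2, contact2, att, th)
          }, character(1))
          want <- vapply(f2s, function(f2) {
            oracle_classify(f1, f2, contact2, att, th)
          }, character(1))
          expect_identical(got, want)
          expect_true(all(got %in% wrap_states()))
        }
      }
    }
  }
})

test_that("classifier reproduces the canonical states and rejects bad input", {
  expect_identical(classify_wrap_state(0.95, 0.95, TRUE, TRUE), "F")
  expect_identical(classify_wrap_state(0.95, 0, FALSE, TRUE), "D")
  expect_identical(classify_wrap_state(0.3, 0, FALSE, TRUE), "B")
  expect_identical(classify_wrap_state(0.02, 0, FALSE, TRUE, theta = 10), "A1")
  expect_identical(classify_wrap_state(0.02, 0, FALSE, TRUE, theta = 70), "A2")
  expect_identical(classify_wrap_state(0.02, 0.01, TRUE, TRUE), "A3")
  expect_error(classify_wrap_state(1.2, 0, FALSE, TRUE), "\\[0, 1\\]")
  expect_error(classify_wrap_state(0.2, 0.5, FALSE, TRUE), "f1")
})

test_that("transition times are measured between run onsets", {
  tt <- transition_times(c(rep("B", 10), rep("E1", 10)),
                         seq(0, 190, by = 10), debounce = 5)
  expect_equal(nrow(tt), 1)
  expect_identical(tt$from, "B")
  expect_identical(tt$to, "E1")
  expect_equal(tt$duration, 100)
})

test_that("single-frame flickers are debounced away", {
  states <- c(rep("B", 20), "C", rep("B", 20))
  tt <- transition_times(states, seq_along(states), debounce = 5)
  expect_equal(nrow(tt), 0)  # B-C-B flicker collapses to a single B run
  # but a sustained C run is kept
  states2 <- c(rep("B", 20), rep("C", 8), rep("B", 20))
  tt2 <- transition_times(states2, seq_along(states2), debounce = 5)
  expect_equal(tt2$from, c("B", "C"))
})

test_that("empty series give an empty transition table", {
  tt <- transition_times(character(0), numeric(0))
  expect_equal(nrow(tt), 0)
})

test_that("time binning reproduces closed-form window means", {
  s <- data.frame(time = seq(0, 10, by = 0.1), theta = 5)
  b <- bin_time_average(s, 1)
  expect_true(all(b$theta == 5))
  # whole-series window: one point, the global mean
  s2 <- data.frame(time = seq(0, 9.9, by = 0.1), theta = seq(0, 9.9, by = 0.1))
  b2 <- bin_time_average(s2, 10)
  expect_equal(nrow(b2), 1)
  expect_equal(b2$theta, mean(s2$theta))
  expect_equal(b2$n, nrow(s2))
  # linear ramp theta(t) = t sampled at bin midpoint offsets
  s3 <- data.frame(time = seq(0.05, 9.95, by = 0.1),
                   theta = seq(0.05, 9.95, by = 0.1))
  b3 <- bin_time_average(s3, 1)
  expect_equal(b3$theta, seq(0.5, 9.5, by = 1), tolerance = 1e-12)
})
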