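test_that("a perfect circle has no fluctuation modes", {
  r <- matrix(7.3, nrow = 3, ncol = 128)
  m <- contour_modes(r)
  expect_true(all(Mod(m) < 1e-14))
})

test_that("a single cosine mode lands in the right bin with the right power", {
  phi <- 2 * pi * (0:127) / 128
  R <- 10
  r <- matrix(R * (1 + 0.01 * cos(3 * phi)), nrow = 1)
  m <- contour_modes(r)
  expect_equal(unname(Mod(m[1, "3"])), 0.005, tolerance = 1e-10)
  expect_true(all(Mod(m[1, setdiff(colnames(m), "3")]) < 1e-14))
})

test_that("mode powers satisfy Parseval's identity", {
  set.seed(31)
  r <- matrix(10 * (1 + 0.01 * rnorm(5 * 128)), nrow = 5)
  rel <- r / rowMeans(r) - 1
  total_var <- mean(rowMeans(rel^2))
  # sum over the full DFT (positive modes count twice; Nyquist bin once)
  m <- contour_modes(r, n_max = 64)
  power <- 2 * rowSums(Mod(m[, 1:63])^2) + Mod(m[, 64])^2
  expect_equal(mean(power), total_var, tolerance = 1e-10)
})

test_that("non-uniform angular sampling is rejected", {
  expect_error(contour_series(matrix(1, 2, 64), angles = sort(runif(64))),
               "uniform")
})

test_that("spectrum model has the right limits and monotonicity", {
  kT <- thermal_energy()
  # tensionless limit: proportional to 1/((n^2-1) n^2)
  n <- 2:12
  m0 <- spectrum_model(n, 0, 20 * kT, 1e-5, kT)
  expect_equal(m0 / m0[1], ((n^2 - 1) * n^2)[1] / ((n^2 - 1) * n^2),
               tolerance = 1e-12)
  # strictly decreasing in sigma and in n
  sig <- 10^seq(-9, -5, length.out = 9)
  for (nn in c(3, 7, 15)) {
    v <- spectrum_model(nn, sig, 20 * kT, 1e-5, kT)
    expect_true(all(diff(v) < 0))
  }
  for (s in sig) {
    v <- spectrum_model(2:20, s, 20 * kT, 1e-5, kT)
    expect_true(all(diff(v) < 0))
  }
  # amplitudes vanish in the high-tension limit
  expect_lt(spectrum_model(3, 1, 20 * kT, 1e-5, kT), 1e-11)
  expect_error(spectrum_model(1, 1e-7, 20 * kT, 1e-5), "n >= 2")
})

test_that("fit recovers exactly from noiseless model powers", {
  kT <- thermal_energy()
  sigma <- 1e-7; kappa <- 20 * kT; R <- 1e-5
  n_angles <- 128
  ns <- 2:floor((n_angles - 1) / 2)
  mvar <- spectrum_model(ns, sigma, kappa, R, kT)
  # frames whose mode amplitudes are exactly sqrt(model mean)
  spec <- complex(real = rep(0, n_angles))
  spec[ns + 1] <- sqrt(mvar) * n_angles
  spec[n_angles + 1 - ns] <- sqrt(mvar) * n_angles
  rel <- Re(fft(spec, inverse = TRUE)) / n_angles
  radii <- matrix(rep(R * (1 + rel), each = 120), nrow = 120, byrow = FALSE)
  fit <- fit_fluctuation_spectrum(radii, R = R, kBT = kT)
  expect_true(fit$converged)
  expect_equal(fit$sigma, sigma, tolerance = 1e-6)
  expect_equal(fit$kappa, kappa, tolerance = 1e-6)
})

test_that("parameters are recovered from synthetic contours", {
  kT <- thermal_energy()
  series <- synth_contours(1e-7, 20 * kT, 1e-5, n_frames = 2000, seed = 42)
  fit <- fit_fluctuation_spectrum(series)
  expect_lt(abs(fit$sigma - 1e-7) / 1e-7, 0.10)
  expect_lt(abs(fit$kappa - 20 * kT) / (20 * kT), 0.20)
})

test_that("estimator precision degrades gracefully with fewer frames", {
  kT <- thermal_energy()
  est <- function(frames, seed) {
    s <- synth_contours(1e-7, 20 * kT, 1e-5, n_frames = frames, seed = seed)
    fit_fluctuation_spectrum(s)$sigma
  }
  seeds <- 1:12
  sd_small <- sd(vapply(seeds, function(s) est(150, s), numeric(1)))
  sd_large <- sd(vapply(seeds, function(s) est(1500, s + 100), numeric(1)))
  expect_gt(sd_small, sd_large)
})

test_that("inference is scale-equivariant", {
  kT <- thermal_energy()
  series <- synth_contours(1e-7, 20 * kT, 1e-5, n_frames = 800, seed = 7)
  f1 <- fit_fluctuation_spectrum(series)
  lam <- 3.7
  f2 <- fit_fluctuation_spectrum(series$radii * lam, R = series$R * lam,
                                 kBT = kT)
  # sigma R^2 / kappa is the dimensionless fitted combination
  x1 <- f1$sigma * f1$R^2 / f1$kappa
  x2 <- f2$sigma * f2$R^2 / f2$kappa
  expect_equal(x1, x2, tolerance = 1e-3)
  expect_equal(f2$kappa, f1$kappa, tolerance = 1e-3)
})

test_that("degenerate input is rejected", {
  expect_error(fit_fluctuation_spectrum(matrix(5, 120, 64)), "degenerate")
  expect_error(fit_fluctuation_spectrum(matrix(5 + rnorm(64 * 50, 0, 1e-3),
                                               50, 64)), "100 frames")
})
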