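# experimental-scale reference values used throughout: lobe radius a = d_s/2,
# d_s = 0.98 um; adhesion 0.69-0.79 uJ/m^2; microviscosity ~0.8 Pa.s
A_LOBE <- 0.49e-6
KT <- thermal_energy()

test_that("wrapped area is zero at the pole and two spheres at the far pole", {
  g <- dumbbell_geometry(A_LOBE)
  expect_equal(wrapped_area(0, g), 0)
  expect_gt(wrapped_area(g$s_max, g), 0.95 * 8 * pi * A_LOBE^2)
  # rho_n -> 0: total area tends to 8 pi a^2
  g2 <- dumbbell_geometry(A_LOBE, rho_n = 1e-4 * A_LOBE)
  expect_equal(wrapped_area(g2$s_max, g2), 8 * pi * A_LOBE^2,
               tolerance = 1e-3)
  expect_error(wrapped_area(-0.1 * g$s_max, g), "outside")
  expect_error(wrapped_area(1.1 * g$s_max, g), "outside")
})

test_that("wrapped area is strictly increasing in the front position", {
  g <- dumbbell_geometry(A_LOBE)
  s <- seq(0, g$s_max, length.out = 500)
  expect_true(all(diff(wrapped_area(s, g)) > 0))
})

test_that("wrapped area matches surface-of-revolution quadrature", {
  g <- dumbbell_geometry(A_LOBE)
  rho_of_s <- function(s) vesiwrap:::meridian(s, g)$rho
  # integrate zone by zone (the integrand has slope kinks at the joins)
  quad_area <- function(s) {
    brk <- c(0, g$s_b1, g$s_b2, g$s_max)
    ends <- pmin(brk[-1], s)
    total <- 0
    lo <- 0
    for (k in 1:3) {
      hi <- ends[k]
      if (hi > lo) {
        total <- total + stats::integrate(function(x) 2 * pi * rho_of_s(x),
                                          lo, hi, rel.tol = 1e-12)$value
      }
      lo <- brk[k + 1]
      if (s <= lo) break
    }
    total
  }
  for (s in seq(0.04, 0.99, length.out = 20) * g$s_max) {
    q <- quad_area(s)
    expect_lt(abs(wrapped_area(s, g) - q) / q, 1e-6)
  }
})

test_that("energy vanishes when all couplings are zero", {
  g <- dumbbell_geometry(A_LOBE)
  ep <- energy_params(0, 0, 0)
  s <- seq(0, g$s_max, length.out = 50)
  expect_true(all(wrapping_energy(s, ep, g) == 0))
})

test_that("single-sphere energy matches the closed sphere-wrapping form", {
  g1 <- dumbbell_geometry(A_LOBE, lobes = 1)
  W <- 0.76e-6; sig <- 1e-7
  ep <- energy_params(W, sig, 0)
  phi <- seq(0.01, pi - 0.01, length.out = 40)
  E_closed <- (-W + sig * (1 - cos(phi)) / 2) * 2 * pi * A_LOBE^2 *
    (1 - cos(phi))
  E_pkg <- wrapping_energy(phi * A_LOBE, ep, g1)
  expect_lt(max(abs(E_pkg - E_closed)) / max(abs(E_closed)), 1e-8)
})

test_that("energy is continuous across the zone boundaries", {
  g <- dumbbell_geometry(A_LOBE)
  ep <- energy_params(0.76e-6, 1e-7, 20 * KT)
  for (sb in c(g$s_b1, g$s_b2)) {
    el <- wrapping_energy(sb - 1e-12, ep, g)
    er <- wrapping_energy(sb + 1e-12, ep, g)
    expect_equal(el, er, tolerance = 1e-6)
  }
})

test_that("front velocity obeys the stall contract and drag linearity", {
  g <- dumbbell_geometry(A_LOBE)
  ep <- energy_params(0.76e-6, 1e-7, 20 * KT)  # strong neck barrier
  kp1 <- kinetic_params(0.8, 2)
  kp2 <- kinetic_params(1.6, 2)
  s <- seq(0.05, 0.95, length.out = 100) * g$s_max
  v1 <- front_velocity(s, ep, kp1, g)
  v2 <- front_velocity(s, ep, kp2, g)
  expect_true(all(v1 >= 0))
  # where the drive is negative (inside the neck) the front stalls
  neck <- s > g$s_b1 & s < g$s_b2
  expect_true(any(v1[neck] == 0))
  # doubling the viscosity halves the velocity wherever it moves
  moving <- v1 > 0
  expect_equal(v2[moving], v1[moving] / 2, tolerance = 1e-12)
})

test_that("sphere limit with constant drive gives v = W/(alpha eta) / L-density", {
  g1 <- dumbbell_geometry(A_LOBE, lobes = 1)
  W <- 0.76e-6
  ep <- energy_params(W, 0, 0)
  kp <- kinetic_params(0.8, 2)
  s <- seq(0.06, 0.94, length.out = 50) * g1$s_max
  # with kappa = sigma = 0, dE/ds = -W L(s), so v = W/(alpha eta) everywhere
  expect_equal(front_velocity(s, ep, kp, g1),
               rep(W / (kp$alpha * kp$eta_eff), length(s)),
               tolerance = 1e-12)
  # and the wrap time is path length / constant speed
  r <- time_to_wrap(0, ep, kp, g1)
  s_lo <- 0.05 * A_LOBE
  expect_equal(r$time, (g1$s_max - 2 * s_lo) / (W / (kp$alpha * kp$eta_eff)),
               tolerance = 1e-8)
})

test_that("overtensioned wrapping stalls immediately at first contact", {
  g <- dumbbell_geometry(A_LOBE)
  ep <- energy_params(1e-8, 0, 1e-21)  # weak adhesion
  kp <- kinetic_params(0.8, 2)
  r <- time_to_wrap(1e-4, ep, kp, g)   # enormous tension
  expect_identical(r$status, "stalled")
  expect_equal(r$s_star, 0.05 * A_LOBE, tolerance = 1e-6)
})

test_that("wrap time grows nonlinearly with tension and falls with adhesion", {
  g <- dumbbell_geometry(A_LOBE, rho_n = 0.6 * A_LOBE)
  kp <- kinetic_params(0.8, 2)
  sig <- seq(1e-9, 2e-8, length.out = 8)
  ep <- energy_params(0.76e-6, 0, 20 * KT)
  Tn <- wrap_time_curve(sig, ep, kp, g)
  expect_true(all(Tn$status == "wrapped"))
  expect_true(all(diff(Tn$time) > 0))
  expect_true(all(diff(diff(Tn$time)) > 0))   # positive discrete curvature
  # larger adhesion wraps faster at the same tension
  for (W in c(0.76e-6, 0.9e-6, 1.2e-6)) {
    T1 <- time_to_wrap(1e-8, energy_params(W, 0, 20 * KT), kp, g)$time
    T2 <- time_to_wrap(1e-8, energy_params(W * 1.1, 0, 20 * KT), kp, g)$time
    expect_lt(T2, T1)
  }
})

test_that("stall locations cluster at the waist at experimental-scale parameters", {
  g <- dumbbell_geometry(A_LOBE)      # geometric neck, rho_n = 0.15 a
  kp <- kinetic_params(0.8, 2)
  ep <- energy_params(0.76e-6, 0, 20 * KT)
  waist_lo <- g$s_b1 - g$rho_n * pi / 2
  waist_hi <- g$s_b2 + g$rho_n * pi / 2
  for (sig in c(2e-9, 5e-9, 1e-8)) {
    r <- time_to_wrap(sig, ep, kp, g)
    expect_identical(r$status, "stalled")
    expect_gt(r$s_star, waist_lo)
    expect_lt(r$s_star, waist_hi)
  }
})

test_that("fit recovers exactly from noiseless theory data", {
  g <- dumbbell_geometry(A_LOBE, rho_n = 0.6 * A_LOBE)
  ds <- synth_wraptime_dataset(W = 0.76e-6, eta_eff = 0.8, cv = 0, geom = g)
  fit <- fit_wrap_time(ds$sigma, ds$time, g, kappa = 20 * KT)
  expect_lt(abs(fit$W - 0.76e-6) / 0.76e-6, 1e-4)
  expect_lt(abs(fit$eta_eff - 0.8) / 0.8, 1e-4)
})

test_that("fit tolerates duplicate tensions with conflicting times", {
  g <- dumbbell_geometry(A_LOBE, rho_n = 0.6 * A_LOBE)
  ds <- synth_wraptime_dataset(cv = 0, geom = g)
  sig <- c(ds$sigma, ds$sigma[4])
  tt <- c(ds$time, ds$time[4] * 1.8)
  fit <- fit_wrap_time(sig, tt, g, kappa = 20 * KT)
  expect_s3_class(fit, "wrap_fit")
  expect_equal(length(fit$residuals), length(sig))
  expect_gt(max(abs(fit$residuals)), 0)
})

test_that("fit refuses underdetermined input", {
  g <- dumbbell_geometry(A_LOBE, rho_n = 0.6 * A_LOBE)
  expect_error(fit_wrap_time(c(1e-9, 2e-9), c(50, 60), g, 20 * KT),
               "at least 3")
})

test_that("rescaling all times rescales viscosity and leaves adhesion fixed", {
  g <- dumbbell_geometry(A_LOBE, rho_n = 0.6 * A_LOBE)
  ds <- synth_wraptime_dataset(cv = 0.03, seed = 5, geom = g)
  f1 <- fit_wrap_time(ds$sigma, ds$time, g, kappa = 20 * KT)
  lam <- 2.5
  f2 <- fit_wrap_time(ds$sigma, ds$time * lam, g, kappa = 20 * KT)
  expect_equal(f2$W, f1$W, tolerance = 1e-6)
  expect_equal(f2$eta_eff, lam * f1$eta_eff, tolerance = 1e-6)
})

test_that("barrierless landscapes give a zero fluctuation scale", {
  g <- dumbbell_geometry(A_LOBE)
  # overwhelming adhesion: monotone downhill, no barrier anywhere
  ep <- energy_params(1e-3, 0, 1e-22)
  expect_equal(barrier_fluctuation_scale(ep, g), 0)
})

test_that("the fluctuation scale shrinks as adhesion approaches threshold", {
  g <- dumbbell_geometry(A_LOBE)
  Ws <- seq(0.7, 4, length.out = 8) * 1e-6
  h <- vapply(Ws, function(W) {
    barrier_fluctuation_scale(energy_params(W, 2e-8, 20 * KT), g)
  }, numeric(1))
  expect_true(all(diff(h) < 0))
})

test_that("experimental-scale waist barrier needs order-100-nm fluctuations", {
  g <- dumbbell_geometry(A_LOBE)  # d_s = 0.98 um
  for (W in c(0.69e-6, 0.76e-6, 0.79e-6)) {
    for (sig in c(5e-9, 2e-8, 1e-7)) {
      h <- barrier_fluctuation_scale(energy_params(W, sig, 20 * KT), g)
      expect_gt(h, 30e-9)
      expect_lt(h, 300e-9)
    }
  }
})
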