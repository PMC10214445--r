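KT <- thermal_energy()

test_that("synthetic contour powers converge to the model spectrum", {
  sigma <- 1e-7; kappa <- 20 * KT; R <- 1e-5
  s <- synth_contours(sigma, kappa, R, n_frames = 2000, seed = 3)
  p <- vesiwrap:::mode_powers(s)
  for (n in c(3, 5, 9)) {
    m <- spectrum_model(n, sigma, kappa, R, KT)
    # mode power is exponential: sd of the mean over F frames = m/sqrt(F)
    expect_lt(abs(p[as.character(n)] - m), 3 * m / sqrt(2000))
  }
})

test_that("contour generation is reproducible from the seed", {
  a <- synth_contours(1e-7, 20 * KT, 1e-5, 50, seed = 9)
  b <- synth_contours(1e-7, 20 * KT, 1e-5, 50, seed = 9)
  expect_identical(a$radii, b$radii)
  c_ <- synth_contours(1e-7, 20 * KT, 1e-5, 50, seed = 10)
  expect_false(identical(a$radii, c_$radii))
})

test_that("doubling the tension suppresses the low modes", {
  p1 <- p2 <- numeric(8)
  for (s in 1:8) {
    p1[s] <- vesiwrap:::mode_powers(
      synth_contours(1e-7, 20 * KT, 1e-5, 400, seed = s))["3"]
    p2[s] <- vesiwrap:::mode_powers(
      synth_contours(2e-7, 20 * KT, 1e-5, 400, seed = s + 50))["3"]
  }
  expect_lt(mean(p2), mean(p1))
})

test_that("pathway templates carry their defining milestones", {
  # parallel -> full: overshoot beyond 1.2 d_s, then settle near 0.7 d_s
  pw <- synth_pathway("parallel_full", seed = 2)
  b <- bin_time_average(pw, 1)
  expect_gte(max(b$d), 1.2)
  expect_true(tail(b$d, 1) > 0.5 && tail(b$d, 1) < 0.9)
  # first retained frame starts parallel
  kept <- filter_equatorial_band(pw)
  expect_gt(kept$theta[1], 80)
  # perpendicular -> full: near-axial tilt when covered halfway
  pw2 <- synth_pathway("perpendicular_full", seed = 2)
  b2 <- bin_time_average(pw2, 1)
  i0 <- which.min(abs(b2$d))
  expect_lt(b2$theta[i0], 20)
  # half-wrapped endings settle near 0.5 d_s, close to perpendicular
  for (tpl in c("parallel_half", "perpendicular_half")) {
    pwh <- synth_pathway(tpl, seed = 3)
    bh <- bin_time_average(pwh, 1)
    expect_equal(tail(bh$d, 1), 0.5, tolerance = 0.2)
    expect_lt(tail(bh$theta, 1), 30)
  }
  expect_error(synth_pathway("sideways_full"), "unknown pathway")
})

test_that("classified end states match each template's declared outcome", {
  ends <- list(parallel_full = "F", perpendicular_full = "F",
               parallel_half = "D", perpendicular_half = "D")
  for (tpl in names(ends)) {
    for (seed in 1:20) {
      pw <- synth_pathway(tpl, seed = seed)
      st <- classify_series(pw)
      expect_identical(st[length(st)], ends[[tpl]])
      # irreversibility: no D after F and no F after D
      iF <- which(st == "F"); iD <- which(st == "D")
      if (length(iF) && length(iD)) {
        expect_true(max(iD) < min(iF) || max(iF) < min(iD))
      }
    }
  }
})

test_that("waist crossing is the slow step on perpendicular pathways", {
  tabs <- lapply(1:10, function(s) {
    pw <- synth_pathway("perpendicular_full", seed = s)
    transition_times(classify_series(pw), pw$time)
  })
  agg <- aggregate_transitions(tabs)
  t_attach <- agg$mean[agg$from == "A1" & agg$to == "B"]
  t_waist <- agg$mean[agg$from == "B" & agg$to == "E1"]
  expect_length(t_attach, 1)
  expect_length(t_waist, 1)
  expect_gt(t_waist, t_attach)
})

test_that("wrap-time datasets are exact at zero noise and monotone", {
  g <- dumbbell_geometry(0.49e-6, rho_n = 0.6 * 0.49e-6)
  ds <- synth_wraptime_dataset(cv = 0, geom = g)
  expect_equal(ds$time, ds$time_exact)
  expect_true(all(diff(ds$time) > 0))
  # stalled tensions are refused with the offending values named
  expect_error(
    synth_wraptime_dataset(sigma_grid = c(1e-9, 5e-7), cv = 0, geom = g),
    "5e-07")
})

test_that("noisy wrap-time fits recover the generating parameters", {
  g <- dumbbell_geometry(0.49e-6, rho_n = 0.6 * 0.49e-6)
  errs <- t(vapply(1:8, function(s) {
    ds <- synth_wraptime_dataset(W = 0.76e-6, eta_eff = 0.8, cv = 0.05,
                                 seed = s, geom = g)
    fit <- fit_wrap_time(ds$sigma, ds$time, g, kappa = 20 * KT)
    c(abs(fit$W - 0.76e-6) / 0.76e-6, abs(fit$eta_eff - 0.8) / 0.8)
  }, numeric(2)))
  expect_lt(median(errs[, 1]), 0.10)
  expect_lt(median(errs[, 2]), 0.10)
})
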