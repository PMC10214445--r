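#' Thermal energy scale
#'
#' `k_B * T` in joules; the default temperature is 298 K.
#'
#' @param temperature Absolute temperature (K).
#' @return Energy (J).
#' @export
thermal_energy <- function(temperature = 298) {
  1.380649e-23 * temperature
}

#' Energy parameters of the wrapping model
#'
#' @param W Adhesion energy per unit area (J/m^2), gained where membrane and
#'   particle are in contact.
#' @param sigma Membrane tension (N/m).
#' @param kappa Bending rigidity (J); phospholipid bilayers are typically a
#'   few tens of `thermal_energy()`.
#' @return An object of class `energy_params`.
#' @export
energy_params <- function(W, sigma, kappa) {
  stopifnot(W >= 0, sigma >= 0, kappa >= 0)
  structure(list(W = W, sigma = sigma, kappa = kappa), class = "energy_params")
}

#' Kinetic parameters of the contact-line dynamics
#'
#' @param eta_eff Membrane microviscosity (Pa s): the effective viscosity felt
#'   by lipids rearranging at the advancing adhesion front.
#' @param alpha Dimensionless drag coefficient converting `eta_eff` into a
#'   contact-line friction per unit length.
#' @return An object of class `kinetic_params`.
#' @export
kinetic_params <- function(eta_eff, alpha = 2) {
  stopifnot(eta_eff > 0, alpha > 0)
  structure(list(eta_eff = eta_eff, alpha = alpha), class = "kinetic_params")
}

#' Wrapping energy landscape E(s)
#'
#' Energy of the partially wrapped configuration with the axisymmetric
#' adhesion front at meridian arc length `s`:
#' `E(s) = -W A_w(s) + sigma * A_w(s) (1 - cos psi(s))/2 + kappa * Q(s)`,
#' where `A_w` is the wrapped area, `psi` the meridional tangent angle at the
#' front (the far-field pulling approximation for the excess-area cost of
#' tension), and `kappa*Q` the Helfrich bending energy `int 2 kappa H^2 dA`
#' of the membrane conforming to the wrapped, neck-smoothed surface.
#'
#' @param s Front position(s), arc length in `[0, s_max]`.
#' @param params An [energy_params()].
#' @param geom A [dumbbell_geometry()].
#' @return Energy (J), continuous in `s`.
#' @export
wrapping_energy <- function(s, params, geom) {
  stopifnot(inherits(params, "energy_params"))
  A <- wrapped_area(s, geom)
  m <- meridian(pmin(pmax(s, 0), geom$s_max), geom)
  -params$W * A + params$sigma * A * (1 - cos(m$psi)) / 2 +
    params$kappa * bend_shape(s, geom)
}

# dE/ds, analytic per zone (used by the front dynamics).
denergy_ds <- function(s, params, geom) {
  m <- meridian(s, geom)
  A <- wrapped_area(s, geom)
  dA <- 2 * pi * m$rho
  dDeltaA <- dA * (1 - cos(m$psi)) / 2 + A * sin(m$psi) * m$dpsi / 2
  -params$W * dA + params$sigma * dDeltaA + params$kappa * 2 * m$H^2 * dA
}

#' Overdamped velocity of the wrapping front
#'
#' Force balance of adhesion drive against contact-line friction:
#' `v(s) = max(0, -dE/ds) / (alpha * eta_eff * L(s))` with contact-line
#' circumference `L(s) = 2 pi rho(s)`, floored at `0.05 a` near the poles
#' where the circumference vanishes. The front stalls (`v = 0`) wherever the
#' net drive is non-positive.
#'
#' @param s Front position(s) (m).
#' @param params An [energy_params()].
#' @param kinetics A [kinetic_params()].
#' @param geom A [dumbbell_geometry()].
#' @return Speed (m/s), non-negative.
#' @export
front_velocity <- function(s, params, kinetics, geom) {
  stopifnot(inherits(kinetics, "kinetic_params"))
  m <- meridian(pmin(pmax(s, 0), geom$s_max), geom)
  L <- pmax(2 * pi * m$rho, 0.05 * geom$a)
  drive <- pmax(0, -denergy_ds(s, params, geom))
  drive / (kinetics$alpha * kinetics$eta_eff * L)
}

#' Time to wrap, or stall location
#'
#' Integrates `T = int ds / v(s)` of the overdamped front from pole to pole
#' (offset by the pole-regularisation length `0.05 a` at both ends, where a
#' finite initial contact patch forms). If the drive is non-positive anywhere
#' on the path the front cannot pass: the result is a stall, reported with
#' the first stall location `s_star`.
#'
#' @param sigma Membrane tension (N/m); overrides `params$sigma`.
#' @param params An [energy_params()] carrying `W` and `kappa` (its `sigma`
#'   entry is replaced by the `sigma` argument).
#' @param kinetics A [kinetic_params()].
#' @param geom A [dumbbell_geometry()].
#' @param n_grid Grid resolution for stall detection.
#' @return An object of class `wrap_time`: list with `status`
#'   (`"wrapped"`/`"stalled"`), `time` (s, `NA` if stalled), `s_star`
#'   (first stall location, `NA` if wrapped) and `sigma`.
#' @export
time_to_wrap <- function(sigma, params, kinetics, geom, n_grid = 2001L) {
  stopifnot(length(sigma) == 1L, sigma >= 0)
  p <- energy_params(params$W, sigma, params$kappa)
  s_lo <- 0.05 * geom$a
  s_hi <- geom$s_max - 0.05 * geom$a
  sg <- seq(s_lo, s_hi, length.out = n_grid)
  drive <- -denergy_ds(sg, p, geom)
  out <- list(sigma = sigma, status = "wrapped", time = NA_real_,
              s_star = NA_real_)
  if (any(drive <= 0)) {
    out$status <- "stalled"
    out$s_star <- sg[which(drive <= 0)[1L]]
  } else {
    out$time <- stats::integrate(
      function(s) 1 / front_velocity(s, p, kinetics, geom),
      s_lo, s_hi, subdivisions = 500L, rel.tol = 1e-9)$value
  }
  class(out) <- "wrap_time"
  out
}

#' @export
print.wrap_time <- function(x, ...) {
  if (x$status == "wrapped") {
    cat(sprintf("wrap_time: wrapped in %.4g s at sigma = %.4g N/m\n",
                x$time, x$sigma))
  } else {
    cat(sprintf("wrap_time: STALLED at s* = %.4g m (sigma = %.4g N/m)\n",
                x$s_star, x$sigma))
  }
  invisible(x)
}

#' Wrap time over a tension grid
#'
#' @param sigma Vector of tensions (N/m).
#' @inheritParams time_to_wrap
#' @return data.frame with columns `sigma`, `time`, `status`, `s_star`.
#' @export
wrap_time_curve <- function(sigma, params, kinetics, geom, n_grid = 2001L) {
  res <- lapply(sigma, time_to_wrap, params = params, kinetics = kinetics,
                geom = geom, n_grid = n_grid)
  data.frame(sigma = sigma,
             time = vapply(res, `[[`, numeric(1), "time"),
             status = vapply(res, `[[`, character(1), "status"),
             s_star = vapply(res, `[[`, numeric(1), "s_star"))
}

#' Fit adhesion energy and microviscosity to wrap-time data
#'
#' Least squares on `log T` over `(W, eta_eff)` for measured
#' (tension, wrap-time) pairs, with bending rigidity fixed. Because the
#' theory is exactly linear in `eta_eff`, `log(eta_eff)` is profiled out
#' analytically and the fit reduces to a 1-D optimisation in `log W`.
#' Stalled predictions are excluded by a penalty; data rows with
#' non-finite times are dropped and reported.
#'
#' @param sigma Tensions (N/m).
#' @param time Measured wrap times (s).
#' @param geom A [dumbbell_geometry()].
#' @param kappa Fixed bending rigidity (J).
#' @param kinetics_alpha Dimensionless drag coefficient (held fixed).
#' @param W_range Search interval for `W` (J/m^2).
#' @return Object of class `wrap_fit`: estimates `W`, `eta_eff`, their
#'   standard errors on the log scale (`se_logW`, `se_logeta`), 95%
#'   multiplicative confidence intervals, residuals on `log T`, and the
#'   fitted times.
#' @export
fit_wrap_time <- function(sigma, time, geom, kappa,
                          kinetics_alpha = 2,
                          W_range = c(2e-8, 2e-5)) {
  keep <- is.finite(sigma) & is.finite(time) & time > 0
  if (sum(keep) < 3L) stop("need at least 3 finite (sigma, time) points")
  sig <- sigma[keep]; tt <- time[keep]
  kin1 <- kinetic_params(eta_eff = 1, alpha = kinetics_alpha)

  # log of the unit-viscosity wrap time for every sigma, at adhesion W
  logI <- function(logW) {
    p <- energy_params(exp(logW), 0, kappa)
    Ti <- vapply(sig, function(s) {
      r <- time_to_wrap(s, p, kin1, geom, n_grid = 801L)
      if (r$status == "stalled") NA_real_ else r$time
    }, numeric(1))
    log(Ti)
  }
  obj <- function(logW) {
    li <- logI(logW)
    if (any(!is.finite(li))) return(1e10 + logW^2)  # stalled: penalised
    r <- log(tt) - li
    sum((r - mean(r))^2)                            # log-eta profiled out
  }
  # coarse scan then local refinement
  lw <- seq(log(W_range[1]), log(W_range[2]), length.out = 40L)
  ov <- vapply(lw, obj, numeric(1))
  if (all(ov >= 1e10)) stop("all candidate adhesion energies predict stalls")
  i0 <- which.min(ov)
  lo <- lw[max(1L, i0 - 1L)]; hi <- lw[min(length(lw), i0 + 1L)]
  opt <- stats::optimize(obj, c(lo, hi), tol = 1e-12)
  logW <- opt$minimum
  li <- logI(logW)
  logeta <- mean(log(tt) - li)
  resid <- log(tt) - li - logeta
  n <- length(tt)
  s2 <- sum(resid^2) / max(1L, n - 2L)
  # Jacobian of predictions wrt (logW, logeta)
  h <- 1e-5
  dW <- (logI(logW + h) - logI(logW - h)) / (2 * h)
  J <- cbind(dW, rep(1, n))
  cov <- tryCatch(s2 * solve(crossprod(J)), error = function(e) {
    matrix(NA_real_, 2, 2)
  })
  se <- sqrt(pmax(0, diag(cov)))
  z <- stats::qnorm(0.975)
  out <- list(W = exp(logW), eta_eff = exp(logeta),
              se_logW = se[1], se_logeta = se[2],
              ci_W = exp(logW + c(-1, 1) * z * se[1]),
              ci_eta = exp(logeta + c(-1, 1) * z * se[2]),
              residuals = resid, fitted = exp(li + logeta),
              sigma = sig, time = tt, kappa = kappa,
              alpha = kinetics_alpha, n_used = n,
              n_dropped = sum(!keep), converged = TRUE)
  class(out) <- "wrap_fit"
  out
}

#' @export
print.wrap_fit <- function(x, ...) {
  cat(sprintf(
    "wrap_fit: W = %.4g J/m^2 [%.3g, %.3g], eta_eff = %.4g Pa.s [%.3g, %.3g]\n",
    x$W, x$ci_W[1], x$ci_W[2], x$eta_eff, x$ci_eta[1], x$ci_eta[2]))
  cat(sprintf("  n = %d points (%d dropped), RMS log-residual = %.3g\n",
              x$n_used, x$n_dropped, sqrt(mean(x$residuals^2))))
  invisible(x)
}

#' Membrane-fluctuation amplitude needed to cross the waist barrier
#'
#' Order-of-magnitude estimate of the normal-displacement amplitude `h*` a
#' symmetric membrane excursion over the waist region must have to supply the
#' energy barrier `dE` between the half-wrapped local minimum and the maximum
#' of the landscape at the neck. The excursion is modelled as a single
#' effective mode of wavevector `q = pi/a` over the waist annulus
#' (area `pi (a^2 - rho_n^2)`), with areal stiffness
#' `(sigma q^2 + kappa q^4)`, so `dE = (sigma + kappa q^2) q^2 A h*^2 / 2`.
#' This is an estimate of scale, not a precise transition theory.
#'
#' @param params An [energy_params()].
#' @param geom A [dumbbell_geometry()] (2 lobes).
#' @param n_grid Landscape grid resolution.
#' @return `h*` (m); 0 when the landscape is barrierless (monotone descent).
#' @export
barrier_fluctuation_scale <- function(params, geom, n_grid = 4001L) {
  stopifnot(geom$lobes == 2L)
  sg <- seq(0, geom$s_max, length.out = n_grid)
  E <- wrapping_energy(sg, params, geom)
  # first local minimum of E, then the highest subsequent point
  dE <- diff(E)
  imin <- which(dE[-1] > 0 & dE[-length(dE)] <= 0)[1L] + 1L
  if (is.na(imin)) return(0)   # monotone: no barrier
  deltaE <- max(E[imin:n_grid]) - E[imin]
  if (deltaE <= 0) return(0)
  q <- pi / geom$a
  A_ann <- pi * (geom$a^2 - geom$rho_n^2)
  k_eff <- (params$sigma + params$kappa * q^2) * q^2 * A_ann
  sqrt(2 * deltaE / k_eff)
}
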