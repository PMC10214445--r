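#' Equatorial contour series of a quasi-spherical vesicle
#'
#' Container for flicker-spectroscopy input: the equatorial radius
#' `r(phi, t)` of a vesicle sampled at equally spaced polar angles, one row
#' per video frame.
#'
#' @param radii Numeric matrix, frames x angles; `radii[t, k]` is the contour
#'   radius at angle `phi_k = 2*pi*(k-1)/n_angles` in frame `t`. All radii
#'   must be positive and at least 64 angular samples are required.
#' @param frame_interval Time between frames (s).
#' @param angles Optional explicit angles; if given they must be equally
#'   spaced over the circle (non-uniform sampling is rejected).
#' @return Object of class `contour_series`.
#' @export
contour_series <- function(radii, frame_interval = 1, angles = NULL) {
  radii <- as.matrix(radii)
  if (ncol(radii) < 64L) stop("need at least 64 angular samples")
  if (any(!is.finite(radii)) || any(radii <= 0)) {
    stop("all contour radii must be positive and finite")
  }
  if (!is.null(angles)) {
    d <- diff(angles)
    if (length(unique(round(d / d[1], 9))) != 1L ||
        abs(sum(d) + d[1] - 2 * pi) > 1e-8) {
      stop("angular sampling must be uniform over the full circle")
    }
  }
  structure(list(radii = radii, frame_interval = frame_interval,
                 R = mean(radii)),
            class = "contour_series")
}

#' @export
print.contour_series <- function(x, ...) {
  cat(sprintf("contour_series: %d frames x %d angles, mean radius %.4g\n",
              nrow(x$radii), ncol(x$radii), x$R))
  invisible(x)
}

#' Fourier modes of the contour fluctuations
#'
#' Per-frame discrete Fourier amplitudes
#' `c_n = (1/N) sum_k [r(phi_k)/R_t - 1] exp(-i n phi_k)` of the relative
#' contour deviation, with `R_t` the frame's mean radius (which removes the
#' `n = 0` dilation mode from the fluctuation set).
#'
#' @param x A [contour_series()] or a numeric matrix of radii.
#' @param n_max Largest mode retained (default: the Nyquist limit).
#' @return Complex matrix frames x modes, columns named `n = 1, 2, ...`.
#' @export
contour_modes <- function(x, n_max = NULL) {
  if (inherits(x, "contour_series")) x <- x$radii
  x <- as.matrix(x)
  N <- ncol(x)
  if (is.null(n_max)) n_max <- floor((N - 1) / 2)
  rel <- x / rowMeans(x) - 1
  cf <- t(apply(rel, 1L, stats::fft)) / N
  if (nrow(x) == 1L) cf <- matrix(cf, nrow = 1L)
  modes <- cf[, seq(2L, n_max + 1L), drop = FALSE]
  colnames(modes) <- as.character(seq_len(n_max))
  modes
}

# Mean power per mode over frames, for modes n >= 1.
mode_powers <- function(x, n_max = NULL) {
  m <- contour_modes(x, n_max = n_max)
  colMeans(Mod(m)^2)
}

#' Equilibrium fluctuation spectrum of a quasi-spherical vesicle
#'
#' Expected equatorial mode power of a membrane with tension `sigma` and
#' bending rigidity `kappa` in the quasi-circular reduction:
#' `<|c_n|^2> = (kBT / 2 kappa) / ((n^2 - 1)(n^2 + sigma R^2 / kappa))`.
#' Modes `n < 2` (translation/dilation) are outside the fluctuation set.
#'
#' @param n Mode number(s), `n >= 2`.
#' @param sigma Tension (N/m).
#' @param kappa Bending rigidity (J).
#' @param R Mean vesicle radius (m).
#' @param kBT Thermal energy (J), see [thermal_energy()].
#' @return Expected `<|c_n|^2>` (dimensionless).
#' @export
spectrum_model <- function(n, sigma, kappa, R, kBT = thermal_energy()) {
  if (any(n < 2)) stop("spectrum_model requires mode numbers n >= 2")
  stopifnot(sigma >= 0, kappa > 0, R > 0)
  (kBT / (2 * kappa)) / ((n^2 - 1) * (n^2 + sigma * R^2 / kappa))
}

#' Fit tension and rigidity to a fluctuation spectrum
#'
#' Maximum-likelihood fit of `(sigma, kappa)` (optionally plus an additive
#' white noise floor for tracking error) to the per-mode contour powers.
#' For a thermally fluctuating contour each mode power is exponentially
#' distributed about its model mean, so the per-mode mean power over frames
#' is a sufficient statistic and the negative log-likelihood is
#' `sum_n F [log m_n + pbar_n / m_n]`.
#'
#' @param x A [contour_series()], or a matrix of radii.
#' @param R Mean radius (m); defaults to the series mean.
#' @param kBT Thermal energy (J).
#' @param n_range Fitted mode range, default `c(3, 20)`: below, long-lived
#'   drift contaminates; above, tracking noise dominates.
#' @param noise_floor If `TRUE`, fit an additive per-mode noise power as a
#'   third parameter.
#' @return Object of class `spectrum_estimate`: `sigma`, `kappa` (J) and
#'   `kappa_kBT`, standard errors, the fitted mode range, the per-mode mean
#'   powers, and a convergence flag.
#' @export
fit_fluctuation_spectrum <- function(x, R = NULL, kBT = thermal_energy(),
                                     n_range = c(3, 20),
                                     noise_floor = FALSE) {
  if (inherits(x, "contour_series")) {
    if (is.null(R)) R <- x$R
    n_frames <- nrow(x$radii)
  } else {
    x <- as.matrix(x)
    if (is.null(R)) R <- mean(x)
    n_frames <- nrow(x)
  }
  if (n_frames < 100L) stop("need at least 100 frames for a spectrum fit")
  pbar_all <- mode_powers(x)
  ns <- seq(n_range[1], n_range[2])
  if (max(ns) > length(pbar_all)) stop("n_range exceeds available modes")
  pbar <- pbar_all[ns]
  if (all(pbar == 0)) stop("degenerate input: all mode powers are zero")

  # moment-based starting values: high modes give kappa, low modes sigma
  n_hi <- max(ns)
  kappa0 <- kBT / (2 * n_hi^4 * pbar[length(pbar)])
  kappa0 <- max(kappa0, 1e-3 * kBT)
  n_lo <- min(ns)
  x0 <- kBT / (2 * kappa0 * (n_lo^2 - 1) * pbar[1]) - n_lo^2 # sigma R^2/kappa
  sigma0 <- max(x0, 1) * kappa0 / R^2

  nll <- function(par) {
    sig <- exp(par[1]); kap <- exp(par[2])
    m <- spectrum_model(ns, sig, kap, R, kBT)
    if (noise_floor) m <- m + exp(par[3])
    n_frames * sum(log(m) + pbar / m)
  }
  par0 <- c(log(sigma0), log(kappa0))
  if (noise_floor) par0 <- c(par0, log(max(min(pbar) * 0.1, 1e-30)))
  opt <- stats::optim(par0, nll, method = "L-BFGS-B",
                      control = list(factr = 1e2, maxit = 500L),
                      hessian = TRUE)
  se <- tryCatch(sqrt(pmax(0, diag(solve(opt$hessian)))),
                 error = function(e) rep(NA_real_, length(par0)))
  sigma_hat <- exp(opt$par[1]); kappa_hat <- exp(opt$par[2])
  out <- list(sigma = sigma_hat, kappa = kappa_hat,
              kappa_kBT = kappa_hat / kBT,
              se_sigma = sigma_hat * se[1], se_kappa = kappa_hat * se[2],
              noise_floor = if (noise_floor) exp(opt$par[3]) else 0,
              n_range = n_range, R = R, kBT = kBT,
              mode_powers = pbar, modes = ns, n_frames = n_frames,
              converged = opt$convergence == 0L)
  class(out) <- "spectrum_estimate"
  out
}

#' @export
print.spectrum_estimate <- function(x, ...) {
  cat(sprintf(
    "spectrum_estimate: sigma = %.4g +/- %.2g N/m, kappa = %.4g kBT (%.3g J)\n",
    x$sigma, x$se_sigma, x$kappa_kBT, x$kappa))
  cat(sprintf("  modes n in [%d, %d], %d frames%s\n", x$n_range[1],
              x$n_range[2], x$n_frames,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}
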