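#' Synthetic equatorial contour series with known tension and rigidity
#'
#' Draws, frame by frame, independent equatorial Fourier modes from the
#' equilibrium spectrum [spectrum_model()] (real and imaginary parts
#' Gaussian, so mode powers are exponential), inverse-transforms to
#' `r(phi)` and adds white radial tracking noise. The generator feeds the
#' flicker-spectroscopy estimator with data of exactly known parameters.
#'
#' @param sigma Tension (N/m).
#' @param kappa Bending rigidity (J).
#' @param R Mean vesicle radius (m).
#' @param n_frames Number of frames (>= 1).
#' @param n_angles Angular samples per frame.
#' @param noise_floor Radial tracking noise, standard deviation (m).
#' @param kBT Thermal energy (J).
#' @param frame_interval Frame spacing (s).
#' @param seed Integer seed; identical seeds give identical series.
#' @return A [contour_series()].
#' @export
synth_contours <- function(sigma, kappa, R, n_frames, n_angles = 128L,
                           noise_floor = 0, kBT = thermal_energy(),
                           frame_interval = 1, seed = 1L) {
  stopifnot(n_frames >= 1)
  set.seed(seed)
  n_max <- floor((n_angles - 1) / 2)
  ns <- 2:n_max
  mvar <- spectrum_model(ns, sigma, kappa, R, kBT)
  radii <- matrix(0, n_frames, n_angles)
  for (t in seq_len(n_frames)) {
    spec <- complex(real = rep(0, n_angles))
    cn <- complex(real = stats::rnorm(length(ns), 0, sqrt(mvar / 2)),
                  imaginary = stats::rnorm(length(ns), 0, sqrt(mvar / 2)))
    spec[ns + 1L] <- cn * n_angles
    spec[n_angles + 1L - ns] <- Conj(cn) * n_angles
    rel <- Re(stats::fft(spec, inverse = TRUE)) / n_angles
    radii[t, ] <- R * (1 + rel) + stats::rnorm(n_angles, 0, noise_floor)
  }
  contour_series(radii, frame_interval = frame_interval)
}

# Milestone tables for the four canonical pathway shapes. Times are
# fractions of the run duration; theta in degrees, d in units of the sphere
# diameter d_s, f1/f2 wrapped fractions, contact2 the time fraction at which
# the second lobe first touches (NA: never).
pathway_templates <- list(
  "parallel_full" = list(
    theta = cbind(t = c(0, .25, .45, .6, .75, 1), v = c(90, 75, 60, 55, 65, 75)),
    d     = cbind(t = c(0, .3, .55, .7, .85, 1), v = c(0, .3, .9, 1.5, .9, .7)),
    f1    = cbind(t = c(0, .05, .3, .45, .6, 1), v = c(0, .03, .3, .6, .95, 1)),
    f2    = cbind(t = c(0, .35, .55, .8, 1), v = c(0, .05, .3, .95, 1)),
    contact2 = 0, end_state = "F"),
  "perpendicular_full" = list(
    theta = cbind(t = c(0, .2, .45, .7, 1), v = c(15, 8, 10, 40, 70)),
    d     = cbind(t = c(0, .3, .45, .6, .8, 1), v = c(-1, -.2, 0, .25, .6, .7)),
    f1    = cbind(t = c(0, .07, .3, .5, .6, 1), v = c(0, .07, .55, .85, .96, 1)),
    f2    = cbind(t = c(0, .42, .6, .8, .95, 1), v = c(0, 0, .3, .7, .95, 1)),
    contact2 = 0.42, end_state = "F"),
  "parallel_half" = list(
    theta = cbind(t = c(0, .4, .8, 1), v = c(85, 50, 15, 10)),
    d     = cbind(t = c(0, .5, .8, 1), v = c(0, .2, .42, .5)),
    f1    = cbind(t = c(0, .1, .5, .8, 1), v = c(0, .1, .6, .95, .97)),
    f2    = cbind(t = c(0, 1), v = c(0, 0)),
    contact2 = NA, end_state = "D"),
  "perpendicular_half" = list(
    theta = cbind(t = c(0, .3, .7, 1), v = c(10, 45, 20, 8)),
    d     = cbind(t = c(0, .5, .8, 1), v = c(-1, -.2, .3, .5)),
    f1    = cbind(t = c(0, .1, .5, .85, 1), v = c(0, .1, .6, .95, .97)),
    f2    = cbind(t = c(0, 1), v = c(0, 0)),
    contact2 = NA, end_state = "D")
)

#' Names of the built-in wrapping-pathway templates
#' @return Character vector.
#' @export
pathway_template_names <- function() names(pathway_templates)

#' Synthetic wrapping trajectory with a prescribed pathway shape
#'
#' Generates a smooth observable series through the milestones of one of the
#' four canonical engulfment pathways -- initially parallel or perpendicular
#' particles ending fully wrapped (both lobes covered, with the tilt-overshoot
#' -recoil signature: insertion depth reaching about `1.5 d_s` before settling
#' near `0.7 d_s`) or half wrapped (one lobe engulfed to the waist, settling
#' near `0.5 d_s` with a near-perpendicular tilt, without overshoot) -- plus
#' additive tracking noise. These are milestone interpolants built to
#' exercise the observables and the state classifier, not mechanistic
#' simulations.
#'
#' @param template One of [pathway_template_names()].
#' @param duration Run length (s).
#' @param dt Frame interval (s).
#' @param d_s Sphere (lobe) diameter (um); sets the depth unit.
#' @param R_ves Vesicle radius (um), used for the `z`/`R` columns.
#' @param theta_noise Tilt tracking noise, rms degrees.
#' @param d_noise Depth tracking noise, rms um.
#' @param seed Integer seed.
#' @return data.frame with columns `time` (s), `theta` (deg), `d` (units of
#'   `d_s`), `z`, `R` (um), `f1`, `f2`, `second_lobe_contact`, `attached`.
#' @export
synth_pathway <- function(template, duration = 100, dt = 0.1,
                          d_s = 0.98, R_ves = 5,
                          theta_noise = 3, d_noise = 0.03, seed = 1L) {
  if (!template %in% names(pathway_templates)) {
    stop("unknown pathway template '", template, "'; see pathway_template_names()")
  }
  tpl <- pathway_templates[[template]]
  set.seed(seed)
  tfrac <- seq(0, 1, by = dt / duration)
  n <- length(tfrac)
  interp <- function(ms) {
    stats::spline(ms[, "t"], ms[, "v"], xout = tfrac, method = "natural")$y
  }
  theta <- interp(tpl$theta) + stats::rnorm(n, 0, theta_noise)
  theta <- pmin(90, pmax(0, theta))
  d <- interp(tpl$d) + stats::rnorm(n, 0, d_noise / d_s)
  f1 <- pmin(1, pmax(0, interp(tpl$f1) + stats::rnorm(n, 0, 0.01)))
  f2 <- pmin(1, pmax(0, interp(tpl$f2) + stats::rnorm(n, 0, 0.01)))
  f2 <- pmin(f1, f2)
  contact2 <- if (is.na(tpl$contact2)) rep(FALSE, n) else tfrac >= tpl$contact2
  # slow latitude drift of the wrapping site, well inside the tracking band
  zfrac <- 0.3 + 0.1 * sin(2 * pi * tfrac * 0.5 + stats::runif(1, 0, 2 * pi)) +
    stats::rnorm(n, 0, 0.01)
  data.frame(time = tfrac * duration, theta = theta, d = d,
             z = zfrac * R_ves, R = R_ves, f1 = f1, f2 = f2,
             second_lobe_contact = contact2, attached = TRUE)
}

#' Synthetic wrap-time-versus-tension dataset
#'
#' Evaluates the analytical wrap time on a tension grid and applies
#' multiplicative lognormal noise `T_i = T(sigma_i) * exp(e_i)`,
#' `e_i ~ N(0, cv^2)`. All grid tensions must lie below the stall
#' threshold; stalled entries raise an error naming them.
#'
#' @param W Adhesion energy per area (J/m^2).
#' @param eta_eff Membrane microviscosity (Pa s).
#' @param sigma_grid Tensions (N/m).
#' @param cv Coefficient of variation of the noise (0 = exact theory).
#' @param seed Integer seed.
#' @param geom A [dumbbell_geometry()]; the default uses lobe radius
#'   `a = 0.49` um with a wide, membrane-bridged neck (`rho_n = 0.6 a`).
#' @param kappa Bending rigidity (J).
#' @param alpha Dimensionless drag coefficient.
#' @return data.frame with columns `sigma`, `time`, `time_exact`.
#' @export
synth_wraptime_dataset <- function(W = 0.76e-6, eta_eff = 0.8,
                                   sigma_grid = seq(2e-9, 2e-8,
                                                    length.out = 8L),
                                   cv = 0.05, seed = 1L,
                                   geom = dumbbell_geometry(0.49e-6,
                                                            rho_n = 0.6 * 0.49e-6),
                                   kappa = 20 * thermal_energy(),
                                   alpha = 2) {
  ep <- energy_params(W, 0, kappa)
  kp <- kinetic_params(eta_eff, alpha)
  curve <- wrap_time_curve(sigma_grid, ep, kp, geom)
  if (any(curve$status == "stalled")) {
    bad <- curve$sigma[curve$status == "stalled"]
    stop("tension(s) above the stall threshold: ",
         paste(format(bad), collapse = ", "))
  }
  set.seed(seed)
  eps <- if (cv > 0) stats::rnorm(nrow(curve), 0, cv) else rep(0, nrow(curve))
  data.frame(sigma = curve$sigma, time = curve$time * exp(eps),
             time_exact = curve$time)
}
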