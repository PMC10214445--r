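#' Place a dumbbell tangent to the vesicle at a pole
#'
#' Initial condition for wrapping runs: the dumbbell touches the vesicle
#' exterior at the +z pole, oriented either `"parallel"` (axis
#' perpendicular to the local surface normal, both lobes at contact
#' height) or `"perpendicular"` (axis along the normal, one lobe at
#' contact), with a small random tilt drawn from the seed.
#'
#' @param state A [membrane_state()].
#' @param a Lobe radius (sigma_b).
#' @param orientation `"parallel"` or `"perpendicular"`.
#' @param gap Initial bead-surface clearance (sigma_b).
#' @param max_tilt Maximum random tilt (degrees).
#' @param seed Integer seed.
#' @return A [dumbbell_body()].
#' @export
place_dumbbell <- function(state, a, orientation = c("perpendicular",
                                                     "parallel"),
                           gap = 0.6, max_tilt = 5, seed = 1L) {
  orientation <- match.arg(orientation)
  set.seed(seed)
  cves <- colMeans(state$beads)
  rad <- sqrt(rowSums(sweep(state$beads, 2, cves, `-`)^2))
  # clearance is measured from the highest bead under the landing site, so
  # no bead starts inside the colloid's repulsive core
  zhat <- c(0, 0, 1)
  cosang <- sweep(state$beads, 2, cves, `-`)[, 3] / rad
  cap <- cosang > cos(30 * pi / 180)
  Rnow <- max(rad[cap])
  tilt <- stats::runif(1, 0, max_tilt) * pi / 180
  phi <- stats::runif(1, 0, 2 * pi)
  perturb <- function(v) {
    # rotate v by `tilt` about a random axis perpendicular to it
    e1 <- if (abs(v[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    u1 <- e1 - sum(e1 * v) * v; u1 <- u1 / sqrt(sum(u1^2))
    u2 <- c(v[2] * u1[3] - v[3] * u1[2],
            v[3] * u1[1] - v[1] * u1[3],
            v[1] * u1[2] - v[2] * u1[1])
    ax <- cos(phi) * u1 + sin(phi) * u2
    cos(tilt) * v + sin(tilt) * ax
  }
  if (orientation == "perpendicular") {
    axis <- perturb(zhat)
    center <- cves + (Rnow + gap + 2 * a) * zhat
  } else {
    axis <- perturb(c(1, 0, 0))
    center <- cves + (Rnow + gap + a) * zhat
  }
  dumbbell_body(center, axis, a)
}

#' Wrapping observables of a simulated trajectory
#'
#' Extracts, for every snapshot, the quantities used to describe the
#' engulfment: tilt angle `theta` between dumbbell axis and the radial
#' direction of the fitted undistorted sphere at the particle's centre of
#' mass, insertion depth `d = R - |com - center|` (positive inward, also
#' given in units of the sphere diameter `d_s = 2a`), height `z` above the
#' equator (the plane through the vesicle centre perpendicular to the
#' initial contact direction), per-lobe wrapped fractions with the
#' more-wrapped lobe first, contact flags (second-lobe contact is latched:
#' the ligand-receptor bonds it represents are effectively irreversible),
#' and the wrapping-state label of every frame.
#'
#' @param traj A `wrap_trajectory` from [run_dynamics()].
#' @param contact_cutoff Contact distance for the wrapped fractions;
#'   defaults to the adhesion cutoff of the run.
#' @param mesh_n Mesh points per lobe for the fraction estimate.
#' @param ... Passed to [classify_wrap_state()].
#' @return data.frame (one row per snapshot): `time`, `theta`, `d`, `d_ds`,
#'   `z`, `R`, `f1`, `f2`, `second_lobe_contact`, `attached`, `state`.
#' @export
trajectory_observables <- function(traj, contact_cutoff = NULL,
                                   mesh_n = 500L, ...) {
  stopifnot(inherits(traj, "wrap_trajectory"), traj$has_dumbbell)
  if (is.null(contact_cutoff)) contact_cutoff <- traj$sim$r_cut_ad
  a <- traj$a_lobe
  nfr <- length(traj$times)
  cves0 <- colMeans(traj$beads[[1]])
  zref <- traj$dumbbell_center[1, ] - cves0
  zref <- zref / sqrt(sum(zref^2))
  out <- data.frame(time = traj$times, theta = NA_real_, d = NA_real_,
                    d_ds = NA_real_, z = NA_real_, R = NA_real_,
                    f1 = NA_real_, f2 = NA_real_,
                    second_lobe_contact = FALSE, attached = FALSE)
  fA <- fB <- numeric(nfr)    # unrelabelled per-lobe fractions
  for (i in seq_len(nfr)) {
    b <- traj$beads[[i]]
    cves <- colMeans(b)
    R <- mean(sqrt(rowSums(sweep(b, 2, cves, `-`)^2)))
    com <- traj$dumbbell_center[i, ]
    axis <- traj$dumbbell_axis[i, ]
    out$theta[i] <- compute_theta(axis, com - cves)
    out$d[i] <- compute_depth(com, cves, R)
    out$z[i] <- sum((com - cves) * zref)
    out$R[i] <- R
    fr <- wrapped_fraction(b, com, axis, a, contact_cutoff, mesh_n = mesh_n)
    fA[i] <- fr[1]; fB[i] <- fr[2]
  }
  out$d_ds <- out$d / (2 * a)
  # latch per-lobe contact (binding is irreversible on these timescales)
  touchA <- cummax(fA > 0) > 0
  touchB <- cummax(fB > 0) > 0
  out$f1 <- pmax(fA, fB)
  out$f2 <- pmin(fA, fB)
  less_is_A <- fA <= fB
  out$second_lobe_contact <- ifelse(less_is_A, touchA, touchB)
  out$attached <- touchA | touchB
  out$state <- classify_series(out, ...)
  out
}

#' Equatorial contour series of a simulated vesicle
#'
#' Extracts, frame by frame, the equatorial radius profile `r(phi)` of the
#' membrane from bead positions: beads within `band * R` of the equatorial
#' plane (through the instantaneous centre, perpendicular to the lab z axis)
#' are binned by azimuth and averaged; empty bins are filled by periodic
#' linear interpolation. The result feeds [fit_fluctuation_spectrum()] the
#' same way a video of a GUV cross-section would.
#'
#' @param traj A `wrap_trajectory`.
#' @param n_angles Azimuthal bins.
#' @param band Half-width of the equatorial slab in units of the radius.
#' @return A [contour_series()] (radii in sigma_b; `frame_interval` in tau0).
#' @export
equatorial_contour <- function(traj, n_angles = 64L, band = 0.2) {
  nfr <- length(traj$times)
  radii <- matrix(NA_real_, nfr, n_angles)
  edges <- seq(-pi, pi, length.out = n_angles + 1L)
  for (i in seq_len(nfr)) {
    b <- traj$beads[[i]]
    ctr <- colMeans(b)
    x <- sweep(b, 2, ctr, `-`)
    r3 <- sqrt(rowSums(x^2))
    keep <- abs(x[, 3]) < band * mean(r3)
    req <- sqrt(x[keep, 1]^2 + x[keep, 2]^2)
    phi <- atan2(x[keep, 2], x[keep, 1])
    bin <- findInterval(phi, edges, rightmost.closed = TRUE)
    prof <- as.numeric(tapply(req, factor(bin, levels = 1:n_angles), mean))
    if (anyNA(prof)) {
      # periodic linear fill of empty bins
      idx <- seq_len(n_angles)
      ok <- !is.na(prof)
      prof <- stats::approx(c(idx[ok] - n_angles, idx[ok], idx[ok] + n_angles),
                            rep(prof[ok], 3), xout = idx)$y
    }
    radii[i, ] <- prof
  }
  dt_frame <- if (nfr > 1) diff(traj$times[1:2]) else 1
  contour_series(radii, frame_interval = dt_frame)
}

#' Simulate a complete wrapping run
#'
#' Convenience pipeline: build a relaxed vesicle, add tension-setting
#' solutes, place the dumbbell at a pole, run the Langevin dynamics and
#' return the trajectory. The tension is imposed through the solute
#' concentration imbalance (see [set_tension_by_solutes()]); with
#' `target_sigma = 0` the concentrations match and the vesicle keeps its
#' excess area free for wrapping.
#'
#' @param n_beads,R0 Vesicle size.
#' @param a Dumbbell lobe radius (sigma_b).
#' @param orientation Initial orientation, see [place_dumbbell()].
#' @param target_sigma Imposed tension (epsilon/sigma_b^2).
#' @param sim A [sim_params()].
#' @param pot A [membrane_potential_params()].
#' @param c_out Baseline solute concentration outside.
#' @param seed Integer seed for construction and dynamics (overrides
#'   `sim$seed`).
#' @return A `wrap_trajectory`.
#' @export
simulate_wrapping <- function(n_beads = 1600L, R0 = 12, a = 2.5,
                              orientation = "perpendicular",
                              target_sigma = 0,
                              sim = sim_params(n_steps = 50000L),
                              pot = membrane_potential_params(),
                              c_out = 0.02, seed = 1L) {
  sim$seed <- as.integer(seed)
  ves <- build_vesicle(n_beads, R0, pot = pot, seed = seed)
  db <- place_dumbbell(ves, a, orientation, seed = seed)
  cnt <- set_tension_by_solutes(target_sigma, R0, max(sim$kBT, 1e-6),
                                geometry = list(R_wall = 1.6 * R0,
                                                c_out = c_out))
  # keep solutes clear of the already placed colloid
  ves <- add_solutes(ves, cnt$n_in, cnt$n_out, R_wall = 1.6 * R0,
                     seed = seed,
                     exclude = list(centers = lobe_centers(db),
                                    radius = a + 0.8))
  run_dynamics(ves, db, sim = sim, pot = pot)
}
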