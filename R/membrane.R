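#' Parameters of the one-particle-thick membrane pair potential
#'
#' The membrane is a fluid surface of orientable beads. A bead pair at
#' separation r with normals n_i, n_j interacts through a repulsive core
#' \deqn{u_R(r) = \epsilon[(r_{min}/r)^4 - 2(r_{min}/r)^2] + (1-\Phi)\epsilon,
#'   \quad r < r_{min}}
#' and an orientation-weighted attraction
#' \deqn{u_A(r) = -\epsilon \cos^{2\zeta}\left(\frac{\pi}{2}
#'   \frac{r - r_{min}}{r_{cut} - r_{min}}\right)\Phi,
#'   \quad r_{min} \le r < r_{cut}}
#' where \eqn{\Phi = 1 + \mu[(n_i \times \hat r)\cdot(n_j \times \hat r) +
#' \sin\theta_0 (n_j - n_i)\cdot\hat r - \sin^2\theta_0 - 1]} favours
#' aligned normals (and, for nonzero `theta0`, spontaneous curvature).
#' `mu` controls the bending rigidity and self-healing propensity; `zeta`
#' the attraction decay (diffusivity of the fluid phase).
#'
#' @param epsilon Bond energy scale (simulation units), > 0.
#' @param mu Bending/self-healing exponent weight, >= 1.
#' @param zeta Attraction-decay exponent, >= 1.
#' @param theta0 Spontaneous-curvature angle (radians).
#' @param r_min Potential-minimum distance (bead diameters).
#' @param r_cut Interaction cutoff (bead diameters), > `r_min`.
#' @return Object of class `membrane_potential_params`.
#' @export
membrane_potential_params <- function(epsilon = 1, mu = 3, zeta = 4,
                                      theta0 = 0, r_min = 2^(1/6),
                                      r_cut = 2.6) {
  stopifnot(epsilon > 0, mu >= 1, zeta >= 1, r_min > 0, r_cut > r_min)
  structure(list(epsilon = epsilon, mu = mu, zeta = zeta, theta0 = theta0,
                 r_min = r_min, r_cut = r_cut),
            class = "membrane_potential_params")
}

#' Membrane pair potential: energy, force and normal gradients
#'
#' Evaluates the orientation-dependent bead-bead interaction for one pair,
#' returning the energy, the forces on both beads and the gradients of the
#' energy with respect to the two normals (whose projections perpendicular
#' to the normals drive its rotational dynamics). Forces and gradients are
#' exact derivatives of the energy; energy and force vanish at and beyond
#' the cutoff.
#'
#' @param r_vec Displacement `x_j - x_i` (length-3, nonzero).
#' @param n_i,n_j Unit normals of beads i and j.
#' @param params A [membrane_potential_params()].
#' @return List with `energy`, `force_i`, `force_j`, `dU_dni`, `dU_dnj`.
#' @export
membrane_pair_potential <- function(r_vec, n_i, n_j,
                                    params = membrane_potential_params()) {
  if (sqrt(sum(r_vec^2)) == 0) stop("overlapping beads: |r_vec| must be > 0")
  pair_potential_cpp(as.numeric(r_vec), as.numeric(n_i), as.numeric(n_j),
                     params$epsilon, params$mu, params$zeta, params$theta0,
                     params$r_min, params$r_cut)
}

#' Rigid dumbbell colloid
#'
#' Two tangent spheres of radius `a` (sphere diameter `d_s = 2a`, long axis
#' `2 d_s`) rigidly joined; the state is the centre and the unit long axis,
#' and the lobe centres are derived as `center +/- a * axis`.
#'
#' @param center Length-3 centre position.
#' @param axis Length-3 axis (normalised internally).
#' @param a Lobe radius (> 0).
#' @return Object of class `dumbbell_body`.
#' @export
dumbbell_body <- function(center, axis, a) {
  stopifnot(length(center) == 3L, length(axis) == 3L, a > 0,
            sqrt(sum(axis^2)) > 0)
  structure(list(center = as.numeric(center),
                 axis = as.numeric(axis) / sqrt(sum(axis^2)),
                 a = a),
            class = "dumbbell_body")
}

#' Lobe centres of a dumbbell
#' @param db A [dumbbell_body()].
#' @return 2 x 3 matrix, one lobe centre per row.
#' @export
lobe_centers <- function(db) {
  rbind(db$center + db$a * db$axis, db$center - db$a * db$axis)
}

#' Simulation parameters
#'
#' @param dt Timestep (tau0).
#' @param n_steps Number of steps.
#' @param kBT Thermal energy (units of epsilon); 0.2-0.3 keeps the default
#'   membrane in its fluid phase.
#' @param gamma_t,gamma_r Translational and rotational friction rates
#'   (1/tau0); 0 switches the thermostat off (microcanonical dynamics).
#' @param epsilon_ad Adhesion well depth per bead (epsilon).
#' @param r_cut_ad Adhesion cutoff: bead-to-lobe-surface distance (sigma_b).
#' @param seed Integer RNG seed; identical seed and configuration give an
#'   identical trajectory.
#' @param stride Snapshot interval (steps).
#' @param diag_stride Diagnostics sampling interval (steps).
#' @param tau0 The MD time unit (for record-keeping; dynamics are run in
#'   reduced units where tau0 = 1).
#' @param contact_h Bead-surface contact distance (sigma_b).
#' @param R_wall Radius of the spherical wall confining outer solutes.
#' @param k_rep,f_cap Core repulsion stiffness and force cap.
#' @param interactions Disable all forces when `FALSE` (free streaming).
#' @param store_solutes Keep solute coordinates in snapshots.
#' @param rupture_check Terminate on sustained membrane rupture (a bead with
#'   fewer than 3 neighbours within `r_cut` for more than 100 steps).
#' @param thermal_init Draw initial velocities from the Maxwell distribution.
#' @return Object of class `sim_params`.
#' @export
sim_params <- function(dt = 0.01, n_steps = 1000L, kBT = 0.23,
                       gamma_t = 1, gamma_r = 1,
                       epsilon_ad = 1.6, r_cut_ad = 1.8, seed = 1L,
                       stride = max(1L, as.integer(n_steps %/% 200)),
                       diag_stride = 20L, tau0 = 1,
                       contact_h = 0.5, R_wall = NA_real_,
                       k_rep = 200, f_cap = 100,
                       interactions = TRUE, store_solutes = FALSE,
                       rupture_check = TRUE, thermal_init = TRUE) {
  stopifnot(dt > 0, n_steps >= 0, kBT >= 0, gamma_t >= 0, gamma_r >= 0,
            epsilon_ad >= 0, r_cut_ad > 0)
  structure(list(dt = dt, n_steps = as.integer(n_steps), kBT = kBT,
                 gamma_t = gamma_t, gamma_r = gamma_r,
                 epsilon_ad = epsilon_ad, r_cut_ad = r_cut_ad,
                 seed = as.integer(seed), stride = as.integer(stride),
                 diag_stride = as.integer(diag_stride), tau0 = tau0,
                 contact_h = contact_h, R_wall = R_wall,
                 k_rep = k_rep, f_cap = f_cap, k_wall = 100,
                 interactions = interactions, store_solutes = store_solutes,
                 rupture_check = rupture_check,
                 rupture_every = 50L,
                 m_solute = 0.5, inertia_n = 1,
                 thermal_init = thermal_init),
            class = "sim_params")
}

# quasi-uniform bead placement on a sphere (generalised spiral)
sphere_spiral <- function(n, R) {
  p <- fibonacci_sphere(n)
  p * R
}

#' Equilibrium bead spacing of the flat membrane lattice
#'
#' Lattice constant minimising the energy per bead of an ideal flat
#' hexagonal sheet with aligned normals, summing the pair potential over
#' all shells within the cutoff. Slightly below `r_min` because of the
#' attractive tails of the outer shells; used to pick vesicle radii with
#' near-equilibrium area per bead.
#'
#' @param pot A [membrane_potential_params()].
#' @return Lattice constant (sigma_b).
#' @export
equilibrium_bead_spacing <- function(pot = membrane_potential_params()) {
  kmax <- ceiling(pot$r_cut / 0.8)
  k <- expand.grid(k1 = -kmax:kmax, k2 = -kmax:kmax)
  k <- k[!(k$k1 == 0 & k$k2 == 0), ]
  ex <- k$k1 + k$k2 / 2
  ey <- k$k2 * sqrt(3) / 2
  dist1 <- sqrt(ex^2 + ey^2)           # distances at unit lattice constant
  n <- c(0, 0, 1)
  e_per_bead <- function(s) {
    r <- dist1 * s
    r <- r[r < pot$r_cut]
    0.5 * sum(vapply(r, function(ri) {
      membrane_pair_potential(c(ri, 0, 0), n, n, pot)$energy
    }, numeric(1)))
  }
  stats::optimize(e_per_bead, c(0.85, 1.35))$minimum
}

#' Working bead spacing of the fluid membrane
#'
#' Mean lattice constant the membrane adopts in its fluid phase at the
#' default working temperature (`kBT` about 0.2-0.3 epsilon), calibrated
#' once from equilibrated vesicle simulations. It lies between the
#' zero-temperature lattice optimum ([equilibrium_bead_spacing()]) and
#' `r_min`: thermal motion swells the energetically densified sheet.
#'
#' @return Lattice constant (sigma_b).
#' @export
fluid_bead_spacing <- function() 1.05

#' Vesicle radius giving equilibrium area per bead
#'
#' @param n_beads Bead count.
#' @param spacing Target lattice constant; defaults to the fluid-phase
#'   working spacing.
#' @return Radius (sigma_b) at which `n_beads` tile the sphere at that
#'   spacing.
#' @export
vesicle_radius_for <- function(n_beads, spacing = fluid_bead_spacing()) {
  sqrt(n_beads * (sqrt(3) / 2) * spacing^2 / (4 * pi))
}

#' Build a closed quasi-spherical vesicle
#'
#' Places `n_beads` on a generalised spiral over a sphere of radius `R0`
#' with outward normals, then relaxes the packing by a short overdamped
#' quench so the local spacing settles near the potential minimum. The
#' combination of `n_beads` and `R0` must imply a bead spacing within
#' `[0.8, 1.5] r_min` (a hexagonal-packing estimate), otherwise the lattice
#' would be torn or crumpled from the start.
#'
#' @param n_beads Number of membrane beads (>= 100).
#' @param R0 Target vesicle radius (sigma_b).
#' @param pot A [membrane_potential_params()].
#' @param relax_steps Quench steps (0 skips relaxation).
#' @param seed Integer seed (used by the relaxation dynamics).
#' @return Object of class `membrane_state`: `beads`, `normals` (n x 3
#'   matrices), `solutes_in`, `solutes_out` (0 x 3 until solutes are added),
#'   `R0`, and the potential parameters used.
#' @export
build_vesicle <- function(n_beads, R0, pot = membrane_potential_params(),
                          relax_steps = 600L, seed = 1L) {
  stopifnot(n_beads >= 100)
  spacing <- sqrt(4 * pi * R0^2 / n_beads / (sqrt(3) / 2))
  if (spacing < 0.8 * pot$r_min || spacing > 1.5 * pot$r_min) {
    stop(sprintf(
      "implied bead spacing %.3f outside [0.8, 1.5] r_min for n = %d, R0 = %.3g",
      spacing, n_beads, R0))
  }
  beads <- sphere_spiral(n_beads, R0)
  normals <- beads / R0
  state <- structure(list(beads = beads, normals = normals,
                          solutes_in = matrix(0, 0, 3),
                          solutes_out = matrix(0, 0, 3),
                          R0 = R0, pot = pot),
                     class = "membrane_state")
  if (relax_steps > 0) {
    sp <- sim_params(dt = 0.005, n_steps = relax_steps, kBT = 0,
                     gamma_t = 5, gamma_r = 5, epsilon_ad = 0,
                     seed = seed, stride = relax_steps,
                     rupture_check = FALSE, thermal_init = FALSE,
                     R_wall = 2 * R0)
    tr <- run_dynamics(state, dumbbell = NULL, sim = sp)
    state$beads <- tr$final$beads
    state$normals <- tr$final$normals
  }
  state
}

#' @export
print.membrane_state <- function(x, ...) {
  cat(sprintf(
    "membrane_state: %d beads, R0 = %.3g, %d inner / %d outer solutes\n",
    nrow(x$beads), x$R0, nrow(x$solutes_in), nrow(x$solutes_out)))
  invisible(x)
}

#' Solute counts that impose a target membrane tension
#'
#' Solute particles interacting only by volume exclusion exert, at dilute
#' concentrations, an ideal-gas pressure `P = kBT c` on each side of the
#' membrane; a concentration imbalance inflates the vesicle and the Laplace
#' relation `dP = kBT (c_in - c_out) = 2 sigma / R` ties the imbalance to
#' the membrane tension. Given a target tension this returns the integer
#' solute counts for the vesicle interior and the shell between vesicle and
#' confining wall.
#'
#' @param target_sigma Target tension (epsilon / sigma_b^2), >= 0.
#' @param R Vesicle radius (sigma_b).
#' @param kBT Thermal energy (epsilon).
#' @param geometry List with `R_wall` (confinement radius), `c_out`
#'   (baseline outer concentration, 1/sigma_b^3), and optionally `margin`
#'   (solute-membrane excluded-shell width, sigma_b) and `wall_margin`.
#'   Concentrations refer to the *accessible* volumes: solutes cannot
#'   approach the membrane closer than the bead-solute repulsion range.
#' @param packing_limit Maximum admissible concentration (1/sigma_b^3).
#' @return List with `n_in`, `n_out`, `c_in`, `c_out` (accessible-volume
#'   concentrations) and the ideal-gas `dP` the counts realise.
#' @export
set_tension_by_solutes <- function(target_sigma, R, kBT,
                                   geometry = list(R_wall = 1.6 * R,
                                                   c_out = 0.02),
                                   packing_limit = 1.5) {
  stopifnot(target_sigma >= 0, R > 0, kBT > 0)
  margin <- if (is.null(geometry$margin)) 0.35 else geometry$margin
  wmargin <- if (is.null(geometry$wall_margin)) -0.05 else geometry$wall_margin
  dP <- 2 * target_sigma / R
  c_out <- geometry$c_out
  c_in <- c_out + dP / kBT
  if (c_in > packing_limit) {
    stop(sprintf(
      "target tension requires c_in = %.3g above the packing limit %.3g",
      c_in, packing_limit))
  }
  V_in <- 4 / 3 * pi * (R - margin)^3
  V_out <- 4 / 3 * pi * ((geometry$R_wall - wmargin)^3 - (R + margin)^3)
  n_in <- round(c_in * V_in)
  n_out <- round(c_out * V_out)
  list(n_in = as.integer(n_in), n_out = as.integer(n_out),
       c_in = n_in / V_in, c_out = n_out / V_out,
       dP = kBT * (n_in / V_in - n_out / V_out))
}

#' Scatter solutes inside and outside the vesicle
#'
#' Uniform placement of `n_in` solutes in the vesicle interior and `n_out`
#' in the shell between vesicle and confining wall, with margins keeping
#' them clear of the membrane.
#'
#' @param state A [membrane_state()] from [build_vesicle()].
#' @param n_in,n_out Solute counts.
#' @param R_wall Confinement radius.
#' @param seed Integer seed.
#' @param margin Clearance from the membrane (sigma_b).
#' @param exclude Optional keep-out spheres (e.g. around an already placed
#'   colloid): list with `centers` (k x 3 matrix) and `radius`.
#' @return The state with `solutes_in` / `solutes_out` filled.
#' @export
add_solutes <- function(state, n_in, n_out, R_wall = 1.6 * state$R0,
                        seed = 1L, margin = 1.2, exclude = NULL) {
  set.seed(seed)
  sample_shell <- function(n, r_lo, r_hi, min_sep = 0.55) {
    if (n == 0L) return(matrix(0, 0, 3))
    out <- matrix(NA_real_, n, 3)
    placed <- 0L
    tries <- 0L
    while (placed < n) {
      tries <- tries + 1L
      if (tries > 200L * n) stop("cannot place solutes at this density")
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      p <- u * (stats::runif(1) * (r_hi^3 - r_lo^3) + r_lo^3)^(1 / 3)
      if (!is.null(exclude) &&
          min(rowSums(sweep(exclude$centers, 2, p, `-`)^2)) <
            exclude$radius^2) next
      if (placed > 0L) {
        d2 <- min(rowSums(sweep(out[seq_len(placed), , drop = FALSE],
                                2, p, `-`)^2))
        if (d2 < min_sep^2) next
      }
      placed <- placed + 1L
      out[placed, ] <- p
    }
    out
  }
  state$solutes_in <- sample_shell(n_in, 0, state$R0 - margin)
  state$solutes_out <- sample_shell(n_out, state$R0 + margin, R_wall - 0.6)
  state$R_wall <- R_wall
  state
}

#' Adhesion energy and force between a membrane bead and the dumbbell
#'
#' The adhesive interaction acts between a bead and the *nearest* lobe
#' surface (no double counting at the neck): a cosine-squared well of depth
#' `epsilon_ad` with its minimum at the contact distance `contact_h`,
#' vanishing at `r_cut_ad`; inside contact a harmonic core with capped
#' force. Mirrors the interaction used by [run_dynamics()].
#'
#' @param bead Length-3 bead position.
#' @param db A [dumbbell_body()].
#' @param epsilon_ad Well depth (epsilon).
#' @param r_cut_ad Cutoff distance from the lobe surface (sigma_b).
#' @param contact_h Contact distance (sigma_b).
#' @param k_rep,f_cap Core stiffness and force cap.
#' @return List with `energy` and `force` (on the bead).
#' @export
adhesion_energy <- function(bead, db, epsilon_ad, r_cut_ad,
                            contact_h = 0.5, k_rep = 200, f_cap = 100) {
  lc <- lobe_centers(db)
  d1 <- sqrt(sum((bead - lc[1, ])^2))
  d2 <- sqrt(sum((bead - lc[2, ])^2))
  k <- if (d1 <= d2) 1L else 2L
  d <- min(d1, d2)
  h <- d - db$a
  if (h >= r_cut_ad) {
    return(list(energy = 0, force = c(0, 0, 0)))
  }
  if (h >= contact_h) {
    w <- pi / 2 / (r_cut_ad - contact_h)
    xi <- w * (h - contact_h)
    U <- -epsilon_ad * cos(xi)^2
    dUdh <- epsilon_ad * w * sin(2 * xi)
  } else {
    U <- -epsilon_ad + 0.5 * k_rep * (h - contact_h)^2
    dUdh <- max(-f_cap, k_rep * (h - contact_h))
  }
  u <- (bead - lc[k, ]) / d
  list(energy = U, force = -dUdh * u)
}

#' Run Langevin dynamics of the membrane (+ solutes, + dumbbell)
#'
#' Integrates the coupled dynamics with a BAOAB-splitting Langevin
#' integrator: translational Langevin for beads and solutes, rotational
#' Langevin of the bead normals about their two in-plane axes, and
#' rigid-body Langevin of the dumbbell (centre plus axis; the spin about
#' the symmetry axis is irrelevant and not tracked, so the lobe separation
#' is exactly `2a` by construction). With `gamma_t = gamma_r = 0` the
#' scheme reduces to velocity-Verlet microcanonical dynamics.
#'
#' @param state A [membrane_state()].
#' @param dumbbell A [dumbbell_body()] or `NULL`.
#' @param sim A [sim_params()].
#' @param pot Overrides the potential stored in `state`.
#' @return Object of class `wrap_trajectory`: snapshot `times`, lists
#'   `beads` and `normals`, matrices `dumbbell_center` / `dumbbell_axis`,
#'   a `diag` data.frame (time, potential and kinetic energies, measured
#'   inner/outer solute pressures), the `final` state, and rupture flags.
#' @export
run_dynamics <- function(state, dumbbell = NULL, sim = sim_params(),
                         pot = NULL) {
  stopifnot(inherits(state, "membrane_state"), inherits(sim, "sim_params"))
  if (is.null(pot)) pot <- state$pot
  simlist <- unclass(sim)
  if (is.na(simlist$R_wall)) {
    simlist$R_wall <- if (!is.null(state$R_wall)) state$R_wall else 1.6 * state$R0
  }
  db <- if (is.null(dumbbell)) list() else
    list(center = dumbbell$center, axis = dumbbell$axis, a = dumbbell$a)
  res <- run_dynamics_cpp(state$beads, state$normals,
                          state$solutes_in, state$solutes_out,
                          db, unclass(pot), simlist)
  res$diag <- as.data.frame(res$diag)
  res$has_dumbbell <- !is.null(dumbbell)
  res$a_lobe <- if (!is.null(dumbbell)) dumbbell$a else NA_real_
  res$sim <- sim
  res$pot <- pot
  res$n_beads <- nrow(state$beads)
  res$n_solutes <- c(nrow(state$solutes_in), nrow(state$solutes_out))
  class(res) <- "wrap_trajectory"
  res
}

#' @export
print.wrap_trajectory <- function(x, ...) {
  cat(sprintf(
    "wrap_trajectory: %d snapshots, %d beads, t in [0, %.4g] tau0%s\n",
    length(x$times), x$n_beads, max(x$times),
    if (isTRUE(x$ruptured)) sprintf(" [RUPTURED at step %d]", x$rupture_step)
    else ""))
  invisible(x)
}
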