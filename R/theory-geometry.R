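#' Dumbbell surface geometry for the wrapping theory
#'
#' Constructs the axisymmetric surface over which the wrapping front of the
#' analytical engulfment model advances: two tangent spheres of radius `a`
#' (lobe radius, half the sphere diameter `d_s`) joined by a torus fillet of
#' radius `rho_n` that smooths the tangent-point singularity at the neck. The
#' meridian is parameterised by arc length `s` from the first-contact pole
#' (`s = 0`, the pole of lobe 1) to the far pole of lobe 2 (`s = s_max`).
#'
#' With `lobes = 1` the geometry degenerates to a single sphere of radius
#' `a` (meridian `s` in `[0, pi*a]`), which is the classical sphere-wrapping
#' limit used for closed-form cross-checks.
#'
#' @param a Lobe radius (m). For the colloids this model targets,
#'   `a = d_s/2` with sphere diameter `d_s` around a micrometre.
#' @param rho_n Neck (fillet) regularisation radius (m), `0 < rho_n < a`.
#'   The default `0.15*a` is a geometric smoothing of the tangent-sphere
#'   junction; larger values emulate a membrane that bridges the neck with a
#'   wide, nearly minimal surface.
#' @param lobes 1 or 2.
#' @return An object of class `dumbbell_geometry`.
#' @examples
#' geom <- dumbbell_geometry(a = 0.49e-6)
#' geom$s_max
#' wrapped_area(geom$s_max, geom) / (8 * pi * geom$a^2) # slightly < 1
#' @export
dumbbell_geometry <- function(a, rho_n = 0.15 * a, lobes = 2) {
  stopifnot(is.numeric(a), length(a) == 1L, a > 0)
  lobes <- as.integer(lobes)
  if (!lobes %in% c(1L, 2L)) stop("'lobes' must be 1 or 2")
  if (lobes == 2L) {
    if (!(rho_n > 0 && rho_n < a)) {
      stop("'rho_n' must satisfy 0 < rho_n < a")
    }
    alpha <- acos(a / (a + rho_n))     # polar offset of the sphere/fillet tangency
    u_m   <- pi / 2 - alpha            # fillet half-angle
    rho_c <- sqrt(2 * a * rho_n + rho_n^2) # axial distance of the fillet centre
    s_b1  <- a * (pi - alpha)          # end of the lobe-1 spherical zone
    s_b2  <- s_b1 + 2 * rho_n * u_m    # end of the fillet zone
    s_max <- s_b2 + a * (pi - alpha)   # far pole of lobe 2
    A_b1  <- 2 * pi * a^2 * (1 + cos(alpha))
    A_fil <- 2 * pi * rho_n * (2 * rho_c * u_m - 2 * rho_n * sin(u_m))
    g <- list(a = a, rho_n = rho_n, lobes = 2L,
              alpha = alpha, u_m = u_m, rho_c = rho_c,
              s_b1 = s_b1, s_b2 = s_b2, s_max = s_max,
              A_b1 = A_b1, A_fil = A_fil)
    # cumulative bending-energy shape factor over the fillet: Q(u) such that
    # E_bend = kappa * Q; spheres are handled in closed form, the fillet band
    # numerically on a dense grid (the integrand is smooth).
    ugrid <- seq(-u_m, u_m, length.out = 2001L)
    rho_u <- rho_c - rho_n * cos(ugrid)
    H_u <- 0.5 * (-1 / rho_n + cos(ugrid) / rho_u)
    integrand <- 2 * H_u^2 * 2 * pi * rho_u * rho_n
    Qcum <- c(0, cumsum((integrand[-1] + integrand[-length(integrand)]) / 2 *
                          diff(ugrid)))
    g$fillet_Q <- stats::approxfun(ugrid, Qcum, rule = 2)
    g$Q_fil_total <- Qcum[length(Qcum)]
  } else {
    g <- list(a = a, rho_n = 0, lobes = 1L, s_max = pi * a)
  }
  class(g) <- "dumbbell_geometry"
  g
}

#' @export
print.dumbbell_geometry <- function(x, ...) {
  cat("dumbbell_geometry:", x$lobes, "lobe(s), a =", format(x$a),
      if (x$lobes == 2L) paste0("rho_n = ", format(x$rho_n)) else "",
      "s_max =", format(x$s_max), "\n")
  invisible(x)
}

# Meridian profile at arc length s: distance from the symmetry axis rho(s),
# outward-normal polar angle psi(s) (measured from the first-contact
# direction), its derivative dpsi/ds, mean curvature H(s) and region id
# (1 sphere-1, 2 fillet, 3 sphere-2). Vectorised over s; returns plain
# vectors (this sits in the inner loop of the wrap-time quadrature).
meridian <- function(s, geom) {
  a <- geom$a
  if (geom$lobes == 1L) {
    phi <- s / a
    return(list(s = s, rho = a * sin(phi), psi = phi,
                dpsi = rep(1 / a, length(s)),
                H = rep(1 / a, length(s)), region = rep(1L, length(s))))
  }
  rn <- geom$rho_n
  nn <- length(s)
  out <- list(s = s, rho = rep(NA_real_, nn), psi = rep(NA_real_, nn),
              dpsi = rep(NA_real_, nn), H = rep(NA_real_, nn),
              region = rep(NA_integer_, nn))
  i1 <- s <= geom$s_b1
  i2 <- s > geom$s_b1 & s < geom$s_b2
  i3 <- s >= geom$s_b2
  phi1 <- s[i1] / a
  out$rho[i1] <- a * sin(phi1); out$psi[i1] <- phi1
  out$dpsi[i1] <- 1 / a; out$H[i1] <- 1 / a; out$region[i1] <- 1L
  u <- (s[i2] - geom$s_b1) / rn - geom$u_m
  rho_u <- geom$rho_c - rn * cos(u)
  out$rho[i2] <- rho_u; out$psi[i2] <- pi / 2 - u
  out$dpsi[i2] <- -1 / rn
  out$H[i2] <- 0.5 * (-1 / rn + cos(u) / rho_u); out$region[i2] <- 2L
  phi2 <- geom$alpha + (s[i3] - geom$s_b2) / a
  out$rho[i3] <- a * sin(phi2); out$psi[i3] <- phi2
  out$dpsi[i3] <- 1 / a; out$H[i3] <- 1 / a; out$region[i3] <- 3L
  out
}

#' Wrapped surface area poleward of the contact line
#'
#' Area of the dumbbell surface between the first-contact pole and the
#' axisymmetric wrapping front at meridian arc length `s`, in closed form
#' per zone (spherical caps and a torus band). Strictly increasing in `s`;
#' at `s = s_max` and `rho_n -> 0` it tends to `8*pi*a^2` (two full
#' spheres minus the vanishing junction caps).
#'
#' @param s Arc length(s) along the meridian, in `[0, s_max]`.
#' @param geom A [dumbbell_geometry()].
#' @return Area(s) (m^2).
#' @export
wrapped_area <- function(s, geom) {
  stopifnot(inherits(geom, "dumbbell_geometry"))
  tol <- 1e-9 * geom$s_max
  if (any(s < -tol | s > geom$s_max + tol)) {
    stop("front position 's' outside [0, s_max]")
  }
  s <- pmin(pmax(s, 0), geom$s_max)
  a <- geom$a
  if (geom$lobes == 1L) {
    return(2 * pi * a^2 * (1 - cos(s / a)))
  }
  rn <- geom$rho_n
  A <- numeric(length(s))
  i1 <- s <= geom$s_b1
  i2 <- s > geom$s_b1 & s < geom$s_b2
  i3 <- s >= geom$s_b2
  A[i1] <- 2 * pi * a^2 * (1 - cos(s[i1] / a))
  u <- (s[i2] - geom$s_b1) / rn - geom$u_m
  A[i2] <- geom$A_b1 + 2 * pi * rn *
    (geom$rho_c * (u + geom$u_m) - rn * (sin(u) + sin(geom$u_m)))
  phi2 <- geom$alpha + (s[i3] - geom$s_b2) / a
  A[i3] <- geom$A_b1 + geom$A_fil + 2 * pi * a^2 * (cos(geom$alpha) - cos(phi2))
  A
}

# Bending shape factor Q(s) = E_bend(s)/kappa = int 2 H^2 dA over the wrapped
# surface; closed form on the spherical zones, tabulated on the fillet.
bend_shape <- function(s, geom) {
  a <- geom$a
  if (geom$lobes == 1L) {
    return((2 / a^2) * wrapped_area(s, geom))
  }
  s <- pmin(pmax(s, 0), geom$s_max)
  Q <- numeric(length(s))
  i1 <- s <= geom$s_b1
  i2 <- s > geom$s_b1 & s < geom$s_b2
  i3 <- s >= geom$s_b2
  Q[i1] <- (2 / a^2) * 2 * pi * a^2 * (1 - cos(s[i1] / a))
  Q1 <- (2 / a^2) * geom$A_b1
  u <- (s[i2] - geom$s_b1) / geom$rho_n - geom$u_m
  Q[i2] <- Q1 + geom$fillet_Q(u)
  phi2 <- geom$alpha + (s[i3] - geom$s_b2) / a
  Q[i3] <- Q1 + geom$Q_fil_total +
    (2 / a^2) * 2 * pi * a^2 * (cos(geom$alpha) - cos(phi2))
  Q
}
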