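#' Tilt angle between dumbbell axis and vesicle surface normal
#'
#' `theta = acos(|axis . normal|)` in degrees, folded into `[0, 90]` because
#' the dumbbell is fore-aft symmetric. The reference normal is the radial
#' direction of the undistorted (fitted) vesicle sphere at the dumbbell's
#' centre of mass, matching how tilt is measured against a GUV.
#'
#' @param axis Dumbbell long-axis vector (any nonzero length).
#' @param normal Outward surface-normal vector (any nonzero length).
#' @return Angle in degrees, in `[0, 90]`.
#' @export
compute_theta <- function(axis, normal) {
  na <- sqrt(sum(axis^2)); nn <- sqrt(sum(normal^2))
  if (na == 0 || nn == 0) stop("zero-length vector given to compute_theta")
  acos(pmin(1, abs(sum(axis * normal)) / (na * nn))) * 180 / pi
}

#' Insertion depth of the dumbbell relative to the undistorted vesicle
#'
#' `d = R - |com - vesicle_center|`: positive when the centre of mass lies
#' inside the undistorted sphere of radius `R` (i.e. the particle has moved
#' toward the vesicle interior).
#'
#' @param com Dumbbell centre of mass (length-3).
#' @param vesicle_center Vesicle centre (length-3).
#' @param R Undistorted vesicle radius.
#' @return Depth `d`, in the units of the inputs.
#' @export
compute_depth <- function(com, vesicle_center, R) {
  stopifnot(R > 0)
  R - sqrt(sum((com - vesicle_center)^2))
}

#' Equatorial tracking band filter
#'
#' Keeps only frames whose dumbbell centre of mass lies in the equatorial
#' band `-0.8 R < z < 0.8 R`, where both lobes can be located reliably.
#'
#' @param frames data.frame with columns `z` and (unless `R` is given) `R`.
#' @param R Vesicle radius; if missing, taken per-frame from `frames$R`.
#' @param band Half-width of the band in units of `R` (default 0.8).
#' @return The retained subset of `frames`.
#' @export
filter_equatorial_band <- function(frames, R = NULL, band = 0.8) {
  Rv <- if (is.null(R)) frames$R else R
  keep <- frames$z > -band * Rv & frames$z < band * Rv
  frames[keep, , drop = FALSE]
}

# Quasi-uniform Fibonacci point set on the unit sphere.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Per-lobe wrapped fractions from a simulation frame
#'
#' Estimates, for each lobe of the dumbbell, the fraction of its accessible
#' surface that is in adhesive contact with the membrane: a fixed
#' quasi-uniform mesh of points is placed on each lobe sphere, mesh points in
#' the neck-occluded cap (where a membrane bead at contact distance would
#' overlap the other lobe) are excluded, and a point counts as covered when
#' at least one membrane bead lies within the contact cutoff.
#'
#' @param beads Numeric matrix (n x 3) of membrane bead positions; may be
#'   empty.
#' @param center,axis,a Dumbbell centre (length-3), unit axis, lobe radius.
#' @param contact_cutoff Bead-to-lobe-surface distance counted as contact
#'   (normally the adhesion cutoff of the simulation).
#' @param bead_radius Membrane bead radius used for the occlusion test.
#' @param mesh_n Mesh points per lobe.
#' @return Named numeric `c(f1, f2)` in lobe order (no relabelling applied).
#' @export
wrapped_fraction <- function(beads, center, axis, a, contact_cutoff,
                             bead_radius = 0.5, mesh_n = 500L) {
  axis <- axis / sqrt(sum(axis^2))
  mesh <- fibonacci_sphere(mesh_n)
  f <- numeric(2)
  lobe_centers <- rbind(center + a * axis, center - a * axis)
  for (k in 1:2) {
    ck <- lobe_centers[k, ]
    cother <- lobe_centers[3 - k, ]
    pts <- sweep(mesh * a, 2L, ck, `+`)
    # neck occlusion: where a bead adhering to the other lobe would also
    # register as contact here, coverage is ambiguous; that cap is excluded
    d_other <- sqrt(rowSums(sweep(pts, 2L, cother, `-`)^2))
    accessible <- d_other >= a + (bead_radius + contact_cutoff) * 0.999
    if (!any(accessible)) { f[k] <- 0; next }
    pts <- pts[accessible, , drop = FALSE]
    if (is.null(beads) || NROW(beads) == 0L) { f[k] <- 0; next }
    b <- as.matrix(beads)
    # pre-filter beads to the lobe's neighbourhood
    db <- sqrt(rowSums(sweep(b, 2L, ck, `-`)^2))
    b <- b[db <= a + contact_cutoff + 2 * bead_radius, , drop = FALSE]
    if (nrow(b) == 0L) { f[k] <- 0; next }
    covered <- logical(nrow(pts))
    for (j in seq_len(nrow(b))) {
      dd <- sqrt(rowSums(sweep(pts, 2L, b[j, ], `-`)^2))
      covered <- covered | (dd <= contact_cutoff)
      if (all(covered)) break
    }
    f[k] <- mean(covered)
  }
  c(f1 = f[1], f2 = f[2])
}

#' Wrapping-state labels
#'
#' The nine configurations a wrapping dumbbell passes through, plus "none"
#' for an unattached particle: initial attachment perpendicular (A1), oblique
#' (A2) or parallel with both lobes bound (A3); first lobe partially wrapped
#' with a single lobe in contact (B); both lobes shallowly bound (C); one
#' lobe engulfed to the waist with the other free (D, a terminal state);
#' asymmetric (E1) or symmetric (E2) wrapping of both lobes; fully wrapped
#' (F, terminal).
#'
#' @return Character vector of the valid labels.
#' @export
wrap_states <- function() {
  c("A1", "A2", "A3", "B", "C", "D", "E1", "E2", "F", "none")
}

#' Classify a frame into a wrapping state
#'
#' Decision table over the per-lobe wrapped fractions (`f1 >= f2` by the
#' more-wrapped-lobe-first convention), contact flags and tilt angle. The
#' fraction thresholds (0.05 attachment, 0.2 symmetric co-wrapping, 0.45
#' shallow/deep, 0.9 engulfed) and the 30 degree perpendicular band are
#' classifier conventions, configurable via `thresholds`.
#'
#' @param f1,f2 Wrapped fractions in `[0, 1]`, `f1 >= f2`.
#' @param second_lobe_contact Has the less-wrapped lobe touched the membrane?
#' @param attached Is the particle bound to the membrane at all?
#' @param theta Tilt angle in degrees (used only to split A1/A2).
#' @param thresholds Named list `attach`, `sym`, `shallow`, `engulfed`,
#'   `perp_deg`.
#' @return A single state label (see [wrap_states()]).
#' @export
classify_wrap_state <- function(f1, f2, second_lobe_contact, attached,
                                theta = NA_real_,
                                thresholds = list(attach = 0.05, sym = 0.2,
                                                  shallow = 0.45,
                                                  engulfed = 0.9,
                                                  perp_deg = 30)) {
  th <- thresholds
  if (any(c(f1, f2) < 0) || any(c(f1, f2) > 1)) {
    stop("wrapped fractions must lie in [0, 1]")
  }
  if (f1 < f2) stop("f1 must be the more-wrapped lobe (f1 >= f2)")
  if (!attached) return("none")
  if (f1 < th$attach) {
    if (second_lobe_contact) return("A3")
    if (!is.na(theta) && theta < th$perp_deg) return("A1")
    return("A2")
  }
  if (f1 < th$shallow) {
    if (!second_lobe_contact) return("B")
    if (f1 >= th$sym && f2 >= th$sym) return("E2")
    return("C")
  }
  if (f1 < th$engulfed) {
    if (!second_lobe_contact) return("B")
    if (f2 >= th$sym) return("E2")
    return("E1")
  }
  # f1 >= engulfed
  if (f2 >= th$engulfed) return("F")
  if (f2 >= th$attach) return("E1")
  if (second_lobe_contact) return("E1")
  "D"
}

#' Classify every frame of an observable series
#'
#' Vectorised wrapper around [classify_wrap_state()]. Applies the
#' more-wrapped-lobe-first relabelling before classification.
#'
#' @param series data.frame with columns `f1`, `f2`, `second_lobe_contact`,
#'   `attached` and optionally `theta`.
#' @param ... Passed to [classify_wrap_state()].
#' @return Character vector of state labels, one per row.
#' @export
classify_series <- function(series, ...) {
  f1 <- pmax(series$f1, series$f2)
  f2 <- pmin(series$f1, series$f2)
  th <- if ("theta" %in% names(series)) series$theta else rep(NA_real_, nrow(series))
  vapply(seq_len(nrow(series)), function(i) {
    classify_wrap_state(f1[i], f2[i], series$second_lobe_contact[i],
                        series$attached[i], th[i], ...)
  }, character(1))
}

#' Transition times between wrapping states
#'
#' Collapses the per-frame state sequence into runs, removes flickers
#' shorter than the debounce window (merging the surrounding runs when they
#' agree), and reports the elapsed time of every consecutive ordered state
#' pair, measured between run onsets.
#'
#' @param states Character vector of per-frame labels.
#' @param times Monotone non-decreasing frame times.
#' @param debounce Minimum run length, in frames, for a state to count.
#' @return data.frame with columns `from`, `to`, `t_start`, `duration`;
#'   zero rows for an empty or single-state series.
#' @export
transition_times <- function(states, times, debounce = 5L) {
  stopifnot(length(states) == length(times))
  empty <- data.frame(from = character(), to = character(),
                      t_start = numeric(), duration = numeric())
  if (length(states) == 0L) return(empty)
  if (is.unsorted(times)) stop("frame times must be monotone")
  r <- rle(states)
  starts <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
  keep <- r$lengths >= debounce
  if (!any(keep)) return(empty)
  vals <- r$values[keep]; st <- starts[keep]
  # merge adjacent identical runs that debouncing exposed
  m <- c(TRUE, vals[-1] != vals[-length(vals)])
  vals <- vals[m]; st <- st[m]
  if (length(vals) < 2L) return(empty)
  t0 <- times[st]
  data.frame(from = vals[-length(vals)], to = vals[-1],
             t_start = t0[-length(t0)], duration = diff(t0))
}

#' Aggregate transition times over an ensemble of runs
#'
#' @param tables List of data.frames from [transition_times()].
#' @return data.frame with one row per ordered state pair: mean, sd and
#'   count of the observed durations.
#' @export
aggregate_transitions <- function(tables) {
  all <- do.call(rbind, tables)
  if (is.null(all) || nrow(all) == 0L) {
    return(data.frame(from = character(), to = character(),
                      mean = numeric(), sd = numeric(), n = integer()))
  }
  key <- paste(all$from, all$to, sep = "->")
  agg <- lapply(split(all$duration, key), function(d) {
    c(mean = mean(d), sd = stats::sd(d), n = length(d))
  })
  pairs <- do.call(rbind, strsplit(names(agg), "->", fixed = TRUE))
  out <- data.frame(from = pairs[, 1], to = pairs[, 2],
                    mean = vapply(agg, `[[`, numeric(1), "mean"),
                    sd = vapply(agg, `[[`, numeric(1), "sd"),
                    n = as.integer(vapply(agg, `[[`, numeric(1), "n")))
  rownames(out) <- NULL
  out
}

#' Non-overlapping time-window averages of an observable series
#'
#' Means of the numeric columns over consecutive windows of fixed duration
#' (e.g. the 1 s averaging used when plotting wrapping pathways), with the
#' per-bin frame count.
#'
#' @param series data.frame with a `time` column.
#' @param window Window length (> 0), in the units of `time`.
#' @param cols Columns to average; default all numeric columns except `time`.
#' @return data.frame: `time` (bin centre), averaged columns, `n` frames.
#' @export
bin_time_average <- function(series, window, cols = NULL) {
  stopifnot(window > 0)
  if (nrow(series) == 0L) return(series)
  if (is.null(cols)) {
    cols <- names(series)[vapply(series, is.numeric, logical(1))]
    cols <- setdiff(cols, "time")
  }
  t0 <- min(series$time)
  n_bins <- max(1, ceiling((max(series$time) - t0) / window - 1e-9))
  bin <- pmin(floor((series$time - t0) / window + 1e-9), n_bins - 1)
  out <- data.frame(time = t0 + (sort(unique(bin)) + 0.5) * window)
  for (cc in cols) {
    out[[cc]] <- as.numeric(tapply(series[[cc]], bin, mean))
  }
  out$n <- as.integer(tapply(series$time, bin, length))
  out
}
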