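config_defaults <- function() {
  list(
    stage = "",
    seed = 1L,
    out = ".",
    log_level = "info",
    potential = unclass(membrane_potential_params()),
    simulation = list(dt = 0.01, n_steps = 10000L, kBT = 0.23,
                      gamma_t = 1, gamma_r = 1, epsilon_ad = 1.6,
                      r_cut_ad = 1.8, stride = 100L),
    vesicle = list(n_beads = 1600L, R0 = 12, target_sigma = 0,
                   c_out = 0.02),
    dumbbell = list(a = 2.2, orientation = "parallel"),
    spectroscopy = list(sigma = 1e-7, kappa_kBT = 20, R = 1e-5,
                        n_frames = 2000L, n_angles = 128L,
                        noise_floor = 0, n_min = 3L, n_max = 20L),
    theory = list(a = 0.49e-6, rho_n_frac = 0.6, W = 0.76e-6,
                  eta_eff = 0.8, kappa_kBT = 20, alpha = 2,
                  sigma_min = 2e-9, sigma_max = 2e-8, n_sigma = 8L,
                  cv = 0.05)
  )
}

# recursively merge user values into defaults, rejecting unknown keys
merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      stop("unknown configuration key '", full, "'", call. = FALSE)
    }
    dv <- defaults[[key]]
    uv <- user[[key]]
    if (is.null(uv)) next
    if (is.list(dv) && !is.null(names(dv))) {
      if (!is.list(uv)) stop("key '", full, "' must be a block", call. = FALSE)
      defaults[[key]] <- merge_config(dv, uv, full)
    } else {
      if (!is.null(dv) && !is.null(uv) &&
          is.numeric(dv) != is.numeric(uv)) {
        stop("type mismatch for key '", full, "'", call. = FALSE)
      }
      defaults[[key]] <- uv
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, checks every key against the schema (unknown
#' keys and type mismatches are errors naming the offending key) and fills
#' unset values with the package defaults.
#'
#' @param path Path to a YAML file.
#' @return Named list of class `run_config` with all defaults resolved.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  cfg <- merge_config(config_defaults(), user)
  class(cfg) <- "run_config"
  cfg
}

#' Write a resolved configuration next to run outputs
#' @param cfg A `run_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 15L)
  invisible(path)
}

artifact_header <- function(seed) {
  sprintf("# vesiwrap %s seed=%d",
          as.character(utils::packageVersion("vesiwrap")), as.integer(seed))
}

#' Write an observable series to CSV
#'
#' Column layout: `time, theta_deg, d, z, f1, f2, state`, preceded by a
#' comment line carrying the package version and seed.
#'
#' @param series data.frame with columns `time`, `theta`, `d`, `z`, `f1`,
#'   `f2`, `state` (extra columns are ignored).
#' @param path Output path.
#' @param seed Seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_observables <- function(series, path, seed = 0L) {
  df <- data.frame(time = series$time, theta_deg = series$theta,
                   d = series$d, z = series$z, f1 = series$f1,
                   f2 = series$f2, state = series$state)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(artifact_header(seed), con)
  writeLines(paste(names(df), collapse = ","), con)
  if (nrow(df) > 0L) {
    utils::write.table(df, con, sep = ",", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read an observable series written by [write_observables()]
#'
#' Validates the layout line by line: malformed rows and unknown state
#' labels raise errors naming the line number.
#'
#' @param path CSV path.
#' @return data.frame with columns `time`, `theta`, `d`, `z`, `f1`, `f2`,
#'   `state`.
#' @export
read_observables <- function(path) {
  lines <- readLines(path)
  body <- which(!startsWith(lines, "#"))
  if (length(body) == 0L) stop("no header line found in ", path)
  hdr_line <- body[1]
  header <- strsplit(lines[hdr_line], ",", fixed = TRUE)[[1]]
  expected <- c("time", "theta_deg", "d", "z", "f1", "f2", "state")
  if (!identical(header, expected)) {
    stop("line ", hdr_line, ": expected header '",
         paste(expected, collapse = ","), "'")
  }
  rows <- body[-1]
  n <- length(rows)
  out <- data.frame(time = numeric(n), theta = numeric(n), d = numeric(n),
                    z = numeric(n), f1 = numeric(n), f2 = numeric(n),
                    state = character(n))
  valid <- wrap_states()
  for (k in seq_along(rows)) {
    ln <- rows[k]
    parts <- strsplit(lines[ln], ",", fixed = TRUE)[[1]]
    if (length(parts) != 7L) {
      stop("line ", ln, ": expected 7 fields, found ", length(parts))
    }
    vals <- suppressWarnings(as.numeric(parts[1:6]))
    if (any(is.na(vals))) {
      stop("line ", ln, ": non-numeric value in a numeric field")
    }
    if (!parts[7] %in% valid) {
      stop("line ", ln, ": unknown state label '", parts[7], "'")
    }
    out[k, 1:6] <- as.list(vals)
    out$state[k] <- parts[7]
  }
  out
}

#' Write simulation snapshots as extended XYZ
#'
#' One frame per snapshot; each line carries species (`M` membrane bead,
#' `S` solute, `D` dumbbell lobe), position and, for membrane beads, the
#' orientation vector.
#'
#' @param traj A `wrap_trajectory`.
#' @param path Output path.
#' @param seed Seed recorded in the frame comments.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path, seed = 0L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(traj$times)) {
    b <- traj$beads[[i]]
    nrm <- traj$normals[[i]]
    lines <- sprintf("M %.6f %.6f %.6f %.6f %.6f %.6f",
                     b[, 1], b[, 2], b[, 3], nrm[, 1], nrm[, 2], nrm[, 3])
    nl <- nrow(b)
    if (traj$has_dumbbell) {
      ctr <- traj$dumbbell_center[i, ]
      ax <- traj$dumbbell_axis[i, ]
      lc <- rbind(ctr + traj$a_lobe * ax, ctr - traj$a_lobe * ax)
      lines <- c(lines, sprintf("D %.6f %.6f %.6f 0 0 0",
                                lc[, 1], lc[, 2], lc[, 3]))
      nl <- nl + 2L
    }
    writeLines(as.character(nl), con)
    writeLines(sprintf(
      'Lattice="" Properties=species:S:1:pos:R:3:normal:R:3 Time=%.6f %s',
      traj$times[i], artifact_header(seed)), con)
    writeLines(lines, con)
  }
  invisible(path)
}

cli_usage <- function() {
  paste(
    "vesiwrap <command> [options]",
    "",
    "commands:",
    "  simulate --config FILE --seed N --out DIR   wrapping simulation",
    "  analyze  --in traj.csv --out DIR            observables -> states",
    "  tension  --in contours.csv --out DIR        flicker-spectroscopy fit",
    "  theory curve|fit|barrier [options] --out DIR",
    "  synth contours|pathway|wraptime [options] --out DIR",
    "",
    "common options: --seed N, --config FILE, --out DIR",
    sep = "\n")
}

parse_argv <- function(argv) {
  opts <- list()
  pos <- character()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3)
      if (i == length(argv) || startsWith(argv[i + 1L], "--")) {
        opts[[key]] <- TRUE
        i <- i + 1L
      } else {
        opts[[key]] <- argv[i + 1L]
        i <- i + 2L
      }
    } else {
      pos <- c(pos, a)
      i <- i + 1L
    }
  }
  list(opts = opts, pos = pos)
}

opt_num <- function(opts, key, default) {
  if (is.null(opts[[key]])) default else as.numeric(opts[[key]])
}

#' Command-line dispatcher
#'
#' Entry point behind the `vesiwrap` script: routes
#' `simulate | analyze | tension | theory (curve|fit|barrier) | synth
#' (contours|pathway|wraptime)` to the package functions, writes outputs
#' under `--out`, and returns an exit code (0 on success) instead of
#' quitting, so it is directly testable.
#'
#' @param argv Character vector of command-line arguments.
#' @return Integer exit code.
#' @export
cli_dispatch <- function(argv) {
  res <- tryCatch({
    p <- parse_argv(argv)
    if (length(p$pos) == 0L) {
      message(cli_usage())
      return(2L)
    }
    cmd <- p$pos[1]
    seed <- as.integer(opt_num(p$opts, "seed", 1))
    outdir <- if (is.null(p$opts$out)) "." else p$opts$out
    if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
    cfg <- if (!is.null(p$opts$config)) load_config(p$opts$config) else {
      c0 <- config_defaults(); class(c0) <- "run_config"; c0
    }
    cfg$seed <- seed
    switch(cmd,
      simulate = cli_simulate(cfg, seed, outdir),
      analyze = cli_analyze(p$opts, outdir),
      tension = cli_tension(p$opts, cfg, outdir),
      theory = cli_theory(p$pos, p$opts, cfg, seed, outdir),
      synth = cli_synth(p$pos, p$opts, cfg, seed, outdir),
      defaults = { cat(yaml::as.yaml(unclass(cfg))); 0L },
      { message("unknown command '", cmd, "'\n", cli_usage()); 2L }
    )
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  as.integer(res)
}

cli_simulate <- function(cfg, seed, outdir) {
  sm <- cfg$simulation
  sim <- sim_params(dt = sm$dt, n_steps = sm$n_steps, kBT = sm$kBT,
                    gamma_t = sm$gamma_t, gamma_r = sm$gamma_r,
                    epsilon_ad = sm$epsilon_ad, r_cut_ad = sm$r_cut_ad,
                    stride = sm$stride, seed = seed)
  pot <- do.call(membrane_potential_params, cfg$potential)
  traj <- simulate_wrapping(n_beads = cfg$vesicle$n_beads,
                            R0 = cfg$vesicle$R0, a = cfg$dumbbell$a,
                            orientation = cfg$dumbbell$orientation,
                            target_sigma = cfg$vesicle$target_sigma,
                            sim = sim, pot = pot,
                            c_out = cfg$vesicle$c_out, seed = seed)
  obs <- trajectory_observables(traj)
  write_observables(obs, file.path(outdir, "observables.csv"), seed)
  write_xyz(traj, file.path(outdir, "trajectory.xyz"), seed)
  save_config(cfg, file.path(outdir, "config.yaml"))
  0L
}

cli_analyze <- function(opts, outdir) {
  if (is.null(opts[["in"]])) stop("analyze requires --in observables.csv")
  obs <- read_observables(opts[["in"]])
  obs$theta <- obs$theta  # read_observables returns theta already
  tt <- transition_times(obs$state, obs$time)
  jsonlite::write_json(tt, file.path(outdir, "transitions.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  0L
}

cli_tension <- function(opts, cfg, outdir) {
  sp <- cfg$spectroscopy
  if (!is.null(opts[["in"]])) {
    radii <- as.matrix(utils::read.csv(opts[["in"]], comment.char = "#",
                                       header = FALSE))
    series <- contour_series(radii)
  } else {
    series <- synth_contours(sp$sigma, sp$kappa_kBT * thermal_energy(),
                             sp$R, sp$n_frames, sp$n_angles,
                             sp$noise_floor, seed = cfg$seed)
  }
  est <- fit_fluctuation_spectrum(series, n_range = c(sp$n_min, sp$n_max))
  jsonlite::write_json(
    list(sigma = est$sigma, se_sigma = est$se_sigma, kappa = est$kappa,
         kappa_kBT = est$kappa_kBT, se_kappa = est$se_kappa,
         n_frames = est$n_frames, converged = est$converged),
    file.path(outdir, "tension.json"), auto_unbox = TRUE, digits = NA)
  0L
}

cli_theory <- function(pos, opts, cfg, seed, outdir) {
  sub <- if (length(pos) >= 2L) pos[2] else stop(
    "theory requires a subcommand: curve, fit or barrier")
  th <- cfg$theory
  kT <- thermal_energy()
  geom <- dumbbell_geometry(th$a, rho_n = th$rho_n_frac * th$a)
  ep <- energy_params(th$W, 0, th$kappa_kBT * kT)
  kp <- kinetic_params(th$eta_eff, th$alpha)
  sig <- seq(th$sigma_min, th$sigma_max, length.out = th$n_sigma)
  if (sub == "curve") {
    cur <- wrap_time_curve(sig, ep, kp, geom)
    utils::write.csv(cur, file.path(outdir, "wrap_time_curve.csv"),
                     row.names = FALSE)
    0L
  } else if (sub == "fit") {
    ds <- if (!is.null(opts[["in"]])) {
      utils::read.csv(opts[["in"]], comment.char = "#")
    } else {
      synth_wraptime_dataset(th$W, th$eta_eff, sig, th$cv, seed, geom,
                             th$kappa_kBT * kT, th$alpha)
    }
    fit <- fit_wrap_time(ds$sigma, ds$time, geom, th$kappa_kBT * kT,
                         th$alpha)
    jsonlite::write_json(
      list(W = fit$W, eta_eff = fit$eta_eff, ci_W = fit$ci_W,
           ci_eta = fit$ci_eta, n_used = fit$n_used),
      file.path(outdir, "wrap_fit.json"), auto_unbox = TRUE, digits = NA)
    0L
  } else if (sub == "barrier") {
    gb <- dumbbell_geometry(th$a, rho_n = 0.15 * th$a)
    epb <- energy_params(th$W, th$sigma_min, th$kappa_kBT * kT)
    h <- barrier_fluctuation_scale(epb, gb)
    jsonlite::write_json(list(h_star_m = h, h_star_nm = h * 1e9),
                         file.path(outdir, "barrier.json"),
                         auto_unbox = TRUE, digits = NA)
    0L
  } else stop("unknown theory subcommand '", sub, "'")
}

cli_synth <- function(pos, opts, cfg, seed, outdir) {
  sub <- if (length(pos) >= 2L) pos[2] else stop(
    "synth requires a subcommand: contours, pathway or wraptime")
  if (sub == "contours") {
    sp <- cfg$spectroscopy
    sigma <- opt_num(opts, "sigma", sp$sigma)
    kappa <- opt_num(opts, "kappa", sp$kappa_kBT) * thermal_energy()
    frames <- as.integer(opt_num(opts, "frames", sp$n_frames))
    series <- synth_contours(sigma, kappa, sp$R, frames, sp$n_angles,
                             sp$noise_floor, seed = seed)
    path <- file.path(outdir, "contours.csv")
    con <- file(path, "w"); on.exit(close(con))
    writeLines(artifact_header(seed), con)
    utils::write.table(series$radii, con, sep = ",", row.names = FALSE,
                       col.names = FALSE)
    0L
  } else if (sub == "pathway") {
    tpl <- if (is.null(opts$template)) "perpendicular_full" else opts$template
    pw <- synth_pathway(tpl, seed = seed)
    pw$state <- classify_series(pw)
    write_observables(pw, file.path(outdir, "pathway.csv"), seed)
    0L
  } else if (sub == "wraptime") {
    th <- cfg$theory
    sig <- seq(th$sigma_min, th$sigma_max, length.out = th$n_sigma)
    geom <- dumbbell_geometry(th$a, rho_n = th$rho_n_frac * th$a)
    ds <- synth_wraptime_dataset(th$W, th$eta_eff, sig, th$cv, seed, geom,
                                 th$kappa_kBT * thermal_energy(), th$alpha)
    path <- file.path(outdir, "wraptime.csv")
    con <- file(path, "w"); on.exit(close(con))
    writeLines(artifact_header(seed), con)
    utils::write.table(ds, con, sep = ",", row.names = FALSE,
                       col.names = TRUE, quote = FALSE)
    0L
  } else stop("unknown synth subcommand '", sub, "'")
}
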