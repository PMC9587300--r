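# End-to-end experiment protocols: the three frequency sweeps, the
# fixed-frequency scaling-factor sweep, the static-field sweep, and
# closed-loop letter trajectories. Each run_* function is a pure function of
# (configuration, seed) and returns a result bundle of raw trial tables plus
# aggregated profiles/fits.

#' Frequency-sweep protocol
#'
#' The three standard protocols pair a frequency range with a scaling
#' factor chosen so the coil drive stays within its power budget:
#' 1-19 Hz at 1 Hz steps with beta = 0.5; 5-50 Hz at 5 Hz steps with
#' beta = 0.175; 10-100 Hz at 10 Hz steps with beta = 0.1. Default particle
#' counts per coating follow the experimental cohorts (9/9/10/7, 5 each,
#' and 4/5/4/5 respectively), each with 3 independent trials.
#'
#' @param regime `"sweep_1_19"`, `"sweep_5_50"` or `"sweep_10_100"`.
#' @param n_trials trials per particle (>= 1). Default 3.
#' @param n_particles optional named vector of particles per coating,
#'   overriding the cohort defaults.
#' @param duration simulated time per trial, s.
#' @param dt integration step, s.
#' @param B_select static selection field applied during sweeps, mT. A small
#'   positive value pins the U+ state so the signed x-velocity is
#'   well-defined.
#' @param max_B_r rotating-amplitude cap, mT; protocols whose peak
#'   `beta * f` exceeds it are rejected.
#' @return object of class `sweep_protocol`.
#' @export
sweep_protocol <- function(regime, n_trials = 3, n_particles = NULL,
                           duration = 10, dt = 1 / 30, B_select = 0.5,
                           max_B_r = Inf) {
  regime <- match.arg(regime, c("sweep_1_19", "sweep_5_50", "sweep_10_100"))
  info <- attr(coating_presets(regime), "protocol")
  f <- seq(info$f_min, info$f_max, by = info$f_step)
  if (info$f_step <= 0) stop("`f_step` must be > 0")
  if (n_trials < 1) stop("`n_trials` must be >= 1")
  defaults <- switch(regime,
    sweep_1_19   = c(avidin = 9, biotin = 9, biotin_peg3_amine = 10,
                     biotin_chitosan = 7),
    sweep_5_50   = c(avidin = 5, biotin = 5, biotin_peg3_amine = 5,
                     biotin_chitosan = 5),
    sweep_10_100 = c(avidin = 4, biotin = 5, biotin_peg3_amine = 4,
                     biotin_chitosan = 5))
  n_particles <- n_particles %||% defaults
  if (max(f) * info$beta > max_B_r) {
    stop("protocol exceeds the rotating-amplitude cap: beta * f_max = ",
         format(max(f) * info$beta), " mT > ", format(max_B_r), " mT")
  }
  structure(
    list(regime = regime, f = f, beta = info$beta, n_trials = n_trials,
         n_particles = n_particles, duration = duration, dt = dt,
         B_select = B_select),
    class = "sweep_protocol"
  )
}

result_bundle <- function(kind, seed, params, ...) {
  structure(
    list(metadata = list(kind = kind, seed = seed, params = params,
                         timestamp = format(Sys.time(), tz = "UTC")),
         ...),
    class = "result_bundle"
  )
}

#' @export
print.result_bundle <- function(x, ...) {
  cat(sprintf("<result_bundle> %s (seed %s)\n", x$metadata$kind,
              format(x$metadata$seed)))
  for (nm in setdiff(names(x), "metadata")) {
    cat(" $", nm, "\n", sep = "")
  }
  invisible(x)
}

#' Run a frequency-sweep experiment
#'
#' For each coating, particle and trial, simulates propulsion along the
#' x-axis (heading theta = pi, U+ pinned by the selection field) at every
#' frequency of the protocol, records the time-averaged x-velocity,
#' aggregates trials into a per-coating velocity profile (mean +/- standard
#' error) and fits a zero-intercept line through it.
#'
#' When a `fluid` is supplied each particle is anchored at a random location
#' and experiences that location's mucus mobility for all its trials,
#' producing particle-to-particle speed variation.
#'
#' @param protocol a [sweep_protocol()].
#' @param coatings named list of [coating_params()]; defaults to the
#'   regime's presets.
#' @param fluid optional [make_mucus_field()].
#' @param seed integer seed; bundles are reproducible bit-for-bit from
#'   (config, seed).
#' @return `result_bundle` with `trials` (coating / particle / trial / f /
#'   vx table), `profiles` (named list of [aggregate_trials()] outputs) and
#'   `fits` (named list of [fit_through_origin()] outputs).
#' @export
run_frequency_sweep <- function(protocol, coatings = NULL, fluid = NULL,
                                seed = 1) {
  stopifnot(inherits(protocol, "sweep_protocol"))
  coatings <- coatings %||% coating_presets(protocol$regime)
  with_seed_opt(seed, {
    rows <- list()
    for (cn in names(coatings)) {
      co <- coatings[[cn]]
      n_p <- protocol$n_particles[[cn]] %||% 3
      for (pid in seq_len(n_p)) {
        m_local <- if (!is.null(fluid)) {
          sample_mobility(fluid,
                          stats::runif(1, 0, fluid$extent[1]),
                          stats::runif(1, 0, fluid$extent[2]))
        } else 1
        for (tr in seq_len(protocol$n_trials)) {
          for (f in protocol$f) {
            traj <- simulate_propulsion(
              co, f = f, beta = protocol$beta, B_s = protocol$B_select,
              theta = pi, m_local = m_local, duration = protocol$duration,
              dt = protocol$dt)
            rows[[length(rows) + 1]] <- data.frame(
              coating = cn, particle = pid, trial = tr, f = f,
              vx_um_s = mean_x_velocity(traj))
          }
        }
      }
    }
    trials <- do.call(rbind, rows)
    profiles <- fits <- list()
    for (cn in names(coatings)) {
      tc <- trials[trials$coating == cn, ]
      # f is the innermost simulation loop, so each consecutive block of
      # length(f) velocities is one (particle, trial) sweep in f-order
      mat <- matrix(tc$vx_um_s, ncol = length(protocol$f), byrow = TRUE)
      profiles[[cn]] <- aggregate_trials(protocol$f, mat)
      fits[[cn]] <- fit_through_origin(profiles[[cn]])
    }
    result_bundle("frequency_sweep", seed,
                  params = protocol[c("regime", "f", "beta", "n_trials",
                                      "n_particles", "duration", "dt",
                                      "B_select")],
                  trials = trials, profiles = profiles, fits = fits)
  })
}

#' Run a scaling-factor sweep at fixed frequency
#'
#' Holds the drive frequency fixed (14 Hz in the standard protocol) and
#' sweeps the scaling factor beta downward, reporting per-coating mean
#' velocity against 1/beta (the conventional axis for this experiment).
#'
#' @param beta_values positive scaling factors, mT/Hz (descending allowed;
#'   zero rejected). Default: 1/beta from 2 to 10 in steps of 0.5.
#' @param f fixed drive frequency, Hz. Default 14.
#' @param coatings named list of [coating_params()]; defaults to the
#'   `beta_sweep_14Hz` presets.
#' @param n_particles particles per coating. Default 4.
#' @param n_trials trials per particle. Default 3.
#' @param duration simulated time per trial, s.
#' @param dt integration step, s.
#' @param B_select static selection field, mT.
#' @param seed integer seed.
#' @return `result_bundle` with `trials` and `table` (coating / beta /
#'   inv_beta / mean_v / se / n).
#' @export
run_beta_sweep <- function(beta_values = 1 / seq(2, 10, by = 0.5), f = 14,
                           coatings = NULL, n_particles = 4, n_trials = 3,
                           duration = 10, dt = 1 / 30, B_select = 0.5,
                           seed = 1) {
  if (any(beta_values <= 0)) stop("`beta_values` must all be > 0")
  coatings <- coatings %||% coating_presets("beta_sweep_14Hz")
  with_seed_opt(seed, {
    rows <- list()
    for (cn in names(coatings)) {
      co <- coatings[[cn]]
      for (pid in seq_len(n_particles)) {
        for (tr in seq_len(n_trials)) {
          for (b in beta_values) {
            traj <- simulate_propulsion(co, f = f, beta = b, B_s = B_select,
                                        theta = pi, duration = duration,
                                        dt = dt)
            rows[[length(rows) + 1]] <- data.frame(
              coating = cn, particle = pid, trial = tr, beta = b,
              inv_beta = 1 / b, vx_um_s = mean_x_velocity(traj))
          }
        }
      }
    }
    trials <- do.call(rbind, rows)
    agg <- do.call(rbind, lapply(split(
      trials, list(trials$coating, trials$beta), drop = TRUE),
      function(g) data.frame(
        coating = g$coating[1], beta = g$beta[1], inv_beta = g$inv_beta[1],
        mean_v = mean(g$vx_um_s),
        se = if (nrow(g) > 1) stats::sd(g$vx_um_s) / sqrt(nrow(g)) else 0,
        n = nrow(g))))
    agg <- agg[order(agg$coating, agg$inv_beta), ]
    rownames(agg) <- NULL
    result_bundle("beta_sweep", seed,
                  params = list(f = f, beta_values = beta_values,
                                n_particles = n_particles,
                                n_trials = n_trials, duration = duration,
                                dt = dt, B_select = B_select),
                  trials = trials, table = agg)
  })
}

#' Run a static-field sweep
#'
#' Sweeps the static field over a grid (the standard protocol uses -2 to
#' 2 mT at 0.2 mT increments, rotating at 15 Hz with beta = 0.5) and
#' records the signed x-velocity at each set point: the propulsion sign is
#' selected by the static field (random at set points within the selection
#' threshold), the magnitude by the speed law.
#'
#' @param B_s_values static field grid, mT; see [static_sweep_values()].
#' @param f drive frequency, Hz. Default 15.
#' @param beta scaling factor, mT/Hz. Default 0.5.
#' @param coatings named list of [coating_params()]; defaults to the
#'   `static_sweep_15Hz` presets.
#' @param n_trials trials per set point. Default 3.
#' @param duration simulated time per trial, s.
#' @param dt integration step, s.
#' @param seed integer seed.
#' @return `result_bundle` with `trials` (per-trial signed velocities) and
#'   `table` (coating / B_s / mean_vx / se / n).
#' @export
run_static_sweep <- function(B_s_values = static_sweep_values(-2, 2, 0.2),
                             f = 15, beta = 0.5, coatings = NULL,
                             n_trials = 3, duration = 10, dt = 1 / 30,
                             seed = 1) {
  coatings <- coatings %||% coating_presets("static_sweep_15Hz")
  with_seed_opt(seed, {
    rows <- list()
    for (cn in names(coatings)) {
      co <- coatings[[cn]]
      for (tr in seq_len(n_trials)) {
        for (B in B_s_values) {
          traj <- simulate_propulsion(co, f = f, beta = beta, B_s = B,
                                      theta = pi, duration = duration,
                                      dt = dt)
          rows[[length(rows) + 1]] <- data.frame(
            coating = cn, trial = tr, B_s = B, sign = traj$sign[1],
            vx_um_s = mean_x_velocity(traj))
        }
      }
    }
    trials <- do.call(rbind, rows)
    agg <- do.call(rbind, lapply(split(
      trials, list(trials$coating, trials$B_s), drop = TRUE),
      function(g) data.frame(
        coating = g$coating[1], B_s = g$B_s[1],
        mean_vx = mean(g$vx_um_s),
        se = if (nrow(g) > 1) stats::sd(g$vx_um_s) / sqrt(nrow(g)) else 0,
        n = nrow(g))))
    agg <- agg[order(agg$coating, agg$B_s), ]
    rownames(agg) <- NULL
    result_bundle("static_sweep", seed,
                  params = list(f = f, beta = beta, B_s_values = B_s_values,
                                n_trials = n_trials, duration = duration,
                                dt = dt),
                  trials = trials, table = agg)
  })
}

#' Run a closed-loop letter trajectory
#'
#' Navigates a particle through one of the bundled letter waypoint plans
#' under proportional heading control at 15 Hz drive with beta = 0.5,
#' then post-processes the path exactly like the experimental videos:
#' instantaneous total velocity at the control rate, conditioned by the
#' 3x-mean outlier rule and a 60-point moving average, plus the per-step
#' error-to-target series.
#'
#' @param label a bundled plan label (see [waypoint_plan_labels()]) or a
#'   [waypoint_plan()].
#' @param coating a [coating_params()]; defaults to the biotin preset of the
#'   low-frequency regime.
#' @param f drive frequency, Hz. Default 15.
#' @param beta scaling factor, mT/Hz. Default 0.5.
#' @param controller a [controller_config()].
#' @param fluid optional [make_mucus_field()]; when supplied the plant speed
#'   tracks the local mucus mobility along the path.
#' @param start length-2 start position, um; defaults to 10 um left of the
#'   first waypoint.
#' @param B_select static selection field, mT.
#' @param sigma_xy positional noise sd per axis per step, um.
#' @param seed integer seed.
#' @return `result_bundle` with `nav` (the [navigate()] result), `velocity`
#'   (conditioned total-velocity series), `velocity_raw`, `error`
#'   (error-to-target series) and `status`. A timeout is reported in
#'   `status` (with a warning) rather than an error.
#' @export
run_trajectory <- function(label, coating = NULL, f = 15, beta = 0.5,
                           controller = controller_config(), fluid = NULL,
                           start = NULL, B_select = 0.5, sigma_xy = 0,
                           seed = 1) {
  plan <- if (inherits(label, "waypoint_plan")) label
          else make_waypoint_plan(label)
  coating <- coating %||% coating_presets("sweep_1_19")$biotin
  with_seed_opt(seed, {
    eps <- rnorm_trunc(1, coating$sigma_U)
    speed_fn <- function(x, y) {
      m <- if (!is.null(fluid)) sample_mobility(fluid, x, y) else 1
      propulsion_speed(coating, f, beta, B_s = B_select, m_local = m,
                       eps = eps)
    }
    start <- start %||% (plan$points[1, ] + c(-10, 0))
    nav <- navigate(plan, start = start, controller = controller,
                    speed_fn = speed_fn, sigma_xy = sigma_xy)
    if (nav$status == "timeout") {
      warning("trajectory '", plan$label, "' timed out after ",
              controller$timeout, " s")
    }
    track <- data.frame(x_um = nav$trace$x_um, y_um = nav$trace$y_um)
    vel_raw <- instantaneous_velocity(track, fps = 1 / controller$dt)
    vel <- clean_and_smooth(vel_raw, window = 60, outlier_factor = 3)
    result_bundle("trajectory", seed,
                  params = list(label = plan$label, f = f, beta = beta,
                                k = controller$k, dt = controller$dt,
                                capture_radius = controller$capture_radius,
                                B_select = B_select, sigma_xy = sigma_xy),
                  nav = nav, velocity = vel, velocity_raw = vel_raw,
                  error = error_series(nav), status = nav$status)
  })
}

#' Write a result bundle to a directory
#'
#' Writes the raw trial table and aggregated tables as CSV and the metadata
#' (plus any fits) as JSON. Results are written even for partially failed
#' runs, with the run status in the metadata.
#'
#' @param bundle a `result_bundle`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_result_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "result_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  meta <- bundle$metadata
  if (!is.null(bundle$status)) meta$status <- bundle$status
  jsonlite::write_json(meta, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  if (!is.null(bundle$trials)) {
    utils::write.csv(bundle$trials, file.path(dir, "trials.csv"),
                     row.names = FALSE)
  }
  if (!is.null(bundle$table)) {
    utils::write.csv(bundle$table, file.path(dir, "table.csv"),
                     row.names = FALSE)
  }
  if (!is.null(bundle$profiles)) {
    for (cn in names(bundle$profiles)) {
      utils::write.csv(as.data.frame(bundle$profiles[[cn]]),
                       file.path(dir, paste0("profile_", cn, ".csv")),
                       row.names = FALSE)
    }
  }
  if (!is.null(bundle$fits)) {
    jsonlite::write_json(
      lapply(bundle$fits, function(ft) ft[c("slope", "r2", "n")]),
      file.path(dir, "fits.json"), auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(bundle$nav)) {
    utils::write.csv(bundle$nav$trace, file.path(dir, "trace.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(bundle$velocity),
                     file.path(dir, "velocity.csv"), row.names = FALSE)
    utils::write.csv(bundle$error, file.path(dir, "error.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
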