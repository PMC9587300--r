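# Spontaneous-symmetry-breaking propulsion simulator. A rotating magnetic
# microparticle in a rod-climbing-like fluid translates along its rotation
# axis in one of two equal and opposite propulsion states (U+, U-). The
# state is selected at random when no static field is applied and
# deterministically by the sign of the static field otherwise. Above the
# step-out frequency the particle rotates asynchronously with the field and
# its mean rotation rate (hence speed) drops.

#' Particle state
#'
#' @param x,y planar position, um.
#' @param s propulsion sign, +1 (U+) or -1 (U-).
#' @param phi dipole phase, rad.
#' @return object of class `particle_state`.
#' @export
particle_state <- function(x = 0, y = 0, s = 1L, phi = 0) {
  stopifnot_num(x, "x"); stopifnot_num(y, "y"); stopifnot_num(phi, "phi")
  if (!(identical(as.numeric(s), 1) || identical(as.numeric(s), -1))) {
    stop("`s` must be exactly +1 or -1")
  }
  structure(list(x = x, y = y, s = as.integer(s), phi = phi),
            class = "particle_state")
}

#' Mean rotation rate of an overdamped driven rotor
#'
#' Below the step-out frequency `f_c` the particle phase-locks to the field
#' and rotates at the drive frequency `f`. Above it, the classical
#' overdamped driven-rotor average applies:
#' \deqn{\bar f = f - \sqrt{f^2 - f_c^2}, \qquad f > f_c,}
#' the long-time average of \eqn{\dot\phi = \omega_c \sin(\omega t - \phi)}.
#' The function is continuous at \eqn{f = f_c} and vectorised over both
#' arguments.
#'
#' @param f drive frequency, Hz (>= 0).
#' @param f_c step-out frequency, Hz (>= 0).
#' @return mean rotation rate, Hz.
#' @export
#' @examples
#' mean_rotation_rate(10, 20)  # synchronous: 10
#' mean_rotation_rate(5, 4)    # asynchronous: 5 - 3 = 2
mean_rotation_rate <- function(f, f_c) {
  stopifnot_num(f, "f", min = 0)
  stopifnot_num(f_c, "f_c", min = 0)
  ifelse(f <= f_c, f, f - sqrt(pmax(f^2 - f_c^2, 0)))
}

#' Propulsion-state selection
#'
#' Returns the propulsion sign: deterministic `sign(B_s)` when the static
#' field exceeds the selection threshold in magnitude, otherwise +1 or -1
#' with equal probability (spontaneous symmetry breaking). Uses the current
#' RNG stream; seed via `set.seed()` or `withr::with_seed()` for
#' reproducibility.
#'
#' @param B_s static field, mT (signed).
#' @param B_th selection threshold, mT (>= 0).
#' @return +1 or -1 (integer).
#' @export
propulsion_sign <- function(B_s, B_th) {
  stopifnot_num(B_s, "B_s")
  stopifnot_num(B_th, "B_th", min = 0)
  if (abs(B_s) > B_th) {
    as.integer(sign(B_s))
  } else {
    if (stats::runif(1) < 0.5) 1L else -1L
  }
}

#' Propulsion speed (unsigned)
#'
#' Phenomenological speed law: slope times attained rotation rate, shaped by
#' the static field, the local mucus mobility and multiplicative noise (see
#' [coating_params()] for the full formula). Direction is carried separately
#' by the propulsion sign.
#'
#' @param coating a [coating_params()].
#' @param f drive frequency, Hz.
#' @param beta scaling factor, mT/Hz.
#' @param B_s static field, mT.
#' @param m_local local mucus mobility multiplier (> 0).
#' @param eps optional fixed noise value; when `NULL` and `sigma_U > 0` a
#'   truncated Normal(0, sigma_U) draw (bounded below at -0.9) is taken from
#'   the current RNG stream.
#' @return speed, um/s (non-negative).
#' @export
#' @examples
#' av <- coating_params("avidin", c = 0.3, f_c0 = 150, p = 0.7)
#' propulsion_speed(av, f = 15, beta = 0.5)  # 0.3 * 15 = 4.5
propulsion_speed <- function(coating, f, beta, B_s = 0, m_local = 1,
                             eps = NULL) {
  stopifnot(inherits(coating, "coating_params"))
  stopifnot_num(f, "f", min = 0)
  stopifnot_num(beta, "beta", min = 0)
  stopifnot_num(B_s, "B_s")
  if (any(m_local <= 0)) stop("`m_local` must be > 0")
  if (is.null(eps)) eps <- rnorm_trunc(1, coating$sigma_U)
  f_c <- step_out_frequency(coating, beta)
  base <- coating$c * mean_rotation_rate(f, f_c)
  g <- 1 + coating$g_shape * B_s^2
  bump <- if (coating$bump_amp > 0 && beta > 0) {
    1 + coating$bump_amp *
      exp(-((1 / beta - coating$bump_center)^2) / (2 * coating$bump_width^2))
  } else 1
  pmax(base * g * bump * m_local * (1 + eps), 0)
}

#' Advance a particle by one time step
#'
#' Displacement is `s * speed * dt` along the heading vector
#' \eqn{(-\cos\theta, \sin\theta)}, plus optional Gaussian positional noise
#' of sd `sigma_xy` per axis. Sign and dipole phase carry forward.
#'
#' @param state a [particle_state()].
#' @param theta heading angle, rad.
#' @param speed unsigned speed, um/s.
#' @param dt time step, s (> 0).
#' @param sigma_xy positional noise sd per axis, um.
#' @return updated `particle_state`.
#' @export
step_particle <- function(state, theta, speed, dt, sigma_xy = 0) {
  stopifnot(inherits(state, "particle_state"))
  if (dt <= 0) stop("`dt` must be > 0")
  noise <- if (sigma_xy > 0) stats::rnorm(2, 0, sigma_xy) else c(0, 0)
  particle_state(
    x = state$x + state$s * speed * dt * (-cos(theta)) + noise[1],
    y = state$y + state$s * speed * dt * sin(theta) + noise[2],
    s = state$s, phi = state$phi
  )
}

#' Simulate straight-heading propulsion
#'
#' Runs the propulsion model at a fixed commanded heading for a fixed
#' duration with forward-Euler integration at the controller sample
#' interval. The propulsion sign is drawn once per run via
#' [propulsion_sign()]; the speed-noise factor is likewise drawn once per
#' run (trial-to-trial variability), while the mucus mobility is sampled at
#' the current position each step when a fluid field is supplied.
#'
#' @param coating a [coating_params()].
#' @param f drive frequency, Hz.
#' @param beta scaling factor, mT/Hz.
#' @param B_s static field, mT (selects the propulsion state when above the
#'   coating threshold).
#' @param theta commanded heading, rad (`pi` propels along +x for the U+
#'   state).
#' @param fluid optional [make_mucus_field()] heterogeneous mobility field.
#' @param m_local constant mobility multiplier used when `fluid` is `NULL`.
#' @param duration simulated time, s.
#' @param dt integration step, s (default 1/30, the control sample
#'   interval).
#' @param sigma_xy positional noise sd per axis per step, um.
#' @param seed optional integer seed (RNG state restored afterwards).
#' @param start length-2 start position, um.
#' @return data frame with columns `t_s`, `x_um`, `y_um`, `sign`,
#'   `speed_um_s` (`nrow = duration/dt + 1`).
#' @export
simulate_propulsion <- function(coating, f, beta, B_s = 0, theta = pi,
                                fluid = NULL, m_local = 1, duration = 10,
                                dt = 1 / 30, sigma_xy = 0, seed = NULL,
                                start = c(0, 0)) {
  stopifnot(inherits(coating, "coating_params"))
  if (duration <= 0 || dt <= 0) stop("`duration` and `dt` must be > 0")
  with_seed_opt(seed, {
    s <- propulsion_sign(B_s, coating$B_th)
    eps <- rnorm_trunc(1, coating$sigma_U)
    n <- max(1L, round(duration / dt))
    dir <- c(-cos(theta), sin(theta))
    if (is.null(fluid)) {
      speed <- propulsion_speed(coating, f, beta, B_s, m_local, eps = eps)
      speeds <- rep(speed, n)
      dx <- s * speeds * dt * dir[1]
      dy <- s * speeds * dt * dir[2]
      if (sigma_xy > 0) {
        dx <- dx + stats::rnorm(n, 0, sigma_xy)
        dy <- dy + stats::rnorm(n, 0, sigma_xy)
      }
      x <- start[1] + cumsum(c(0, dx))
      y <- start[2] + cumsum(c(0, dy))
    } else {
      x <- y <- numeric(n + 1)
      speeds <- numeric(n)
      x[1] <- start[1]; y[1] <- start[2]
      for (i in seq_len(n)) {
        m <- sample_mobility(fluid, x[i], y[i])
        sp <- propulsion_speed(coating, f, beta, B_s, m, eps = eps)
        speeds[i] <- sp
        nx <- x[i] + s * sp * dt * dir[1]
        ny <- y[i] + s * sp * dt * dir[2]
        if (sigma_xy > 0) {
          nx <- nx + stats::rnorm(1, 0, sigma_xy)
          ny <- ny + stats::rnorm(1, 0, sigma_xy)
        }
        x[i + 1] <- nx; y[i + 1] <- ny
      }
    }
    data.frame(
      t_s = (0:n) * dt, x_um = x, y_um = y, sign = s,
      speed_um_s = c(speeds[1], speeds)
    )
  })
}

#' Mean x-velocity of a trajectory
#'
#' Time-averaged x-component of velocity (net x displacement over elapsed
#' time), the quantity reported by the frequency-sweep protocols.
#'
#' @param traj data frame with columns `t_s` and `x_um` (e.g. from
#'   [simulate_propulsion()]).
#' @return mean x-velocity, um/s (signed).
#' @export
mean_x_velocity <- function(traj) {
  n <- nrow(traj)
  if (n < 2) stop("trajectory needs at least two samples")
  (traj$x_um[n] - traj$x_um[1]) / (traj$t_s[n] - traj$t_s[1])
}

#' Write a trajectory to CSV
#'
#' @param traj data frame from [simulate_propulsion()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(traj, path, row.names = FALSE)
  invisible(path)
}
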