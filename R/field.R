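# Magnetic field model: a constant-magnitude rotating field in the plane
# normal to the heading vector, superimposed with a static field along the
# heading vector. Units are mT, Hz, radians and seconds throughout.

#' Field configuration
#'
#' Bundles the static amplitude \eqn{B_s}, scaling factor \eqn{\beta}, drive
#' frequency \eqn{f} and in-plane heading angle \eqn{\theta}, and derives the
#' rotating amplitude \eqn{B_r = \beta f} and angular rate
#' \eqn{\omega = 2\pi f}. The rotating amplitude grows linearly with
#' frequency because the coil waveform couples amplitude to frequency; this
#' is what keeps the drive torque ahead of viscous step-out.
#'
#' @param B_s static field amplitude along the heading vector, mT (signed).
#' @param beta scaling factor, mT per Hz (non-negative).
#' @param f rotation frequency, Hz (non-negative).
#' @param theta heading angle in the x-y plane, radians; stored wrapped to
#'   (-pi, pi].
#' @param max_B_r optional cap on the rotating amplitude, mT. Protocols whose
#'   derived \eqn{B_r} exceeds the cap are rejected, mimicking the power
#'   budget of a physical coil driver.
#' @return an object of class `field_config` with elements `B_s`, `beta`,
#'   `f`, `theta`, `B_r`, `omega`.
#' @export
#' @examples
#' cfg <- field_config(B_s = 1, beta = 0.5, f = 15, theta = 0)
#' cfg$B_r  # 7.5 mT
field_config <- function(B_s = 0, beta = 0, f = 0, theta = 0, max_B_r = Inf) {
  stopifnot_num(B_s, "B_s")
  stopifnot_num(beta, "beta", min = 0)
  stopifnot_num(f, "f", min = 0)
  stopifnot_num(theta, "theta")
  B_r <- rotational_amplitude(beta, f)
  if (B_r > max_B_r) {
    stop("derived rotating amplitude B_r = ", format(B_r),
         " mT exceeds the configured cap of ", format(max_B_r), " mT")
  }
  structure(
    list(B_s = B_s, beta = beta, f = f, theta = wrap_angle(theta),
         B_r = B_r, omega = 2 * pi * f),
    class = "field_config"
  )
}

#' @export
print.field_config <- function(x, ...) {
  cat(sprintf(
    "<field_config> B_s = %g mT, beta = %g mT/Hz, f = %g Hz (B_r = %g mT), theta = %g rad\n",
    x$B_s, x$beta, x$f, x$B_r, x$theta))
  invisible(x)
}

#' Rotating field amplitude
#'
#' \eqn{B_r = \beta f}: the rotating-field amplitude is proportional to the
#' drive frequency through the scaling factor.
#'
#' @param beta scaling factor, mT/Hz (non-negative).
#' @param f frequency, Hz (non-negative).
#' @return amplitude in mT.
#' @export
#' @examples
#' rotational_amplitude(0.5, 15)  # 7.5
rotational_amplitude <- function(beta, f) {
  stopifnot_num(beta, "beta", min = 0)
  stopifnot_num(f, "f", min = 0)
  beta * f
}

#' Field vector at given times
#'
#' Evaluates the triaxial coil waveform: a circle of radius \eqn{B_r} traced
#' at angular rate \eqn{\omega} in the plane normal to the heading vector,
#' plus a constant component \eqn{B_s} along the heading vector
#' \eqn{n = (-\cos\theta, \sin\theta, 0)}:
#' \deqn{B(t) = (-B_s\cos\theta + B_r\sin\theta\cos\omega t,\;
#'              B_s\sin\theta + B_r\cos\theta\cos\omega t,\;
#'              B_r\sin\omega t).}
#' The total magnitude is constant: \eqn{\|B\|^2 = B_s^2 + B_r^2}.
#'
#' @param config a [field_config()].
#' @param t numeric vector of times, s.
#' @return data frame with columns `t_s`, `Bx_mT`, `By_mT`, `Bz_mT`.
#' @export
#' @examples
#' field_at(field_config(B_s = 1, beta = 0.5, f = 15), t = 0)
field_at <- function(config, t) {
  stopifnot(inherits(config, "field_config"))
  stopifnot_num(t, "t")
  th <- config$theta
  cwt <- cos(config$omega * t)
  data.frame(
    t_s = t,
    Bx_mT = -config$B_s * cos(th) + config$B_r * sin(th) * cwt,
    By_mT = config$B_s * sin(th) + config$B_r * cos(th) * cwt,
    Bz_mT = config$B_r * sin(config$omega * t)
  )
}

#' Heading vector
#'
#' Unit vector giving the propulsion direction for a heading angle
#' \eqn{\theta}: \eqn{n = (-\cos\theta, \sin\theta, 0)}. Note the
#' convention: theta = 0 points along -x; theta = pi points along +x.
#'
#' @param theta heading angle, radians.
#' @return named numeric vector `c(nx, ny, nz)`, unit length, nz = 0.
#' @export
#' @examples
#' heading_vector(0)    # (-1, 0, 0)
#' heading_vector(pi)   # (+1, 0, 0)
heading_vector <- function(theta) {
  stopifnot_num(theta, "theta")
  c(nx = -cos(theta), ny = sin(theta), nz = 0)
}

#' Static field sweep values
#'
#' Inclusive arithmetic sequence of static-field set points, as used in the
#' propulsion-state switching protocol (-2 to 2 mT at 0.2 mT increments).
#' The endpoint is included when `(stop - start) / step` is integral within
#' 1e-9.
#'
#' @param start,stop sweep limits, mT (`stop >= start`).
#' @param step increment, mT (> 0).
#' @return numeric vector of field values.
#' @export
#' @examples
#' length(static_sweep_values(-2, 2, 0.2))  # 21
static_sweep_values <- function(start, stop, step) {
  stopifnot_num(start, "start")
  stopifnot_num(stop, "stop")
  if (!is.numeric(step) || step <= 0) stop("`step` must be > 0")
  if (stop < start) stop("`stop` must be >= `start`")
  n <- (stop - start) / step
  start + step * (0:floor(n + 1e-9))
}

#' Sample a field waveform on a regular time grid
#'
#' @param config a [field_config()].
#' @param duration total duration, s.
#' @param sample_rate samples per second, Hz.
#' @return data frame with columns `t_s`, `Bx_mT`, `By_mT`, `Bz_mT`.
#' @export
field_waveform <- function(config, duration, sample_rate) {
  if (duration <= 0 || sample_rate <= 0) {
    stop("`duration` and `sample_rate` must be > 0")
  }
  field_at(config, seq(0, duration, by = 1 / sample_rate))
}

#' Write a waveform to CSV
#'
#' Deterministic row order (time-ascending), columns `t_s, Bx_mT, By_mT,
#' Bz_mT`.
#'
#' @param waveform data frame from [field_waveform()] or [field_at()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(waveform, path) {
  utils::write.csv(waveform, path, row.names = FALSE)
  invisible(path)
}
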