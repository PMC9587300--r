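# Proportional heading controller and waypoint navigation. The commanded
# heading angle theta is steered toward the bearing of the active target by
# theta_dot = k * alpha_d with alpha_d = wrap(psi - theta), discretised by
# forward Euler at the control sample interval. Targets switch automatically
# when the particle comes within a capture radius.

#' Controller configuration
#'
#' Proportional gain `k`, control interval `dt`, waypoint capture radius and
#' run timeout. The linearised closed loop contracts the heading error by a
#' factor `(1 - k*dt)` per step; `k*dt >= 2` is divergent, and a warning is
#' issued above 1.
#'
#' @param k proportional gain, 1/s (> 0). Default 5.
#' @param dt control interval, s (> 0). Default 1/30.
#' @param capture_radius waypoint capture distance, um.
#' @param timeout maximum run time, s.
#' @return object of class `controller_config`.
#' @export
controller_config <- function(k = 5, dt = 1 / 30, capture_radius = 3,
                              timeout = 180) {
  if (k <= 0) stop("`k` must be > 0")
  if (dt <= 0) stop("`dt` must be > 0")
  if (capture_radius <= 0) stop("`capture_radius` must be > 0")
  if (timeout <= 0) stop("`timeout` must be > 0")
  if (k * dt > 1) {
    warning("k * dt = ", format(k * dt),
            " > 1: heading error will overshoot (divergent at k * dt >= 2)")
  }
  structure(list(k = k, dt = dt, capture_radius = capture_radius,
                 timeout = timeout),
            class = "controller_config")
}

#' Waypoint plan
#'
#' An ordered list of target points in the plane. Consecutive targets must
#' be distinct.
#'
#' @param points numeric matrix (n x 2) or data frame of target coordinates,
#'   um.
#' @param label plan label (e.g. a letter shape).
#' @return object of class `waypoint_plan` with elements `points` (matrix)
#'   and `label`.
#' @export
waypoint_plan <- function(points, label = "") {
  points <- as.matrix(points)
  if (nrow(points) < 1 || ncol(points) != 2) {
    stop("`points` must be a non-empty n x 2 matrix")
  }
  storage.mode(points) <- "double"
  if (any(!is.finite(points))) stop("waypoints must be finite")
  if (nrow(points) > 1) {
    d <- sqrt(rowSums((points[-1, , drop = FALSE] -
                         points[-nrow(points), , drop = FALSE])^2))
    if (any(d == 0)) stop("consecutive waypoints must be distinct")
  }
  colnames(points) <- c("x_um", "y_um")
  structure(list(points = points, label = label), class = "waypoint_plan")
}

#' Desired heading toward a target
#'
#' Returns the heading angle `psi` whose heading vector
#' \eqn{(-\cos\psi, \sin\psi)} points from `pos` toward `target`:
#' `psi = atan2(dy, -dx)` for the displacement `target - pos`.
#'
#' @param pos,target length-2 positions, um.
#' @return heading angle, rad, in (-pi, pi].
#' @export
#' @examples
#' desired_heading(c(0, 0), c(-1, 0))  # 0 (the -x direction)
#' desired_heading(c(0, 0), c(1, 1))   # 3*pi/4
desired_heading <- function(pos, target) {
  d <- c(target[1] - pos[1], target[2] - pos[2])
  if (sqrt(sum(d^2)) < 1e-12) {
    stop("degenerate direction: position and target coincide")
  }
  wrap_angle(atan2(d[2], -d[1]))
}

#' One proportional control update
#'
#' Forward-Euler discretisation of `theta_dot = k * alpha_d` with the
#' shortest-arc heading error `alpha_d = wrap(psi - theta)`:
#' `theta <- wrap(theta + k * alpha_d * dt)`.
#'
#' @param theta current heading, rad.
#' @param psi desired heading, rad.
#' @param k proportional gain, 1/s.
#' @param dt control interval, s.
#' @return updated heading, rad, in (-pi, pi].
#' @export
control_step <- function(theta, psi, k, dt) {
  wrap_angle(theta + k * wrap_angle(psi - theta) * dt)
}

#' Closed-loop waypoint navigation
#'
#' Runs the proportional heading controller against a kinematic plant at
#' rate `1/dt`: each step the bearing to the active target is recomputed,
#' the commanded heading updated by [control_step()], and the particle
#' advanced along the heading vector at the plant speed. The next target is
#' activated when the distance to the current one falls below the capture
#' radius; the run ends when the last target is captured or the timeout
#' elapses. The plant follows the commanded field heading (the particle is
#' assumed phase-locked and pinned in the U+ state); when the particle sits
#' exactly on the target mid-step the previous desired heading is held.
#'
#' @param plan a [waypoint_plan()].
#' @param start length-2 start position, um.
#' @param controller a [controller_config()].
#' @param speed_fn plant speed model: `function(x, y)` returning um/s.
#'   Use [constant_speed()] for the ideal plant.
#' @param theta0 initial heading, rad; defaults to the bearing of the first
#'   target.
#' @param sigma_xy positional noise sd per axis per step, um.
#' @param seed optional integer seed.
#' @return object of class `nav_result`: list with `trace` (data frame with
#'   columns `t_s`, `x_um`, `y_um`, `theta_rad`, `psi_rad`, `alpha_rad`,
#'   `error_um`, `target_idx`), `status` (`"completed"` or `"timeout"`),
#'   `plan`, `controller`.
#' @export
navigate <- function(plan, start, controller = controller_config(),
                     speed_fn = constant_speed(5), theta0 = NULL,
                     sigma_xy = 0, seed = NULL) {
  stopifnot(inherits(plan, "waypoint_plan"),
            inherits(controller, "controller_config"))
  with_seed_opt(seed, {
    k <- controller$k; dt <- controller$dt
    max_steps <- ceiling(controller$timeout / dt)
    n_t <- nrow(plan$points)
    pos <- c(start[1], start[2])
    tgt_i <- 1L
    theta <- theta0 %||% desired_heading(pos, plan$points[1, ])
    psi <- theta
    tr_t <- tr_x <- tr_y <- tr_th <- tr_psi <- tr_al <- tr_er <-
      numeric(max_steps)
    tr_ti <- integer(max_steps)
    status <- "timeout"
    used <- 0L
    for (i in seq_len(max_steps)) {
      err <- sqrt(sum((plan$points[tgt_i, ] - pos)^2))
      # capture / target switch before recording, so the error column always
      # refers to the active target and shows the jump at the switch step
      while (err < controller$capture_radius) {
        if (tgt_i == n_t) break
        tgt_i <- tgt_i + 1L
        err <- sqrt(sum((plan$points[tgt_i, ] - pos)^2))
      }
      if (err < controller$capture_radius && tgt_i == n_t) {
        status <- "completed"
        used <- i - 1L
        break
      }
      if (err > 1e-9) psi <- desired_heading(pos, plan$points[tgt_i, ])
      alpha <- wrap_angle(psi - theta)
      tr_t[i] <- (i - 1) * dt; tr_x[i] <- pos[1]; tr_y[i] <- pos[2]
      tr_th[i] <- theta; tr_psi[i] <- psi; tr_al[i] <- alpha
      tr_er[i] <- err; tr_ti[i] <- tgt_i
      theta <- control_step(theta, psi, k, dt)
      sp <- speed_fn(pos[1], pos[2])
      h <- heading_vector(theta)
      pos <- pos + sp * dt * h[1:2]
      if (sigma_xy > 0) pos <- pos + stats::rnorm(2, 0, sigma_xy)
      used <- i
    }
    idx <- seq_len(used)
    structure(
      list(
        trace = data.frame(
          t_s = tr_t[idx], x_um = tr_x[idx], y_um = tr_y[idx],
          theta_rad = tr_th[idx], psi_rad = tr_psi[idx],
          alpha_rad = tr_al[idx], error_um = tr_er[idx],
          target_idx = tr_ti[idx]),
        status = status, plan = plan, controller = controller),
      class = "nav_result"
    )
  })
}

#' Constant-speed plant
#'
#' The ideal kinematic plant: constant speed everywhere.
#'
#' @param v speed, um/s.
#' @return `function(x, y)` returning `v`.
#' @export
constant_speed <- function(v) {
  force(v)
  function(x, y) v
}

#' Error series of a navigation run
#'
#' Per-step Euclidean distance to the active target, preserving the
#' discontinuities at target switches.
#'
#' @param nav a `nav_result` from [navigate()], or its `trace` data frame.
#' @return data frame with columns `t_s`, `error_um`, `target_idx`.
#' @export
error_series <- function(nav) {
  trace <- if (inherits(nav, "nav_result")) nav$trace else nav
  if (is.null(trace) || nrow(trace) == 0) stop("empty trace")
  trace[, c("t_s", "error_um", "target_idx")]
}

#' Write a control trace to CSV
#'
#' @param nav a `nav_result` from [navigate()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(nav, path) {
  stopifnot(inherits(nav, "nav_result"))
  utils::write.csv(
    nav$trace[, c("t_s", "theta_rad", "psi_rad", "alpha_rad", "error_um",
                  "target_idx")],
    path, row.names = FALSE)
  invisible(path)
}
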