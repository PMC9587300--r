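# Tracking and velocity-analysis chain, exercised against rendered
# synthetic frames with known ground truth.

static_stack <- function(x_um, y_um, n = 3, noise_sd = 0, seed = 1) {
  traj <- data.frame(t_s = (seq_len(n) - 1) / 30, x_um = x_um, y_um = y_um)
  render_frames(traj, render_spec(noise_sd = noise_sd, seed = seed))
}

test_that("centroid of a noiseless rendered disk is recovered within 0.1 px", {
  st <- static_stack(25.0, 20.0)  # 50.0, 40.0 px at 0.5 um/px
  det <- detect_centroid(st$frames[[1]])
  expect_lt(abs(det$centroid_px[1] - 50.0), 0.1)
  expect_lt(abs(det$centroid_px[2] - 40.0), 0.1)
  # bbox is tight around a 10 px radius disk
  expect_true(det$bbox[1] <= 41 && det$bbox[3] >= 60)
  # sub-pixel offsets are resolved by the anti-aliased rim
  st2 <- static_stack(25.17, 20.31)
  det2 <- detect_centroid(st2$frames[[1]])
  expect_lt(abs(det2$centroid_px[1] - 50.34), 0.1)
  expect_lt(abs(det2$centroid_px[2] - 40.62), 0.1)
})

test_that("blank frames raise a detection error", {
  blank <- matrix(0.8, 64, 64)
  expect_error(detect_centroid(blank), "no particle")
})

test_that("a prior bounding box selects the matching particle among two", {
  spec <- render_spec(width = 200, height = 100, noise_sd = 0)
  left <- render_frames(
    data.frame(t_s = c(0, 1 / 30), x_um = 25, y_um = 25), spec)
  right <- render_frames(
    data.frame(t_s = c(0, 1 / 30), x_um = 75, y_um = 25), spec)
  two <- pmin(left$frames[[1]], right$frames[[1]])
  det_l <- detect_centroid(two, prior_bbox = c(40, 40, 60, 60))
  expect_lt(abs(det_l$centroid_px[1] - 50), 0.1)
  det_r <- detect_centroid(two, prior_bbox = c(140, 40, 160, 60))
  expect_lt(abs(det_r$centroid_px[1] - 150), 0.1)
})

test_that("instantaneous velocity matches uniform drift and circular motion", {
  # stationary track
  tk <- data.frame(x_um = rep(5, 10), y_um = rep(7, 10))
  v0 <- instantaneous_velocity(tk, fps = 30)
  expect_true(all(v0$speed_um_s == 0))
  expect_equal(nrow(v0), 9)
  # uniform x drift: 0.5 um/frame at 30 fps -> 15 um/s
  tk1 <- data.frame(x_um = 0.5 * (0:20), y_um = 0)
  v1 <- instantaneous_velocity(tk1, fps = 30)
  expect_true(all(abs(v1$vx_um_s - 15) < 1e-9))
  expect_true(all(abs(v1$vy_um_s) < 1e-12))
  # circular track of radius R at rate Omega: mean speed -> R * Omega
  R <- 20; Om <- 0.5; fps <- 100
  tt <- seq(0, 4 * pi / Om, by = 1 / fps)
  tk2 <- data.frame(x_um = R * cos(Om * tt), y_um = R * sin(Om * tt))
  v2 <- instantaneous_velocity(tk2, fps = fps)
  expect_equal(mean(v2$speed_um_s), R * Om, tolerance = 0.01)
})

test_that("outlier rule replaces spikes with the pre-replacement mean", {
  mk_series <- function(speed) {
    s <- data.frame(t_s = seq_along(speed) / 30, vx_um_s = speed,
                    vy_um_s = 0, speed_um_s = speed)
    class(s) <- c("velocity_series", "data.frame")
    s
  }
  # 99 ones and one 1000: mean = 10.99; the spike alone exceeds 3 x mean
  sp <- c(rep(1, 99), 1000)
  cl <- clean_and_smooth(mk_series(sp), window = 1)
  expect_equal(cl$speed_um_s[100], 10.99)
  expect_true(all(cl$speed_um_s[1:99] == 1))
  expect_identical(attr(cl, "n_outliers"), 1L)
  # constant series is a fixed point of both stages
  cst <- clean_and_smooth(mk_series(rep(4, 50)), window = 60)
  expect_true(all(cst$speed_um_s == 4))
  # window larger than the series: every output is the global mean
  big <- clean_and_smooth(mk_series(c(1, 2, 3)), window = 1000)
  expect_true(all(abs(big$speed_um_s - 2) < 1e-12))
  # outlier replacement is idempotent when no new outliers arise
  mild <- c(rep(1, 9), 10)  # replaced value (1.9) is below the new 3x-mean
  once <- clean_and_smooth(mk_series(mild), window = 1)
  twice <- clean_and_smooth(once, window = 1)
  expect_equal(twice$speed_um_s, once$speed_um_s)
  expect_error(clean_and_smooth(mk_series(sp), window = 0), ">= 1")
})

test_that("moving average uses truncated centered windows at the edges", {
  s <- data.frame(t_s = (1:5) / 30, vx_um_s = 0, vy_um_s = 0,
                  speed_um_s = c(9, 3, 3, 3, 3))
  class(s) <- c("velocity_series", "data.frame")
  sm <- clean_and_smooth(s, window = 3)
  expect_equal(sm$speed_um_s, c(6, 5, 3, 3, 3))
})

test_that("zero-intercept fit recovers exact lines and known closed forms", {
  perfect <- fit_through_origin(data.frame(f = 1:10, mean_v = 2 * (1:10)))
  expect_equal(perfect$slope, 2)
  expect_equal(perfect$r2, 1)
  # constant response: slope = 5 * 6 / 14 = 15/7; r2 undefined (SS_tot = 0)
  const <- fit_through_origin(data.frame(f = 1:3, mean_v = rep(5, 3)))
  expect_equal(const$slope, 15 / 7)
  expect_true(is.na(const$r2))
  # a single outlier strictly lowers r2 below 1
  dirty <- fit_through_origin(
    data.frame(f = 1:10, mean_v = 2 * (1:10) + c(rep(0, 9), 5)))
  expect_lt(dirty$r2, 1)
  expect_error(fit_through_origin(data.frame(f = c(0, 0), mean_v = c(1, 2))),
               "zero")
  expect_error(fit_through_origin(data.frame(f = 1, mean_v = 1)), "at least")
})

test_that("trial aggregation reports mean, standard error and counts", {
  pr <- aggregate_trials(5, list(1, 2, 3))
  expect_equal(pr$mean_v, 2)
  expect_equal(pr$se, 1 / sqrt(3), tolerance = 1e-12)
  expect_equal(pr$n, 3)
  # identical trials -> zero SE
  pr2 <- aggregate_trials(c(1, 2), list(c(1, 4), c(1, 4)))
  expect_true(all(pr2$se == 0))
  # single trial flagged with SE 0
  pr3 <- aggregate_trials(c(1, 2), list(c(1, 4)))
  expect_true(all(pr3$se == 0))
  expect_true(attr(pr3, "single_trial"))
  expect_error(aggregate_trials(c(2, 1), list(c(1, 2), c(3, 4))),
               "increasing")
  expect_error(aggregate_trials(numeric(0), list()), "no trials")
})

test_that("tracking pipeline round-trips a rendered constant-velocity stack", {
  v_true <- 6  # um/s along x
  tt <- (0:59) / 30
  traj <- data.frame(t_s = tt, x_um = 30 + v_true * tt, y_um = 60)
  st <- render_frames(traj, render_spec(noise_sd = 0, seed = 2))
  tk <- track_frames(st)
  vel <- instantaneous_velocity(tk)
  v_est <- sqrt(mean(vel$vx_um_s)^2 + mean(vel$vy_um_s)^2)
  expect_equal(v_est, v_true, tolerance = 0.02)
  # pipeline is deterministic for fixed inputs
  tk2 <- track_frames(st)
  expect_identical(tk$x_px, tk2$x_px)
})

test_that("origin fit on a noise-free simulated sweep recovers the preset slope", {
  co <- coating_params("avidin", c = 0.3, f_c0 = 150, p = 0.7, sigma_U = 0)
  f <- 1:19
  v <- vapply(f, function(fi) {
    mean_x_velocity(simulate_propulsion(co, f = fi, beta = 0.5, B_s = 0.5,
                                        theta = pi, m_local = 1.3,
                                        duration = 5, seed = 1))
  }, numeric(1))
  fit <- fit_through_origin(data.frame(f = f, mean_v = v))
  expect_equal(fit$slope, 0.3 * 1.3, tolerance = 1e-9)
})
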