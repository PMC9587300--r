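# End-to-end experiment protocols.

small_sweep <- function(regime, n_particles = 2, n_trials = 2,
                        duration = 2) {
  counts <- c(avidin = n_particles, biotin = n_particles,
              biotin_peg3_amine = n_particles, biotin_chitosan = n_particles)
  sweep_protocol(regime, n_trials = n_trials, n_particles = counts,
                 duration = duration)
}

test_that("the three printed sweep protocols validate as presets", {
  p1 <- sweep_protocol("sweep_1_19")
  expect_equal(p1$f, 1:19)
  expect_equal(p1$beta, 0.5)
  expect_equal(unname(p1$n_particles),
               c(9, 9, 10, 7))
  p2 <- sweep_protocol("sweep_5_50")
  expect_equal(p2$f, seq(5, 50, by = 5))
  expect_equal(p2$beta, 0.175)
  p3 <- sweep_protocol("sweep_10_100")
  expect_equal(p3$f, seq(10, 100, by = 10))
  expect_equal(p3$beta, 0.1)
  # protocols exceeding the rotating-amplitude cap are rejected
  expect_error(sweep_protocol("sweep_1_19", max_B_r = 5), "cap")
})

test_that("noise-free frequency sweep recovers the preset slope exactly", {
  co <- list(avidin = coating_params("avidin", c = 0.3, f_c0 = 150,
                                     p = 0.7, sigma_U = 0))
  prot <- sweep_protocol("sweep_1_19", n_trials = 1,
                         n_particles = c(avidin = 1), duration = 2)
  rb <- run_frequency_sweep(prot, coatings = co, seed = 1)
  expect_equal(rb$fits$avidin$slope, 0.3, tolerance = 1e-9)
  expect_equal(rb$fits$avidin$r2, 1, tolerance = 1e-9)
})

test_that("frequency-sweep bundles are reproducible bit-for-bit from the seed", {
  prot <- small_sweep("sweep_1_19", duration = 1)
  a <- run_frequency_sweep(prot, seed = 42)
  b <- run_frequency_sweep(prot, seed = 42)
  expect_identical(a$trials, b$trials)
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$fits, b$fits)
  c <- run_frequency_sweep(prot, seed = 43)
  expect_false(identical(a$trials, c$trials))
})

test_that("step-out makes the 10-50 Hz sub-fit cleaner than the full 10-100 Hz fit", {
  prot <- small_sweep("sweep_10_100", duration = 2)
  rb <- run_frequency_sweep(prot, seed = 3)
  for (cn in names(rb$profiles)) {
    prof <- rb$profiles[[cn]]
    full <- fit_through_origin(prof)
    sub <- fit_through_origin(prof[prof$f <= 50, ])
    expect_lt(full$r2, sub$r2)
  }
})

test_that("beta sweep reports velocity against 1/beta and rejects zero beta", {
  expect_error(run_beta_sweep(beta_values = c(0.5, 0)), "> 0")
  rb <- run_beta_sweep(beta_values = 1 / c(2, 4, 6), n_particles = 1,
                       n_trials = 2, duration = 1, seed = 5)
  tb <- rb$table
  expect_setequal(unique(tb$inv_beta), c(2, 4, 6))
  expect_true(all(tb$n == 2))
  # single beta value gives a single row per coating
  rb1 <- run_beta_sweep(beta_values = 0.5, n_particles = 1, n_trials = 1,
                        duration = 1, seed = 5)
  expect_equal(nrow(rb1$table), 4)
})

test_that("a coating without beta-coupled step-out is flat across the sweep", {
  co <- list(flat = coating_params("flat", c = 0.3, f_c0 = 100, p = 0,
                                   sigma_U = 0))
  rb <- run_beta_sweep(beta_values = 1 / seq(2, 10, 2), coatings = co,
                       n_particles = 1, n_trials = 1, duration = 1,
                       seed = 1)
  expect_true(all(abs(rb$table$mean_v - 0.3 * 14) < 1e-9))
})

test_that("chitosan presets give a rise-then-fall velocity curve in 1/beta", {
  rb <- run_beta_sweep(n_particles = 4, n_trials = 3, duration = 2,
                       seed = 8)
  ch <- rb$table[rb$table$coating == "biotin_chitosan", ]
  ch <- ch[order(ch$inv_beta), ]
  imax <- which.max(ch$mean_v)
  # the peak sits strictly inside the sweep: slow at low 1/beta, fast at
  # moderate values, collapsing again at high 1/beta
  expect_gt(imax, 1)
  expect_lt(imax, nrow(ch))
  expect_gt(ch$mean_v[imax], 1.2 * ch$mean_v[1])
  expect_lt(ch$mean_v[nrow(ch)], 0.5 * ch$mean_v[imax])
})

test_that("static sweep signs are deterministic above threshold and odd overall", {
  rb <- run_static_sweep(n_trials = 2, duration = 2, seed = 2)
  tr <- rb$trials
  above <- tr[abs(tr$B_s) > 0.1, ]
  expect_true(all(sign(above$vx_um_s) == sign(above$B_s)))
  # odd symmetry of the aggregated curve (avidin: symmetric preset)
  tb <- rb$table[rb$table$coating == "avidin", ]
  v_pos <- tb$mean_vx[match(round(seq(0.2, 2, 0.2), 10), round(tb$B_s, 10))]
  v_neg <- tb$mean_vx[match(round(seq(-0.2, -2, -0.2), 10), round(tb$B_s, 10))]
  expect_lt(max(abs(v_neg + v_pos)) / mean(abs(v_pos)), 0.35)
})

test_that("both propulsion states appear at zero static field across seeds", {
  co <- coating_presets("static_sweep_15Hz")$avidin
  signs <- vapply(1:200, function(s) {
    simulate_propulsion(co, f = 15, beta = 0.5, B_s = 0, duration = 0.1,
                        seed = s)$sign[1]
  }, integer(1))
  expect_true(any(signs == 1L) && any(signs == -1L))
})

test_that("letter trajectories complete and report conditioned velocities", {
  rb <- run_trajectory("A", controller = controller_config(timeout = 120),
                       seed = 4)
  expect_equal(rb$status, "completed")
  expect_true(attr(rb$velocity, "smoothed"))
  expect_true(attr(rb$velocity, "cleaned"))
  expect_equal(nrow(rb$velocity), nrow(rb$nav$trace) - 1)
  expect_equal(names(rb$error), c("t_s", "error_um", "target_idx"))
})

test_that("the same particle repeats its velocity across different plans", {
  co <- coating_params("biotin", c = 0.2, f_c0 = 150, p = 0.7, sigma_U = 0)
  v <- vapply(c("A", "S"), function(lab) {
    rb <- run_trajectory(lab, coating = co,
                         controller = controller_config(timeout = 120),
                         seed = 6)
    mean(rb$velocity_raw$speed_um_s)
  }, numeric(1))
  expect_lt(abs(v[1] - v[2]) / v[1], 0.05)
})

test_that("heterogeneous mucus separates particle velocities by region", {
  fl <- make_mucus_field(extent = c(300, 300), step = 4,
                         correlation_length = 25, cv = 0.4, seed = 21)
  # anchor two particles in a slow and a fast region
  idx_hi <- which(fl$m == max(fl$m), arr.ind = TRUE)[1, ]
  idx_lo <- which(fl$m == min(fl$m), arr.ind = TRUE)[1, ]
  co <- coating_presets("sweep_1_19")$biotin
  v_at <- function(idx) {
    pos <- c(fl$xs[idx[1]], fl$ys[idx[2]])
    start <- pmin(pmax(pos, 40), 260)
    plan <- waypoint_plan(matrix(start + c(25, 0), 1, 2))
    rb <- run_trajectory(plan, coating = co, fluid = fl, start = start,
                         controller = controller_config(timeout = 120),
                         seed = 9)
    mean(rb$velocity_raw$speed_um_s)
  }
  v_hi <- v_at(idx_hi)
  v_lo <- v_at(idx_lo)
  expect_gt(abs(v_hi - v_lo) / max(v_hi, v_lo), 0.2)
})

test_that("result bundles write their tables and metadata to disk", {
  prot <- small_sweep("sweep_1_19", n_particles = 1, n_trials = 1,
                      duration = 1)
  rb <- run_frequency_sweep(prot, seed = 7)
  dir <- withr::local_tempdir()
  write_result_bundle(rb, dir)
  expect_true(file.exists(file.path(dir, "metadata.json")))
  expect_true(file.exists(file.path(dir, "trials.csv")))
  expect_true(file.exists(file.path(dir, "profile_avidin.csv")))
  fits <- jsonlite::read_json(file.path(dir, "fits.json"))
  expect_setequal(names(fits), names(rb$fits))
})
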