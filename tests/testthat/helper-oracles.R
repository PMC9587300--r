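# Independent oracles used by the tests.

# Time-domain average rotation rate of the overdamped driven rotor
# dphi/dt = omega_c * sin(omega * t - phi), computed by integrating the
# slip-frame phase chi = omega * t - phi (dchi/dt = omega - omega_c * sin chi)
# with deSolve over many drive periods and averaging dphi/dt = omega - dchi/dt.
# Returns the mean rotation rate in Hz. Independent of the closed-form
# implementation in the package.
rotor_mean_rate_ode <- function(f, f_c, n_periods = 400) {
  if (f == 0) return(0)
  omega <- 2 * pi * f
  omega_c <- 2 * pi * f_c
  T_end <- n_periods / f
  sol <- deSolve::ode(
    y = c(chi = 0),
    times = seq(0, T_end, length.out = 2001),
    func = function(t, y, p) list(p$omega - p$omega_c * sin(y)),
    parms = list(omega = omega, omega_c = omega_c),
    rtol = 1e-9, atol = 1e-9
  )
  chi_T <- unname(sol[nrow(sol), "chi"])
  mean_dphi <- (omega * T_end - chi_T) / T_end  # phi = omega * t - chi
  mean_dphi / (2 * pi)
}

# Count upward jumps in an error series: increases larger than `threshold`
# relative to the previous step. Motion alone can raise the error by at most
# speed * dt per step, so a threshold well above that isolates target-switch
# discontinuities.
count_error_jumps <- function(error, threshold) {
  sum(diff(error) > threshold)
}

# (f, f_c) grid used by the step-out oracle comparison: 10 step-out scales
# crossed with 10 drive/step-out ratios, avoiding the near-critical band
# where the beat period diverges and any finite-time average is slow.
steppout_grid <- function() {
  expand.grid(
    f_c = seq(2, 20, by = 2),
    ratio = c(0.3, 0.5, 0.7, 0.9, 1.0, 1.3, 1.6, 2, 3, 5)
  )
}
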