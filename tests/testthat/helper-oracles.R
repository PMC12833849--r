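# Independent oracles used across the suite. These re-derive the model
# quantities through different algebra/algorithms than the package code.

# Straight real-arithmetic transcription of the loss spectrum: each term's
# imaginary part written out by hand instead of complex division.
oracle_eps_imag <- function(p, freq) {
  x_s <- 2 * pi * freq * p$tau_slow
  x_f <- 2 * pi * freq * p$tau_fast
  debye_slow <- p$delta_eps_slow * x_s / (1 + x_s^2)
  debye_fast <- p$delta_eps_fast * x_f / (1 + x_f^2)
  dr <- p$freq_stretch^2 - freq^2
  di <- freq * p$damping_stretch
  stretch <- p$amp_stretch * di / (dr^2 + di^2)
  p$water_volume_fraction * (debye_slow + debye_fast + stretch)
}

oracle_eps_real <- function(p, freq) {
  x_s <- 2 * pi * freq * p$tau_slow
  x_f <- 2 * pi * freq * p$tau_fast
  dr <- p$freq_stretch^2 - freq^2
  di <- freq * p$damping_stretch
  p$water_volume_fraction * (
    p$delta_eps_slow / (1 + x_s^2) +
    p$delta_eps_fast / (1 + x_f^2) +
    p$amp_stretch * dr / (dr^2 + di^2)
  )
}

# Profiled dense grid search for the two-amplitude solution fit. Each
# amplitude is scanned on a fine grid while the other is minimized exactly
# (the loss is linear in the amplitudes, so the conditional optimum has a
# closed form). The two SSE profiles are exact 1-D quadratics, so each grid
# argmin localizes the least-squares solution to within one grid step.
oracle_grid_fit <- function(spectrum, c_frac, amp_stretch = 35.0,
                            slow_range, fast_range, step = 0.01) {
  keep <- spectrum$frequencies >= 0.3 & spectrum$frequencies <= 2.5
  freq <- spectrum$frequencies[keep]
  y <- spectrum$eps_imag[keep]
  base <- list(tau_slow = 9.20, tau_fast = 0.245, amp_stretch = amp_stretch,
               freq_stretch = 5.30, damping_stretch = 32.5,
               water_volume_fraction = c_frac)
  x_s <- 2 * pi * freq * base$tau_slow
  x_f <- 2 * pi * freq * base$tau_fast
  a <- c_frac * x_s / (1 + x_s^2)                     # basis for slow amp
  b <- c_frac * x_f / (1 + x_f^2)                     # basis for fast amp
  dr <- base$freq_stretch^2 - freq^2
  di <- freq * base$damping_stretch
  fx <- c_frac * amp_stretch * di / (dr^2 + di^2)     # fixed stretch part
  d <- fx - y
  Saa <- sum(a * a); Sbb <- sum(b * b); Sab <- sum(a * b)
  Sad <- sum(a * d); Sbd <- sum(b * d); Sdd <- sum(d * d)
  slow_grid <- seq(slow_range[1], slow_range[2], by = step)
  fast_grid <- seq(fast_range[1], fast_range[2], by = step)
  # profile over slow: fast minimized in closed form (bounded below by 0)
  fast_star <- pmax(-(Sbd + slow_grid * Sab) / Sbb, 0)
  sse_slow <- slow_grid^2 * Saa + 2 * slow_grid * Sad +
    fast_star^2 * Sbb + 2 * fast_star * Sbd +
    2 * slow_grid * fast_star * Sab + Sdd
  # profile over fast: slow minimized in closed form
  slow_star <- pmax(-(Sad + fast_grid * Sab) / Saa, 0)
  sse_fast <- fast_grid^2 * Sbb + 2 * fast_grid * Sbd +
    slow_star^2 * Saa + 2 * slow_star * Sad +
    2 * fast_grid * slow_star * Sab + Sdd
  c(delta_eps_slow = slow_grid[which.min(sse_slow)],
    delta_eps_fast = fast_grid[which.min(sse_fast)])
}

# OLS through explicit normal equations, independent of stats::lm.
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# random valid parameter set for property tests
random_params <- function() {
  dielectric_params(
    delta_eps_slow = runif(1, 10, 100),
    delta_eps_fast = runif(1, 0.1, 5),
    tau_slow = runif(1, 5, 15),
    tau_fast = runif(1, 0.1, 0.5),
    amp_stretch = runif(1, 10, 60),
    freq_stretch = runif(1, 4, 7),
    damping_stretch = runif(1, 20, 45),
    water_volume_fraction = runif(1, 0.5, 1)
  )
}
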