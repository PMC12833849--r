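test_that("noiseless pure-water spectrum refits to the generating amplitudes", {
  sp <- gen_spectrum(water_reference_params())
  fit <- fit_pure_water(sp)
  expect_true(fit$converged)
  expect_equal(fit$params$delta_eps_slow, 73.8, tolerance = 1e-3)
  expect_equal(fit$params$delta_eps_fast, 1.85, tolerance = 1e-3)
  expect_equal(fit$params$amp_stretch, 35.0, tolerance = 1e-3)
  expect_lt(fit$residual_rms, 1e-8)
})

test_that("zero fast amplitude is recovered at the lower bound, not negative", {
  p <- dielectric_params(73.8, 0)
  sp <- gen_spectrum(p)
  fit <- fit_pure_water(sp)
  expect_gte(fit$params$delta_eps_fast, 0)
  expect_lt(fit$params$delta_eps_fast, 1e-4)
})

test_that("mean recovered slow amplitude over 50 noisy replicates is within 1%", {
  est <- vapply(1:50, function(s) {
    sp <- gen_spectrum(water_reference_params(), noise_sd = 0.02, seed = s)
    fit_pure_water(sp)$params$delta_eps_slow
  }, numeric(1))
  expect_equal(mean(est), 73.8, tolerance = 0.01)
})

test_that("solution fit round-trips generating amplitudes and scales with c", {
  comp_c <- 0.95
  p <- dielectric_params(66.42, 1.85, water_volume_fraction = comp_c)
  sp <- gen_spectrum(p)
  fit <- fit_solution(sp, comp_c)
  expect_equal(fit$params$delta_eps_slow, 66.42, tolerance = 1e-3)
  expect_equal(fit$params$delta_eps_fast, 1.85, tolerance = 1e-3)

  # same spectrum declared at c/2 doubles the fitted amplitudes exactly.
  # The stretch term must be absent for this to be an identity: the model
  # scales it by c while the fit holds A_s fixed, so a nonzero fixed stretch
  # contribution breaks strict 2x scaling of the free amplitudes.
  cfg0 <- fit_config(amp_stretch = 0)
  p0 <- dielectric_params(66.42, 1.85, amp_stretch = 0,
                          water_volume_fraction = comp_c)
  sp0 <- gen_spectrum(p0)
  fit_full <- fit_solution(sp0, comp_c, cfg0)
  fit_half <- fit_solution(sp0, comp_c / 2, cfg0)
  expect_equal(fit_half$params$delta_eps_slow,
               2 * fit_full$params$delta_eps_slow, tolerance = 1e-6)
  expect_equal(fit_half$params$delta_eps_fast,
               2 * fit_full$params$delta_eps_fast, tolerance = 1e-6)
})

test_that("urea-like amplitudes above the water value are not clipped", {
  p <- dielectric_params(77.0, 1.85)
  fit <- fit_solution(gen_spectrum(p), 1)
  expect_equal(fit$params$delta_eps_slow, 77.0, tolerance = 1e-3)
})

test_that("a pure-water spectrum fit as a solution at c = 1 matches the water fit", {
  sp <- gen_spectrum(water_reference_params(), noise_sd = 0.01, seed = 3)
  wfit <- fit_pure_water(sp)
  sfit <- fit_solution(sp, 1)
  expect_equal(sfit$params$delta_eps_slow, wfit$params$delta_eps_slow,
               tolerance = 5e-3)
  expect_equal(sfit$params$delta_eps_fast, wfit$params$delta_eps_fast,
               tolerance = 0.2)
})

test_that("round-trip recovery holds across random generating parameters", {
  set.seed(99)
  for (i in 1:10) {
    ds <- runif(1, 40, 90)
    df <- runif(1, 0.5, 4)
    cc <- runif(1, 0.6, 1)
    sp <- gen_spectrum(dielectric_params(ds, df, water_volume_fraction = cc))
    fit <- fit_solution(sp, cc)
    expect_equal(fit$params$delta_eps_slow, ds, tolerance = 1e-3)
    expect_equal(fit$params$delta_eps_fast, df, tolerance = 1e-3)
  }
})

test_that("recovery bias and spread shrink as the noise level shrinks", {
  sds <- c(0.05, 0.02, 0.005)
  spread <- bias <- numeric(length(sds))
  for (j in seq_along(sds)) {
    est <- vapply(1:30, function(s) {
      sp <- gen_spectrum(water_reference_params(), noise_sd = sds[j],
                         seed = 1000 * j + s)
      fit_pure_water(sp)$params$delta_eps_slow
    }, numeric(1))
    bias[j] <- abs(mean(est) - 73.8)
    spread[j] <- sd(est)
  }
  expect_true(all(diff(spread) < 0))
  expect_lt(bias[3], bias[1] + 0.05)
  expect_lt(bias[3], 0.05)
})

test_that("out-of-band points do not influence the fit", {
  grid_in <- default_thz_grid()
  p <- dielectric_params(70, 2)
  sp_in <- gen_spectrum(p, grid = grid_in)
  # append distorted out-of-band points on both sides
  grid_ext <- c(0.1, 0.2, grid_in, 2.6, 3.0)
  eps_ext <- c(99, 99, eval_eps_imag(p, grid_in), 99, 99)
  sp_ext <- dielectric_spectrum(grid_ext, eps_ext)
  f1 <- fit_solution(sp_in, 1)
  f2 <- fit_solution(sp_ext, 1)
  expect_equal(f1$params$delta_eps_slow, f2$params$delta_eps_slow,
               tolerance = 1e-10)
  expect_equal(f1$params$delta_eps_fast, f2$params$delta_eps_fast,
               tolerance = 1e-10)
})

test_that("least-squares solution agrees with a dense grid search", {
  set.seed(7)
  for (i in 1:10) {
    ds <- round(runif(1, 55, 80), 2)
    df <- round(runif(1, 0.5, 3.5), 2)
    cc <- runif(1, 0.7, 1)
    sp <- gen_spectrum(dielectric_params(ds, df, water_volume_fraction = cc),
                       noise_sd = 0.02, seed = 500 + i)
    fit <- fit_solution(sp, cc)
    g <- oracle_grid_fit(sp, cc,
                         slow_range = c(ds - 2, ds + 2),
                         fast_range = c(max(df - 1, 0), df + 1), step = 0.01)
    expect_lte(abs(fit$params$delta_eps_slow - g[["delta_eps_slow"]]), 0.011)
    expect_lte(abs(fit$params$delta_eps_fast - g[["delta_eps_fast"]]), 0.011)
  }
})

test_that("too few in-band points raise an insufficient-data error", {
  sp <- dielectric_spectrum(seq(0.5, 0.9, by = 0.1),
                            eval_eps_imag(water_reference_params(),
                                          seq(0.5, 0.9, by = 0.1)))
  expect_error(fit_pure_water(sp), "inside the fit band")
  expect_error(fit_solution(sp, 1), "inside the fit band")
  expect_error(fit_solution(gen_spectrum(water_reference_params()), 0),
               "0, 1")
})
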