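test_that("pure water at the reference density has volume fraction 1", {
  comp <- solution_composition(0, 0.9975, 342.30)
  expect_equal(water_volume_fraction(comp), 1, tolerance = 1e-12)
})

test_that("sucrose mass-balance example reproduces the hand arithmetic", {
  comp <- solution_composition(0.75, 1.100, 342.30)
  # m_s = 256.725 g/L, m_w = 843.275 g/L
  expect_equal(water_volume_fraction(comp), 843.275 / 997.5, tolerance = 1e-10)
  expect_equal(water_volume_fraction(comp), 0.8454, tolerance = 1e-4)
  expect_equal(waters_per_osmolyte(comp), (843.275 / 18.015) / 0.75,
               tolerance = 1e-10)
  expect_equal(waters_per_osmolyte(comp), 62.41, tolerance = 1e-4)
})

test_that("volume fraction decreases with molar mass; alpha is inverse in molarity", {
  c1 <- water_volume_fraction(solution_composition(0.75, 1.1, 180))
  c2 <- water_volume_fraction(solution_composition(0.75, 1.1, 360))
  expect_lt(c2, c1)
  # halving C at fixed water mass doubles alpha: density adjusts so that
  # m_w = 1000*rho - C*M stays constant
  m_w <- 750.6
  comp_a <- solution_composition(0.75, (m_w + 0.75 * 342.3) / 1000, 342.3)
  comp_b <- solution_composition(0.375, (m_w + 0.375 * 342.3) / 1000, 342.3)
  expect_equal(waters_per_osmolyte(comp_a), 55.55, tolerance = 1e-3)
  expect_equal(waters_per_osmolyte(comp_b),
               2 * waters_per_osmolyte(comp_a), tolerance = 1e-12)
})

test_that("implausible compositions and pure-water alpha are rejected", {
  expect_error(solution_composition(5, 1.0, 342.3), "water mass")
  expect_error(waters_per_osmolyte(solution_composition(0, 0.9975, 342.3)),
               "undefined")
})

test_that("hydration fraction reproduces the closed-form cases", {
  water <- list(delta_eps_slow = 73.8, delta_eps_fast = 1.85)
  same <- hydration_fraction(water, water)
  expect_equal(same, 0, tolerance = 1e-15)

  bound <- hydration_fraction(water,
                              list(delta_eps_slow = 66.42, delta_eps_fast = 1.85))
  expect_equal(bound, (7.38 / 2.9) / (73.8 / 2.9 + 1.85), tolerance = 1e-12)
  expect_equal(bound, 0.0932, tolerance = 1e-3)

  urea <- hydration_fraction(water,
                             list(delta_eps_slow = 77.0, delta_eps_fast = 1.85))
  expect_equal(urea, -0.0404, tolerance = 1e-3)
  expect_lt(urea, 0)
})

test_that("hydration fraction is bounded by 1 and decreasing in both solution amplitudes", {
  set.seed(21)
  water <- list(delta_eps_slow = 73.8, delta_eps_fast = 1.85)
  for (i in 1:200) {
    s <- list(delta_eps_slow = runif(1, 0, 90), delta_eps_fast = runif(1, 0, 5))
    a <- hydration_fraction(water, s)
    expect_lte(a, 1)
    bump_slow <- hydration_fraction(water,
      list(delta_eps_slow = s$delta_eps_slow + 0.5,
           delta_eps_fast = s$delta_eps_fast))
    bump_fast <- hydration_fraction(water,
      list(delta_eps_slow = s$delta_eps_slow,
           delta_eps_fast = s$delta_eps_fast + 0.5))
    expect_lt(bump_slow, a)
    expect_lt(bump_fast, a)
  }
  # equality at 1 only when both solution amplitudes vanish
  expect_equal(hydration_fraction(water,
                                  list(delta_eps_slow = 0, delta_eps_fast = 0)),
               1, tolerance = 1e-15)
})

test_that("hydration number is the product alpha * a_hyd with sign preserved", {
  expect_equal(hydration_number(0, 50), 0)
  expect_equal(hydration_number(0.0932, 62.41), 5.82, tolerance = 1e-3)
  expect_equal(hydration_number(-0.0404, 70), -2.83, tolerance = 1e-2)
  expect_error(hydration_number(0.1, 0), "positive")
  # n_hyd scales as alpha does at fixed a_hyd
  a <- 0.05
  expect_equal(hydration_number(a, 40) / hydration_number(a, 20), 2,
               tolerance = 1e-12)
})

test_that("a non-converged fit is refused by the hydration stage", {
  sp <- gen_spectrum(water_reference_params())
  fit <- fit_pure_water(sp)
  fit$converged <- FALSE
  expect_error(hydration_fraction(fit, fit), "converge")
})

test_that("end-to-end noiseless recovery of a planted hydration number", {
  comp <- solution_composition(0.75, 1.100, 342.30)
  alpha <- waters_per_osmolyte(comp)
  target <- 5.82
  ssp <- gen_spectrum_for_nhyd(target, comp)
  wsp <- gen_spectrum(water_reference_params())
  wfit <- fit_pure_water(wsp)
  sfit <- fit_solution(ssp, water_volume_fraction(comp))
  a <- hydration_fraction(wfit, sfit)
  expect_equal(hydration_number(a, alpha), target, tolerance = 0.01)
})

test_that("stretch-amplitude sweep brackets the central value and collapses when degenerate", {
  comp <- solution_composition(0.75, 1.100, 342.30)
  wsp <- gen_spectrum(water_reference_params())
  ssp <- gen_spectrum_for_nhyd(5.82, comp)

  res <- hydration_sweep(ssp, wsp, comp)
  expect_equal(res$n_hyd, 5.82, tolerance = 0.01)
  expect_lte(res$n_hyd_lo, res$n_hyd)
  expect_gte(res$n_hyd_hi, res$n_hyd)
  expect_gt(res$n_hyd_hi - res$n_hyd_lo, 0)

  single <- hydration_sweep(ssp, wsp, comp, amp_stretch_values = 35.0)
  expect_identical(single$n_hyd_lo, single$n_hyd)
  expect_identical(single$n_hyd_hi, single$n_hyd)

  expect_error(hydration_sweep(ssp, wsp, comp,
                               amp_stretch_values = c(33, 37), central = 35),
               "central")
})

test_that("the molar-mass table covers the seven-osmolyte panel", {
  mm <- osmolyte_molar_mass(c("urea", "sucrose", "trehalose"))
  expect_equal(unname(mm), c(60.06, 342.30, 342.30))
  expect_length(osmolyte_molar_mass(), 7)
  expect_error(osmolyte_molar_mass("betaine"), "unknown")
})
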