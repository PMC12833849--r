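#' Synthesize a dielectric loss spectrum
#'
#' Evaluates the water dielectric model on a frequency grid and adds i.i.d.
#' Gaussian noise to the loss, emulating one instrument acquisition.
#'
#' @param params A [dielectric_params()] object.
#' @param grid Frequency grid in THz (default the 0.3-2.5 THz band at
#'   0.05 THz).
#' @param noise_sd Standard deviation of the additive noise on eps'' (>= 0).
#' @param seed Optional integer seed; fixed seed gives identical spectra.
#' @param label,temperature Passed to [dielectric_spectrum()].
#' @return A [dielectric_spectrum()].
#' @export
gen_spectrum <- function(params, grid = default_thz_grid(), noise_sd = 0,
                         seed = NULL, label = "synthetic",
                         temperature = 20.0) {
  stopifnot(noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  eps <- eval_eps_imag(params, grid)
  if (noise_sd > 0) eps <- eps + stats::rnorm(length(grid), 0, noise_sd)
  dielectric_spectrum(grid, eps, label = label, temperature = temperature)
}

#' Slow amplitude that plants a target hydration fraction
#'
#' Closed-form inversion of the hydration-fraction formula with the fast
#' amplitude held at the water value: the solution slow amplitude that makes
#' the pipeline recover exactly `a_hyd_target`.
#'
#' @param a_hyd_target Target hydration fraction (may be negative).
#' @param water_params Pure-water [dielectric_params()] reference.
#' @return The solution slow amplitude (errors if it would be negative).
#' @export
solution_slow_amplitude <- function(a_hyd_target,
                                    water_params = water_reference_params()) {
  g <- kirkwood_factors()
  den <- water_params$delta_eps_slow / g[["slow"]] +
    water_params$delta_eps_fast / g[["fast"]]
  d_slow <- water_params$delta_eps_slow - g[["slow"]] * a_hyd_target * den
  if (d_slow < 0) {
    stop(sprintf("infeasible target a_hyd = %.4g: slow amplitude would be negative",
                 a_hyd_target), call. = FALSE)
  }
  unname(d_slow)
}

#' Synthesize a solution spectrum with a planted hydration number
#'
#' Chooses the solution slow amplitude so that the analysis pipeline, run on a
#' noiseless version of this spectrum with the matching composition, recovers
#' `a_hyd = true_n_hyd / alpha` exactly. Negative `true_n_hyd` plants a slow
#' amplitude above the water value (structure-breaking, urea-like). The fast
#' amplitude stays at the water value.
#'
#' @param true_n_hyd Planted hydration number (waters per osmolyte, signed).
#' @param comp [solution_composition()] of the solution; fixes `c` and alpha.
#' @param water_params Pure-water reference parameters.
#' @param grid,noise_sd,seed,label As in [gen_spectrum()].
#' @return A [dielectric_spectrum()].
#' @export
gen_spectrum_for_nhyd <- function(true_n_hyd, comp,
                                  water_params = water_reference_params(),
                                  grid = default_thz_grid(), noise_sd = 0,
                                  seed = NULL, label = "synthetic-solution") {
  alpha <- waters_per_osmolyte(comp)
  a_target <- true_n_hyd / alpha
  d_slow <- solution_slow_amplitude(a_target, water_params)
  params <- dielectric_params(
    delta_eps_slow = d_slow,
    delta_eps_fast = water_params$delta_eps_fast,
    tau_slow = water_params$tau_slow,
    tau_fast = water_params$tau_fast,
    amp_stretch = water_params$amp_stretch,
    freq_stretch = water_params$freq_stretch,
    damping_stretch = water_params$damping_stretch,
    water_volume_fraction = water_volume_fraction(comp)
  )
  gen_spectrum(params, grid = grid, noise_sd = noise_sd, seed = seed,
               label = label)
}

#' Synthesize an absorbance decay trace
#'
#' `Abs(t) = B + A0 exp(-k t)` plus additive Gaussian noise, sampled every 5 s
#' for 10 min by default. The schedule starts at t = 0 so the pre-trim samples
#' exercise the start-trim path of [fit_decay()].
#'
#' @param k Rate constant in 1/s, > 0.
#' @param A0 Initial amplitude above background.
#' @param B Background absorbance.
#' @param times Sampling times in s (default 0 to 600 by 5).
#' @param noise_sd SD of the additive absorbance noise (>= 0).
#' @param seed Optional integer seed.
#' @param osmolyte,bottle_id,replicate_id Metadata for the trace.
#' @return An [absorbance_trace()].
#' @export
gen_decay_trace <- function(k, A0, B, times = seq(0, 600, by = 5),
                            noise_sd = 0, seed = NULL,
                            osmolyte = "water", bottle_id = "b1",
                            replicate_id = "r1") {
  stopifnot(k > 0, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  y <- B + A0 * exp(-k * times)
  if (noise_sd > 0) y <- y + stats::rnorm(length(times), 0, noise_sd)
  absorbance_trace(times, y, osmolyte = osmolyte, bottle_id = bottle_id,
                   replicate_id = replicate_id)
}

#' Design of a synthetic osmolyte study
#'
#' Fixes every condition of a simulated campaign: the osmolyte panel with
#' planted hydration numbers and compositions, the linear activity law mapping
#' n_hyd to the expected normalized rate, the number of amylose bottles with
#' their concentration-factor range, replicates per condition, and the two
#' noise levels. The defaults emulate the real study: seven osmolytes at
#' 0.75 mol/L spanning structure-breaking (urea) to strongly water-binding
#' (trehalose), five bottles, and an activity law with negative slope so that
#' water-binding osmolytes slow the enzyme.
#'
#' @param osmolytes data.frame with columns `label`, `true_n_hyd`,
#'   `molar_mass`, `molarity`, `density`.
#' @param activity_slope,activity_intercept Linear law
#'   `k/k_water = intercept + slope * n_hyd`.
#' @param n_bottles Number of amylose bottles.
#' @param bottle_factor_range Multiplicative per-bottle factor range (> 0).
#' @param replicates Kinetics replicates per osmolyte and bottle.
#' @param base_k Pure-water rate constant in 1/s before the bottle factor.
#' @param decay_A0,decay_B Decay amplitude and background.
#' @param noise_eps SD of the additive spectrum noise.
#' @param noise_abs SD of the additive absorbance noise.
#' @param k_noise_sdlog sdlog of the multiplicative lognormal run-to-run rate
#'   noise.
#' @return An object of class `study_design`.
#' @export
study_design <- function(osmolytes = default_osmolyte_panel(),
                         activity_slope = -0.04,
                         activity_intercept = 1.0,
                         n_bottles = 5L,
                         bottle_factor_range = c(0.7, 1.3),
                         replicates = 3L,
                         base_k = 0.010,
                         decay_A0 = 1.0,
                         decay_B = 0.20,
                         noise_eps = 0.02,
                         noise_abs = 0.005,
                         k_noise_sdlog = 0.02) {
  stopifnot(is.data.frame(osmolytes),
            all(c("label", "true_n_hyd", "molar_mass", "molarity",
                  "density") %in% names(osmolytes)),
            nrow(osmolytes) >= 1,
            is.finite(activity_slope), n_bottles >= 1, replicates >= 1,
            all(bottle_factor_range > 0), base_k > 0,
            noise_eps >= 0, noise_abs >= 0, k_noise_sdlog >= 0)
  expected <- activity_intercept + activity_slope * osmolytes$true_n_hyd
  if (any(expected <= 0)) {
    stop("activity law yields non-positive expected k/k_water for some osmolyte",
         call. = FALSE)
  }
  structure(
    list(osmolytes = osmolytes,
         activity_slope = activity_slope,
         activity_intercept = activity_intercept,
         n_bottles = as.integer(n_bottles),
         bottle_factor_range = as.numeric(bottle_factor_range),
         replicates = as.integer(replicates),
         base_k = base_k, decay_A0 = decay_A0, decay_B = decay_B,
         noise_eps = noise_eps, noise_abs = noise_abs,
         k_noise_sdlog = k_noise_sdlog),
    class = "study_design"
  )
}

#' Default seven-osmolyte panel
#'
#' The panel emulated by the generator: urea, propylene glycol (PG),
#' diethylene glycol (DEG), glycerol, fructose, sucrose and trehalose, all at
#' 0.75 mol/L. Planted hydration numbers span -3 (urea, structure breaking)
#' to +7 (trehalose, strongly binding); densities are realistic values for
#' 0.75 M aqueous solutions at 23 degrees C (synthetic stand-ins, not
#' measured data).
#'
#' @return A data.frame with columns `label`, `true_n_hyd`, `molar_mass`,
#'   `molarity`, `density`.
#' @export
default_osmolyte_panel <- function() {
  mm <- osmolyte_molar_mass()
  data.frame(
    label = c("urea", "pg", "deg", "glycerol", "fructose", "sucrose",
              "trehalose"),
    true_n_hyd = c(-3.0, 0.5, 1.5, 2.5, 4.0, 5.5, 7.0),
    molar_mass = unname(mm[c("urea", "pg", "deg", "glycerol", "fructose",
                             "sucrose", "trehalose")]),
    molarity = rep(0.75, 7),
    density = c(1.009, 1.003, 1.008, 1.014, 1.044, 1.094, 1.095),
    stringsAsFactors = FALSE
  )
}

#' Generate a full synthetic study
#'
#' Simulates the whole campaign defined by a [study_design()]: one pure-water
#' spectrum, one solution spectrum per osmolyte (slow amplitude planted from
#' `true_n_hyd`), and for every amylose bottle a set of water-control and
#' osmolyte decay traces. Each bottle's water rate is `base_k` times a
#' uniform bottle factor; each osmolyte run's rate is the bottle's water rate
#' times the activity-law ratio times multiplicative lognormal noise. The
#' planted ground truth is returned for recovery scoring.
#'
#' @param design A [study_design()].
#' @param seed Integer seed controlling every random draw.
#' @return A list of class `synthetic_study` with `water_spectrum`,
#'   `solution_spectra` (named by osmolyte), `compositions`, `traces`,
#'   `ground_truth` and the `design`.
#' @export
gen_study <- function(design = study_design(), seed = 1L) {
  stopifnot(inherits(design, "study_design"))
  set.seed(seed)
  wp <- water_reference_params()
  osm <- design$osmolytes

  water_spectrum <- gen_spectrum(wp, noise_sd = design$noise_eps,
                                 label = "water")

  compositions <- lapply(seq_len(nrow(osm)), function(i) {
    solution_composition(osm$molarity[i], osm$density[i], osm$molar_mass[i])
  })
  names(compositions) <- osm$label

  solution_spectra <- lapply(seq_len(nrow(osm)), function(i) {
    gen_spectrum_for_nhyd(osm$true_n_hyd[i], compositions[[i]],
                          water_params = wp, noise_sd = design$noise_eps,
                          label = osm$label[i])
  })
  names(solution_spectra) <- osm$label

  bottle_ids <- paste0("b", seq_len(design$n_bottles))
  bottle_factors <- stats::runif(design$n_bottles,
                                 design$bottle_factor_range[1],
                                 design$bottle_factor_range[2])
  names(bottle_factors) <- bottle_ids

  expected_ratio <- design$activity_intercept +
    design$activity_slope * osm$true_n_hyd
  names(expected_ratio) <- osm$label

  traces <- list()
  for (b in bottle_ids) {
    k_water <- design$base_k * bottle_factors[[b]]
    for (r in seq_len(design$replicates)) {
      traces[[length(traces) + 1L]] <- gen_decay_trace(
        k_water, design$decay_A0, design$decay_B,
        noise_sd = design$noise_abs,
        osmolyte = "water", bottle_id = b, replicate_id = paste0("r", r)
      )
    }
    for (i in seq_len(nrow(osm))) {
      for (r in seq_len(design$replicates)) {
        k_run <- k_water * expected_ratio[[osm$label[i]]] *
          (if (design$k_noise_sdlog > 0)
             stats::rlnorm(1, 0, design$k_noise_sdlog) else 1)
        traces[[length(traces) + 1L]] <- gen_decay_trace(
          k_run, design$decay_A0, design$decay_B,
          noise_sd = design$noise_abs,
          osmolyte = osm$label[i], bottle_id = b,
          replicate_id = paste0("r", r)
        )
      }
    }
  }

  structure(
    list(water_spectrum = water_spectrum,
         solution_spectra = solution_spectra,
         compositions = compositions,
         traces = traces,
         ground_truth = list(
           true_n_hyd = stats::setNames(osm$true_n_hyd, osm$label),
           activity_slope = design$activity_slope,
           activity_intercept = design$activity_intercept,
           expected_ratio = expected_ratio,
           bottle_factors = bottle_factors,
           base_k = design$base_k
         ),
         design = design,
         seed = seed),
    class = "synthetic_study"
  )
}
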