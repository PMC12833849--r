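#' Kirkwood correlation factors for the two relaxation modes
#'
#' Dipole-correlation corrections applied when converting amplitude changes to
#' water-molecule counts: 2.9 for the collective slow relaxation, 1.0 for the
#' fast relaxation of isolated water molecules.
#' @keywords internal
kirkwood_factors <- function() c(slow = 2.9, fast = 1.0)

#' Solution composition from molarity and density
#'
#' Describes an aqueous osmolyte solution by its molar concentration, measured
#' density and the solute molar mass; from these the water volume fraction `c`
#' and the waters-per-osmolyte ratio \eqn{\alpha} follow by mass balance.
#'
#' @param molarity Osmolyte concentration in mol/L, >= 0.
#' @param density Solution density in g/mL, > 0.
#' @param molar_mass_osmolyte Osmolyte molar mass in g/mol.
#' @param molar_mass_water Water molar mass in g/mol.
#' @param water_density_ref Pure-water density in g/mL at the temperature of
#'   the density measurement; default 0.9975 g/mL at 23 degrees C.
#' @return An object of class `solution_composition`.
#' @export
solution_composition <- function(molarity, density, molar_mass_osmolyte,
                                 molar_mass_water = 18.015,
                                 water_density_ref = 0.9975) {
  stopifnot(molarity >= 0, density > 0, molar_mass_osmolyte > 0,
            molar_mass_water > 0, water_density_ref > 0)
  comp <- structure(
    list(molarity = as.numeric(molarity),
         density = as.numeric(density),
         molar_mass_osmolyte = as.numeric(molar_mass_osmolyte),
         molar_mass_water = as.numeric(molar_mass_water),
         water_density_ref = as.numeric(water_density_ref)),
    class = "solution_composition"
  )
  if (water_mass_per_litre(comp) <= 0) {
    stop("implausible composition: computed water mass per litre is <= 0",
         call. = FALSE)
  }
  comp
}

# grams of water per litre of solution: total mass minus solute mass
water_mass_per_litre <- function(comp) {
  1000 * comp$density - comp$molarity * comp$molar_mass_osmolyte
}

#' Water volume fraction of a solution
#'
#' Mass-balance estimate: the water mass per litre (total minus solute) is
#' converted to a volume via the pure-water reference density and divided by
#' the litre, giving the fraction `c` that scales the water dielectric
#' response.
#'
#' @param comp A [solution_composition()].
#' @return Water volume fraction in (0, 1].
#' @examples
#' sucrose <- solution_composition(0.75, 1.100, 342.30)
#' water_volume_fraction(sucrose)  # about 0.845
#' @export
water_volume_fraction <- function(comp) {
  stopifnot(inherits(comp, "solution_composition"))
  m_w <- water_mass_per_litre(comp)
  c_frac <- (m_w / comp$water_density_ref) / 1000
  if (!(c_frac > 0 && c_frac <= 1)) {
    stop(sprintf("water volume fraction %.4f outside (0, 1]", c_frac),
         call. = FALSE)
  }
  c_frac
}

#' Number of water molecules per osmolyte molecule
#'
#' \eqn{\alpha} = (moles of water per litre) / (moles of osmolyte per litre).
#' Undefined for pure water.
#'
#' @param comp A [solution_composition()] with `molarity > 0`.
#' @return alpha, the waters-per-osmolyte ratio.
#' @export
waters_per_osmolyte <- function(comp) {
  stopifnot(inherits(comp, "solution_composition"))
  if (comp$molarity <= 0) {
    stop("alpha is undefined for pure water (molarity = 0)", call. = FALSE)
  }
  (water_mass_per_litre(comp) / comp$molar_mass_water) / comp$molarity
}

#' Fraction of mobility-altered hydration water
#'
#' Converts the drop in the two fitted relaxation amplitudes between pure
#' water and a solution into the fraction `a_hyd` of all water molecules
#' whose picosecond dynamics the solute has altered, applying the Kirkwood
#' correlation factors (2.9 slow, 1.0 fast):
#' \deqn{a_{hyd} = \frac{(\Delta\varepsilon_{slow}^{w} - \Delta\varepsilon_{slow}^{s})/2.9
#'   - (\Delta\varepsilon_{fast}^{s} - \Delta\varepsilon_{fast}^{w})/1.0}
#'   {\Delta\varepsilon_{slow}^{w}/2.9 + \Delta\varepsilon_{fast}^{w}/1.0}}
#' A gain in the fast mode counts against hydration, and a slow amplitude
#' above the water value gives a negative `a_hyd` (structure breaking,
#' urea-like).
#'
#' @param water_fit `spectral_fit` for pure water (or its `params`).
#' @param solution_fit `spectral_fit` for the solution (or its `params`).
#' @return a_hyd, a dimensionless fraction <= 1 (possibly negative).
#' @export
hydration_fraction <- function(water_fit, solution_fit) {
  w <- fit_amplitudes(water_fit)
  s <- fit_amplitudes(solution_fit)
  if (w[["slow"]] <= 0 || w[["fast"]] <= 0) {
    stop("pure-water amplitudes must be positive", call. = FALSE)
  }
  g <- kirkwood_factors()
  num <- (w[["slow"]] - s[["slow"]]) / g[["slow"]] -
    (s[["fast"]] - w[["fast"]]) / g[["fast"]]
  den <- w[["slow"]] / g[["slow"]] + w[["fast"]] / g[["fast"]]
  unname(num / den)
}

# accept a spectral_fit, dielectric_params, or a plain named list
fit_amplitudes <- function(x) {
  if (inherits(x, "spectral_fit")) {
    if (!isTRUE(x$converged)) {
      stop("fit did not converge; refusing to compute hydration from it",
           call. = FALSE)
    }
    x <- x$params
  }
  c(slow = x$delta_eps_slow, fast = x$delta_eps_fast)
}

#' Hydration number: altered waters per osmolyte molecule
#'
#' `n_hyd = alpha * a_hyd`. Positive values mean waters bound per osmolyte
#' molecule; negative values mean osmolyte-induced structure breaking that
#' accelerates collective water dynamics.
#'
#' @param a_hyd Hydration fraction from [hydration_fraction()].
#' @param alpha Waters-per-osmolyte ratio from [waters_per_osmolyte()], > 0.
#' @return n_hyd (signed).
#' @export
hydration_number <- function(a_hyd, alpha) {
  stopifnot(is.numeric(a_hyd), is.numeric(alpha))
  if (any(alpha <= 0)) stop("alpha must be positive", call. = FALSE)
  alpha * a_hyd
}

#' Hydration estimate with stretch-amplitude sensitivity bounds
#'
#' Full hydration analysis of one solution spectrum against a pure-water
#' reference spectrum. Both spectra are refit at each stretch amplitude A_s in
#' `amp_stretch_values` (the water reference consistently with the solution),
#' and a_hyd / n_hyd are recomputed at each; the central value is taken at
#' `central` (default 35.0 THz^2) and the bounds are the min/max over the
#' sweep, mirroring the error bars obtained by moving A_s from 33 to 37 THz^2.
#'
#' @param solution_spectrum [dielectric_spectrum()] of the solution.
#' @param water_spectrum [dielectric_spectrum()] of pure water.
#' @param comp [solution_composition()] of the solution; supplies both the
#'   volume fraction `c` used in the fit and alpha.
#' @param amp_stretch_values A_s values in THz^2 to sweep.
#' @param central The A_s value whose result is reported as the central one;
#'   must be among `amp_stretch_values`.
#' @param config Base [fit_config()].
#' @return An object of class `hydration_result` with fields `a_hyd`, `n_hyd`,
#'   `a_hyd_lo/hi`, `n_hyd_lo/hi`, `alpha`, `c`, and the per-A_s table.
#' @export
hydration_sweep <- function(solution_spectrum, water_spectrum, comp,
                            amp_stretch_values = c(33.0, 35.0, 37.0),
                            central = 35.0,
                            config = fit_config()) {
  stopifnot(length(amp_stretch_values) >= 1)
  if (!any(abs(amp_stretch_values - central) < 1e-12)) {
    stop("central A_s must be among amp_stretch_values", call. = FALSE)
  }
  c_frac <- water_volume_fraction(comp)
  alpha <- if (comp$molarity > 0) waters_per_osmolyte(comp) else NA_real_
  rows <- lapply(amp_stretch_values, function(a_s) {
    cfg <- config
    cfg$amp_stretch <- a_s
    wfit <- fit_pure_water(water_spectrum, cfg)
    sfit <- fit_solution(solution_spectrum, c_frac, cfg)
    if (!wfit$converged || !sfit$converged) {
      stop(sprintf("non-convergent sub-fit at A_s = %.3g THz^2", a_s),
           call. = FALSE)
    }
    a <- hydration_fraction(wfit, sfit)
    data.frame(amp_stretch = a_s, a_hyd = a,
               n_hyd = if (is.na(alpha)) NA_real_ else alpha * a)
  })
  tab <- do.call(rbind, rows)
  i0 <- which(abs(tab$amp_stretch - central) < 1e-12)[1]
  structure(
    list(a_hyd = tab$a_hyd[i0],
         a_hyd_lo = min(tab$a_hyd), a_hyd_hi = max(tab$a_hyd),
         n_hyd = tab$n_hyd[i0],
         n_hyd_lo = if (is.na(alpha)) NA_real_ else min(tab$n_hyd),
         n_hyd_hi = if (is.na(alpha)) NA_real_ else max(tab$n_hyd),
         alpha = alpha, water_volume_fraction = c_frac, sweep = tab),
    class = "hydration_result"
  )
}

#' @export
print.hydration_result <- function(x, ...) {
  cat(sprintf(
    "<hydration_result> a_hyd=%.4f [%.4f, %.4f]  n_hyd=%.3f [%.3f, %.3f]  alpha=%.2f c=%.4f\n",
    x$a_hyd, x$a_hyd_lo, x$a_hyd_hi, x$n_hyd, x$n_hyd_lo, x$n_hyd_hi,
    x$alpha, x$water_volume_fraction
  ))
  invisible(x)
}

#' Molar masses of the studied osmolytes
#'
#' Lookup table (g/mol, anhydrous) for the seven osmolytes of the panel:
#' urea, propylene glycol (PG), diethylene glycol (DEG), glycerol, fructose,
#' sucrose, trehalose.
#'
#' @param osmolyte Optional character vector of names; if given, returns the
#'   matching molar masses and errors on unknown names.
#' @return Named numeric vector of molar masses.
#' @export
osmolyte_molar_mass <- function(osmolyte = NULL) {
  tab <- c(urea = 60.06, pg = 76.09, deg = 106.12, glycerol = 92.09,
           fructose = 180.16, sucrose = 342.30, trehalose = 342.30)
  if (is.null(osmolyte)) return(tab)
  key <- tolower(osmolyte)
  unknown <- setdiff(unique(key), names(tab))
  if (length(unknown)) {
    stop("unknown osmolyte(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(tab[key], osmolyte)
}
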