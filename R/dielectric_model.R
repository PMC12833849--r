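#' Dielectric model parameters for liquid water in the terahertz band
#'
#' Bundles the parameters of the water dielectric function used throughout the
#' package: two Debye relaxations (a slow, collective reorientational mode and
#' a fast mode of under-coordinated water molecules) plus one damped harmonic
#' oscillator for the intermolecular stretching vibration of hydrogen-bonded
#' water, the whole scaled by the water volume fraction of the sample.
#'
#' The model evaluated by [eval_dielectric()] is
#' \deqn{\varepsilon(\nu) = c\left(\frac{\Delta\varepsilon_{slow}}{1 + i\,2\pi\nu\tau_{slow}}
#'   + \frac{\Delta\varepsilon_{fast}}{1 + i\,2\pi\nu\tau_{fast}}
#'   + \frac{A_s}{\nu_s^2 - \nu^2 + i\,\nu\gamma_s}\right)}
#' with \eqn{\nu} in THz and \eqn{\tau} in ps, so the Debye products
#' \eqn{2\pi\nu\tau} are dimensionless and the oscillator term is evaluated in
#' THz\eqn{^2} over THz\eqn{^2}. Results are returned in the loss-positive
#' convention \eqn{\varepsilon = \varepsilon' + i\varepsilon''},
#' \eqn{\varepsilon'' \ge 0}.
#'
#' @param delta_eps_slow Amplitude of the slow relaxation (dimensionless, >= 0).
#' @param delta_eps_fast Amplitude of the fast relaxation (dimensionless, >= 0).
#' @param tau_slow Slow relaxation time in ps; must exceed `tau_fast`.
#' @param tau_fast Fast relaxation time in ps, > 0.
#' @param amp_stretch Oscillator amplitude \eqn{A_s} in THz^2, >= 0.
#' @param freq_stretch Oscillator resonance frequency \eqn{\nu_s} in THz, > 0.
#' @param damping_stretch Oscillator damping \eqn{\gamma_s} in THz, > 0.
#' @param water_volume_fraction Volume fraction of water `c` in (0, 1].
#' @return An object of class `dielectric_params` (a named list).
#' @seealso [water_reference_params()] for the pure-water defaults,
#'   [eval_dielectric()], [eval_eps_imag()].
#' @export
dielectric_params <- function(delta_eps_slow,
                              delta_eps_fast,
                              tau_slow = 9.20,
                              tau_fast = 0.245,
                              amp_stretch = 35.0,
                              freq_stretch = 5.30,
                              damping_stretch = 32.5,
                              water_volume_fraction = 1) {
  p <- list(
    delta_eps_slow = as.numeric(delta_eps_slow),
    delta_eps_fast = as.numeric(delta_eps_fast),
    tau_slow = as.numeric(tau_slow),
    tau_fast = as.numeric(tau_fast),
    amp_stretch = as.numeric(amp_stretch),
    freq_stretch = as.numeric(freq_stretch),
    damping_stretch = as.numeric(damping_stretch),
    water_volume_fraction = as.numeric(water_volume_fraction)
  )
  validate_dielectric_params(p)
  structure(p, class = "dielectric_params")
}

validate_dielectric_params <- function(p) {
  stopifnot(
    length(p$delta_eps_slow) == 1L, is.finite(p$delta_eps_slow),
    length(p$delta_eps_fast) == 1L, is.finite(p$delta_eps_fast)
  )
  if (p$delta_eps_slow < 0 || p$delta_eps_fast < 0) {
    stop("relaxation amplitudes must be non-negative", call. = FALSE)
  }
  if (!(p$tau_slow > p$tau_fast && p$tau_fast > 0)) {
    stop("relaxation times must satisfy tau_slow > tau_fast > 0", call. = FALSE)
  }
  if (p$amp_stretch < 0) stop("amp_stretch must be >= 0", call. = FALSE)
  if (p$freq_stretch <= 0 || p$damping_stretch <= 0) {
    stop("oscillator frequency and damping must be positive", call. = FALSE)
  }
  if (!(p$water_volume_fraction > 0 && p$water_volume_fraction <= 1)) {
    stop("water_volume_fraction must lie in (0, 1]", call. = FALSE)
  }
  invisible(p)
}

#' Pure-water reference parameters at 20 degrees C
#'
#' Literature parameter set for pure water: relaxation times 9.20 ps and
#' 0.245 ps, stretch resonance 5.30 THz with damping 32.5 THz and amplitude
#' 35.0 THz^2, and fitted relaxation amplitudes 73.8 (slow) and 1.85 (fast).
#' These are the values held fixed during spectral fitting.
#'
#' @return A `dielectric_params` object with `water_volume_fraction = 1`.
#' @export
water_reference_params <- function() {
  dielectric_params(
    delta_eps_slow = 73.8,
    delta_eps_fast = 1.85,
    tau_slow = 9.20,
    tau_fast = 0.245,
    amp_stretch = 35.0,
    freq_stretch = 5.30,
    damping_stretch = 32.5,
    water_volume_fraction = 1
  )
}

#' Evaluate the complex dielectric function of water
#'
#' Forward evaluation of the two-Debye-plus-oscillator model at one or more
#' frequencies. The returned complex values follow the loss-positive
#' convention: `Im(eval_dielectric(...))` is the dielectric loss
#' \eqn{\varepsilon'' \ge 0}.
#'
#' @param params A [dielectric_params()] object.
#' @param freq Frequencies in THz, all > 0.
#' @return Complex vector of the same length as `freq`.
#' @examples
#' w <- water_reference_params()
#' eval_dielectric(w, 1.0)  # loss about 2.76 at 1 THz
#' @export
eval_dielectric <- function(params, freq) {
  validate_dielectric_params(params)
  freq <- as.numeric(freq)
  if (length(freq) == 0L) stop("frequency grid is empty", call. = FALSE)
  if (any(!is.finite(freq)) || any(freq <= 0)) {
    stop("frequencies must be finite and positive", call. = FALSE)
  }
  x_slow <- 2 * pi * freq * params$tau_slow
  x_fast <- 2 * pi * freq * params$tau_fast
  debye_slow <- params$delta_eps_slow / complex(real = 1, imaginary = x_slow)
  debye_fast <- params$delta_eps_fast / complex(real = 1, imaginary = x_fast)
  stretch <- params$amp_stretch /
    complex(real = params$freq_stretch^2 - freq^2,
            imaginary = freq * params$damping_stretch)
  eps <- params$water_volume_fraction * (debye_slow + debye_fast + stretch)
  # flip to the loss-positive convention eps' + i eps''
  complex(real = Re(eps), imaginary = -Im(eps))
}

#' Evaluate the dielectric loss on a frequency grid
#'
#' Vectorized imaginary part of [eval_dielectric()]; this is the quantity the
#' spectral fitter matches, since only the loss spectrum carries a usable
#' hydration signal in the 0.3-2.5 THz band.
#'
#' @inheritParams eval_dielectric
#' @param freq Strictly increasing frequency grid in THz.
#' @return Numeric vector of \eqn{\varepsilon''} values, same length as `freq`.
#' @export
eval_eps_imag <- function(params, freq) {
  freq <- as.numeric(freq)
  if (length(freq) == 0L) stop("frequency grid is empty", call. = FALSE)
  if (length(freq) > 1L && any(diff(freq) <= 0)) {
    stop("frequency grid must be strictly increasing", call. = FALSE)
  }
  Im(eval_dielectric(params, freq))
}

#' Construct a dielectric spectrum
#'
#' Container for a measured (or synthesized) permittivity spectrum: a strictly
#' increasing frequency grid with the dielectric loss \eqn{\varepsilon''} and,
#' optionally, the real part \eqn{\varepsilon'}.
#'
#' @param frequencies Frequencies in THz, strictly increasing, all > 0.
#' @param eps_imag Dielectric loss per frequency; finite, same length.
#' @param eps_real Optional real permittivity per frequency.
#' @param label Sample identifier.
#' @param temperature Sample temperature in degrees C.
#' @return An object of class `dielectric_spectrum`.
#' @export
dielectric_spectrum <- function(frequencies, eps_imag, eps_real = NULL,
                                label = "", temperature = 20.0) {
  frequencies <- as.numeric(frequencies)
  eps_imag <- as.numeric(eps_imag)
  if (length(frequencies) == 0L) stop("spectrum has no points", call. = FALSE)
  if (any(!is.finite(frequencies)) || any(frequencies <= 0)) {
    stop("frequencies must be finite and positive", call. = FALSE)
  }
  if (length(frequencies) > 1L && any(diff(frequencies) <= 0)) {
    stop("frequencies must be strictly increasing", call. = FALSE)
  }
  if (length(eps_imag) != length(frequencies)) {
    stop("eps_imag length must equal frequencies length", call. = FALSE)
  }
  if (any(!is.finite(eps_imag))) stop("eps_imag must be finite", call. = FALSE)
  if (!is.null(eps_real)) {
    eps_real <- as.numeric(eps_real)
    if (length(eps_real) != length(frequencies)) {
      stop("eps_real length must equal frequencies length", call. = FALSE)
    }
  }
  structure(
    list(frequencies = frequencies, eps_imag = eps_imag, eps_real = eps_real,
         label = as.character(label), temperature = as.numeric(temperature)),
    class = "dielectric_spectrum"
  )
}

#' @export
print.dielectric_spectrum <- function(x, ...) {
  cat(sprintf(
    "<dielectric_spectrum> '%s': %d points, %.3g-%.3g THz, %.1f degC\n",
    x$label, length(x$frequencies), min(x$frequencies), max(x$frequencies),
    x$temperature
  ))
  invisible(x)
}

#' @export
print.dielectric_params <- function(x, ...) {
  cat(sprintf(
    paste0("<dielectric_params> d_eps_slow=%.4g d_eps_fast=%.4g ",
           "tau=%.3g/%.3g ps A_s=%.3g THz^2 nu_s=%.3g gamma_s=%.3g c=%.4g\n"),
    x$delta_eps_slow, x$delta_eps_fast, x$tau_slow, x$tau_fast,
    x$amp_stretch, x$freq_stretch, x$damping_stretch, x$water_volume_fraction
  ))
  invisible(x)
}

#' Default terahertz frequency grid
#'
#' The reliable band of the attenuated-total-reflection measurement,
#' 0.3-2.5 THz, sampled at `step` THz.
#'
#' @param step Grid spacing in THz.
#' @return Numeric vector of frequencies.
#' @export
default_thz_grid <- function(step = 0.05) {
  seq(0.3, 2.5, by = step)
}
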