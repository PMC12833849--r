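#' Configuration for spectral fitting
#'
#' Controls the fit band, fixed parameters, bounds and start values used when
#' fitting the dielectric loss. Defaults implement the standard protocol: fit
#' only 0.3-2.5 THz, hold both relaxation times and the stretch-oscillator
#' shape at the pure-water literature values, and leave the relaxation
#' amplitudes free.
#'
#' @param fit_band Two-element numeric, (min, max) frequency in THz.
#' @param amp_stretch Fixed oscillator amplitude A_s in THz^2 used for
#'   solution fits (default 35.0); swept to 33.0 and 37.0 for error bars.
#' @param tau_slow,tau_fast,freq_stretch,damping_stretch Fixed shape
#'   parameters (ps, ps, THz, THz).
#' @param max_iter Maximum optimizer iterations.
#' @param ftol Convergence tolerance on the cost reduction.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(fit_band = c(0.3, 2.5),
                       amp_stretch = 35.0,
                       tau_slow = 9.20,
                       tau_fast = 0.245,
                       freq_stretch = 5.30,
                       damping_stretch = 32.5,
                       max_iter = 1000L,
                       ftol = 1e-10) {
  fit_band <- as.numeric(fit_band)
  if (length(fit_band) != 2L || any(fit_band <= 0) || fit_band[1] >= fit_band[2]) {
    stop("fit_band must be (min, max) with 0 < min < max", call. = FALSE)
  }
  structure(
    list(fit_band = fit_band, amp_stretch = amp_stretch,
         tau_slow = tau_slow, tau_fast = tau_fast,
         freq_stretch = freq_stretch, damping_stretch = damping_stretch,
         max_iter = as.integer(max_iter), ftol = ftol),
    class = "fit_config"
  )
}

# restrict a spectrum to the fit band; errors if too few points remain
band_restrict <- function(spectrum, fit_band, min_points = 10L) {
  keep <- spectrum$frequencies >= fit_band[1] & spectrum$frequencies <= fit_band[2]
  if (sum(keep) < min_points) {
    stop(sprintf("only %d points inside the fit band %.3g-%.3g THz (need >= %d)",
                 sum(keep), fit_band[1], fit_band[2], min_points), call. = FALSE)
  }
  list(freq = spectrum$frequencies[keep], eps = spectrum$eps_imag[keep])
}

# shared bounded Levenberg-Marquardt driver over the loss spectrum.
# free: named start values; fixed: remaining model parameters incl. c.
lm_fit_eps <- function(freq, eps, free, lower, upper, fixed, config) {
  make_params <- function(v) {
    all <- utils::modifyList(fixed, as.list(v))
    dielectric_params(
      delta_eps_slow = all$delta_eps_slow,
      delta_eps_fast = all$delta_eps_fast,
      tau_slow = all$tau_slow,
      tau_fast = all$tau_fast,
      amp_stretch = all$amp_stretch,
      freq_stretch = all$freq_stretch,
      damping_stretch = all$damping_stretch,
      water_volume_fraction = all$water_volume_fraction
    )
  }
  resid_fn <- function(v) {
    v <- pmin(pmax(v, lower), upper)
    eval_eps_imag(make_params(v), freq) - eps
  }
  out <- minpack.lm::nls.lm(
    par = free, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      maxiter = config$max_iter, ftol = config$ftol, ptol = 1e-12
    )
  )
  est <- stats::setNames(as.numeric(out$par), names(free))
  params <- make_params(est)
  res <- eval_eps_imag(params, freq) - eps
  converged <- out$info %in% 1:4
  structure(
    list(params = params,
         free_names = names(free),
         residual_rms = sqrt(mean(res^2)),
         n_points = length(freq),
         converged = converged,
         info = out$info,
         message = out$message),
    class = "spectral_fit"
  )
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat(sprintf(
    "<spectral_fit> free: %s | d_eps_slow=%.4f d_eps_fast=%.4f A_s=%.3f c=%.4f | rms=%.3g n=%d %s\n",
    paste(x$free_names, collapse = ","),
    x$params$delta_eps_slow, x$params$delta_eps_fast,
    x$params$amp_stretch, x$params$water_volume_fraction,
    x$residual_rms, x$n_points,
    if (x$converged) "converged" else "NOT CONVERGED"
  ))
  invisible(x)
}

#' Fit the pure-water loss spectrum
#'
#' Fits the dielectric loss of pure water in the configured band with the two
#' relaxation amplitudes and the stretch amplitude free, and the relaxation
#' times and oscillator shape held at the literature values (9.20 ps,
#' 0.245 ps, 5.30 THz, 32.5 THz). The water volume fraction is 1 by
#' definition.
#'
#' @param spectrum A [dielectric_spectrum()] with at least 10 in-band points.
#' @param config A [fit_config()].
#' @return A `spectral_fit` object: merged parameters, residual RMS, point
#'   count and a convergence flag (non-convergence is flagged, never silent).
#' @export
fit_pure_water <- function(spectrum, config = fit_config()) {
  stopifnot(inherits(spectrum, "dielectric_spectrum"))
  d <- band_restrict(spectrum, config$fit_band)
  ref <- water_reference_params()
  free <- c(delta_eps_slow = ref$delta_eps_slow,
            delta_eps_fast = ref$delta_eps_fast,
            amp_stretch = ref$amp_stretch)
  lower <- c(0, 0, 0)
  upper <- c(10 * ref$delta_eps_slow, 10 * ref$delta_eps_fast,
             10 * ref$amp_stretch)
  fixed <- list(tau_slow = config$tau_slow, tau_fast = config$tau_fast,
                freq_stretch = config$freq_stretch,
                damping_stretch = config$damping_stretch,
                water_volume_fraction = 1)
  lm_fit_eps(d$freq, d$eps, free, lower, upper, fixed, config)
}

#' Fit an osmolyte-solution loss spectrum
#'
#' Fits the dielectric loss of a solution with only the two relaxation
#' amplitudes free. The stretch amplitude is fixed (default 35.0 THz^2), the
#' relaxation times and oscillator shape are held at the pure-water values,
#' and the water volume fraction `c` computed from the solution density is
#' supplied by the caller. Amplitudes are bounded below by zero but not above
#' by the pure-water values: structure-breaking solutes such as urea can
#' legitimately exceed them.
#'
#' @param spectrum A [dielectric_spectrum()] with at least 10 in-band points.
#' @param composition_c Water volume fraction in (0, 1].
#' @param config A [fit_config()]; `config$amp_stretch` is the fixed A_s.
#' @return A `spectral_fit` object.
#' @export
fit_solution <- function(spectrum, composition_c, config = fit_config()) {
  stopifnot(inherits(spectrum, "dielectric_spectrum"))
  composition_c <- as.numeric(composition_c)
  if (!(length(composition_c) == 1L && composition_c > 0 && composition_c <= 1)) {
    stop("composition_c must be a single value in (0, 1]", call. = FALSE)
  }
  d <- band_restrict(spectrum, config$fit_band)
  ref <- water_reference_params()
  # start from the pure-water amplitudes: the solution signal is mostly
  # c-scaled water, so this is already close for realistic samples
  free <- c(delta_eps_slow = ref$delta_eps_slow,
            delta_eps_fast = ref$delta_eps_fast)
  lower <- c(0, 0)
  upper <- c(10 * ref$delta_eps_slow, 10 * ref$delta_eps_fast)
  fixed <- list(tau_slow = config$tau_slow, tau_fast = config$tau_fast,
                amp_stretch = config$amp_stretch,
                freq_stretch = config$freq_stretch,
                damping_stretch = config$damping_stretch,
                water_volume_fraction = composition_c)
  lm_fit_eps(d$freq, d$eps, free, lower, upper, fixed, config)
}
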