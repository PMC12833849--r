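#' Absorbance decay trace
#'
#' One iodine-starch bleaching measurement: absorbance at 615 nm sampled on a
#' strictly increasing time grid, labelled by osmolyte, amylose bottle and
#' replicate. The bottle label matters because amylose concentration varies
#' between bottles, and rates are only comparable after normalization by a
#' water control from the same bottle.
#'
#' @param times Times in seconds, strictly increasing, >= 0.
#' @param absorbance Absorbance values (dimensionless), finite.
#' @param osmolyte Osmolyte label, or "water" for a control run.
#' @param bottle_id Amylose-bottle label.
#' @param replicate_id Replicate label.
#' @return An object of class `absorbance_trace`.
#' @export
absorbance_trace <- function(times, absorbance, osmolyte = "water",
                             bottle_id = "b1", replicate_id = "r1") {
  times <- as.numeric(times)
  absorbance <- as.numeric(absorbance)
  if (length(times) != length(absorbance)) {
    stop("times and absorbance must have the same length", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("times must be finite and >= 0", call. = FALSE)
  }
  if (length(times) > 1L && any(diff(times) <= 0)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(absorbance))) {
    stop("absorbance must be finite", call. = FALSE)
  }
  structure(
    list(times = times, absorbance = absorbance,
         osmolyte = as.character(osmolyte),
         bottle_id = as.character(bottle_id),
         replicate_id = as.character(replicate_id)),
    class = "absorbance_trace"
  )
}

#' Fit a first-order decay to an absorbance trace
#'
#' Fits `Abs(t) = B + A0 * exp(-k t)` to the bleaching curve by bounded
#' nonlinear least squares. Samples earlier than `start_trim_s` are discarded
#' (stirring transients), and the time axis is re-originated at the first
#' retained sample so that `A0 + B` is the absorbance at the trim point.
#'
#' @param trace An [absorbance_trace()] covering at least 60 s beyond the trim
#'   and with at least 10 retained samples.
#' @param start_trim_s Seconds discarded from the start (default 15).
#' @return An object of class `kinetics_run` with fields `k` (1/s), `A0`, `B`,
#'   `residual_rms`, `n_points`, `converged`, and the trace metadata. A trace
#'   whose absorbance trends upward is flagged (`converged = FALSE`,
#'   `flag = "non-decay"`), never silently fitted.
#' @export
fit_decay <- function(trace, start_trim_s = 15) {
  stopifnot(inherits(trace, "absorbance_trace"))
  keep <- trace$times >= start_trim_s
  if (sum(keep) < 10L) {
    stop("fewer than 10 samples after the start trim", call. = FALSE)
  }
  t_raw <- trace$times[keep]
  y <- trace$absorbance[keep]
  if (max(t_raw) - min(t_raw) < 60) {
    stop("trace must cover at least 60 s beyond the trim", call. = FALSE)
  }
  t <- t_raw - t_raw[1]

  meta <- list(osmolyte = trace$osmolyte, bottle_id = trace$bottle_id,
               replicate_id = trace$replicate_id)

  # a rising trend cannot be a bleaching decay: flag instead of fitting
  slope <- stats::coef(stats::lm(y ~ t))[2]
  if (slope > 0 && y[length(y)] > y[1]) {
    return(structure(
      c(list(k = NA_real_, A0 = NA_real_, B = NA_real_,
             residual_rms = NA_real_, n_points = length(t),
             converged = FALSE, flag = "non-decay"), meta),
      class = "kinetics_run"
    ))
  }

  # start values: background from the tail, amplitude from the head,
  # k from the time to decay ~63% of the observed drop
  b0 <- max(min(y), 0)
  a0 <- max(y[1] - b0, 1e-6)
  drop <- y[1] - y
  i63 <- which(drop >= 0.632 * max(drop))[1]
  k0 <- if (!is.na(i63) && t[i63] > 0) 1 / t[i63] else 1 / (max(t) / 3)

  resid_fn <- function(p) p[["B"]] + p[["A0"]] * exp(-p[["k"]] * t) - y
  out <- minpack.lm::nls.lm(
    par = c(B = b0, A0 = a0, k = k0),
    lower = c(B = 0, A0 = 1e-12, k = 1e-12),
    upper = c(B = Inf, A0 = Inf, k = Inf),
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 1000, ftol = 1e-12,
                                         ptol = 1e-12)
  )
  est <- as.numeric(out$par)
  names(est) <- names(out$par)
  res <- resid_fn(out$par)
  structure(
    c(list(k = est[["k"]], A0 = est[["A0"]], B = est[["B"]],
           residual_rms = sqrt(mean(res^2)), n_points = length(t),
           converged = out$info %in% 1:4, flag = NA_character_), meta),
    class = "kinetics_run"
  )
}

#' @export
print.kinetics_run <- function(x, ...) {
  cat(sprintf(
    "<kinetics_run> %s/%s/%s k=%.5g 1/s A0=%.4g B=%.4g rms=%.3g n=%d %s\n",
    x$osmolyte, x$bottle_id, x$replicate_id, x$k, x$A0, x$B,
    x$residual_rms, x$n_points,
    if (isTRUE(x$converged)) "converged" else paste0("FLAGGED:", x$flag)
  ))
  invisible(x)
}

#' Normalize rate constants by bottle-paired water controls
#'
#' Each osmolyte run's rate constant is divided by the mean rate of the
#' pure-water control runs measured with the same amylose bottle, cancelling
#' the bottle-to-bottle variation in amylose concentration. Ratios are then
#' grouped by osmolyte and summarized with the sample (n-1) standard
#' deviation.
#'
#' @param runs A list of `kinetics_run` objects (water controls identified by
#'   `osmolyte == "water"`).
#' @return A list with `rates`: a data.frame of one row per osmolyte
#'   (`osmolyte`, `mean_ratio`, `sd_ratio`, `n_runs`), `ratios`: per-run
#'   ratios with metadata, and `rejected`: runs excluded for lack of a
#'   same-bottle water control (reported with a warning).
#' @export
normalize_rates <- function(runs) {
  stopifnot(is.list(runs), length(runs) > 0)
  ok <- vapply(runs, function(r) isTRUE(r$converged), logical(1))
  runs <- runs[ok]
  osm <- vapply(runs, `[[`, character(1), "osmolyte")
  bottle <- vapply(runs, `[[`, character(1), "bottle_id")
  k <- vapply(runs, `[[`, numeric(1), "k")

  is_water <- osm == "water"
  if (!any(is_water)) stop("no water control runs present", call. = FALSE)
  k_water_by_bottle <- tapply(k[is_water], bottle[is_water], mean)

  idx <- which(!is_water)
  have_ctrl <- bottle[idx] %in% names(k_water_by_bottle)
  rejected <- data.frame(
    osmolyte = osm[idx][!have_ctrl],
    bottle_id = bottle[idx][!have_ctrl],
    reason = if (any(!have_ctrl)) "no same-bottle water control" else character(0),
    stringsAsFactors = FALSE
  )
  if (nrow(rejected) > 0) {
    warning(sprintf("%d run(s) excluded: no same-bottle water control (%s)",
                    nrow(rejected),
                    paste(unique(rejected$bottle_id), collapse = ", ")),
            call. = FALSE)
  }
  idx <- idx[have_ctrl]
  ratios <- data.frame(
    osmolyte = osm[idx],
    bottle_id = bottle[idx],
    ratio = k[idx] / as.numeric(k_water_by_bottle[bottle[idx]]),
    stringsAsFactors = FALSE
  )
  if (any(ratios$ratio <= 0)) {
    stop("non-positive normalized ratio encountered", call. = FALSE)
  }
  agg <- do.call(rbind, lapply(split(ratios, ratios$osmolyte), function(d) {
    data.frame(osmolyte = d$osmolyte[1],
               mean_ratio = mean(d$ratio),
               sd_ratio = if (nrow(d) > 1) stats::sd(d$ratio) else NA_real_,
               n_runs = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  list(rates = agg, ratios = ratios, rejected = rejected)
}
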