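#' Correlation input: hydration measure versus normalized activity
#'
#' One point per osmolyte: a water-dynamics measure on the x axis (`n_hyd` for
#' binary osmolyte/water systems, `a_hyd` for ternary amylase/osmolyte/water
#' systems) against the mean normalized rate constant `k/k_water` on the y
#' axis, with the kinetics standard deviation and the stretch-amplitude sweep
#' half-width carried along for reporting.
#'
#' @param x Hydration measure per osmolyte (n_hyd or a_hyd).
#' @param y Mean normalized rate k/k_water per osmolyte, > 0.
#' @param label Osmolyte labels.
#' @param y_err Optional kinetics SD per point.
#' @param x_err Optional sweep half-width per point.
#' @param axis_kind Which hydration measure `x` is: "n_hyd" or "a_hyd".
#' @return An object of class `correlation_input`.
#' @export
correlation_input <- function(x, y, label = NULL, y_err = NULL, x_err = NULL,
                              axis_kind = c("n_hyd", "a_hyd")) {
  axis_kind <- match.arg(axis_kind)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 points", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("x and y must be finite", call. = FALSE)
  }
  if (any(y <= 0)) stop("normalized rates must be positive", call. = FALSE)
  if (is.null(label)) label <- paste0("osmolyte", seq_along(x))
  structure(
    list(x = x, y = y, label = as.character(label),
         y_err = if (is.null(y_err)) rep(NA_real_, length(x)) else as.numeric(y_err),
         x_err = if (is.null(x_err)) rep(NA_real_, length(x)) else as.numeric(x_err),
         axis_kind = axis_kind),
    class = "correlation_input"
  )
}

#' Ordinary least-squares line relating hydration to activity
#'
#' Unweighted OLS of the normalized rate on the hydration measure, with
#' \eqn{R^2 = 1 - SS_{res}/SS_{tot}} (identical to the squared Pearson
#' correlation for a simple regression). Error bars are carried for reporting
#' only and never weight the fit.
#'
#' @param input A [correlation_input()].
#' @return An object of class `correlation_result` with `slope`, `intercept`,
#'   `r_squared` and `n_points`.
#' @export
linear_fit <- function(input) {
  stopifnot(inherits(input, "correlation_input"))
  if (stats::var(input$x) == 0) {
    stop("degenerate fit: all x values are equal", call. = FALSE)
  }
  fit <- stats::lm(y ~ x, data = data.frame(x = input$x, y = input$y))
  co <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((input$y - mean(input$y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(
    list(slope = unname(co[2]), intercept = unname(co[1]),
         r_squared = r2, n_points = length(input$x),
         axis_kind = input$axis_kind),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %s: slope=%.4g intercept=%.4g R^2=%.2f n=%d\n",
              x$axis_kind, x$slope, x$intercept, x$r_squared, x$n_points))
  invisible(x)
}

#' Joint study summary of the binary and ternary correlations
#'
#' Combines the binary-system fit (n_hyd vs k/k_water) and, when available,
#' the ternary-system fit (a_hyd vs k/k_water) into one structured summary
#' with a sign-consistency check: both slopes negative means water-binding
#' osmolytes suppress activity in both system types.
#'
#' @param binary `correlation_result` for the binary panel.
#' @param ternary Optional `correlation_result` for the ternary panel
#'   (`NULL` marks it as omitted).
#' @param binary_points,ternary_points Optional `correlation_input` objects
#'   echoed into the summary as point tables.
#' @return A list summary with fits, point tables, `consistent_negative`
#'   flag and a `note`.
#' @export
correlation_report <- function(binary, ternary = NULL,
                               binary_points = NULL, ternary_points = NULL) {
  stopifnot(inherits(binary, "correlation_result"))
  points_tab <- function(p) {
    if (is.null(p)) return(NULL)
    data.frame(label = p$label, x = p$x, y = p$y,
               x_err = p$x_err, y_err = p$y_err,
               stringsAsFactors = FALSE)
  }
  if (is.null(ternary)) {
    return(list(
      binary = unclass(binary), ternary = NULL,
      binary_points = points_tab(binary_points), ternary_points = NULL,
      consistent_negative = NA,
      note = "ternary panel omitted: no amylase/osmolyte spectra supplied"
    ))
  }
  stopifnot(inherits(ternary, "correlation_result"))
  consistent <- binary$slope < 0 && ternary$slope < 0
  list(
    binary = unclass(binary), ternary = unclass(ternary),
    binary_points = points_tab(binary_points),
    ternary_points = points_tab(ternary_points),
    consistent_negative = consistent,
    note = if (consistent) {
      "both slopes negative: water-binding osmolytes suppress activity"
    } else {
      "slope signs disagree between binary and ternary panels"
    }
  )
}
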