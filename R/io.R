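#' Read a dielectric spectrum from CSV
#'
#' Expects columns `frequency_thz`, `eps_imag` and optionally `eps_real`.
#' Lines starting with `#` are metadata comments; `# label: x` and
#' `# temperature_C: y` are honoured. Malformed rows are reported with their
#' line number.
#'
#' @param path Path to the CSV file.
#' @return A [dielectric_spectrum()].
#' @export
read_spectrum <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  meta_lines <- grep("^\\s*#", lines, value = TRUE)
  label <- sub("^\\s*#\\s*label:\\s*", "",
               grep("^\\s*#\\s*label:", meta_lines, value = TRUE))
  temp <- sub("^\\s*#\\s*temperature_C:\\s*", "",
              grep("^\\s*#\\s*temperature_C:", meta_lines, value = TRUE))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("frequency_thz", "eps_imag")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  check_numeric_col(df$frequency_thz, "frequency_thz", path)
  check_numeric_col(df$eps_imag, "eps_imag", path)
  bad <- which(df$frequency_thz <= 0)
  if (length(bad)) {
    stop(sprintf("non-positive frequency at data row %d of %s", bad[1], path),
         call. = FALSE)
  }
  bad <- which(diff(df$frequency_thz) <= 0)
  if (length(bad)) {
    stop(sprintf("non-increasing frequency at data row %d of %s",
                 bad[1] + 1L, path), call. = FALSE)
  }
  dielectric_spectrum(
    df$frequency_thz, df$eps_imag,
    eps_real = if ("eps_real" %in% names(df)) df$eps_real else NULL,
    label = if (length(label)) label[1] else basename(path),
    temperature = if (length(temp)) as.numeric(temp[1]) else 20.0
  )
}

check_numeric_col <- function(x, name, path) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(x))))[1]
    stop(sprintf("non-numeric value in column '%s' at data row %d of %s",
                 name, if (is.na(bad)) 1L else bad, path), call. = FALSE)
  }
  invisible(x)
}

#' Write a dielectric spectrum to CSV
#'
#' Writes `# label:` and `# temperature_C:` comment headers followed by the
#' data columns at full double precision, so a write-read round trip
#' reproduces the values exactly.
#'
#' @param spectrum A [dielectric_spectrum()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "dielectric_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# label: ", spectrum$label),
               paste0("# temperature_C: ",
                      format(spectrum$temperature, digits = 17))), con)
  df <- data.frame(frequency_thz = spectrum$frequencies,
                   eps_imag = spectrum$eps_imag)
  if (!is.null(spectrum$eps_real)) df$eps_real <- spectrum$eps_real
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read absorbance traces from a manifest
#'
#' The manifest is a CSV with columns `path`, `osmolyte`, `bottle_id`,
#' `replicate_id`; each referenced file is a CSV with columns `time_s`,
#' `absorbance`. Relative paths are resolved against the manifest's
#' directory.
#'
#' @param manifest_path Path to the manifest CSV.
#' @return A list of [absorbance_trace()] objects.
#' @export
read_traces <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop("manifest not found: ", manifest_path, call. = FALSE)
  }
  man <- utils::read.csv(manifest_path, comment.char = "#",
                         stringsAsFactors = FALSE)
  required <- c("path", "osmolyte", "bottle_id", "replicate_id")
  missing_cols <- setdiff(required, names(man))
  if (length(missing_cols)) {
    stop("manifest missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  base <- dirname(manifest_path)
  lapply(seq_len(nrow(man)), function(i) {
    p <- man$path[i]
    if (!file.exists(p)) p <- file.path(base, man$path[i])
    if (!file.exists(p)) {
      stop(sprintf("manifest row %d references missing file: %s",
                   i, man$path[i]), call. = FALSE)
    }
    df <- utils::read.csv(p, comment.char = "#", stringsAsFactors = FALSE)
    if (!all(c("time_s", "absorbance") %in% names(df))) {
      stop("trace file missing time_s/absorbance columns: ", p, call. = FALSE)
    }
    check_numeric_col(df$time_s, "time_s", p)
    check_numeric_col(df$absorbance, "absorbance", p)
    absorbance_trace(df$time_s, df$absorbance,
                     osmolyte = man$osmolyte[i],
                     bottle_id = man$bottle_id[i],
                     replicate_id = man$replicate_id[i])
  })
}

#' Write a trace to CSV
#'
#' @param trace An [absorbance_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "absorbance_trace"))
  df <- data.frame(time_s = trace$times, absorbance = trace$absorbance)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an analysis record as JSON
#'
#' Serializes a result object (fit, hydration result, pipeline summary) to
#' JSON with stable key order and full numeric precision, so repeated runs on
#' identical inputs give byte-identical files.
#'
#' @param record A list-like result object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result <- function(record, path) {
  record <- strip_result(record)
  jsonlite::write_json(record, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(path)
}

# drop classes/closures so jsonlite serializes plainly and stably
strip_result <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    x <- lapply(x, strip_result)
  }
  if (is.object(x) && !is.data.frame(x)) x <- unclass(x)
  x
}

#' Run the full analysis pipeline on a study bundle
#'
#' Executes the complete workflow on a study bundle (as produced by
#' [gen_study()], or assembled from [read_spectrum()] / [read_traces()]
#' output): spectral fits of water and every solution with the
#' stretch-amplitude sensitivity sweep, hydration fractions and numbers,
#' decay fits with bottle-paired normalization, and the ordinary
#' least-squares correlation of `n_hyd` against the mean `k/k_water`. When
#' the bundle carries ternary (amylase/osmolyte) spectra under
#' `ternary_spectra`, an `a_hyd` correlation is added; otherwise the summary
#' carries an explicit omission marker.
#'
#' @param study A list with `water_spectrum`, named `solution_spectra`,
#'   matching named `compositions`, and `traces`; optionally
#'   `ternary_spectra` (+ `ternary_compositions`).
#' @param config A [fit_config()].
#' @param sweep Stretch-amplitude values for the sensitivity sweep.
#' @return A list summary: `hydration` (per-osmolyte table), `rates`,
#'   `binary_fit`, `ternary_fit` (or NULL), `report`, `rejected_runs`.
#' @export
run_pipeline <- function(study, config = fit_config(),
                         sweep = c(33.0, 35.0, 37.0)) {
  needed <- c("water_spectrum", "solution_spectra", "compositions", "traces")
  missing_parts <- setdiff(needed, names(study))
  if (length(missing_parts)) {
    stop("study bundle missing: ", paste(missing_parts, collapse = ", "),
         call. = FALSE)
  }
  labels <- names(study$solution_spectra)
  if (is.null(labels) || !all(labels %in% names(study$compositions))) {
    stop("every solution spectrum needs a matching composition", call. = FALSE)
  }

  hyd <- lapply(labels, function(lab) {
    res <- tryCatch(
      hydration_sweep(study$solution_spectra[[lab]], study$water_spectrum,
                      study$compositions[[lab]], amp_stretch_values = sweep,
                      central = 35.0, config = config),
      error = function(e) stop("hydration stage failed for sample '", lab,
                               "': ", conditionMessage(e), call. = FALSE)
    )
    data.frame(osmolyte = lab, a_hyd = res$a_hyd, n_hyd = res$n_hyd,
               n_hyd_lo = res$n_hyd_lo, n_hyd_hi = res$n_hyd_hi,
               a_hyd_lo = res$a_hyd_lo, a_hyd_hi = res$a_hyd_hi,
               alpha = res$alpha, c = res$water_volume_fraction,
               stringsAsFactors = FALSE)
  })
  hyd <- do.call(rbind, hyd)

  runs <- lapply(study$traces, function(tr) {
    tryCatch(fit_decay(tr),
             error = function(e) stop("kinetics stage failed for trace '",
                                      tr$osmolyte, "/", tr$bottle_id,
                                      "': ", conditionMessage(e),
                                      call. = FALSE))
  })
  norm <- normalize_rates(runs)

  merged <- merge(hyd, norm$rates, by = "osmolyte")
  merged <- merged[match(labels[labels %in% merged$osmolyte],
                         merged$osmolyte), ]
  if (nrow(merged) < 3) {
    stop("fewer than 3 osmolytes with both hydration and kinetics results",
         call. = FALSE)
  }
  binary_in <- correlation_input(
    merged$n_hyd, merged$mean_ratio, label = merged$osmolyte,
    y_err = merged$sd_ratio,
    x_err = (merged$n_hyd_hi - merged$n_hyd_lo) / 2,
    axis_kind = "n_hyd"
  )
  binary_fit <- linear_fit(binary_in)

  ternary_fit <- NULL
  ternary_in <- NULL
  if (!is.null(study$ternary_spectra) && length(study$ternary_spectra) >= 3) {
    tlabels <- names(study$ternary_spectra)
    tcomp <- study$ternary_compositions
    if (is.null(tcomp)) tcomp <- study$compositions
    thyd <- do.call(rbind, lapply(tlabels, function(lab) {
      res <- hydration_sweep(study$ternary_spectra[[lab]],
                             study$water_spectrum, tcomp[[lab]],
                             amp_stretch_values = sweep, central = 35.0,
                             config = config)
      data.frame(osmolyte = lab, a_hyd = res$a_hyd,
                 a_hyd_lo = res$a_hyd_lo, a_hyd_hi = res$a_hyd_hi,
                 stringsAsFactors = FALSE)
    }))
    tm <- merge(thyd, norm$rates, by = "osmolyte")
    if (nrow(tm) >= 3) {
      ternary_in <- correlation_input(
        tm$a_hyd, tm$mean_ratio, label = tm$osmolyte,
        y_err = tm$sd_ratio, x_err = (tm$a_hyd_hi - tm$a_hyd_lo) / 2,
        axis_kind = "a_hyd"
      )
      ternary_fit <- linear_fit(ternary_in)
    }
  }

  list(
    hydration = hyd,
    rates = norm$rates,
    rejected_runs = norm$rejected,
    binary_fit = binary_fit,
    ternary_fit = ternary_fit,
    report = correlation_report(binary_fit, ternary_fit,
                                binary_points = binary_in,
                                ternary_points = ternary_in),
    config = unclass(config),
    sweep = sweep
  )
}
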