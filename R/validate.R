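#' Signed retention-time prediction error
#'
#' `error (%) = (predicted - experimental) / experimental * 100` — the
#' convention used in method-validation tables: negative when the model
#' predicts earlier elution than observed.
#'
#' @param predicted,experimental Retention times in minutes (vectorized).
#' @return Signed percent error(s).
#' @examples
#' retention_error_pct(23.72, 25.73) # -7.81...
#' @export
retention_error_pct <- function(predicted, experimental) {
  if (any(!is.finite(experimental)) || any(experimental <= 0)) {
    stop("experimental retention times must be positive", call. = FALSE)
  }
  (predicted - experimental) / experimental * 100
}

#' Mean absolute retention-time error of a setpoint
#'
#' The per-setpoint summary statistic of validation tables: the arithmetic
#' mean of the absolute signed errors. (The absolute convention is the one
#' that reproduces published tables whose per-compound errors carry mixed
#' signs.) Rounding to 2 decimals is left to the reporting layer.
#'
#' @param error_pct Vector of signed percent errors.
#' @return Mean absolute error in percent.
#' @export
mean_abs_error <- function(error_pct) {
  if (length(error_pct) == 0L) {
    stop("cannot average an empty error vector", call. = FALSE)
  }
  mean(abs(error_pct))
}

#' Column-level summary of setpoint errors
#'
#' Averages the per-setpoint mean absolute errors (each setpoint weighted
#' equally, regardless of how many compounds it reports — the convention
#' that reproduces published column-level summaries).
#'
#' @param setpoint_means Vector of per-setpoint mean absolute errors (%).
#' @return Overall mean in percent.
#' @export
column_summary <- function(setpoint_means) {
  if (length(setpoint_means) == 0L) {
    stop("cannot summarize zero setpoints", call. = FALSE)
  }
  mean(setpoint_means)
}

#' Compare predicted and experimental retention times
#'
#' Builds the per-setpoint comparison report: one row per compound with the
#' signed error, plus the setpoint's mean absolute error via `glance()` on
#' the returned object or the `mean_abs_error_pct` attribute.
#'
#' @param data A data frame with columns `analyte`, `predicted_rt`,
#'   `experimental_rt` (and optionally `setpoint`).
#' @return A tibble of class `setpoint_report` with an added `error_pct`
#'   column; per-setpoint mean absolute errors are available through
#'   [glance.setpoint_report()].
#' @export
setpoint_report <- function(data) {
  stopifnot(is.data.frame(data))
  need <- c("analyte", "predicted_rt", "experimental_rt")
  if (!all(need %in% names(data))) {
    stop("data needs columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::mutate(
    tibble::as_tibble(data),
    error_pct = retention_error_pct(.data$predicted_rt, .data$experimental_rt))
  class(out) <- c("setpoint_report", class(out))
  out
}

#' @method tidy setpoint_report
#' @export
tidy.setpoint_report <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Summarize a setpoint comparison report
#'
#' @param x A [setpoint_report()].
#' @param digits Decimals for the reported means (default 2, matching table
#'   formatting; the unrounded value is in `mean_abs_error_raw`).
#' @param ... Unused.
#' @return One row per setpoint (or a single row when no `setpoint` column
#'   is present): `n`, `mean_abs_error_pct` (rounded half-up),
#'   `mean_abs_error_raw`.
#' @method glance setpoint_report
#' @export
glance.setpoint_report <- function(x, digits = 2, ...) {
  df <- tibble::as_tibble(x)
  if (!"setpoint" %in% names(df)) df$setpoint <- 1L
  df |>
    dplyr::group_by(.data$setpoint) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_abs_error_raw = mean_abs_error(.data$error_pct),
      .groups = "drop") |>
    dplyr::mutate(mean_abs_error_pct = round_half_up(.data$mean_abs_error_raw,
                                                     digits)) |>
    dplyr::select("setpoint", "n", "mean_abs_error_pct", "mean_abs_error_raw")
}

# round half away from zero, the convention of formatted report tables
# (base round() rounds half to even)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Repeatability statistics over replicate injections
#'
#' Sample mean and sample standard deviation (n - 1 denominator) of a
#' repeated measurement — retention times or critical resolutions over
#' consecutive injections.
#'
#' @param values Numeric vector of replicate measurements.
#' @return A one-row tibble: `n`, `mean`, `sd` (`NA` with a message when
#'   n < 2).
#' @export
repeatability_stats <- function(values) {
  if (!is.numeric(values) || length(values) == 0L) {
    stop("values must be a non-empty numeric vector", call. = FALSE)
  }
  n <- length(values)
  tibble::tibble(
    n = n,
    mean = mean(values),
    sd = if (n >= 2L) stats::sd(values) else NA_real_
  )
}
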