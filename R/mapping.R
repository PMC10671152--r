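#' Simulate a virtual chromatogram at a setpoint
#'
#' Predicts one peak per included analyte from the calibrated cube models
#' (coefficients interpolated to the setpoint's temperature and ternary
#' composition, retention solved under the setpoint's gradient, flow and
#' dwell), sorts peaks by retention time, and computes the resolution of
#' every adjacent pair, `Rs = 2 (tR2 - tR1) / (w1 + w2)` with 4-sigma
#' baseline widths. Excluding analytes never changes the predicted retention
#' of the remaining ones — exclusion only re-partitions the adjacent pairs.
#'
#' @param cube_set An [assemble_cube()] result.
#' @param program A [gradient_program()].
#' @param conditions A [run_conditions()].
#' @param column A [column_spec()].
#' @param instrument An [instrument_spec()].
#' @param include Character vector of analytes to simulate; default all.
#' @param compression Band-compression factor for the width model.
#' @return An object of class `virtual_chromatogram`: a list with `peaks`
#'   (tibble sorted by `rt_min`), `resolutions` (tibble of adjacent pairs)
#'   and `critical` (limiting pair and its Rs; `NULL` with fewer than two
#'   peaks).
#' @export
simulate_separation <- function(cube_set, program, conditions, column,
                                instrument, include = NULL,
                                compression = 1.0) {
  stopifnot(inherits(cube_set, "lss_cube_set"))
  if (is.null(include)) include <- names(cube_set$models)
  if (length(include) == 0L) {
    stop("include must name at least one analyte", call. = FALSE)
  }
  unknown <- setdiff(include, names(cube_set$models))
  if (length(unknown)) {
    stop("analyte(s) not in the model set: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  peaks <- purrr::map_dfr(include, function(a) {
    cf <- interpolate_coefficients(cube_set$models[[a]], conditions$temp_c,
                                   conditions$ternary_fraction)
    predict_peak(cf, program, conditions, column, instrument,
                 analyte_id = a, compression = compression)
  })
  peaks <- dplyr::arrange(peaks, .data$rt_min)
  res <- adjacent_resolutions(peaks)
  structure(list(peaks = peaks, resolutions = res,
                 critical = critical_from_resolutions(res)),
            class = "virtual_chromatogram")
}

# Rs for every adjacent pair of an rt-sorted peak table.
adjacent_resolutions <- function(peaks) {
  n <- nrow(peaks)
  if (n < 2L) {
    return(tibble::tibble(first = character(), second = character(),
                          rs = numeric()))
  }
  tibble::tibble(
    first = peaks$analyte[-n],
    second = peaks$analyte[-1],
    rs = 2 * diff(peaks$rt_min) / (peaks$width_min[-n] + peaks$width_min[-1])
  )
}

critical_from_resolutions <- function(res) {
  if (nrow(res) == 0L) return(NULL)
  i <- which.min(res$rs) # which.min takes the first minimum: earlier pair wins ties
  list(first = res$first[i], second = res$second[i], rs = res$rs[i])
}

#' @export
print.virtual_chromatogram <- function(x, ...) {
  cat(sprintf("<virtual_chromatogram> %d peaks\n", nrow(x$peaks)))
  print(x$peaks)
  if (!is.null(x$critical)) {
    cat(sprintf("  Rs,crit = %.2f (%s / %s)\n", x$critical$rs,
                x$critical$first, x$critical$second))
  } else {
    cat("  Rs,crit: undefined (fewer than two peaks)\n")
  }
  invisible(x)
}

#' Critical resolution of a chromatogram
#'
#' The minimum resolution over adjacent peak pairs — the quantity mapped
#' over the design space. Ties go to the earlier-eluting pair.
#'
#' @param chromatogram A `virtual_chromatogram`.
#' @return A one-row tibble (`first`, `second`, `rs`), or a zero-row tibble
#'   when the chromatogram has fewer than two peaks.
#' @export
critical_resolution <- function(chromatogram) {
  stopifnot(inherits(chromatogram, "virtual_chromatogram"))
  cr <- chromatogram$critical
  if (is.null(cr)) {
    return(tibble::tibble(first = character(), second = character(),
                          rs = numeric()))
  }
  tibble::tibble(first = cr$first, second = cr$second, rs = cr$rs)
}

#' Map the critical resolution over the design space
#'
#' Evaluates [simulate_separation()] on every cell of a tG x T x tC grid and
#' records the critical resolution and its limiting pair. Grid axes outside
#' the calibrated ranges trigger a warning (temperature extrapolation beyond
#' 10 degC is an error). All corner runs share the design's ramp shape
#' (phi0 -> phif over tG) and the supplied flow.
#'
#' @param cube_set An [assemble_cube()] result.
#' @param column A [column_spec()].
#' @param instrument An [instrument_spec()].
#' @param tG_grid,T_grid,tC_grid Numeric axes of the map. Defaults span the
#'   calibrated cube: 21 tG points, 31 temperatures, 11 ternary fractions.
#' @param flow Flow rate for the mapped methods; defaults to the
#'   calibration flow.
#' @param include Analyte subset to map; default all.
#' @param compression Band-compression factor.
#' @return An object of class `resolution_map`: a tibble with one row per
#'   cell (`tG_min`, `temp_c`, `ternary_fraction`, `rs_crit`, `pair`) plus
#'   axis metadata.
#' @export
compute_resolution_map <- function(cube_set, column, instrument,
                                   tG_grid = NULL, T_grid = NULL,
                                   tC_grid = NULL, flow = NULL,
                                   include = NULL, compression = 1.0) {
  stopifnot(inherits(cube_set, "lss_cube_set"))
  spec <- cube_set$spec
  if (is.null(tG_grid)) tG_grid <- seq(spec$tG_levels[1], spec$tG_levels[2],
                                       length.out = 21)
  if (is.null(T_grid)) T_grid <- seq(spec$T_levels[1], spec$T_levels[2],
                                     length.out = 31)
  if (is.null(tC_grid)) tC_grid <- seq(min(spec$tC_levels), max(spec$tC_levels),
                                       length.out = 11)
  if (is.null(flow)) flow <- cube_set$flow
  if (any(T_grid < spec$T_levels[1] | T_grid > spec$T_levels[2]) ||
      any(tC_grid < min(spec$tC_levels) | tC_grid > max(spec$tC_levels))) {
    warning("map grid extends beyond the calibrated ranges; treat extrapolated cells with care",
            call. = FALSE)
  }
  cells <- tidyr::expand_grid(ternary_fraction = tC_grid, temp_c = T_grid,
                              tG_min = tG_grid)
  rows <- purrr::pmap_dfr(cells, function(ternary_fraction, temp_c, tG_min) {
    prog <- gradient_program(c(0, tG_min), c(spec$phi0, spec$phif))
    cond <- run_conditions(flow = flow, temp_c = temp_c,
                           ternary_fraction = ternary_fraction)
    chrom <- simulate_separation(cube_set, prog, cond, column, instrument,
                                 include = include,
                                 compression = compression)
    cr <- chrom$critical
    tibble::tibble(tG_min = tG_min, temp_c = temp_c,
                   ternary_fraction = ternary_fraction,
                   rs_crit = if (is.null(cr)) NA_real_ else cr$rs,
                   pair = if (is.null(cr)) NA_character_ else
                     paste(cr$first, cr$second, sep = " / "))
  })
  structure(rows,
            class = c("resolution_map", class(rows)),
            axes = list(tG_min = tG_grid, temp_c = T_grid,
                        ternary_fraction = tC_grid),
            flow = flow,
            include = if (is.null(include)) names(cube_set$models) else include)
}

#' Extract the method operable design region (MODR)
#'
#' Cells of a resolution map whose critical resolution meets the baseline
#' criterion (default Rs >= 1.5). An empty MODR is a valid, informative
#' result: it means no parameter combination in the studied ranges separates
#' the included peaks.
#'
#' @param map A [compute_resolution_map()] result.
#' @param threshold Minimum acceptable critical resolution (default 1.5).
#' @return A list: `cells` (tibble of passing cells), `n_pass`, `n_total`,
#'   `fraction`, `threshold`.
#' @export
extract_modr <- function(map, threshold = 1.5) {
  stopifnot(inherits(map, "resolution_map"))
  pass <- dplyr::filter(tibble::as_tibble(map), .data$rs_crit >= threshold)
  list(cells = pass, n_pass = nrow(pass), n_total = nrow(map),
       fraction = nrow(pass) / nrow(map), threshold = threshold)
}

#' In-silico robustness scan around a setpoint
#'
#' Evaluates the critical resolution on a full-factorial grid of small
#' deviations around a nominal method: each parameter with a nonzero
#' tolerance takes `levels` equally spaced values in nominal +/- delta.
#' The nominal point is always part of the factorial, so the worst case can
#' never exceed it spuriously. Ternary fractions pushed outside \[0, 1\] are
#' clipped with a warning.
#'
#' @param cube_set An [assemble_cube()] result.
#' @param column A [column_spec()].
#' @param instrument An [instrument_spec()].
#' @param tG Nominal gradient time (min); the scanned program is the design
#'   ramp over tG.
#' @param conditions Nominal [run_conditions()].
#' @param tolerances Named list of half-widths: any of `tG` (min), `temp_c`
#'   (degC), `ternary_fraction`, `flow` (mL/min). Omitted or zero entries are
#'   held at nominal.
#' @param levels Points per varied parameter, 2 or 3 (default 3; 3 includes
#'   the nominal level).
#' @param include Analyte subset.
#' @return A list: `table` (one row per combination with the varied
#'   parameters and `rs_crit`), `nominal`, `worst`, `best`.
#' @export
robustness_scan <- function(cube_set, column, instrument, tG, conditions,
                            tolerances = list(), levels = 3,
                            include = NULL) {
  stopifnot(inherits(cube_set, "lss_cube_set"))
  if (!levels %in% c(2, 3)) stop("levels must be 2 or 3", call. = FALSE)
  tol <- function(name) {
    v <- tolerances[[name]]
    if (is.null(v)) 0 else v
  }
  if (any(unlist(tolerances) < 0)) {
    stop("tolerances must be >= 0", call. = FALSE)
  }
  vals <- function(nominal, delta) {
    if (delta == 0) return(nominal)
    seq(nominal - delta, nominal + delta, length.out = levels)
  }
  x_vals <- vals(conditions$ternary_fraction, tol("ternary_fraction"))
  if (any(x_vals < 0 | x_vals > 1)) {
    warning("ternary tolerance exceeds [0, 1]; deviated levels clipped",
            call. = FALSE)
    x_vals <- unique(pmin(pmax(x_vals, 0), 1))
  }
  grid <- tidyr::expand_grid(
    tG_min = vals(tG, tol("tG")),
    temp_c = vals(conditions$temp_c, tol("temp_c")),
    ternary_fraction = x_vals,
    flow_ml_min = vals(conditions$flow, tol("flow"))
  )
  spec <- cube_set$spec
  grid$rs_crit <- purrr::pmap_dbl(grid, function(tG_min, temp_c,
                                                 ternary_fraction,
                                                 flow_ml_min) {
    prog <- gradient_program(c(0, tG_min), c(spec$phi0, spec$phif))
    cond <- run_conditions(flow = flow_ml_min, temp_c = temp_c,
                           ternary_fraction = ternary_fraction)
    chrom <- simulate_separation(cube_set, prog, cond, column, instrument,
                                 include = include)
    if (is.null(chrom$critical)) NA_real_ else chrom$critical$rs
  })
  nominal_chrom <- simulate_separation(
    cube_set, gradient_program(c(0, tG), c(spec$phi0, spec$phif)),
    conditions, column, instrument, include = include)
  nominal_rs <- if (is.null(nominal_chrom$critical)) NA_real_ else
    nominal_chrom$critical$rs
  # with 2 levels the nominal is not a factorial level; carry it as its own row
  if (!any(grid$tG_min == tG & grid$temp_c == conditions$temp_c &
           grid$ternary_fraction == conditions$ternary_fraction &
           grid$flow_ml_min == conditions$flow)) {
    grid <- dplyr::bind_rows(grid, tibble::tibble(
      tG_min = tG, temp_c = conditions$temp_c,
      ternary_fraction = conditions$ternary_fraction,
      flow_ml_min = conditions$flow, rs_crit = nominal_rs))
  }
  list(table = grid,
       nominal = nominal_rs,
       worst = min(grid$rs_crit, na.rm = TRUE),
       best = max(grid$rs_crit, na.rm = TRUE))
}

#' Heat-map of a resolution map
#'
#' One tG x T panel per ternary-composition level, coloured by critical
#' resolution; cells meeting the MODR criterion are outlined.
#'
#' @param object A [compute_resolution_map()] result.
#' @param threshold MODR criterion drawn as a fill midpoint (default 1.5).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot resolution_map
#' @export
autoplot.resolution_map <- function(object, threshold = 1.5, ...) {
  df <- tibble::as_tibble(object)
  df$tc_label <- sprintf("x(MeOH) = %.2f", df$ternary_fraction)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tG_min, y = .data$temp_c,
                                   fill = .data$rs_crit)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "grey20", mid = "goldenrod",
                                  high = "firebrick", midpoint = threshold,
                                  name = "Rs,crit") +
    ggplot2::facet_wrap(~tc_label) +
    ggplot2::labs(x = "gradient time tG (min)",
                  y = "column temperature (°C)") +
    ggplot2::theme_minimal()
}

#' Stick plot of a virtual chromatogram
#'
#' @param object A `virtual_chromatogram`.
#' @param ... Unused.
#' @return A ggplot object: Gaussian peak outlines at the predicted
#'   positions and widths, labelled by analyte.
#' @method autoplot virtual_chromatogram
#' @export
autoplot.virtual_chromatogram <- function(object, ...) {
  pk <- object$peaks
  grid <- purrr::pmap_dfr(pk, function(analyte, rt_min, width_min, ...) {
    sigma <- width_min / 4
    t <- seq(rt_min - 4 * sigma, rt_min + 4 * sigma, length.out = 80)
    tibble::tibble(analyte = analyte, t = t,
                   y = exp(-(t - rt_min)^2 / (2 * sigma^2)))
  })
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$t, y = .data$y,
                                     group = .data$analyte)) +
    ggplot2::geom_line() +
    ggplot2::geom_text(data = pk,
                       ggplot2::aes(x = .data$rt_min, y = 1.05,
                                    label = .data$analyte),
                       angle = 90, hjust = 0, size = 2.7,
                       inherit.aes = FALSE) +
    ggplot2::scale_y_continuous(limits = c(0, 1.6), breaks = c(0, 0.5, 1)) +
    ggplot2::labs(x = "time (min)", y = "relative response") +
    ggplot2::theme_minimal()
}
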