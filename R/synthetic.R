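#' Draw a ground-truth analyte panel
#'
#' Generates per-analyte retention-parameter truths from which corner runs,
#' setpoint chromatograms and mixture peak lists can be forward-simulated.
#' Each analyte follows the same law family the calibration assumes:
#' `log_kw` and `S` linear in 1/T (van't Hoff) and quadratic in the ternary
#' fraction. Base values are drawn as `log_kw ~ U[1.5, 4.5]` and
#' `S ~ U[3, 8]`; the van't Hoff slope corresponds to a 1-3% decrease in k
#' per degree; ternary perturbations have amplitude at most 0.5 (log_kw)
#' and 1.5 (S). Draws whose induced corner retention times leave the
#' plausible window (elution after the dead time plus dwell, before 1.5x
#' the run length) are resampled with a bounded number of attempts.
#'
#' When `n_analytes = 9` the panel carries the ezetimibe study roster and
#' its nominal concentrations; otherwise analytes are labelled generically
#' with concentrations drawn in 4-16 ug/mL.
#'
#' @param n_analytes Number of analytes (default 9).
#' @param seed Integer seed; identical seeds give identical panels.
#' @param design The [design_spec()] whose corner runs the truths must
#'   elute sensibly under.
#' @param column,instrument System the constraint check simulates with.
#' @param max_attempts Resampling budget per analyte.
#' @return A tibble of class `analyte_truth` with one row per analyte.
#' @export
sample_truth <- function(n_analytes = 9, seed = 1, design = design_spec(),
                         column = default_column(),
                         instrument = instrument_spec(),
                         max_attempts = 500) {
  if (n_analytes < 1) stop("n_analytes must be at least 1", call. = FALSE)
  set.seed(seed)
  Tlo <- design$T_levels[1]; Thi <- design$T_levels[2]
  invT_mid <- mean(1 / kelvin(c(Tlo, Thi)))
  T_mid_K <- 1 / invT_mid

  roster <- if (n_analytes == 9) ezetimibe_scheme() else NULL
  names_out <- if (!is.null(roster)) {
    roster$analytes
  } else {
    sprintf("analyte%02d", seq_len(n_analytes))
  }
  concs <- if (!is.null(roster)) {
    comp <- roster$composition
    vapply(names_out, function(a) {
      comp$conc_ug_ml[comp$analyte == a][1]
    }, numeric(1))
  } else {
    stats::runif(n_analytes, 4, 16)
  }

  t0 <- dead_time(column, design$flow)
  tD <- dwell_time(instrument, design$flow)
  corner <- build_design(design)

  draw_one <- function() {
    p_per_degC <- stats::runif(1, 0.01, 0.03)
    list(
      base_log_kw = stats::runif(1, 1.5, 4.5),
      vh_log_kw = p_per_degC * T_mid_K^2 / log(10),
      tc_lin_log_kw = stats::runif(1, -0.25, 0.25),
      tc_quad_log_kw = stats::runif(1, -0.25, 0.25),
      base_S = stats::runif(1, 3, 8),
      vh_S = stats::runif(1, -100, 100),
      tc_lin_S = stats::runif(1, -0.75, 0.75),
      tc_quad_S = stats::runif(1, -0.75, 0.75)
    )
  }

  eval_law <- function(par, temp_c, x) {
    dInvT <- 1 / kelvin(temp_c) - invT_mid
    lss(par$base_log_kw + par$vh_log_kw * dInvT +
          par$tc_lin_log_kw * x + par$tc_quad_log_kw * x^2,
        max(par$base_S + par$vh_S * dInvT +
              par$tc_lin_S * x + par$tc_quad_S * x^2, 0))
  }

  admissible <- function(par) {
    for (i in seq_len(nrow(corner))) {
      cf <- eval_law(par, corner$temp_c[i], corner$ternary_fraction[i])
      if (cf$S < 0.5) return(FALSE)
      prog <- gradient_program(c(0, corner$tG_min[i]),
                               c(design$phi0, design$phif))
      sol <- solve_migration(cf, prog, t0, tD)
      tR <- t0 + sol$te
      if (tR < t0 + tD + 1) return(FALSE)       # must outlast the dwell
      if (tR > 1.5 * corner$tG_min[i]) return(FALSE)
    }
    TRUE
  }

  rows <- purrr::map(seq_len(n_analytes), function(i) {
    for (a in seq_len(max_attempts)) {
      par <- draw_one()
      if (admissible(par)) {
        return(tibble::tibble(
          analyte = names_out[i], !!!par,
          conc_ug_ml = concs[[i]],
          response = stats::runif(1, 0.8, 1.25)))
      }
    }
    stop("could not draw an admissible truth for analyte ", i,
         " within ", max_attempts, " attempts", call. = FALSE)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "invT_mid") <- invT_mid
  attr(out, "design") <- design
  class(out) <- c("analyte_truth", class(out))
  out
}

#' Default 250 x 4.6 mm column
#'
#' The shared geometry of the study columns (250 x 4.6 mm); 10 um particles
#' unless overridden.
#'
#' @param particle_um Particle size (default 10).
#' @return A [column_spec()].
#' @export
default_column <- function(particle_um = 10) {
  column_spec(250, 4.6, particle_um = particle_um)
}

#' Evaluate a truth law at arbitrary conditions
#'
#' The ground-truth counterpart of [interpolate_coefficients()]: exact
#' coefficients of one truth analyte at any temperature and ternary
#' fraction.
#'
#' @param truth An [sample_truth()] panel.
#' @param analyte Analyte name.
#' @param temp_c Temperature (degC).
#' @param x Ternary fraction.
#' @return An [lss()] pair.
#' @export
truth_coefficients <- function(truth, analyte, temp_c, x) {
  stopifnot(inherits(truth, "analyte_truth"))
  row <- truth[truth$analyte == analyte, ]
  if (nrow(row) != 1L) stop("unknown analyte: ", analyte, call. = FALSE)
  dInvT <- 1 / kelvin(temp_c) - attr(truth, "invT_mid")
  S <- row$base_S + row$vh_S * dInvT + row$tc_lin_S * x + row$tc_quad_S * x^2
  lss(row$base_log_kw + row$vh_log_kw * dInvT +
        row$tc_lin_log_kw * x + row$tc_quad_log_kw * x^2,
      max(S, 0))
}

#' Forward-simulate a corner-run table
#'
#' Runs every (corner run, analyte) pair of the design through the
#' retention engine at the truth coefficients, adds additive Gaussian
#' retention-time noise and multiplicative Gaussian area noise, and emits a
#' complete calibration table.
#'
#' @param truth An [sample_truth()] panel.
#' @param design A [design_spec()]; defaults to the design the truth was
#'   drawn for.
#' @param column,instrument System description.
#' @param rt_noise_sd Additive retention-time noise SD in minutes
#'   (default 0.02).
#' @param area_cv Multiplicative area noise CV (default 0.03).
#' @param seed Seed for the noise draws.
#' @return A corner-run tibble (`run_id`, `tG_min`, `temp_c`,
#'   `ternary_fraction`, `flow_ml_min`, `analyte`, `rt_min`, `area`).
#' @export
simulate_corner_table <- function(truth, design = attr(truth, "design"),
                                  column = default_column(),
                                  instrument = instrument_spec(),
                                  rt_noise_sd = 0.02, area_cv = 0.03,
                                  seed = 1) {
  stopifnot(inherits(truth, "analyte_truth"))
  if (rt_noise_sd < 0 || area_cv < 0) {
    stop("noise magnitudes must be >= 0", call. = FALSE)
  }
  set.seed(seed)
  runs <- build_design(design)
  out <- tidyr::expand_grid(run_id = runs$run_id, analyte = truth$analyte)
  out <- dplyr::left_join(out, runs, by = "run_id")
  cond <- function(flow, temp_c, x) run_conditions(flow, temp_c, x)
  out$rt_min <- purrr::pmap_dbl(
    out[, c("analyte", "tG_min", "temp_c", "ternary_fraction", "flow_ml_min")],
    function(analyte, tG_min, temp_c, ternary_fraction, flow_ml_min) {
      cf <- truth_coefficients(truth, analyte, temp_c, ternary_fraction)
      prog <- gradient_program(c(0, tG_min), c(design$phi0, design$phif))
      predict_retention_time(cf, prog,
                             cond(flow_ml_min, temp_c, ternary_fraction),
                             column, instrument)
    })
  n <- nrow(out)
  out$rt_min <- out$rt_min + stats::rnorm(n, 0, rt_noise_sd)
  base_area <- truth$conc_ug_ml * truth$response
  names(base_area) <- truth$analyte
  out$area <- base_area[out$analyte] * (1 + stats::rnorm(n, 0, area_cv))
  dplyr::select(out, "run_id", "tG_min", "temp_c", "ternary_fraction",
                "flow_ml_min", "analyte", "rt_min", "area")
}

#' Simulate the mixture injections of one condition
#'
#' For peak tracking every design condition is injected once per mixture of
#' the spiking scheme. This renders those peak lists: each mixture contains
#' only its member analytes, retention times agree across mixtures up to
#' replicate noise, and areas follow the scheme's concentrations times the
#' analyte's response factor.
#'
#' @param truth An [sample_truth()] panel.
#' @param scheme A [mixture_scheme()] over (a subset of) the truth panel.
#' @param program A [gradient_program()] for the condition.
#' @param conditions A [run_conditions()].
#' @param column,instrument System description.
#' @param rt_noise_sd Replicate retention-time noise SD (min).
#' @param area_cv Area noise CV.
#' @param seed Seed.
#' @return A tibble of observed peaks: `mixture_id`, `analyte_true`
#'   (ground-truth label, for scoring), `rt_min`, `area`.
#' @export
render_mixture_peaklists <- function(truth, scheme, program, conditions,
                                     column = default_column(),
                                     instrument = instrument_spec(),
                                     rt_noise_sd = 0.02, area_cv = 0.03,
                                     seed = 1) {
  stopifnot(inherits(truth, "analyte_truth"), inherits(scheme, "mixture_scheme"))
  unknown <- setdiff(scheme$analytes, truth$analyte)
  if (length(unknown)) {
    stop("scheme references analytes missing from the truth panel: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  set.seed(seed)
  clean_rt <- vapply(scheme$analytes, function(a) {
    cf <- truth_coefficients(truth, a, conditions$temp_c,
                             conditions$ternary_fraction)
    predict_retention_time(cf, program, conditions, column, instrument)
  }, numeric(1))
  responses <- truth$response
  names(responses) <- truth$analyte
  purrr::map_dfr(scheme$mixtures, function(m) {
    comp <- scheme$composition[scheme$composition$mixture_id == m, ]
    n <- nrow(comp)
    tibble::tibble(
      mixture_id = m,
      analyte_true = comp$analyte,
      rt_min = clean_rt[comp$analyte] + stats::rnorm(n, 0, rt_noise_sd),
      area = comp$conc_ug_ml * responses[comp$analyte] *
        (1 + stats::rnorm(n, 0, area_cv))
    )
  })
}

#' Render a detector-style trace from predicted peaks
#'
#' Sums Gaussian peaks (sigma = width / 4, height scaled so each peak
#' integrates to its area) on a uniform time grid and adds baseline noise.
#'
#' @param peaks A tibble with `rt_min`, `width_min`, `area` columns (e.g.
#'   the `peaks` element of a [simulate_separation()] result with an added
#'   `area` column).
#' @param sampling_hz Detector sampling rate in Hz (> 0).
#' @param baseline_sd Baseline noise SD in signal units.
#' @param t_range Time window (min); defaults to span all peaks with a
#'   margin.
#' @param seed Seed for the baseline noise.
#' @return A tibble: `time_min`, `intensity`.
#' @export
render_trace <- function(peaks, sampling_hz = 5, baseline_sd = 0,
                         t_range = NULL, seed = 1) {
  if (sampling_hz <= 0) stop("sampling_hz must be positive", call. = FALSE)
  set.seed(seed)
  if (is.null(t_range)) {
    if (nrow(peaks) == 0L) {
      t_range <- c(0, 1)
    } else {
      t_range <- c(max(0, min(peaks$rt_min - 2 * peaks$width_min)),
                   max(peaks$rt_min + 2 * peaks$width_min))
    }
  }
  t <- seq(t_range[1], t_range[2], by = 1 / (sampling_hz * 60))
  y <- numeric(length(t))
  if (nrow(peaks) > 0L) {
    for (i in seq_len(nrow(peaks))) {
      sigma <- peaks$width_min[i] / 4
      area <- if ("area" %in% names(peaks)) peaks$area[i] else 1
      y <- y + area / (sigma * sqrt(2 * pi)) *
        exp(-(t - peaks$rt_min[i])^2 / (2 * sigma^2))
    }
  }
  if (baseline_sd > 0) y <- y + stats::rnorm(length(t), 0, baseline_sd)
  tibble::tibble(time_min = t, intensity = y)
}
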