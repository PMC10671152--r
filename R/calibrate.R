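#' Specify the calibration design
#'
#' The calibration design is a tG x T x tC cube: two gradient times, two
#' column temperatures and three ternary compositions of the organic
#' modifier, all run as the same linear ramp at the same flow. The defaults
#' are the conditions of the reference study: tG in \{20, 60\} min, T in
#' \{5, 35\} degC, tC in \{100% ACN, 50/50, 100% MeOH\}, gradient 30 -> 100% B
#' at 0.5 mL/min.
#'
#' @param tG_levels Two gradient times (min); a ratio of at least 3 between
#'   them is recommended and a warning is issued otherwise.
#' @param T_levels Two column temperatures (degC).
#' @param tC_levels Ternary fractions (0 = pure primary organic). Three
#'   levels support quadratic ternary interpolation; a two-level design can
#'   be enumerated but not calibrated into a ternary cube.
#' @param phi0,phif Initial and final organic fraction of the ramp.
#' @param flow Flow rate (mL/min).
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(tG_levels = c(20, 60), T_levels = c(5, 35),
                        tC_levels = c(0, 0.5, 1), phi0 = 0.30, phif = 1.00,
                        flow = 0.5) {
  if (length(tG_levels) != 2L || any(tG_levels <= 0)) {
    stop("exactly 2 positive tG levels are required", call. = FALSE)
  }
  tG_levels <- sort(tG_levels)
  if (tG_levels[1] == tG_levels[2]) {
    stop("the two tG levels must differ (two-run fitting is impossible otherwise)",
         call. = FALSE)
  }
  if (tG_levels[2] / tG_levels[1] < 3) {
    warning("a tG ratio of at least 3 between the two gradient times is recommended",
            call. = FALSE)
  }
  if (length(T_levels) != 2L || T_levels[1] == T_levels[2]) {
    stop("exactly 2 distinct T levels are required", call. = FALSE)
  }
  if (!length(tC_levels) %in% c(2L, 3L) || anyDuplicated(tC_levels) ||
      any(tC_levels < 0 | tC_levels > 1)) {
    stop("2 or 3 distinct tC levels in [0, 1] are required (3 for ternary interpolation)",
         call. = FALSE)
  }
  if (!(phi0 < phif)) stop("phi0 must be smaller than phif", call. = FALSE)
  if (flow <= 0) stop("flow must be positive", call. = FALSE)
  structure(list(tG_levels = tG_levels, T_levels = sort(T_levels),
                 tC_levels = sort(tC_levels), phi0 = phi0, phif = phif,
                 flow = flow),
            class = "design_spec")
}

#' @export
print.design_spec <- function(x, ...) {
  cat(sprintf("<design_spec> tG {%s} min x T {%s} degC x tC {%s}\n",
              paste(x$tG_levels, collapse = ", "),
              paste(x$T_levels, collapse = ", "),
              paste(x$tC_levels, collapse = ", ")))
  cat(sprintf("  ramp %g%% -> %g%% B at %g mL/min; %d corner runs\n",
              100 * x$phi0, 100 * x$phif, x$flow,
              2L * 2L * length(x$tC_levels)))
  invisible(x)
}

#' Enumerate the corner runs of a design
#'
#' Expands the design cube into its corner-run conditions in a deterministic
#' order (tC outermost, then T, then tG), one row per run. The default design
#' yields the 12-run 3^1 x 2^2 plan.
#'
#' @param spec A [design_spec()].
#' @return A tibble with columns `run_id`, `tG_min`, `temp_c`,
#'   `ternary_fraction`, `flow_ml_min`, `phi0`, `phif`.
#' @examples
#' nrow(build_design(design_spec())) # 12
#' @export
build_design <- function(spec = design_spec()) {
  stopifnot(inherits(spec, "design_spec"))
  grid <- tidyr::expand_grid(
    ternary_fraction = spec$tC_levels,
    temp_c = spec$T_levels,
    tG_min = spec$tG_levels
  )
  tibble::tibble(
    run_id = sprintf("run%02d", seq_len(nrow(grid))),
    tG_min = grid$tG_min,
    temp_c = grid$temp_c,
    ternary_fraction = grid$ternary_fraction,
    flow_ml_min = spec$flow,
    phi0 = spec$phi0,
    phif = spec$phif
  )
}

# Snyder-style two-run initial estimate for (log_kw, S): treats both runs as
# single linear ramps, uses the large-k0*b approximation of the closed-form
# LSS equation. Good enough to seed Newton; never returned as a fit.
two_run_initial_guess <- function(tR1, tR2, tG1, tG2, phi0, phif, t0, tD) {
  beta <- tG2 / tG1
  tr1 <- max(tR1 - t0 - tD, 1e-3)
  tr2 <- max(tR2 - t0 - tD, 1e-3)
  denom <- tr1 - tr2 / beta
  if (denom <= 0) return(c(log_kw = 2, S = 5))
  b1 <- t0 * log10(beta) / denom
  log_k0 <- tr1 * b1 / t0 - log10(2.303 * b1)
  S <- b1 * tG1 / (t0 * (phif - phi0))
  c(log_kw = log_k0 + S * phi0, S = S)
}

#' Fit LSS coefficients from a two-gradient-run pair
#'
#' Recovers `(log_kw, S)` for one analyte at one (T, tC) node from its
#' retention times in the short- and long-gradient corner runs. The fit
#' targets the full forward model (dwell and hold segments included), solved
#' by a damped 2-D Newton iteration on the residual vector with a
#' Snyder-style two-run approximation as initial guess and a deterministic
#' multi-start grid as fallback. Coefficients are constrained to
#' `log_kw` in \[-2, 12\] and `S` in \[0.1, 100\].
#'
#' @param tR_short,tR_long Measured retention times (min) in the short and
#'   long gradient runs.
#' @param tG_short,tG_long The two gradient times (min).
#' @param phi0,phif Ramp limits shared by both runs.
#' @param flow Flow rate (mL/min) of the corner runs.
#' @param column A [column_spec()].
#' @param instrument An [instrument_spec()].
#' @param tol Convergence tolerance on both residuals (min); default 1e-4.
#' @return An [lss()] pair with attribute `residual_min` (max abs residual).
#' @export
fit_node_coefficients <- function(tR_short, tR_long, tG_short, tG_long,
                                  phi0 = 0.30, phif = 1.00, flow = 0.5,
                                  column, instrument, tol = 1e-4) {
  t0 <- dead_time(column, flow)
  tD <- dwell_time(instrument, flow)
  if (tR_short <= t0 + 1e-6 || tR_long <= t0 + 1e-6) {
    stop("unidentifiable parameters: solute is unretained (tR <= t0) in at ",
         "least one run", call. = FALSE)
  }
  cond <- run_conditions(flow = flow, temp_c = 25)
  prog_s <- gradient_program(c(0, tG_short), c(phi0, phif))
  prog_l <- gradient_program(c(0, tG_long), c(phi0, phif))
  target <- c(tR_short, tR_long)

  resid <- function(par) {
    cf <- lss(par[1], par[2])
    c(predict_retention_time(cf, prog_s, cond, column, instrument),
      predict_retention_time(cf, prog_l, cond, column, instrument)) - target
  }
  clamp <- function(par) {
    c(min(max(par[1], -2), 12), min(max(par[2], 0.1), 100))
  }
  newton <- function(par, iters = 60, ctol = 1e-9) {
    par <- clamp(par)
    f <- resid(par)
    for (i in seq_len(iters)) {
      if (max(abs(f)) < ctol) break
      h <- pmax(abs(par), 1) * 1e-6
      J <- matrix(0, 2, 2)
      for (j in 1:2) {
        pj <- par; pj[j] <- pj[j] + h[j]
        J[, j] <- (resid(clamp(pj)) - f) / h[j]
      }
      step <- tryCatch(solve(J, -f), error = function(e) NULL)
      if (is.null(step)) break
      lambda <- 1
      repeat {
        cand <- clamp(par + lambda * step)
        fc <- tryCatch(resid(cand), error = function(e) rep(Inf, 2))
        if (sum(fc^2) < sum(f^2) || lambda < 1e-4) break
        lambda <- lambda / 2
      }
      if (!all(is.finite(fc)) || sum(fc^2) >= sum(f^2)) break
      par <- cand; f <- fc
    }
    list(par = par, resid = max(abs(f)))
  }

  starts <- list(two_run_initial_guess(tR_short, tR_long, tG_short, tG_long,
                                       phi0, phif, t0, tD))
  best <- NULL
  for (st in starts) {
    fit <- newton(st)
    if (is.null(best) || fit$resid < best$resid ||
        (fit$resid == best$resid && fit$par[2] < best$par[2])) best <- fit
    if (best$resid < tol) break
  }
  if (best$resid >= tol) {
    # deterministic fallback grid, ordered; smallest S wins residual ties
    grid <- tidyr::expand_grid(log_kw = c(1, 2, 3, 4, 5, 6, 8),
                               S = c(2, 4, 6, 10, 20, 40))
    for (i in seq_len(nrow(grid))) {
      fit <- newton(c(grid$log_kw[i], grid$S[i]))
      if (fit$resid < best$resid ||
          (fit$resid == best$resid && fit$par[2] < best$par[2])) best <- fit
      if (best$resid < tol) break
    }
  }
  if (best$resid >= tol) {
    stop(sprintf(paste0("node fit failed: residual %.3g min exceeds tolerance ",
                        "%.1g min (tR = %.3f / %.3f)"),
                 best$resid, tol, tR_short, tR_long), call. = FALSE)
  }
  out <- lss(best$par[1], best$par[2])
  attr(out, "residual_min") <- best$resid
  out
}

#' Calibrate coefficient surfaces over the design cube
#'
#' Fits one `(log_kw, S)` pair per analyte per (T, tC) node — each node from
#' its two gradient-time runs — and wraps the six node fits into a cube model
#' that can be interpolated continuously in temperature (linearly in 1/T, the
#' van't Hoff form) and ternary composition (quadratically through the three
#' tC levels).
#'
#' @param table A corner-run table: one row per (run, analyte) with columns
#'   `tG_min`, `temp_c`, `ternary_fraction`, `flow_ml_min`, `analyte`,
#'   `rt_min` (see [read_corner_table()]).
#' @param spec The [design_spec()] the table realizes.
#' @param column A [column_spec()].
#' @param instrument An [instrument_spec()].
#' @return An object of class `lss_cube_set`: one cube model per analyte,
#'   with fit residuals recorded per node.
#' @export
assemble_cube <- function(table, spec = design_spec(), column, instrument) {
  stopifnot(is.data.frame(table))
  need <- c("tG_min", "temp_c", "ternary_fraction", "analyte", "rt_min")
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols)) {
    stop("corner-run table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (length(spec$tC_levels) != 3L) {
    stop("cube calibration requires exactly 3 ternary-composition levels",
         call. = FALSE)
  }
  flow <- if ("flow_ml_min" %in% names(table)) table$flow_ml_min[1] else spec$flow

  cells <- tidyr::expand_grid(ternary_fraction = spec$tC_levels,
                              temp_c = spec$T_levels,
                              tG_min = spec$tG_levels)
  analytes <- unique(table$analyte)
  models <- purrr::map(analytes, function(a) {
    sub <- dplyr::filter(table, .data$analyte == a)
    have <- dplyr::distinct(sub, .data$tG_min, .data$temp_c, .data$ternary_fraction)
    gaps <- dplyr::anti_join(cells, have,
                             by = c("tG_min", "temp_c", "ternary_fraction"))
    if (nrow(gaps) > 0) {
      stop("incomplete design for analyte '", a, "': missing cell(s) ",
           paste(sprintf("(tG=%g, T=%g, tC=%g)", gaps$tG_min, gaps$temp_c,
                         gaps$ternary_fraction), collapse = "; "),
           call. = FALSE)
    }
    nodes <- tidyr::expand_grid(ternary_fraction = spec$tC_levels,
                                temp_c = spec$T_levels)
    node_fits <- purrr::pmap(nodes, function(ternary_fraction, temp_c) {
      rows <- dplyr::filter(sub, .data$temp_c == !!temp_c,
                            .data$ternary_fraction == !!ternary_fraction)
      rows <- dplyr::arrange(rows, .data$tG_min)
      tryCatch(
        fit_node_coefficients(rows$rt_min[1], rows$rt_min[2],
                              rows$tG_min[1], rows$tG_min[2],
                              phi0 = spec$phi0, phif = spec$phif,
                              flow = flow, column = column,
                              instrument = instrument),
        error = function(e) {
          stop("node fit failed for analyte '", a, "' at (T=", temp_c,
               ", tC=", ternary_fraction, "): ", conditionMessage(e),
               call. = FALSE)
        })
    })
    nodes$log_kw <- purrr::map_dbl(node_fits, "log_kw")
    nodes$S <- purrr::map_dbl(node_fits, "S")
    nodes$residual_min <- purrr::map_dbl(node_fits, ~attr(.x, "residual_min"))
    structure(list(analyte = a, nodes = nodes,
                   T_levels = spec$T_levels, tC_levels = spec$tC_levels),
              class = "lss_cube")
  })
  names(models) <- analytes
  structure(list(models = models, spec = spec, flow = flow),
            class = "lss_cube_set")
}

#' @export
print.lss_cube_set <- function(x, ...) {
  cat(sprintf("<lss_cube_set> %d analytes over T {%s} degC x tC {%s}\n",
              length(x$models),
              paste(x$spec$T_levels, collapse = ", "),
              paste(x$spec$tC_levels, collapse = ", ")))
  cat("  analytes:", paste(names(x$models), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.lss_cube <- function(x, ...) {
  cat(sprintf("<lss_cube> analyte '%s'\n", x$analyte))
  print(x$nodes)
  invisible(x)
}

# Quadratic Lagrange interpolation through three (x, y) nodes.
lagrange3 <- function(xs, ys, x) {
  y <- 0
  for (i in 1:3) {
    li <- 1
    for (j in setdiff(1:3, i)) li <- li * (x - xs[j]) / (xs[i] - xs[j])
    y <- y + ys[i] * li
  }
  y
}

#' Interpolate cube coefficients at arbitrary conditions
#'
#' `log_kw` and `S` are each interpolated linearly in 1/T (kelvin) between
#' the two temperature nodes — the van't Hoff form, the natural law when only
#' two temperatures were calibrated — at each of the three tC nodes, then
#' quadratically (Lagrange) in the ternary fraction. Queries at design nodes
#' reproduce the fitted node coefficients exactly. Temperature extrapolation
#' beyond the calibrated range is allowed up to 10 degC with a warning.
#'
#' @param model An `lss_cube` (one element of an [assemble_cube()] result).
#' @param temp_c Query temperature (degC).
#' @param x Query ternary fraction in \[0, 1\].
#' @return An [lss()] pair; `S` is clipped at 0 (with a warning) if the
#'   interpolant dips negative.
#' @export
interpolate_coefficients <- function(model, temp_c, x) {
  stopifnot(inherits(model, "lss_cube"))
  if (x < 0 || x > 1) stop("ternary fraction x must lie in [0, 1]", call. = FALSE)
  Tlo <- model$T_levels[1]; Thi <- model$T_levels[2]
  if (temp_c < Tlo - 10 || temp_c > Thi + 10) {
    stop(sprintf("temperature %g degC is more than 10 degC outside the calibrated range [%g, %g]",
                 temp_c, Tlo, Thi), call. = FALSE)
  }
  if (temp_c < Tlo || temp_c > Thi) {
    warning(sprintf("extrapolating in temperature: %g degC outside [%g, %g]",
                    temp_c, Tlo, Thi), call. = FALSE)
  }
  invT <- 1 / kelvin(temp_c)
  invT1 <- 1 / kelvin(Tlo); invT2 <- 1 / kelvin(Thi)
  w2 <- (invT - invT1) / (invT2 - invT1)
  at_T <- purrr::map(model$tC_levels, function(tc) {
    nd <- model$nodes[model$nodes$ternary_fraction == tc, ]
    nd <- nd[order(nd$temp_c), ]
    list(log_kw = (1 - w2) * nd$log_kw[1] + w2 * nd$log_kw[2],
         S = (1 - w2) * nd$S[1] + w2 * nd$S[2])
  })
  log_kw <- lagrange3(model$tC_levels, purrr::map_dbl(at_T, "log_kw"), x)
  S <- lagrange3(model$tC_levels, purrr::map_dbl(at_T, "S"), x)
  if (S < 0) {
    warning(sprintf("interpolated S = %.4f < 0 at (T=%g, x=%g); clipped to 0",
                    S, temp_c, x), call. = FALSE)
    S <- 0
  }
  lss(log_kw, S)
}

#' @rdname lss_cube_tidiers
#' @method tidy lss_cube_set
#' @export
tidy.lss_cube_set <- function(x, ...) {
  purrr::map_dfr(x$models, function(m) {
    dplyr::mutate(m$nodes, analyte = m$analyte, .before = 1)
  })
}

#' Tidy and summarize calibrated cube models
#'
#' `tidy()` returns one row per analyte per (T, tC) node with the fitted
#' `log_kw`, `S` and fit residual; `glance()` returns one row per analyte
#' with node counts and the worst node residual.
#'
#' @param x An `lss_cube_set` from [assemble_cube()].
#' @param ... Unused.
#' @return A tibble.
#' @name lss_cube_tidiers
#' @method glance lss_cube_set
#' @export
glance.lss_cube_set <- function(x, ...) {
  tidy(x) |>
    dplyr::group_by(.data$analyte) |>
    dplyr::summarise(n_nodes = dplyr::n(),
                     max_residual_min = max(.data$residual_min),
                     S_min = min(.data$S), S_max = max(.data$S),
                     .groups = "drop")
}

#' Serialize a cube model set to JSON
#'
#' Writes the fitted node grids, design metadata and fit residuals to a
#' stable JSON document; [read_cube_json()] restores an equal object.
#'
#' @param x An `lss_cube_set`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cube_json <- function(x, path) {
  stopifnot(inherits(x, "lss_cube_set"))
  doc <- list(
    design = list(tG_levels = x$spec$tG_levels, T_levels = x$spec$T_levels,
                  tC_levels = x$spec$tC_levels, phi0 = x$spec$phi0,
                  phif = x$spec$phif, flow = x$spec$flow),
    flow = x$flow,
    analytes = purrr::map(x$models, function(m) {
      list(analyte = m$analyte, nodes = m$nodes)
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Restore a cube model set written by [write_cube_json()]
#'
#' @param path JSON file path.
#' @return An `lss_cube_set`.
#' @export
read_cube_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- design_spec(tG_levels = doc$design$tG_levels,
                      T_levels = doc$design$T_levels,
                      tC_levels = doc$design$tC_levels,
                      phi0 = doc$design$phi0, phif = doc$design$phif,
                      flow = doc$design$flow)
  models <- purrr::map(doc$analytes, function(entry) {
    structure(list(analyte = entry$analyte,
                   nodes = tibble::as_tibble(entry$nodes),
                   T_levels = spec$T_levels, tC_levels = spec$tC_levels),
              class = "lss_cube")
  })
  names(models) <- purrr::map_chr(models, "analyte")
  structure(list(models = models, spec = spec, flow = doc$flow),
            class = "lss_cube_set")
}
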