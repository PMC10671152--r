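#' Linear-solvent-strength retention coefficients
#'
#' The LSS model describes reverse-phase retention as
#' `log10 k = log_kw - S * phi`: `log_kw` is the (extrapolated) log10
#' retention factor in pure weak solvent (phi = 0) and `S` is the
#' dimensionless solvent-strength slope. Both are properties of one analyte
#' at one temperature and one ternary composition of the organic modifier.
#'
#' @param log_kw log10 retention factor at phi = 0; must be finite.
#' @param S LSS slope (per unit phi); must be >= 0 in reverse phase.
#' @return An object of class `lss_coefficients`.
#' @examples
#' retention_factor(lss(3, 4), phi = 0.5) # 10^(3 - 2) = 10
#' @export
lss <- function(log_kw, S) {
  if (!is.finite(log_kw)) stop("log_kw must be finite", call. = FALSE)
  if (!is.finite(S) || S < 0) {
    stop("S must be finite and >= 0 (reverse-phase convention)", call. = FALSE)
  }
  structure(list(log_kw = log_kw, S = S), class = "lss_coefficients")
}

#' @export
print.lss_coefficients <- function(x, ...) {
  cat(sprintf("<lss> log10 kw = %.4f, S = %.4f\n", x$log_kw, x$S))
  invisible(x)
}

#' Retention factor at a given composition
#'
#' @param coeffs An [lss()] coefficient pair.
#' @param phi Organic fraction(s) in \[0, 1\].
#' @return Retention factor(s) k = 10^(log_kw - S * phi), always > 0.
#' @export
retention_factor <- function(coeffs, phi) {
  stopifnot(inherits(coeffs, "lss_coefficients"))
  if (any(phi < 0 | phi > 1)) stop("phi must lie in [0, 1]", call. = FALSE)
  10^(coeffs$log_kw - coeffs$S * phi)
}

# Build the effective composition segments seen at the column inlet:
# an initial hold of length tD at the programmed phi(0), the (dwell-shifted)
# program breakpoints, then an unbounded hold at the final phi. Returns a
# list of finite segments (ta, tb, pa, pb) plus the final hold phi.
inlet_segments <- function(program, tD) {
  tp <- program$time_min
  pp <- program$phi
  times <- tD + tp
  phis <- pp
  if (tD > 0) {
    times <- c(0, times)
    phis <- c(pp[1], phis)
  }
  n <- length(times)
  segs <- NULL
  if (n > 1L) {
    segs <- data.frame(ta = times[-n], tb = times[-1],
                       pa = phis[-n], pb = phis[-1])
  }
  list(segments = segs, t_end = times[n], phi_end = phis[n])
}

# Migration contribution of a slice of one linear segment:
# integral over dt of 1 / (t0 * k(phi(t))) with phi linear in t.
segment_fraction <- function(dt, t0, k_a, S, r) {
  if (dt <= 0) return(0)
  if (S * r == 0) return(dt / (t0 * k_a))  # flat segment or slope-free solute
  (10^(S * r * dt) - 1) / (t0 * k_a * S * r * log(10))
}

# Time needed inside one linear segment to accumulate `frac` of migration.
segment_invert <- function(frac, t0, k_a, S, r) {
  if (S * r == 0) return(frac * t0 * k_a)
  log10(1 + frac * t0 * k_a * S * r * log(10)) / (S * r)
}

# Core solver: time te at which the migration integral
#   integral_0^te dt / (t0 * k(phi_in(t))) = 1
# reaches 1, walking the inlet-composition segments with the closed-form LSS
# segment integral. Returns list(te, phi_e, k_e).
solve_migration <- function(coeffs, program, t0, tD, tol = 1e-6) {
  S <- coeffs$S
  geom <- inlet_segments(program, tD)
  remaining <- 1
  elapsed <- 0
  segs <- geom$segments
  if (!is.null(segs)) {
    for (i in seq_len(nrow(segs))) {
      ta <- segs$ta[i]; tb <- segs$tb[i]
      pa <- segs$pa[i]; pb <- segs$pb[i]
      r <- (pb - pa) / (tb - ta)
      k_a <- retention_factor(coeffs, pa)
      full <- segment_fraction(tb - ta, t0, k_a, S, r)
      if (full >= remaining) {
        dt <- segment_invert(remaining, t0, k_a, S, r)
        te <- ta + dt
        phi_e <- pa + r * dt
        return(list(te = te, phi_e = phi_e,
                    k_e = retention_factor(coeffs, phi_e)))
      }
      remaining <- remaining - full
      elapsed <- tb
    }
  }
  # isocratic hold at the final composition
  k_f <- retention_factor(coeffs, geom$phi_end)
  te <- geom$t_end + remaining * t0 * k_f
  if (!is.finite(te)) {
    stop("retention solver failed to converge: solute effectively unmoving ",
         sprintf("(log_kw = %g, S = %g)", coeffs$log_kw, S), call. = FALSE)
  }
  list(te = te, phi_e = geom$phi_end, k_e = k_f)
}

#' Predict the gradient retention time of one analyte
#'
#' Solves the ideal gradient migration equation
#' \deqn{\int_0^{t_e} \frac{dt}{t_0\,k(\varphi_{in}(t))} = 1}
#' where the inlet composition is the programmed gradient delayed by the dwell
#' time, and returns `tR = t0 + te`. Each linear composition segment is
#' integrated in closed form, so the solution is exact to machine precision
#' for piecewise-linear programs; solutes still on the column when the
#' program ends continue under an isocratic hold at the final phi.
#'
#' @param coeffs An [lss()] coefficient pair (valid at the run's temperature
#'   and ternary composition).
#' @param program A [gradient_program()].
#' @param conditions A [run_conditions()] (only the flow is used here).
#' @param column A [column_spec()].
#' @param instrument An [instrument_spec()].
#' @return Retention time in minutes (always >= t0).
#' @export
predict_retention_time <- function(coeffs, program, conditions, column,
                                   instrument) {
  t0 <- dead_time(column, conditions$flow)
  tD <- dwell_time(instrument, conditions$flow)
  sol <- solve_migration(coeffs, program, t0, tD)
  t0 + sol$te
}

#' Composition and retention factor at the moment of elution
#'
#' The elution-time composition phi_e and retention factor k_e are needed by
#' the gradient peak-width model: a band leaves the column with the width it
#' has at its (usually much reduced) final retention factor.
#'
#' @inheritParams predict_retention_time
#' @return A list with `phi_e` and `k_e`.
#' @export
elution_state <- function(coeffs, program, conditions, column, instrument) {
  t0 <- dead_time(column, conditions$flow)
  tD <- dwell_time(instrument, conditions$flow)
  sol <- solve_migration(coeffs, program, t0, tD)
  list(phi_e = sol$phi_e, k_e = sol$k_e)
}

#' Gradient peak width (4 sigma)
#'
#' Baseline width of a Gaussian band eluting with retention factor `k_e`:
#' `w = compression * 4 * t0 * (1 + k_e) / sqrt(N)`. Gradient band
#' compression is disabled by default (factor 1).
#'
#' @param k_e Retention factor at elution.
#' @param t0 Dead time in minutes.
#' @param N Plate count (> 0).
#' @param compression Band-compression factor (default 1).
#' @return Baseline (4 sigma) width in minutes.
#' @export
predict_peak_width <- function(k_e, t0, N, compression = 1.0) {
  if (!is.numeric(N) || N <= 0) stop("plate count N must be positive", call. = FALSE)
  compression * 4 * t0 * (1 + k_e) / sqrt(N)
}

#' Predict one chromatographic peak
#'
#' Convenience wrapper running the retention and width models together.
#'
#' @inheritParams predict_retention_time
#' @param analyte_id Label carried into the output.
#' @param compression Band-compression factor passed to
#'   [predict_peak_width()].
#' @return A one-row tibble: `analyte`, `rt_min`, `width_min`, `phi_e`, `k_e`.
#' @export
predict_peak <- function(coeffs, program, conditions, column, instrument,
                         analyte_id = NA_character_, compression = 1.0) {
  t0 <- dead_time(column, conditions$flow)
  tD <- dwell_time(instrument, conditions$flow)
  sol <- solve_migration(coeffs, program, t0, tD)
  tibble::tibble(
    analyte = analyte_id,
    rt_min = t0 + sol$te,
    width_min = predict_peak_width(sol$k_e, t0, plate_count(column), compression),
    phi_e = sol$phi_e,
    k_e = sol$k_e
  )
}

#' Closed-form LSS retention time for a single linear ramp
#'
#' The textbook LSS solution for a solute injected into a single linear
#' gradient phi0 -> phif over tG with dwell time tD:
#' \deqn{t_R = t_0 + t_D + \frac{t_0}{b}\log_{10}\!\left(2.303\,k_0\,b
#'   \left(1 - \frac{t_D}{t_0 k_0}\right) + 1\right)}
#' with `b = t0 * S * (phif - phi0) / tG` and `k0` the retention factor at
#' phi0. Valid when the solute elutes during the ramp. Used as an independent
#' oracle for the numeric segment solver.
#'
#' @param coeffs An [lss()] pair.
#' @param tG Ramp duration (min).
#' @param phi0,phif Initial and final organic fraction.
#' @param t0 Dead time (min).
#' @param tD Dwell time (min).
#' @return Retention time in minutes.
#' @export
lss_closed_form_rt <- function(coeffs, tG, phi0, phif, t0, tD = 0) {
  k0 <- retention_factor(coeffs, phi0)
  b <- t0 * coeffs$S * (phif - phi0) / tG
  arg <- log(10) * k0 * b * (1 - tD / (t0 * k0)) + 1
  if (arg <= 0) return(NA_real_)  # solute consumed by the dwell: formula inapplicable
  t0 + tD + (t0 / b) * log10(arg)
}
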