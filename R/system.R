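#' Describe a chromatographic column
#'
#' Captures the column geometry used to derive the dead time (t0) and, unless
#' overridden, the theoretical plate count. Both quantities feed every
#' retention-time and peak-width prediction.
#'
#' @param length_mm Column length in mm.
#' @param id_mm Internal diameter in mm.
#' @param particle_um Particle size in micrometres.
#' @param porosity Total porosity (fraction of the empty-tube volume that is
#'   accessible mobile phase). Default 0.68, typical of packed silica.
#' @param plate_count Optional explicit plate count N. If `NULL`, N is derived
#'   from a reduced plate height of 2.5: `N = length / (2.5 * particle size)`.
#' @param t0_min Optional measured dead time at `t0_flow` mL/min. When given it
#'   takes precedence over the geometric estimate.
#' @param t0_flow Flow rate (mL/min) at which `t0_min` was measured.
#'
#' @return An object of class `column_spec`.
#' @examples
#' col <- column_spec(250, 4.6, particle_um = 10)
#' dead_time(col, flow = 0.5)
#' @export
column_spec <- function(length_mm, id_mm, particle_um, porosity = 0.68,
                        plate_count = NULL, t0_min = NULL, t0_flow = NULL) {
  stopifnot(is.numeric(length_mm), is.numeric(id_mm), is.numeric(particle_um))
  if (length_mm <= 0 || id_mm <= 0 || particle_um <= 0) {
    stop("column geometry (length, id, particle size) must be positive", call. = FALSE)
  }
  if (!is.numeric(porosity) || porosity <= 0 || porosity >= 1) {
    stop("porosity must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.null(plate_count) && plate_count <= 0) {
    stop("plate_count must be positive", call. = FALSE)
  }
  if (!is.null(t0_min)) {
    if (t0_min <= 0) stop("t0_min must be positive", call. = FALSE)
    if (is.null(t0_flow) || t0_flow <= 0) {
      stop("t0_flow (the flow at which t0_min was measured) is required with t0_min",
           call. = FALSE)
    }
  }
  structure(
    list(length_mm = length_mm, id_mm = id_mm, particle_um = particle_um,
         porosity = porosity, plate_count = plate_count,
         t0_min = t0_min, t0_flow = t0_flow),
    class = "column_spec"
  )
}

#' @export
print.column_spec <- function(x, ...) {
  cat(sprintf("<column_spec> %g x %g mm, %g um, porosity %g\n",
              x$length_mm, x$id_mm, x$particle_um, x$porosity))
  cat(sprintf("  Vm = %.3f mL, N = %d%s\n", column_dead_volume(x),
              round(plate_count(x)),
              if (is.null(x$plate_count)) " (from h = 2.5)" else " (explicit)"))
  invisible(x)
}

# Mobile-phase (dead) volume in mL: porosity * pi * r^2 * L
column_dead_volume <- function(column) {
  r_cm <- column$id_mm / 10 / 2
  l_cm <- column$length_mm / 10
  column$porosity * pi * r_cm^2 * l_cm
}

#' Plate count of a column
#'
#' Returns the explicit `plate_count` if one was supplied, otherwise the
#' estimate from a reduced plate height of 2.5 (N = L / (2.5 dp)); 10000 for a
#' 250 mm column with 10 um particles, 20000 for 5 um.
#'
#' @param column A [column_spec()].
#' @return Plate count (dimensionless).
#' @export
plate_count <- function(column) {
  stopifnot(inherits(column, "column_spec"))
  if (!is.null(column$plate_count)) return(column$plate_count)
  column$length_mm * 1000 / (2.5 * column$particle_um)
}

#' Column dead time
#'
#' Dead time t0 (elution time of an unretained solute) at a given flow. Uses a
#' measured t0 if the column carries one (rescaled inversely with flow),
#' otherwise the geometric estimate Vm / F.
#'
#' @param column A [column_spec()].
#' @param flow Flow rate in mL/min.
#' @return Dead time in minutes.
#' @export
dead_time <- function(column, flow) {
  stopifnot(inherits(column, "column_spec"))
  if (!is.numeric(flow) || length(flow) != 1L || flow <= 0) {
    stop("flow must be a single positive number (mL/min)", call. = FALSE)
  }
  if (!is.null(column$t0_min)) {
    return(column$t0_min * column$t0_flow / flow)
  }
  column_dead_volume(column) / flow
}

#' Describe the gradient delivery system
#'
#' The only instrument property the retention model needs is the dwell volume:
#' the plumbing volume between the gradient mixer and the column inlet, which
#' delays the arrival of the programmed composition by tD = VD / F.
#'
#' @param dwell_ml Dwell volume in mL (default 1.0).
#' @return An object of class `instrument_spec`.
#' @export
instrument_spec <- function(dwell_ml = 1.0) {
  if (!is.numeric(dwell_ml) || dwell_ml < 0) {
    stop("dwell_ml must be >= 0", call. = FALSE)
  }
  structure(list(dwell_ml = dwell_ml), class = "instrument_spec")
}

#' @export
print.instrument_spec <- function(x, ...) {
  cat(sprintf("<instrument_spec> dwell volume %g mL\n", x$dwell_ml))
  invisible(x)
}

#' Dwell time of the system at a given flow
#'
#' @param instrument An [instrument_spec()].
#' @param flow Flow rate in mL/min.
#' @return Dwell time in minutes.
#' @export
dwell_time <- function(instrument, flow) {
  stopifnot(inherits(instrument, "instrument_spec"))
  if (flow <= 0) stop("flow must be positive", call. = FALSE)
  instrument$dwell_ml / flow
}

#' Define a gradient program
#'
#' A gradient program is the piecewise-linear organic fraction phi(t) the pump
#' is asked to deliver: breakpoints at strictly increasing times, linear
#' interpolation between them, and an indefinite hold at the final phi after
#' the last breakpoint.
#'
#' @param time_min Numeric vector of breakpoint times (min); first must be 0,
#'   strictly increasing.
#' @param phi Organic fraction at each breakpoint. Values above 1.5 are taken
#'   to be percentages and divided by 100 (tables in method reports print
#'   "Org. (%)").
#' @return An object of class `gradient_program`.
#' @examples
#' # 30 -> 100 % B over 20 min
#' gradient_program(c(0, 20), c(30, 100))
#' @export
gradient_program <- function(time_min, phi) {
  stopifnot(is.numeric(time_min), is.numeric(phi))
  if (length(time_min) != length(phi) || length(time_min) < 1L) {
    stop("time_min and phi must be equal-length, non-empty vectors", call. = FALSE)
  }
  if (any(phi > 1.5)) phi <- phi / 100
  if (time_min[1] != 0) stop("the first breakpoint must be at time 0", call. = FALSE)
  if (length(time_min) > 1L && any(diff(time_min) <= 0)) {
    stop("breakpoint times must be strictly increasing", call. = FALSE)
  }
  if (any(phi < 0 | phi > 1)) stop("phi must lie in [0, 1]", call. = FALSE)
  structure(list(time_min = as.numeric(time_min), phi = as.numeric(phi)),
            class = "gradient_program")
}

#' Standard single-ramp program
#'
#' Convenience constructor for the linear ramp phi0 -> phif over tG minutes
#' used by the calibration design.
#'
#' @param tG Gradient time in minutes.
#' @param phi0,phif Initial and final organic fraction (defaults 0.30 and 1.00).
#' @return A [gradient_program()].
#' @export
linear_gradient <- function(tG, phi0 = 0.30, phif = 1.00) {
  stopifnot(tG > 0)
  gradient_program(c(0, tG), c(phi0, phif))
}

#' @export
print.gradient_program <- function(x, ...) {
  cat("<gradient_program>\n")
  print(tibble::tibble(time_min = x$time_min, organic_pct = 100 * x$phi))
  invisible(x)
}

#' Evaluate a gradient program
#'
#' Programmed organic fraction at time `t` (min): piecewise-linear between
#' breakpoints, held at the final phi after the program ends. Times before 0
#' evaluate to the initial phi.
#'
#' @param program A [gradient_program()].
#' @param t Numeric vector of times (min).
#' @return Organic fraction(s) in \[0, 1\].
#' @export
program_phi <- function(program, t) {
  stopifnot(inherits(program, "gradient_program"))
  tp <- program$time_min
  pp <- program$phi
  if (length(tp) == 1L) return(rep(pp, length(t)))
  stats::approx(tp, pp, xout = pmin(pmax(t, tp[1]), tp[length(tp)]),
                method = "linear", ties = "ordered")$y
}

#' Composition at the column inlet
#'
#' The composition the solute actually experiences at the column head: the
#' programmed gradient delayed by the dwell time tD = dwell volume / flow.
#' Inside the dwell window the inlet still sees the initial phi.
#'
#' @param program A [gradient_program()].
#' @param instrument An [instrument_spec()].
#' @param flow Flow rate in mL/min.
#' @param t Time(s) in minutes, >= 0.
#' @return Organic fraction(s) at the inlet.
#' @export
inlet_composition <- function(program, instrument, flow, t) {
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  tD <- dwell_time(instrument, flow)
  program_phi(program, t - tD)
}

#' Operating conditions of a run
#'
#' @param flow Flow rate in mL/min (> 0).
#' @param temp_c Column temperature in degrees Celsius.
#' @param ternary_fraction Fraction x of the secondary organic modifier (MeOH)
#'   in the organic blend; 0 = pure primary (ACN), 1 = pure secondary.
#' @return An object of class `run_conditions`.
#' @export
run_conditions <- function(flow, temp_c, ternary_fraction = 0) {
  if (!is.numeric(flow) || flow <= 0) stop("flow must be positive", call. = FALSE)
  if (ternary_fraction < 0 || ternary_fraction > 1) {
    stop("ternary_fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(list(flow = flow, temp_c = temp_c,
                 ternary_fraction = ternary_fraction),
            class = "run_conditions")
}

#' @export
print.run_conditions <- function(x, ...) {
  cat(sprintf("<run_conditions> %g mL/min, %g degC, x(MeOH) = %g\n",
              x$flow, x$temp_c, x$ternary_fraction))
  invisible(x)
}

kelvin <- function(temp_c) temp_c + 273.15

#' Timing quantities after a flow change
#'
#' Corner runs are often calibrated at one flow and the optimized method run
#' at another. Under the LSS model a flow change rescales t0 and tD by
#' old/new while leaving the retention coefficients (and, as a documented
#' simplification, the plate count) unchanged.
#'
#' @param conditions A [run_conditions()].
#' @param column A [column_spec()].
#' @param instrument An [instrument_spec()].
#' @param new_flow New flow rate in mL/min.
#' @return A tibble with one row per flow: `flow`, `t0_min`, `tD_min`.
#' @export
rescale_flow <- function(conditions, column, instrument, new_flow) {
  stopifnot(inherits(conditions, "run_conditions"))
  if (!is.numeric(new_flow) || new_flow <= 0) {
    stop("new_flow must be positive", call. = FALSE)
  }
  flows <- c(conditions$flow, new_flow)
  tibble::tibble(
    flow = flows,
    t0_min = vapply(flows, function(f) dead_time(column, f), numeric(1)),
    tD_min = vapply(flows, function(f) dwell_time(instrument, f), numeric(1))
  )
}
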