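#' Read a corner-run calibration table
#'
#' Strict CSV reader for calibration input: requires columns `run_id`,
#' `tG_min`, `temp_c`, `ternary_fraction`, `flow_ml_min`, `analyte`,
#' `rt_min`; `area` and `mixture_id` are optional. Percent-style ternary
#' values (> 1) are normalized to fractions. Malformed rows are reported
#' with their row numbers.
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_corner_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("run_id", "tG_min", "temp_c", "ternary_fraction", "flow_ml_min",
            "analyte", "rt_min")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("corner table ", path, " lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(df$ternary_fraction > 1)) {
    df$ternary_fraction <- df$ternary_fraction / 100
  }
  bad <- which(!is.finite(df$rt_min) | df$rt_min <= 0)
  if (length(bad)) {
    stop("non-positive or missing rt_min in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  bad <- which(df$tG_min <= 0 | df$flow_ml_min <= 0)
  if (length(bad)) {
    stop("non-positive tG_min or flow_ml_min in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  }
  tibble::as_tibble(df)
}

#' Write a corner-run table
#'
#' @param table A corner-run tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_corner_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Read a gradient program table
#'
#' Two-column CSV (`time_min`, `organic_pct`) in the layout gradient
#' programs are printed in method reports; percentages are converted to
#' fractions.
#'
#' @param path CSV file path.
#' @return A [gradient_program()].
#' @export
read_gradient_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "organic_pct")
  if (!all(need %in% names(df))) {
    stop("gradient table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  gradient_program(df$time_min, df$organic_pct)
}

#' Read a method configuration file
#'
#' Loads a YAML (or JSON) description of the system and method — column
#' geometry, dwell volume, run conditions, optional design levels and an
#' optional measured dead time — and returns constructed objects. Field
#' errors name the offending key.
#'
#' Recognized keys: `length_mm`, `id_mm`, `particle_um`, `porosity`,
#' `plate_count`, `dwell_ml`, `flow_ml_min`, `temp_c`, `ternary_fraction`,
#' `t0_min` (with `t0_flow_ml_min`), and an optional `design` block
#' (`tG_levels`, `T_levels`, `tC_levels`, `phi0`, `phif`, `flow_ml_min`).
#'
#' @param path YAML or JSON file path.
#' @return A list: `column`, `instrument`, `conditions`, `design` (NULL if
#'   no design block).
#' @export
read_method_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  get_num <- function(key, default = NULL) {
    v <- cfg[[key]]
    if (is.null(v)) {
      if (is.null(default)) stop("config field missing: ", key, call. = FALSE)
      return(default)
    }
    if (!is.numeric(v)) stop("config field not numeric: ", key, call. = FALSE)
    v
  }
  column <- column_spec(
    length_mm = get_num("length_mm"),
    id_mm = get_num("id_mm"),
    particle_um = get_num("particle_um"),
    porosity = get_num("porosity", 0.68),
    plate_count = cfg$plate_count,
    t0_min = cfg$t0_min,
    t0_flow = cfg$t0_flow_ml_min
  )
  instrument <- instrument_spec(dwell_ml = get_num("dwell_ml", 1.0))
  conditions <- run_conditions(
    flow = get_num("flow_ml_min"),
    temp_c = get_num("temp_c"),
    ternary_fraction = get_num("ternary_fraction", 0)
  )
  design <- NULL
  if (!is.null(cfg$design)) {
    d <- cfg$design
    design <- design_spec(
      tG_levels = if (is.null(d$tG_levels)) c(20, 60) else unlist(d$tG_levels),
      T_levels = if (is.null(d$T_levels)) c(5, 35) else unlist(d$T_levels),
      tC_levels = if (is.null(d$tC_levels)) c(0, 0.5, 1) else unlist(d$tC_levels),
      phi0 = if (is.null(d$phi0)) 0.30 else d$phi0,
      phif = if (is.null(d$phif)) 1.00 else d$phif,
      flow = if (is.null(d$flow_ml_min)) 0.5 else d$flow_ml_min
    )
  }
  list(column = column, instrument = instrument, conditions = conditions,
       design = design)
}

#' Setpoint validation tables of the ezetimibe study
#'
#' Transcriptions of the published predicted-versus-experimental retention
#' tables shipped with the package: per column ("chiralcel_od",
#' "chiral_cdph"), one row per (setpoint, compound) with the model-predicted
#' and experimentally observed retention times.
#'
#' @param column_id `"chiralcel_od"` or `"chiral_cdph"`.
#' @return A tibble: `setpoint`, `analyte`, `predicted_rt`,
#'   `experimental_rt`.
#' @export
ezetimibe_validation <- function(column_id = c("chiralcel_od", "chiral_cdph")) {
  column_id <- match.arg(column_id)
  path <- system.file("extdata", paste0(column_id, "_setpoints.csv"),
                      package = "lssmodr", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

#' Repeatability tables of the ezetimibe study
#'
#' Transcriptions of the published applicability tables: initial and
#' two-year re-run retention times for the routine setpoint of each column,
#' plus the reported 20-injection mean and SD summaries.
#'
#' @param column_id `"chiralcel_od"` or `"chiral_cdph"`.
#' @return A list: `retention` (tibble of per-compound retention times by
#'   measurement occasion) and `summary` (tibble of reported mean/SD rows).
#' @export
ezetimibe_repeatability <- function(column_id = c("chiralcel_od", "chiral_cdph")) {
  column_id <- match.arg(column_id)
  base <- system.file("extdata", package = "lssmodr", mustWork = TRUE)
  ret <- utils::read.csv(file.path(base, paste0(column_id, "_repeatability.csv")),
                         stringsAsFactors = FALSE)
  summ <- utils::read.csv(file.path(base, paste0(column_id, "_repeatability_summary.csv")),
                          stringsAsFactors = FALSE)
  list(retention = tibble::as_tibble(ret), summary = tibble::as_tibble(summ))
}

#' Export a resolution map as long-format CSV
#'
#' One row per design-space cell; `rs_crit` is rounded to 2 decimals at
#' this reporting layer only (the in-memory map keeps full precision).
#'
#' @param map A [compute_resolution_map()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_map_csv <- function(map, path) {
  stopifnot(inherits(map, "resolution_map"))
  df <- tibble::as_tibble(map)
  df$rs_crit <- round_half_up(df$rs_crit, 2)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export an MODR summary as JSON
#'
#' @param modr An [extract_modr()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_modr_json <- function(modr, path) {
  jsonlite::write_json(list(
    threshold = modr$threshold,
    n_pass = modr$n_pass,
    n_total = modr$n_total,
    fraction = modr$fraction,
    cells = modr$cells
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full synthetic-to-report pipeline
#'
#' End-to-end orchestration of the package stages on a synthetic study:
#' draw a truth panel, simulate the corner runs and the per-condition
#' mixture injections, track peaks into a labelled calibration table,
#' calibrate the cube models, map the design space, extract the MODR, and
#' validate predictions at a held-out setpoint against truth-forward
#' simulation. All artifacts are written under `out_dir`; outputs are
#' deterministic for a fixed seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed driving every stochastic stage.
#' @param n_analytes Panel size.
#' @param design A [design_spec()].
#' @param column,instrument System description.
#' @param rt_noise_sd,area_cv Noise magnitudes for the simulated data.
#' @param map_dims Integer vector (tG, T, tC) of map grid sizes; the
#'   default keeps the demonstration map small.
#' @return A list of the in-memory artifacts: `truth`, `corner_table`,
#'   `tracked_table`, `cube_set`, `map`, `modr`, `validation`, and the
#'   file paths written.
#' @export
run_pipeline <- function(out_dir, seed = 1, n_analytes = 9,
                         design = design_spec(),
                         column = default_column(),
                         instrument = instrument_spec(),
                         rt_noise_sd = 0.02, area_cv = 0.03,
                         map_dims = c(5, 4, 3)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- sample_truth(n_analytes, seed = seed, design = design,
                        column = column, instrument = instrument)
  corner <- simulate_corner_table(truth, design, column, instrument,
                                  rt_noise_sd = rt_noise_sd,
                                  area_cv = area_cv, seed = seed + 1)

  # per-condition mixture injections -> tracked, labelled table; spiking
  # levels are geometrically spaced so area evidence can discriminate within
  # signature groups
  n <- nrow(truth)
  full <- tibble::tibble(mixture_id = "mix1", analyte = truth$analyte,
                         conc_ug_ml = 4 * 1.6^(seq_len(n) - 1))
  part1 <- full[seq(1, n, by = 2), ]
  part1$mixture_id <- "mix2"
  part2 <- full[seq(2, n, by = 2), ]
  part2$mixture_id <- "mix3"
  scheme <- mixture_scheme(dplyr::bind_rows(full, part1, part2))
  runs <- build_design(design)
  peaklists <- purrr::map_dfr(seq_len(nrow(runs)), function(i) {
    prog <- gradient_program(c(0, runs$tG_min[i]), c(design$phi0, design$phif))
    cond <- run_conditions(runs$flow_ml_min[i], runs$temp_c[i],
                           runs$ternary_fraction[i])
    pl <- render_mixture_peaklists(truth, scheme, prog, cond, column,
                                   instrument, rt_noise_sd = rt_noise_sd,
                                   area_cv = area_cv, seed = seed + 100 + i)
    dplyr::mutate(pl, run_id = runs$run_id[i])
  })
  tracked <- track_peaks(peaklists, runs, scheme)

  cube <- assemble_cube(tracked, design, column, instrument)
  map <- compute_resolution_map(
    cube, column, instrument,
    tG_grid = seq(design$tG_levels[1], design$tG_levels[2],
                  length.out = map_dims[1]),
    T_grid = seq(design$T_levels[1], design$T_levels[2],
                 length.out = map_dims[2]),
    tC_grid = seq(min(design$tC_levels), max(design$tC_levels),
                  length.out = map_dims[3]))
  modr <- extract_modr(map)

  # held-out setpoint validation against truth-forward simulation
  sp_T <- mean(design$T_levels)
  sp_x <- 0.25
  sp_tG <- mean(design$tG_levels)
  prog <- gradient_program(c(0, sp_tG), c(design$phi0, design$phif))
  cond <- run_conditions(design$flow, sp_T, sp_x)
  predicted <- simulate_separation(cube, prog, cond, column, instrument)$peaks
  experimental <- vapply(predicted$analyte, function(a) {
    predict_retention_time(truth_coefficients(truth, a, sp_T, sp_x),
                           prog, cond, column, instrument)
  }, numeric(1))
  validation <- setpoint_report(tibble::tibble(
    analyte = predicted$analyte,
    predicted_rt = predicted$rt_min,
    experimental_rt = experimental))

  paths <- list(
    corner_table = file.path(out_dir, "corner_table.csv"),
    tracked_table = file.path(out_dir, "tracked_table.csv"),
    model = file.path(out_dir, "cube_models.json"),
    map = file.path(out_dir, "resolution_map.csv"),
    modr = file.path(out_dir, "modr.json"),
    validation = file.path(out_dir, "validation.csv")
  )
  write_corner_table(corner, paths$corner_table)
  write_corner_table(tracked, paths$tracked_table)
  write_cube_json(cube, paths$model)
  write_map_csv(map, paths$map)
  write_modr_json(modr, paths$modr)
  utils::write.csv(tibble::as_tibble(validation), paths$validation,
                   row.names = FALSE)

  list(truth = truth, corner_table = corner, tracked_table = tracked,
       cube_set = cube, map = map, modr = modr, validation = validation,
       paths = paths)
}
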