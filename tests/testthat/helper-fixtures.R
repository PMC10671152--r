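# Shared fixtures: the study-like system (250 x 4.6 mm, 10 um column,
# 1.0 mL dwell) and small hand-built cube models used across test files.

std_column <- function() column_spec(250, 4.6, particle_um = 10)
std_instrument <- function() instrument_spec(dwell_ml = 1.0)

# A cube model with prescribed node values and no temperature dependence:
# log_kw and S identical at both T nodes, set per tC node. Lets tests pin
# ternary interpolation arithmetic without running any fit.
flat_cube <- function(analyte, log_kw_by_tc, S_by_tc,
                      T_levels = c(5, 35), tC_levels = c(0, 0.5, 1)) {
  nodes <- tidyr::expand_grid(ternary_fraction = tC_levels,
                              temp_c = T_levels)
  nodes$log_kw <- rep(log_kw_by_tc, each = 2)
  nodes$S <- rep(S_by_tc, each = 2)
  nodes$residual_min <- 0
  structure(list(analyte = analyte, nodes = nodes,
                 T_levels = T_levels, tC_levels = tC_levels),
            class = "lss_cube")
}

# Wrap flat cubes into a set usable by simulate_separation() etc.
flat_cube_set <- function(models, spec = design_spec()) {
  names(models) <- purrr::map_chr(models, "analyte")
  structure(list(models = models, spec = spec, flow = spec$flow),
            class = "lss_cube_set")
}

# Truth-forward peak prediction, independent of the cube/calibration path:
# evaluates the truth law and the retention engine directly.
truth_peak <- function(truth, analyte, program, conditions,
                       column = std_column(), instrument = std_instrument()) {
  cf <- truth_coefficients(truth, analyte, conditions$temp_c,
                           conditions$ternary_fraction)
  predict_peak(cf, program, conditions, column, instrument,
               analyte_id = analyte)
}

# A three-mixture tracking scheme with pairwise-distinct concentrations over
# a truth panel's analytes (full mixture + two partial mixtures).
distinct_scheme <- function(analytes) {
  n <- length(analytes)
  concs <- 4 * 1.6^(seq_len(n) - 1)
  full <- tibble::tibble(mixture_id = "mix1", analyte = analytes,
                         conc_ug_ml = concs)
  half1 <- full[seq(1, n, by = 2), ]
  half1$mixture_id <- "mix2"
  half2 <- full[seq(2, n, by = 2), ]
  half2$mixture_id <- "mix3"
  mixture_scheme(dplyr::bind_rows(full, half1, half2))
}
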