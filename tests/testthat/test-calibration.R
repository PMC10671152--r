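test_that("the default design enumerates the 12 corner runs deterministically", {
  d <- build_design(design_spec())
  expect_equal(nrow(d), 12)
  expect_equal(nrow(dplyr::distinct(d, tG_min, temp_c, ternary_fraction)), 12)
  # deterministic ordering: tC outermost, T middle, tG innermost
  expect_equal(d$ternary_fraction, rep(c(0, 0.5, 1), each = 4))
  expect_equal(d$temp_c, rep(rep(c(5, 35), each = 2), 3))
  expect_equal(d$tG_min, rep(c(20, 60), 6))
  expect_identical(d, build_design(design_spec()))
})

test_that("design validation enforces level counts and warns on small tG ratios", {
  expect_equal(nrow(build_design(design_spec(tC_levels = c(0, 1)))), 8)
  expect_error(design_spec(tG_levels = c(30, 30)), "differ")
  expect_error(design_spec(tG_levels = 30), "2 positive tG")
  expect_error(design_spec(T_levels = c(20, 20)), "distinct T")
  expect_error(design_spec(tC_levels = c(0, 0.2, 0.5, 1)), "2 or 3")
  expect_error(design_spec(phi0 = 0.9, phif = 0.5), "smaller")
  expect_warning(design_spec(tG_levels = c(20, 40)), "ratio")
})

test_that("two-run fits recover known coefficients to 1e-4", {
  col <- std_column(); inst <- std_instrument()
  cond <- run_conditions(0.5, 25)
  for (truth in list(c(3.0, 4.0), c(4.2, 7.5), c(2.2, 5.8))) {
    cf <- lss(truth[1], truth[2])
    tRs <- vapply(c(20, 60), function(g) {
      predict_retention_time(cf, gradient_program(c(0, g), c(0.3, 1)),
                             cond, col, inst)
    }, numeric(1))
    fit <- fit_node_coefficients(tRs[1], tRs[2], 20, 60,
                                 column = col, instrument = inst)
    expect_equal(fit$log_kw, truth[1], tolerance = 1e-4)
    expect_equal(fit$S, truth[2], tolerance = 1e-4)
  }
})

test_that("unretained solutes are reported as unidentifiable", {
  col <- std_column(); inst <- std_instrument()
  t0 <- dead_time(col, 0.5)
  expect_error(fit_node_coefficients(t0, t0, 20, 60,
                                     column = col, instrument = inst),
               "unidentifiable")
})

test_that("cube assembly reproduces a noiseless 12-run table", {
  col <- std_column(); inst <- std_instrument()
  truth <- sample_truth(9, seed = 11)
  tab <- simulate_corner_table(truth, rt_noise_sd = 0, area_cv = 0, seed = 1)
  cube <- assemble_cube(tab, design_spec(), col, inst)
  expect_length(cube$models, 9)
  # model must reproduce all 108 input retention times
  spec <- design_spec()
  err <- purrr::pmap_dbl(
    tab[, c("analyte", "tG_min", "temp_c", "ternary_fraction", "rt_min")],
    function(analyte, tG_min, temp_c, ternary_fraction, rt_min) {
      cf <- interpolate_coefficients(cube$models[[analyte]], temp_c,
                                     ternary_fraction)
      prog <- gradient_program(c(0, tG_min), c(spec$phi0, spec$phif))
      abs(predict_retention_time(cf, prog, run_conditions(0.5, temp_c,
                                                          ternary_fraction),
                                 col, inst) - rt_min)
    })
  expect_lt(max(err), 5e-3)
})

test_that("a missing corner run is reported with its design cell", {
  col <- std_column(); inst <- std_instrument()
  truth <- sample_truth(3, seed = 5)
  tab <- simulate_corner_table(truth, rt_noise_sd = 0, seed = 1)
  drop <- !(tab$tG_min == 20 & tab$temp_c == 35 & tab$ternary_fraction == 0.5 &
              tab$analyte == truth$analyte[2])
  expect_error(assemble_cube(tab[drop, ], design_spec(), col, inst),
               "tG=20, T=35, tC=0.5")
})

test_that("interpolation is exact at nodes and quadratic in the ternary axis", {
  cube <- flat_cube("a", log_kw_by_tc = c(1, 2, 5), S_by_tc = c(4, 4, 4))
  # Lagrange through (0,1), (0.5,2), (1,5) is 4x^2 + 1
  expect_equal(interpolate_coefficients(cube, 20, 0.25)$log_kw, 1.25)
  expect_equal(interpolate_coefficients(cube, 20, 0.75)$log_kw, 3.25)
  # node exactness, bit for bit
  for (tc in c(0, 0.5, 1)) {
    for (tmp in c(5, 35)) {
      nd <- cube$nodes[cube$nodes$ternary_fraction == tc &
                         cube$nodes$temp_c == tmp, ]
      got <- interpolate_coefficients(cube, tmp, tc)
      expect_identical(got$log_kw, nd$log_kw)
      expect_identical(got$S, nd$S)
    }
  }
})

test_that("temperature interpolation is linear in reciprocal kelvin", {
  nodes <- tidyr::expand_grid(ternary_fraction = c(0, 0.5, 1),
                              temp_c = c(5, 35))
  nodes$log_kw <- ifelse(nodes$temp_c == 5, 4, 3)
  nodes$S <- ifelse(nodes$temp_c == 5, 6, 5)
  nodes$residual_min <- 0
  cube <- structure(list(analyte = "a", nodes = nodes,
                         T_levels = c(5, 35), tC_levels = c(0, 0.5, 1)),
                    class = "lss_cube")
  invT_mid <- mean(1 / (c(5, 35) + 273.15))
  T_mid <- 1 / invT_mid - 273.15
  got <- interpolate_coefficients(cube, T_mid, 0)
  expect_equal(got$log_kw, 3.5)
  expect_equal(got$S, 5.5)
})

test_that("interpolation guards its domain", {
  cube <- flat_cube("a", c(2, 2, 2), c(4, 4, 4))
  expect_error(interpolate_coefficients(cube, 20, 1.5), "\\[0, 1\\]")
  expect_warning(interpolate_coefficients(cube, 40, 0.5), "extrapolating")
  expect_error(interpolate_coefficients(cube, 50, 0.5), "outside")
  neg <- flat_cube("b", c(2, 2, 2), c(0.5, 0.01, 2)) # quadratic dips negative
  expect_warning(got <- interpolate_coefficients(neg, 20, 0.35), "clipped")
  expect_equal(got$S, 0)
})

test_that("calibration at one flow predicts runs at another (flow extrapolation)", {
  col <- std_column(); inst <- std_instrument()
  truth <- sample_truth(5, seed = 21)
  tab <- simulate_corner_table(truth, rt_noise_sd = 0, seed = 1) # 0.5 mL/min
  cube <- assemble_cube(tab, design_spec(), col, inst)
  cond <- run_conditions(0.7, 18, 0.3)
  prog <- gradient_program(c(0, 35), c(0.30, 1.00))
  for (a in truth$analyte) {
    cf_fit <- interpolate_coefficients(cube$models[[a]], 18, 0.3)
    got <- predict_retention_time(cf_fit, prog, cond, col, inst)
    want <- predict_retention_time(truth_coefficients(truth, a, 18, 0.3),
                                   prog, cond, col, inst)
    expect_equal(got, want, tolerance = 1e-4)
  }
})

test_that("noisy tables still recover the slope within 5% for most nodes", {
  col <- std_column(); inst <- std_instrument()
  truth <- sample_truth(6, seed = 31)
  spec <- design_spec()
  n_ok <- 0; n_tot <- 0
  for (rep in 1:20) {
    tab <- simulate_corner_table(truth, rt_noise_sd = 0.02, seed = 1000 + rep)
    cube <- assemble_cube(tab, spec, col, inst)
    for (a in truth$analyte) {
      nd <- cube$models[[a]]$nodes
      for (i in seq_len(nrow(nd))) {
        S_true <- truth_coefficients(truth, a, nd$temp_c[i],
                                     nd$ternary_fraction[i])$S
        n_tot <- n_tot + 1
        if (abs(nd$S[i] - S_true) / S_true <= 0.05) n_ok <- n_ok + 1
      }
    }
  }
  expect_gte(n_ok / n_tot, 0.95)
})

test_that("cube models survive a JSON round trip", {
  col <- std_column(); inst <- std_instrument()
  truth <- sample_truth(3, seed = 41)
  tab <- simulate_corner_table(truth, rt_noise_sd = 0, seed = 1)
  cube <- assemble_cube(tab, design_spec(), col, inst)
  path <- withr::local_tempfile(fileext = ".json")
  write_cube_json(cube, path)
  back <- read_cube_json(path)
  expect_equal(names(back$models), names(cube$models))
  for (a in names(cube$models)) {
    expect_equal(back$models[[a]]$nodes$log_kw, cube$models[[a]]$nodes$log_kw)
    expect_equal(back$models[[a]]$nodes$S, cube$models[[a]]$nodes$S)
  }
  expect_equal(back$spec$tG_levels, cube$spec$tG_levels)
})

test_that("tidy and glance summarize cube fits", {
  col <- std_column(); inst <- std_instrument()
  truth <- sample_truth(3, seed = 43)
  tab <- simulate_corner_table(truth, rt_noise_sd = 0, seed = 1)
  cube <- assemble_cube(tab, design_spec(), col, inst)
  td <- tidy(cube)
  expect_equal(nrow(td), 3 * 6)
  expect_true(all(c("analyte", "temp_c", "ternary_fraction", "log_kw", "S",
                    "residual_min") %in% names(td)))
  gl <- glance(cube)
  expect_equal(nrow(gl), 3)
  expect_true(all(gl$max_residual_min < 1e-4))
})
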