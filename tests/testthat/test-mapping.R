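test_that("adjacent resolutions follow the half-width formula and its symmetry", {
  peaks <- tibble::tibble(analyte = c("a", "b"),
                          rt_min = c(10, 11), width_min = c(0.5, 0.5))
  rs <- lssmodr:::adjacent_resolutions(peaks)
  expect_equal(rs$rs, 2.0)
  # swapping the labels (same chromatogram) leaves Rs unchanged
  swapped <- peaks[2:1, ] |> dplyr::arrange(rt_min)
  expect_equal(lssmodr:::adjacent_resolutions(swapped)$rs, 2.0)
  # co-elution gives zero
  co <- tibble::tibble(analyte = c("a", "b"), rt_min = c(10, 10),
                       width_min = c(0.5, 0.7))
  expect_equal(lssmodr:::adjacent_resolutions(co)$rs, 0)
})

test_that("the critical pair is the minimum with ties to the earlier pair", {
  res <- tibble::tibble(first = c("a", "b", "c"), second = c("b", "c", "d"),
                        rs = c(2.1, 1.3, 4.0))
  cr <- lssmodr:::critical_from_resolutions(res)
  expect_equal(cr$rs, 1.3)
  expect_equal(c(cr$first, cr$second), c("b", "c"))
  ties <- tibble::tibble(first = c("a", "b"), second = c("b", "c"),
                         rs = c(1.5, 1.5))
  expect_equal(lssmodr:::critical_from_resolutions(ties)$first, "a")
})

test_that("simulated chromatograms match brute-force truth computation", {
  col <- std_column(); inst <- std_instrument()
  truth <- sample_truth(9, seed = 51)
  tab <- simulate_corner_table(truth, rt_noise_sd = 0, seed = 1)
  cube <- assemble_cube(tab, design_spec(), col, inst)
  prog <- gradient_program(c(0, 37), c(0.30, 1.00))
  cond <- run_conditions(0.5, 22, 0.4)
  chrom <- simulate_separation(cube, prog, cond, col, inst)
  # oracle: per-analyte truth-forward peaks, sorted, pairwise Rs by formula
  oracle <- purrr::map_dfr(truth$analyte, function(a) {
    truth_peak(truth, a, prog, cond)
  }) |> dplyr::arrange(rt_min)
  expect_equal(chrom$peaks$analyte, oracle$analyte)
  expect_equal(chrom$peaks$rt_min, oracle$rt_min, tolerance = 1e-6)
  n <- nrow(oracle)
  rs_oracle <- 2 * diff(oracle$rt_min) /
    (oracle$width_min[-n] + oracle$width_min[-1])
  expect_equal(chrom$resolutions$rs, rs_oracle, tolerance = 1e-6)
  expect_equal(chrom$critical$rs, min(rs_oracle), tolerance = 1e-6)
})

test_that("excluding analytes never shifts the remaining peaks", {
  col <- std_column(); inst <- std_instrument()
  truth <- sample_truth(9, seed = 51)
  tab <- simulate_corner_table(truth, rt_noise_sd = 0, seed = 1)
  cube <- assemble_cube(tab, design_spec(), col, inst)
  prog <- gradient_program(c(0, 30), c(0.30, 1.00))
  cond <- run_conditions(0.5, 15, 0.2)
  full <- simulate_separation(cube, prog, cond, col, inst)
  keep <- setdiff(truth$analyte, truth$analyte[c(3, 7)])
  sub <- simulate_separation(cube, prog, cond, col, inst, include = keep)
  joined <- dplyr::inner_join(full$peaks, sub$peaks, by = "analyte")
  expect_equal(nrow(joined), length(keep))
  expect_identical(joined$rt_min.x, joined$rt_min.y)
  expect_identical(joined$width_min.x, joined$width_min.y)
})

test_that("single-analyte chromatograms report no critical pair", {
  col <- std_column(); inst <- std_instrument()
  truth <- sample_truth(3, seed = 53)
  tab <- simulate_corner_table(truth, rt_noise_sd = 0, seed = 1)
  cube <- assemble_cube(tab, design_spec(), col, inst)
  chrom <- simulate_separation(cube, gradient_program(c(0, 30), c(0.3, 1)),
                               run_conditions(0.5, 20, 0), col, inst,
                               include = truth$analyte[1])
  expect_equal(nrow(chrom$resolutions), 0)
  expect_null(chrom$critical)
  expect_equal(nrow(critical_resolution(chrom)), 0)
  expect_error(simulate_separation(cube, gradient_program(c(0, 30), c(0.3, 1)),
                                   run_conditions(0.5, 20, 0), col, inst,
                                   include = character(0)), "at least one")
})

test_that("resolution maps agree cell-by-cell with direct simulation", {
  col <- std_column(); inst <- std_instrument()
  truth <- sample_truth(5, seed = 55)
  tab <- simulate_corner_table(truth, rt_noise_sd = 0, seed = 1)
  cube <- assemble_cube(tab, design_spec(), col, inst)
  tG_g <- seq(20, 60, length.out = 5)
  T_g <- seq(5, 35, length.out = 4)
  tC_g <- c(0, 0.5, 1)
  map <- compute_resolution_map(cube, col, inst, tG_g, T_g, tC_g)
  expect_equal(nrow(map), 5 * 4 * 3)
  for (i in seq_len(nrow(map))) {
    chrom <- simulate_separation(
      cube, gradient_program(c(0, map$tG_min[i]), c(0.30, 1.00)),
      run_conditions(0.5, map$temp_c[i], map$ternary_fraction[i]),
      col, inst)
    expect_equal(map$rs_crit[i], chrom$critical$rs)
  }
  # 1x1x1 grid consistency
  one <- compute_resolution_map(cube, col, inst, 30, 20, 0.5)
  direct <- simulate_separation(cube, gradient_program(c(0, 30), c(0.3, 1)),
                                run_conditions(0.5, 20, 0.5), col, inst)
  expect_equal(one$rs_crit, direct$critical$rs)
})

test_that("MODR extraction is an exact threshold filter and handles emptiness", {
  col <- std_column(); inst <- std_instrument()
  truth <- sample_truth(5, seed = 55)
  tab <- simulate_corner_table(truth, rt_noise_sd = 0, seed = 1)
  cube <- assemble_cube(tab, design_spec(), col, inst)
  map <- compute_resolution_map(cube, col, inst, seq(20, 60, length.out = 4),
                                seq(5, 35, length.out = 3), c(0, 0.5, 1))
  modr <- extract_modr(map, threshold = 1.5)
  want <- tibble::as_tibble(map)[tibble::as_tibble(map)$rs_crit >= 1.5, ]
  expect_equal(modr$cells$rs_crit, want$rs_crit)
  expect_equal(modr$n_pass + nrow(map) - nrow(want), nrow(map))
  # every passing cell re-simulates above threshold
  if (nrow(modr$cells) > 0) {
    for (i in seq_len(nrow(modr$cells))) {
      chrom <- simulate_separation(
        cube, gradient_program(c(0, modr$cells$tG_min[i]), c(0.3, 1)),
        run_conditions(0.5, modr$cells$temp_c[i],
                       modr$cells$ternary_fraction[i]), col, inst)
      expect_gte(chrom$critical$rs, 1.5)
    }
  }
  # a pair of near-identical analytes never separates: the MODR is empty
  twin <- flat_cube_set(list(
    flat_cube("p", c(2.50, 2.45, 2.50), c(5, 5, 5)),
    flat_cube("q", c(2.505, 2.455, 2.505), c(5, 5, 5))))
  tmap <- compute_resolution_map(twin, col, inst,
                                 seq(20, 60, length.out = 4),
                                 seq(5, 35, length.out = 3), c(0, 0.5, 1))
  empty <- extract_modr(tmap)
  expect_equal(empty$n_pass, 0)
  expect_equal(nrow(empty$cells), 0)
})

test_that("well-behaved systems gain resolution with longer gradients", {
  col <- std_column(); inst <- std_instrument()
  cube <- flat_cube_set(list(
    flat_cube("a", c(2.0, 2.0, 2.0), c(5, 5, 5)),
    flat_cube("b", c(2.4, 2.4, 2.4), c(5, 5, 5)),
    flat_cube("c", c(2.8, 2.8, 2.8), c(5, 5, 5))))
  rs <- vapply(seq(20, 60, by = 10), function(g) {
    simulate_separation(cube, gradient_program(c(0, g), c(0.3, 1)),
                        run_conditions(0.5, 20, 0), col, inst)$critical$rs
  }, numeric(1))
  expect_true(all(diff(rs) >= -1e-9))
})

test_that("robustness scans enumerate the full factorial around the nominal", {
  col <- std_column(); inst <- std_instrument()
  truth <- sample_truth(4, seed = 57)
  tab <- simulate_corner_table(truth, rt_noise_sd = 0, seed = 1)
  cube <- assemble_cube(tab, design_spec(), col, inst)
  cond <- run_conditions(0.5, 20, 0.5)
  scan <- robustness_scan(cube, col, inst, tG = 40, conditions = cond,
                          tolerances = list(tG = 2, temp_c = 2,
                                            ternary_fraction = 0.05),
                          levels = 3)
  expect_equal(nrow(scan$table), 27)
  # brute-force enumeration oracle
  worst <- Inf
  for (g in c(38, 40, 42)) for (tmp in c(18, 20, 22))
    for (x in c(0.45, 0.5, 0.55)) {
      chrom <- simulate_separation(cube, gradient_program(c(0, g), c(0.3, 1)),
                                   run_conditions(0.5, tmp, x), col, inst)
      worst <- min(worst, chrom$critical$rs)
    }
  expect_equal(scan$worst, worst)
  expect_lte(scan$worst, scan$nominal)
  # zero tolerances collapse to the nominal
  flat <- robustness_scan(cube, col, inst, tG = 40, conditions = cond,
                          tolerances = list(), levels = 3)
  expect_equal(nrow(flat$table), 1)
  expect_equal(flat$worst, flat$nominal)
  # clipping at the ternary boundary warns
  edge <- run_conditions(0.5, 20, 0.98)
  expect_warning(robustness_scan(cube, col, inst, tG = 40, conditions = edge,
                                 tolerances = list(ternary_fraction = 0.05)),
                 "clipped")
  expect_error(robustness_scan(cube, col, inst, tG = 40, conditions = cond,
                               levels = 4), "2 or 3")
})

test_that("map and chromatogram plots build without error", {
  col <- std_column(); inst <- std_instrument()
  cube <- flat_cube_set(list(
    flat_cube("a", c(2.0, 2.0, 2.0), c(5, 5, 5)),
    flat_cube("b", c(2.4, 2.4, 2.4), c(5, 5, 5))))
  map <- compute_resolution_map(cube, col, inst, c(20, 40), c(5, 35), c(0, 1))
  p <- autoplot(map)
  expect_s3_class(p, "ggplot")
  chrom <- simulate_separation(cube, gradient_program(c(0, 30), c(0.3, 1)),
                               run_conditions(0.5, 20, 0), col, inst)
  expect_s3_class(autoplot(chrom), "ggplot")
})
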