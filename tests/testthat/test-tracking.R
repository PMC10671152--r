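test_that("membership signatures reflect the three-mixture spiking scheme", {
  scheme <- ezetimibe_scheme()
  sig_api <- membership_signature("ezetimibe", scheme)
  expect_equal(unname(sig_api), c(TRUE, FALSE, FALSE))
  sig_des <- membership_signature("desfluoro ezetimibe", scheme)
  expect_equal(unname(sig_des), c(TRUE, FALSE, TRUE))
  sig_diol <- membership_signature("ezetimibe diol", scheme)
  expect_equal(unname(sig_diol), c(TRUE, TRUE, FALSE))
  expect_error(membership_signature("nonexistent", scheme), "unknown")
})

test_that("scheme construction enforces coverage by a full mixture", {
  bad <- tibble::tibble(mixture_id = c("m1", "m2"),
                        analyte = c("a", "b"), conc_ug_ml = c(1, 2))
  expect_error(mixture_scheme(bad), "every analyte")
  expect_error(mixture_scheme(tibble::tibble(mixture_id = "m1", analyte = "a",
                                             conc_ug_ml = 0)), "positive")
})

test_that("unique signatures and area ratios drive the assignment", {
  scheme <- ezetimibe_scheme()
  # clean observation: API at 20 min (mix1 only), desfluoro/THP at 12/14 min
  # (mix1 + mix3) with areas proportional to 4 and 6 ug/mL
  peaks <- tibble::tibble(
    mixture_id = c("mix1", "mix1", "mix1", "mix3", "mix3",
                   rep("mix2", 0)),
    rt_min = c(20, 12, 14, 12.01, 13.99),
    area = c(1000, 4.1, 5.9, 4.0, 6.1))
  # add a token mix2 peak so every mixture is present (far from the others)
  peaks <- dplyr::bind_rows(peaks, tibble::tibble(mixture_id = "mix2",
                                                  rt_min = 5, area = 12))
  got <- assign_peaks(peaks, scheme)
  expect_equal(got$analyte[got$rt_min == 20], "ezetimibe")
  expect_equal(got$analyte[got$rt_min == 12], "desfluoro ezetimibe")
  expect_equal(got$analyte[got$rt_min == 14], "THP compound")
})

test_that("indistinguishable areas with equal concentrations are flagged, not guessed", {
  comp <- tibble::tibble(
    mixture_id = c("m1", "m1", "m1", "m2", "m2"),
    analyte = c("anchor", "x", "y", "x", "y"),
    conc_ug_ml = c(10, 6, 6, 6, 6))
  scheme <- mixture_scheme(comp)
  peaks <- tibble::tibble(
    mixture_id = c("m1", "m1", "m1", "m2", "m2"),
    rt_min = c(5, 10, 12, 10, 12),
    area = c(10, 6.0, 6.1, 6.05, 6.02))
  got <- assign_peaks(peaks, scheme)
  expect_equal(got$analyte[got$rt_min == 5], "anchor")
  expect_true(all(is.na(got$analyte[got$rt_min %in% c(10, 12)])))
  expect_true(all(got$ambiguous[got$rt_min %in% c(10, 12)]))
})

test_that("a missing mixture injection is an incomplete-evidence error", {
  scheme <- ezetimibe_scheme()
  peaks <- tibble::tibble(mixture_id = "mix1", rt_min = 20, area = 100)
  expect_error(assign_peaks(peaks, scheme), "incomplete evidence")
})

test_that("assignment is invariant to input row order and never reuses labels", {
  truth <- sample_truth(6, seed = 61)
  scheme <- distinct_scheme(truth$analyte)
  prog <- gradient_program(c(0, 30), c(0.3, 1))
  cond <- run_conditions(0.5, 20, 0.5)
  pl <- render_mixture_peaklists(truth, scheme, prog, cond,
                                 rt_noise_sd = 0.01, area_cv = 0.03,
                                 seed = 99)
  obs <- pl[, c("mixture_id", "rt_min", "area")]
  a1 <- assign_peaks(obs, scheme)
  set.seed(1)
  a2 <- assign_peaks(obs[sample(nrow(obs)), ], scheme)
  expect_equal(a1, a2)
  labs <- a1$analyte[!is.na(a1$analyte)]
  expect_equal(anyDuplicated(labs), 0L)
})

test_that("tracking labels a full synthetic design correctly", {
  truth <- sample_truth(6, seed = 63)
  scheme <- distinct_scheme(truth$analyte)
  design <- design_spec()
  runs <- build_design(design)
  peaklists <- purrr::map_dfr(seq_len(nrow(runs)), function(i) {
    prog <- gradient_program(c(0, runs$tG_min[i]), c(0.30, 1.00))
    cond <- run_conditions(runs$flow_ml_min[i], runs$temp_c[i],
                           runs$ternary_fraction[i])
    pl <- render_mixture_peaklists(truth, scheme, prog, cond,
                                   rt_noise_sd = 0.01, area_cv = 0.03,
                                   seed = 700 + i)
    dplyr::mutate(pl, run_id = runs$run_id[i])
  })
  tracked <- track_peaks(peaklists, runs, scheme)
  # scoring: tracked rows carry the exact rt/area of their mix1 source rows,
  # so an exact join recovers each peak's generating analyte; every label
  # assigned must be correct
  scored <- dplyr::inner_join(
    tracked, dplyr::filter(peaklists, mixture_id == "mix1"),
    by = c("run_id", "rt_min", "area"))
  expect_equal(nrow(scored), nrow(tracked))
  expect_equal(mean(scored$analyte == scored$analyte_true), 1)
  # peaks may legitimately stay unlabeled only where two analytes genuinely
  # collide within the matching window of that run
  mix1 <- dplyr::filter(peaklists, mixture_id == "mix1")
  dropped <- dplyr::anti_join(mix1, tracked,
                              by = c("run_id", "rt_min", "area"))
  if (nrow(dropped) > 0) {
    for (i in seq_len(nrow(dropped))) {
      others <- dplyr::filter(peaklists, run_id == dropped$run_id[i],
                              analyte_true != dropped$analyte_true[i])
      expect_lt(min(abs(others$rt_min - dropped$rt_min[i])), 0.25)
    }
  }
  # the clear majority of the design is tracked
  expect_gte(nrow(tracked), 0.9 * nrow(mix1))
})
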