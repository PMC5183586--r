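test_that("standard-curve fitting recovers efficiency from the slope", {
  # 3.3219 cycles per 10-fold dilution <=> perfect doubling
  pts <- tibble::tibble(log10_quantity = c(0, -1, -2, -3),
                        ct = 25 + 3.321928 * c(0, 1, 2, 3))
  curve <- fit_standard_curve(pts)
  expect_equal(curve$efficiency, 2, tolerance = 1e-6)
  expect_equal(curve$r_squared, 1, tolerance = 1e-12)

  # closed-form check at slope -3.6
  pts2 <- tibble::tibble(log10_quantity = c(0, -1, -2),
                         ct = 25 + 3.6 * c(0, 1, 2))
  curve2 <- fit_standard_curve(pts2)
  expect_equal(curve2$efficiency, 10^(1 / 3.6), tolerance = 1e-9)
  expect_equal(curve2$efficiency, 1.8957357, tolerance = 1e-6)
})

test_that("standard-curve preconditions are enforced", {
  expect_error(fit_standard_curve(
    tibble::tibble(log10_quantity = c(0, -1), ct = c(25, 28.3))), "3 dilution")
  expect_error(fit_standard_curve(
    tibble::tibble(log10_quantity = c(0, -0.5, -1), ct = c(25, 26, 27))),
    "2 logs")
  expect_error(fit_standard_curve(
    tibble::tibble(log10_quantity = c(0, -1, -2), ct = c(25, 22, 19))),
    "positive slope")
})

test_that("curve fit and Ct regeneration round-trip within 1e-9 cycles", {
  pts <- simulate_dilution_series(efficiency = 1.93, base_ct = 24.2)
  curve <- fit_standard_curve(pts)
  regenerated <- curve$intercept + curve$slope * pts$log10_quantity
  expect_lt(max(abs(regenerated - pts$ct)), 1e-9)
})

test_that("tidy and glance expose the curve fit the broom way", {
  pts <- simulate_dilution_series()
  curve <- fit_standard_curve(pts)
  td <- tidy(curve)
  expect_equal(td$term, c("intercept", "slope"))
  gl <- glance(curve)
  expect_named(gl, c("slope", "intercept", "efficiency", "r_squared", "n"))
  expect_equal(gl$efficiency, 2, tolerance = 1e-9)
})

test_that("comparative TaqMan quantification follows the efficiency-corrected formula", {
  mk <- function(target_cts, ref_cts, cal_target = c(25, 25, 25),
                 cal_ref = c(24, 24, 24)) {
    tibble::tibble(
      sample_id = rep(c("S1", "CAL"), each = 6),
      locus = "FCGR3B",
      role = rep(rep(c("target", "reference"), each = 3), 2),
      replicate = rep(1:3, 4),
      ct = c(target_cts, ref_cts, cal_target, cal_ref))
  }
  # identity: sample == calibrator -> estimate 2.0
  m <- mk(rep(25, 3), rep(24, 3))
  got <- call_taqman(m)
  expect_equal(got$continuous_estimate, 2)
  expect_equal(got$integer_call, 2L)

  # one-cycle doubling: target 1 cycle earlier -> 4 copies
  m2 <- mk(rep(24, 3), rep(24, 3))
  expect_equal(call_taqman(m2)$integer_call, 4L)

  # efficiency-corrected arithmetic: E_t = 1.9, dCt_t = 0.8, E_r = 2,
  # dCt_r = 0.1 -> 2 * 1.9^0.8 / 2^0.1 = 3.1185 -> call 3
  m3 <- mk(rep(25 - 0.8, 3), rep(24 - 0.1, 3))
  got3 <- call_taqman(m3, efficiency_target = 1.9, efficiency_reference = 2)
  expect_equal(got3$continuous_estimate, 2 * 1.9^0.8 / 2^0.1,
               tolerance = 1e-12)
  expect_equal(got3$continuous_estimate, 3.1183860, tolerance = 1e-6)
  expect_equal(got3$integer_call, 3L)
})

test_that("replicate outlier screening and spread flagging work as declared", {
  m <- tibble::tibble(
    sample_id = rep(c("S1", "CAL"), each = 6),
    locus = "FCGR3B",
    role = rep(rep(c("target", "reference"), each = 3), 2),
    replicate = rep(1:3, 4),
    ct = c(25, 25.1, 28,   24, 24, 24,   25, 25, 25,   24, 24, 24))
  got <- call_taqman(m)
  # the 28 replicate is > 0.5 cycles from the median and is discarded
  expect_equal(got$continuous_estimate, 2 * 2^(25 - 25.05), tolerance = 1e-9)
  expect_true(is.na(got$flag))

  # replicates all survive the 0.5-cycle screen but span 0.8 cycles:
  # above a 0.5-cycle spread ceiling the call is flagged missing
  m$ct[1:3] <- c(24.6, 25, 25.4)
  got2 <- call_taqman(m, spread_max = 0.5)
  expect_true(is.na(got2$integer_call))
  expect_equal(got2$flag, "high_replicate_spread")
})

test_that("continuous estimates decrease strictly as target Ct increases", {
  cal <- tibble::tibble(sample_id = "CAL", locus = "FCGR3B",
                        role = rep(c("target", "reference"), each = 3),
                        replicate = rep(1:3, 2), ct = rep(c(25, 24), each = 3))
  ests <- vapply(seq(23, 28, by = 0.5), function(ct0) {
    m <- dplyr::bind_rows(
      tibble::tibble(sample_id = "S1", locus = "FCGR3B",
                     role = rep(c("target", "reference"), each = 3),
                     replicate = rep(1:3, 2), ct = rep(c(ct0, 24), each = 3)),
      cal)
    call_taqman(m)$continuous_estimate
  }, numeric(1))
  expect_true(all(diff(ests) < 0))
})

test_that("SYBR standard-curve calling is exact on-curve and linear in the ratio", {
  curve_t <- fit_standard_curve(simulate_dilution_series(base_ct = 26))
  curve_r <- fit_standard_curve(simulate_dilution_series(base_ct = 25))
  mk <- function(t_ct) {
    tibble::tibble(
      sample_id = rep(c("S1", "CAL"), each = 6), locus = "FCGR3B",
      role = rep(rep(c("target", "reference"), each = 3), 2),
      replicate = rep(1:3, 4),
      ct = c(rep(t_ct, 3), rep(25, 3), rep(26, 3), rep(25, 3)))
  }
  # sample ratio equal to the calibrator's -> estimate 2
  got <- call_sybr(mk(26), curve_t, curve_r)
  expect_equal(got$continuous_estimate, 2, tolerance = 1e-9)
  # sample ratio 1.5x the calibrator's -> estimate 3
  dct <- log2(1.5)
  got2 <- call_sybr(mk(26 - dct), curve_t, curve_r)
  expect_equal(got2$continuous_estimate, 3, tolerance = 1e-9)
  expect_equal(got2$integer_call, 3L)
})

test_that("noise-free SYBR recovers every copy number 0..6 exactly", {
  g <- genotypes_fixture(rep(2L, 7), 0:6,
                         ids = sprintf("S%d", 0:6))
  m <- simulate_taqman(g, "FCGR3B", noise_model())
  curve_t <- fit_standard_curve(simulate_dilution_series(base_ct = 26))
  curve_r <- fit_standard_curve(simulate_dilution_series(base_ct = 25))
  got <- call_sybr(m, curve_t, curve_r)
  expect_equal(got$integer_call[match(g$sample_id, got$sample_id)], 0:6)
})

test_that("poorly fitting standard curves are refused", {
  pts <- tibble::tibble(log10_quantity = c(0, -1, -2, -3),
                        ct = c(25, 30.5, 30.8, 36))
  curve <- fit_standard_curve(pts)
  expect_lt(curve$r_squared, 0.98)
  good <- fit_standard_curve(simulate_dilution_series())
  m <- simulate_taqman(genotypes_fixture(2L, 2L), "FCGR3B", noise_model())
  expect_error(call_sybr(m, curve, good), "r_squared")
})

test_that("gene-level calls sum to the locus total without re-rounding", {
  calls <- dplyr::bind_rows(
    calls_fixture("S1", "taqman", "FCGR3A", 2L, 2.4),
    calls_fixture("S1", "taqman", "FCGR3B", 2L, 2.4))
  total <- sum_locus_calls(calls)
  t3 <- total[total$locus == "FCGR3", ]
  # 2.4 + 2.4 = 4.8 would round to 5; the summed integer calls give 4
  expect_equal(t3$integer_call, 4L)
  expect_equal(t3$continuous_estimate, 4.8)
})
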