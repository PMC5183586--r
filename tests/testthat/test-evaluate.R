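truth90 <- rep(2L, 90)

test_that("pairwise concordance reproduces rates that are multiples of 1/90", {
  a <- agreeing_calls("taqman", "FCGR3B", truth90, 90)
  for (case in list(c(56, 62.22), c(54, 60.00), c(82, 91.11), c(90, 100.00))) {
    b <- agreeing_calls("sybr", "FCGR3B", truth90, case[1])
    got <- tidy(concordance_pairwise(dplyr::bind_rows(a, b),
                                     c("taqman", "sybr")))
    expect_equal(got$n_paired, 90)
    expect_equal(got$n_agree, as.integer(case[1]))
    expect_equal(got$rate, case[2])
  }
})

test_that("pairwise concordance is symmetric in its arguments", {
  a <- agreeing_calls("taqman", "FCGR3", truth90, 71)
  b <- agreeing_calls("prt_redvr", "FCGR3", truth90, 90)
  ab <- tidy(concordance_pairwise(dplyr::bind_rows(a, b),
                                  c("taqman", "prt_redvr")))
  ba <- tidy(concordance_pairwise(dplyr::bind_rows(b, a),
                                  c("prt_redvr", "taqman")))
  expect_equal(ab$rate, ba$rate)
  expect_equal(ab$n_agree, ba$n_agree)
})

test_that("missing calls are excluded pairwise and the denominator is reported", {
  a <- agreeing_calls("taqman", "FCGR3", truth90, 90)
  b <- agreeing_calls("str", "FCGR3", truth90, 90)
  b$integer_call[1:5] <- NA
  got <- tidy(concordance_pairwise(dplyr::bind_rows(a, b),
                                   c("taqman", "str")))
  expect_equal(got$n_paired, 85)
  expect_equal(got$rate, 100)
})

test_that("multiway agreement requires set-wide equality and bounds pairwise rates", {
  a <- agreeing_calls("taqman", "FCGR3B", truth90, 90)
  b <- agreeing_calls("sybr", "FCGR3B", truth90, 56)
  c3 <- agreeing_calls("prt_redvr", "FCGR3B", truth90, 90)
  calls <- dplyr::bind_rows(a, b, c3)
  multi <- tidy(concordance_multiway(calls, c("taqman", "sybr", "prt_redvr")))
  expect_equal(multi$rate, 62.22)

  shifted <- dplyr::mutate(c3, integer_call = integer_call + 1L)
  calls2 <- dplyr::bind_rows(a, b, shifted)
  multi2 <- tidy(concordance_multiway(calls2, c("taqman", "sybr", "prt_redvr")))
  expect_equal(multi2$rate, 0)

  pair_min <- min(purrr::map_dbl(
    list(c("taqman", "sybr"), c("taqman", "prt_redvr"),
         c("sybr", "prt_redvr")),
    function(pr) tidy(concordance_pairwise(calls, pr))$rate))
  expect_lte(multi$rate, pair_min)
})

test_that("reference concordance counts paired samples and errors on empty overlap", {
  ref <- tibble::tibble(sample_id = sprintf("S%03d", 1:85),
                        locus = "FCGR3A", truth_cn = 2L)
  calls <- agreeing_calls("taqman", "FCGR3A", truth90, 83)
  # samples 84..85 disagree within the reference; 86..90 are unpaired
  got <- concordance_with_reference(calls, ref)
  td <- tidy(got)
  expect_equal(td$n_paired, 85)
  expect_equal(td$n_agree, 83L)
  expect_equal(td$rate, 97.65)
  expect_setequal(attr(got, "dropped"), sprintf("S%03d", 86:90))

  ref_elsewhere <- dplyr::mutate(ref, sample_id = paste0("X", sample_id))
  expect_error(concordance_with_reference(calls, ref_elsewhere),
               "zero paired")
})

test_that("a 78/85 agreement reproduces a 91.76% concordance rate", {
  ref <- tibble::tibble(sample_id = sprintf("S%03d", 1:85),
                        locus = "FCGR3A", truth_cn = 2L)
  calls <- agreeing_calls("taqman", "FCGR3A", rep(2L, 85), 78)
  expect_equal(tidy(concordance_with_reference(calls, ref))$rate, 91.76)
})

test_that("Pearson correlation matches the direct formula and handles the degenerate cases", {
  x <- c(1, 2, 3, 4)
  y <- c(1.1, 1.9, 3.2, 3.8)
  # independent formula evaluation
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  calls <- calls_fixture(sprintf("S%d", 1:4), "taqman", "FCGR3", x, x)
  dosage <- tibble::tibble(sample_id = sprintf("S%d", 1:4), dosage = y)
  got <- correlate_with_dosage(calls, dosage)
  expect_equal(got$r, r_hand, tolerance = 1e-12)
  expect_equal(got$used, "continuous")

  up <- tibble::tibble(sample_id = sprintf("S%d", 1:4), dosage = x)
  expect_equal(correlate_with_dosage(calls, up)$r, 1)
  down <- tibble::tibble(sample_id = sprintf("S%d", 1:4), dosage = -x)
  expect_equal(correlate_with_dosage(calls, down)$r, -1)

  flat <- calls_fixture(sprintf("S%d", 1:4), "taqman", "FCGR3",
                        rep(2L, 4), rep(2, 4))
  expect_error(correlate_with_dosage(flat, dosage), "zero variance")
  expect_error(correlate_with_dosage(calls[1:2, ], dosage), ">= 3")
})

test_that("error-direction profiles partition every truth class", {
  truth <- genotypes_fixture(c(1L, 1L, 1L, 1L), c(1L, 1L, 1L, 1L),
                             ids = sprintf("S%d", 1:4))
  calls <- calls_fixture(sprintf("S%d", 1:4), "taqman", "FCGR3",
                         c(3L, 3L, 2L, 2L))
  prof <- tidy(error_direction_profile(calls, truth, locus = "FCGR3"))
  expect_equal(prof$n_above, 2L)
  expect_equal(prof$n_below, 0L)
  expect_equal(prof$n_equal, 2L)
  expect_equal(prof$pct_above, 50)
  expect_equal(prof$pct_equal, 50)
  expect_equal(prof$n_above + prof$n_below + prof$n_equal, prof$n)

  perfect <- calls_fixture(sprintf("S%d", 1:4), "str", "FCGR3", rep(2L, 4))
  prof2 <- tidy(error_direction_profile(perfect, truth, locus = "FCGR3"))
  expect_equal(prof2$pct_equal, 100)
})

test_that("concordance with truth degrades monotonically in noise scale", {
  rates <- purrr::map_dbl(c(0, 0.15, 0.5), function(scale) {
    cohort <- simulate_cohort(
      n = 500, seed = 97,
      noise = noise_model(ct_sd = scale, area_cv = scale))
    calls <- suppressWarnings(call_all_methods(cohort))
    td <- tidy(concordance_with_reference(
      dplyr::filter(calls, method == "taqman"), cohort$truth,
      locus = "FCGR3"))
    td$rate
  })
  expect_true(all(diff(rates) <= 0))
  expect_equal(rates[1], 100)
})

test_that("evaluation objects print, tidy, glance and autoplot coherently", {
  a <- agreeing_calls("taqman", "FCGR3B", truth90, 80)
  b <- agreeing_calls("sybr", "FCGR3B", truth90, 90)
  conc <- concordance_pairwise(dplyr::bind_rows(a, b), c("taqman", "sybr"))
  expect_output(print(conc), "88.89")
  expect_s3_class(autoplot(conc), "ggplot")
  expect_equal(glance(conc)$n_paired_total, 90)

  truth <- genotypes_fixture(rep(1L, 90), rep(1L, 90),
                             ids = sprintf("S%03d", 1:90))
  prof <- error_direction_profile(a, truth, locus = "FCGR3B")
  expect_s3_class(autoplot(prof), "ggplot")
  gl <- glance(prof)
  expect_equal(gl$n_above + gl$n_below +
                 sum(tidy(prof)$n_equal), gl$n)

  calls <- calls_fixture(sprintf("S%d", 1:5), "taqman", "FCGR3",
                         1:5, c(1.1, 2.2, 2.8, 4.1, 4.9))
  dosage <- tibble::tibble(sample_id = sprintf("S%d", 1:5),
                           dosage = c(1, 2, 3, 4, 5))
  corr <- correlate_with_dosage(calls, dosage)
  expect_s3_class(autoplot(corr), "ggplot")
  expect_equal(tidy(corr)$n, 5)
})
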