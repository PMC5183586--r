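test_that("population and noise models validate their parameters", {
  expect_error(population_model(freq_a = c(`0` = 0.5, `1` = 0.6)), "sum to 1")
  expect_error(noise_model(ct_sd = -0.1), ">= 0")
  pm <- population_model()
  expect_equal(sum(pm$freq_a), 1)
})

test_that("a point-mass population yields the degenerate cohort", {
  pm <- population_model(freq_a = c(`1` = 1), freq_b = c(`1` = 1))
  g <- sample_genotypes(pm, 25, seed = 3)
  expect_true(all(g$cn_a == 1 & g$cn_b == 1 & g$cn_total == 2))
})

test_that("empirical class frequencies match a uniform model within 3 binomial sd", {
  pm <- population_model(freq_a = c(`1` = 1, `2` = 1, `3` = 1) / 3,
                         freq_b = c(`1` = 1, `2` = 1, `3` = 1) / 3)
  g <- sample_genotypes(pm, 10000, seed = 11)
  sd3 <- 3 * sqrt((1 / 3) * (2 / 3) / 10000)
  for (k in 1:3) {
    expect_lt(abs(mean(g$cn_a == k) - 1 / 3), sd3)
    expect_lt(abs(mean(g$cn_b == k) - 1 / 3), sd3)
  }
})

test_that("identical seeds reproduce identical cohorts, different seeds differ", {
  c1 <- simulate_cohort(n = 30, noise = noise_model(ct_sd = 0.2, area_cv = 0.1),
                        seed = 5)
  c2 <- simulate_cohort(n = 30, noise = noise_model(ct_sd = 0.2, area_cv = 0.1),
                        seed = 5)
  c3 <- simulate_cohort(n = 30, noise = noise_model(ct_sd = 0.2, area_cv = 0.1),
                        seed = 6)
  expect_identical(c1$truth, c2$truth)
  expect_identical(c1$qpcr_taqman, c2$qpcr_taqman)
  expect_identical(c1$peaks, c2$peaks)
  expect_false(identical(c1$peaks$area, c3$peaks$area))
})

test_that("noise-free duplex qPCR: a 4-copy sample crosses one cycle before the 2-copy calibrator", {
  g <- genotypes_fixture(2L, 2L)  # cn_b = 2 unused; target FCGR3A cn 4 below
  g4 <- genotypes_fixture(4L, 0L)
  m <- simulate_taqman(g4, "FCGR3A", noise_model(), efficiency = 2,
                       calibrator_cn = 2)
  ct_sample <- mean(m$ct[m$sample_id != "CAL" & m$role == "target"])
  ct_cal <- mean(m$ct[m$sample_id == "CAL" & m$role == "target"])
  expect_equal(ct_cal - ct_sample, 1, tolerance = 1e-12)
  # and the caller recovers the fixed point
  calls <- call_taqman(m)
  expect_equal(calls$integer_call, 4L)
  m2 <- simulate_taqman(g, "FCGR3A", noise_model())
  expect_equal(call_taqman(m2)$continuous_estimate, 2, tolerance = 1e-12)
})

test_that("zero-copy samples report the no-amplification sentinel and call 0", {
  g <- genotypes_fixture(0L, 2L)
  m <- simulate_taqman(g, "FCGR3A", noise_model(ct_sd = 0.3))
  tgt <- m$ct[m$sample_id == "G001" & m$role == "target"]
  expect_true(all(tgt > 40))
  expect_equal(call_taqman(m)$integer_call[1], 0L)
})

test_that("Monte-Carlo mean of the TaqMan continuous estimate matches the lognormal closed form", {
  # Per replicate-mean difference: 4 independent mean-of-3 Ct terms,
  # var = 4 * ct_sd^2 / 3; the estimate is 2 * 2^eps, eps ~ N(0, sd_cycles),
  # so E[estimate] = 2 * exp(sigma_ln^2 / 2) with sigma_ln = sd_cycles * ln 2.
  ct_sd <- 0.2
  sd_cycles <- sqrt(4 * ct_sd^2 / 3)
  sigma_ln <- sd_cycles * log(2)
  expected_mean <- 2 * exp(sigma_ln^2 / 2)
  set.seed(101)
  g <- genotypes_fixture(2L, 2L)
  reps <- 400
  est <- vapply(seq_len(reps), function(i) {
    m <- simulate_taqman(g, "FCGR3A", noise_model(ct_sd = ct_sd))
    call_taqman(m)$continuous_estimate
  }, numeric(1))
  mc_se <- sd(est) / sqrt(reps)
  expect_lt(abs(mean(est) - expected_mean), 2 * mc_se + 1e-12)
  # the median stays at the true copy number (log-symmetric noise)
  expect_lt(abs(median(est) - 2), 4 * mc_se)
})

test_that("noise-free PRT areas are proportional to copy number", {
  g <- genotypes_fixture(2L, 2L)
  peaks <- simulate_prt(g, noise_model())
  obs <- compute_prt_ratio(peaks)
  expect_equal(obs$ratio_raw, 2)  # 4 copies vs 2 reference copies
  g0 <- genotypes_fixture(0L, 0L)
  p0 <- simulate_prt(g0, noise_model())
  expect_equal(p0$area[p0$size_bp == 171], 0)
})

test_that("an absent paralog gives a zero-area digest peak and fraction at the boundary", {
  g <- genotypes_fixture(0L, 2L)
  peaks <- simulate_redvr(g, noise_model())
  c733 <- peaks[peaks$assay == "REDVR_C733", ]
  expect_equal(c733$area[c733$size_bp == 120], 0)
  expect_equal(redvr_fractions(peaks)$fraction_a, 0)
})

test_that("Monte-Carlo mean of the digest FCGR3A fraction is 0.5 for a (1,1) genotype", {
  set.seed(202)
  n <- 1000
  g <- genotypes_fixture(rep(1L, n), rep(1L, n))
  peaks <- simulate_redvr(g, noise_model(area_cv = 0.1), hna1a_freq = 0.5)
  fr <- redvr_fractions(peaks)$fraction_a
  mc_se <- sd(fr) / sqrt(n)
  expect_lt(abs(mean(fr) - 0.5), 2 * mc_se + 1e-12)  # exact by symmetry
})

test_that("STR simulation obeys the stutter coincidence and dosage rules", {
  # no stutter, one copy each of 150 and 154: two equal peaks
  al <- tibble::tibble(sample_id = "S1", length_bp = c(150, 154))
  p <- simulate_str(al, noise_model())
  expect_equal(nrow(p), 2)
  expect_equal(p$area[1], p$area[2])

  # alleles 150 and 152 with stutter on: the 150 peak carries its true
  # area plus the 152 peak's stutter
  al2 <- tibble::tibble(sample_id = "S1", length_bp = c(150, 152))
  nm <- noise_model(slippage_alpha = 0.004, slippage_offset = 130)
  p2 <- simulate_str(al2, nm, base_area = 1000)
  a150 <- p2$area[p2$size_bp == 150]
  expect_equal(a150, 1000 + 0.004 * (152 - 130) * 1000)

  # 2 copies of 150 + 1 copy of 154, noise off: areas in ratio 2:1
  al3 <- tibble::tibble(sample_id = "S1", length_bp = c(150, 150, 154))
  p3 <- simulate_str(al3, noise_model())
  expect_equal(p3$area[p3$size_bp == 150] / p3$area[p3$size_bp == 154], 2)

  expect_error(simulate_str(tibble::tibble(sample_id = "S1", length_bp = -4),
                            noise_model()), "non-positive")
})

test_that("distinct per-copy allele assignment is reproducible and spans the genotype", {
  g <- genotypes_fixture(c(2L, 3L), c(2L, 2L))
  set.seed(9); a1 <- assign_str_alleles(g)
  set.seed(9); a2 <- assign_str_alleles(g)
  expect_identical(a1, a2)
  counts <- table(a1$sample_id)
  expect_equal(as.integer(counts[g$sample_id]), g$cn_total)
  expect_false(any(duplicated(a1[c("sample_id", "length_bp")])))
})
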