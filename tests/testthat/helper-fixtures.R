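# Shared fixtures and independent oracles used across the suite.

genotypes_fixture <- function(cn_a, cn_b, ids = NULL) {
  n <- length(cn_a)
  tibble::tibble(
    sample_id = if (is.null(ids)) sprintf("G%03d", seq_len(n)) else ids,
    cn_a = cn_a, cn_b = cn_b, cn_total = cn_a + cn_b)
}

calls_fixture <- function(sample_id, method, locus, integer_call,
                          continuous_estimate = NA_real_) {
  tibble::tibble(sample_id = sample_id, method = method, locus = locus,
                 continuous_estimate = continuous_estimate,
                 integer_call = as.integer(integer_call))
}

# A call table where `method` agrees with a truth vector on exactly
# `n_agree` of `n` samples (disagreements call one copy above truth).
agreeing_calls <- function(method, locus, truth_cn, n_agree) {
  n <- length(truth_cn)
  call <- truth_cn
  if (n_agree < n) call[(n_agree + 1):n] <- truth_cn[(n_agree + 1):n] + 1L
  calls_fixture(sprintf("S%03d", seq_len(n)), method, locus, call)
}

# Independent brute-force maximum-likelihood enumerator: written as plain
# nested loops with the Gaussian log-density spelled out, deliberately
# sharing no code with ml_call().
brute_force_ml <- function(ratio, fraction_a, sigma_ratio, sigma_fraction,
                           ceiling = 8) {
  log_norm <- function(x, mu, s) {
    -0.5 * log(2 * pi) - log(s) - 0.5 * ((x - mu) / s)^2
  }
  n_hyp <- (ceiling + 1) * (ceiling + 2) / 2
  log_prior <- log(1 / n_hyp)
  best <- NULL
  best_ll <- -Inf
  for (total in 0:ceiling) {
    for (a in 0:total) {
      b <- total - a
      ll <- log_prior + log_norm(ratio, total / 2, sigma_ratio)
      if (!is.na(fraction_a) && total > 0) {
        ll <- ll + log_norm(fraction_a, a / total, sigma_fraction)
      }
      if (ll > best_ll + 1e-12) {
        best_ll <- ll
        best <- c(a = a, b = b)
      }
    }
  }
  best
}

# One noise-free end-to-end cohort kept small for reuse.
noise_free_cohort <- function(n = 40, seed = 7) {
  suppressWarnings(simulate_cohort(n = n, noise = noise_model(), seed = seed))
}

expect_no_flag <- function(calls) {
  expect_true(all(is.na(calls$flag)))
}
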