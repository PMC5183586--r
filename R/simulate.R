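#' Population model for FCGR3A/FCGR3B copy numbers
#'
#' Describes the cohort the generator draws from: a distribution over
#' per-gene copy-number classes 0..4 for each gene, drawn independently.
#' The defaults put the mode at the diploid two copies per gene (four
#' total) with minor mass on deletions and duplications, so a simulated
#' cohort spans FCGR3 totals of roughly 2..7 like East Asian reference
#' panels.  The frequencies are stand-in defaults, fully configurable.
#'
#' @param freq_a,freq_b named numeric vectors of class frequencies for
#'   copy numbers `"0"`..`"4"`; each must sum to 1 (tolerance 1e-9).
#' @return object of class `population_model`.
#' @export
population_model <- function(
    freq_a = c(`0` = 0.01, `1` = 0.05, `2` = 0.85, `3` = 0.08, `4` = 0.01),
    freq_b = freq_a) {
  for (f in list(freq_a, freq_b)) {
    if (is.null(names(f)) || any(f < 0) || abs(sum(f) - 1) > 1e-9) {
      abort("class frequencies must be named, non-negative, and sum to 1")
    }
  }
  structure(list(freq_a = freq_a, freq_b = freq_b),
            class = "population_model")
}

#' Assay noise model
#'
#' Collects every stochastic knob of the signal generator.  Ct noise is
#' additive Gaussian in cycles (consistent with log-scale measurement of
#' an exponential process); peak-area noise is multiplicative lognormal
#' with median 1 and coefficient of variation `area_cv`; polymerase
#' slippage produces a stutter peak 2 bp below each true microsatellite
#' allele with area fraction `slippage_alpha * (length - slippage_offset)`
#' of the parent; `efficiency_jitter` perturbs the per-run amplification
#' efficiency on the log scale.  All parameters default to 0 (noise-free),
#' under which every caller recovers the simulated truth exactly.
#'
#' @param ct_sd standard deviation of a single replicate Ct, cycles.
#' @param area_cv lognormal coefficient of variation of peak areas.
#' @param slippage_alpha stutter fraction per bp of allele length above
#'   `slippage_offset`.
#' @param slippage_offset allele length (bp) at which stutter vanishes.
#' @param efficiency_jitter sd of per-run log amplification-efficiency
#'   deviation.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(ct_sd = 0, area_cv = 0, slippage_alpha = 0,
                        slippage_offset = 130, efficiency_jitter = 0) {
  vals <- c(ct_sd = ct_sd, area_cv = area_cv, slippage_alpha = slippage_alpha,
            efficiency_jitter = efficiency_jitter)
  if (any(vals < 0)) abort("noise parameters must be >= 0")
  structure(list(ct_sd = ct_sd, area_cv = area_cv,
                 slippage_alpha = slippage_alpha,
                 slippage_offset = slippage_offset,
                 efficiency_jitter = efficiency_jitter),
            class = "noise_model")
}

#' Draw a cohort of true copy-number genotypes
#'
#' @param model a [population_model()].
#' @param n cohort size.
#' @param seed optional integer seed; identical seeds give identical
#'   cohorts.
#' @return genotype tibble (`sample_id`, `cn_a`, `cn_b`, `cn_total`).
#' @export
sample_genotypes <- function(model, n, seed = NULL) {
  if (!inherits(model, "population_model")) abort("not a population_model")
  if (!is.null(seed)) set.seed(seed)
  classes_a <- as.integer(names(model$freq_a))
  classes_b <- as.integer(names(model$freq_b))
  cn_a <- sample(classes_a, n, replace = TRUE, prob = model$freq_a)
  cn_b <- sample(classes_b, n, replace = TRUE, prob = model$freq_b)
  tibble(sample_id = sprintf("S%04d", seq_len(n)),
         cn_a = cn_a, cn_b = cn_b, cn_total = cn_a + cn_b)
}

#' Simulate duplex qPCR cycle-threshold measurements
#'
#' Emulates a duplex TaqMan-style run: the target amplicon (FCGR3A or
#' FCGR3B) and the fixed two-copy reference amplicon (the coagulation
#' factor V role) amplified in the same tube, each in triplicate.  The
#' expected relative quantity of the target equals `cn / calibrator_cn`
#' at the declared efficiency: a sample with twice the calibrator's
#' copies crosses threshold exactly one cycle earlier at efficiency 2.
#' Zero-copy samples report the no-amplification sentinel (Ct 99, beyond
#' the 40-cycle run).  A calibrator sample with `calibrator_cn` copies is
#' appended under `calibrator_id`.
#'
#' @param genotypes genotype tibble.
#' @param locus `"FCGR3A"` or `"FCGR3B"` — which gene the probe targets.
#' @param noise a [noise_model()].
#' @param efficiency amplification factor per cycle (2 = perfect
#'   doubling).
#' @param calibrator_cn known copy number of the calibrator sample.
#' @param base_ct expected target Ct of the calibrator.
#' @param reference_ct expected Ct of the two-copy reference amplicon.
#' @param replicates replicate count per amplicon (default triplicate).
#' @param run_id run label.
#' @param calibrator_id sample id given to the appended calibrator.
#' @return long qPCR tibble: `sample_id`, `locus`, `role`
#'   (target/reference), `replicate`, `ct`, `run_id`.
#' @export
simulate_taqman <- function(genotypes, locus, noise = noise_model(),
                            efficiency = 2, calibrator_cn = 2,
                            base_ct = 26, reference_ct = 25,
                            replicates = 3, run_id = "run1",
                            calibrator_id = "CAL") {
  locus <- arg_match(locus, c("FCGR3A", "FCGR3B"))
  g <- validate_genotypes(genotypes)
  if (calibrator_cn < 1) abort("calibrator_cn must be >= 1")
  cn <- if (locus == "FCGR3A") g$cn_a else g$cn_b
  ids <- c(g$sample_id, calibrator_id)
  cn <- c(cn, calibrator_cn)
  eff_run <- efficiency * exp(rnorm(1, 0, noise$efficiency_jitter))
  expected_target <- ifelse(cn == 0, CT_NO_AMP,
                            base_ct - log(cn / calibrator_cn) / log(eff_run))
  rows <- purrr::map(seq_along(ids), function(i) {
    tgt <- if (cn[i] == 0) rep(CT_NO_AMP, replicates) else
      expected_target[i] + rnorm(replicates, 0, noise$ct_sd)
    ref <- reference_ct + rnorm(replicates, 0, noise$ct_sd)
    tibble(sample_id = ids[i], locus = locus,
           role = rep(c("target", "reference"), each = replicates),
           replicate = rep(seq_len(replicates), 2),
           ct = c(tgt, ref), run_id = run_id)
  })
  list_rbind(rows)
}

#' Simulate a qPCR dilution series for standard-curve fitting
#'
#' Produces (log10 relative quantity, Ct) pairs on the line implied by the
#' given efficiency (slope `-1/log10(E)` cycles per log), with optional
#' Gaussian Ct noise — the input expected by [fit_standard_curve()].  Each
#' dilution point is measured in `replicates` wells and the replicate mean
#' Ct reported, the way standard curves are run in practice.
#'
#' @inheritParams simulate_taqman
#' @param log10_quantities log10 relative input quantities of the
#'   dilution points (default seven points over three logs).
#' @param base_ct expected Ct at log10 quantity 0.
#' @return tibble with columns `log10_quantity`, `ct`.
#' @export
simulate_dilution_series <- function(efficiency = 2, base_ct = 25,
                                     log10_quantities = seq(0, -3, by = -0.5),
                                     noise = noise_model(), replicates = 3) {
  slope <- -1 / log10(efficiency)
  k <- length(log10_quantities)
  reps <- matrix(rnorm(k * replicates, 0, noise$ct_sd), nrow = k)
  tibble(log10_quantity = log10_quantities,
         ct = base_ct + slope * log10_quantities + rowMeans(reps))
}

#' Default electrophoresis peak layouts
#'
#' Expected product sizes for each capillary assay: the paralog ratio test
#' co-amplifies a product common to FCGR3A and FCGR3B plus a chromosome-18
#' reference of a different length; the C733 (Arg>Stop) digest resolves
#' FCGR3A- from FCGR3B-derived product; the C147T digest resolves the
#' HNA1a and HNA1b alleles within FCGR3B.  Sizes are fixed conventions of
#' the simulator/caller pair, configurable for real exports.
#'
#' @param target_bp,reference_bp expected product sizes, bp.
#' @param tol_bp half-width of the size window used to match peaks.
#' @return a layout tibble with columns `role`, `size_bp` and attribute
#'   `tol_bp`.
#' @export
prt_layout <- function(target_bp = 171, reference_bp = 194, tol_bp = 1) {
  structure(tibble(role = c("target", "reference"),
                   size_bp = c(target_bp, reference_bp)),
            tol_bp = tol_bp)
}

#' @param fcgr3a_bp,fcgr3b_bp digest product sizes of the C733 assay.
#' @param hna1a_bp,hna1b_bp digest product sizes of the C147T assay.
#' @rdname prt_layout
#' @export
redvr_layout <- function(fcgr3a_bp = 120, fcgr3b_bp = 147,
                         hna1a_bp = 89, hna1b_bp = 110, tol_bp = 1) {
  structure(list(
    c733 = tibble(role = c("fcgr3a", "fcgr3b"),
                  size_bp = c(fcgr3a_bp, fcgr3b_bp)),
    c147t = tibble(role = c("hna1a", "hna1b"),
                   size_bp = c(hna1a_bp, hna1b_bp))),
    tol_bp = tol_bp)
}

#' Simulate paralog-ratio-test and digest-variant-ratio peak tables
#'
#' `simulate_prt()` emits, per sample, a combined FCGR3A+FCGR3B product
#' peak with expected area proportional to `cn_a + cn_b` and a
#' chromosome-18 reference peak proportional to 2 copies.  A zero-copy
#' sample yields a zero-area target peak.  `simulate_redvr()` emits the
#' two digest assays: C733 peaks with areas proportional to `cn_a` vs
#' `cn_b`, and C147T peaks proportional to the HNA1a vs HNA1b split of
#' the FCGR3B copies (drawn binomially with frequency `hna1a_freq`).
#' All areas get independent median-one lognormal noise.
#'
#' @inheritParams simulate_taqman
#' @param base_area expected area per gene copy, arbitrary fluorescence
#'   units.
#' @param layout a [prt_layout()] / [redvr_layout()].
#' @param repeats independent assay repeats whose signals are averaged
#'   (the emulated protocol runs each electrophoresis assay three times).
#' @return peak tibble (`sample_id`, `assay`, `size_bp`, `height`, `area`).
#' @export
simulate_prt <- function(genotypes, noise = noise_model(),
                         base_area = 10000, layout = prt_layout(),
                         repeats = 1) {
  g <- validate_genotypes(genotypes)
  n <- nrow(g)
  target <- base_area * g$cn_total *
    lognormal_factor_mean(n, noise$area_cv, repeats)
  refs <- base_area * 2 * lognormal_factor_mean(n, noise$area_cv, repeats)
  out <- tibble(
    sample_id = rep(g$sample_id, 2),
    assay = "PRT",
    size_bp = rep(layout$size_bp[match(c("target", "reference"), layout$role)],
                  each = n),
    area = c(target, refs))
  out$height <- out$area / 10
  arrange(out[, c("sample_id", "assay", "size_bp", "height", "area")],
          .data$sample_id, .data$size_bp)
}

#' @param hna1a_freq population frequency of the HNA1a allele among
#'   FCGR3B copies.
#' @rdname simulate_prt
#' @export
simulate_redvr <- function(genotypes, noise = noise_model(),
                           base_area = 8000, layout = redvr_layout(),
                           hna1a_freq = 0.5, repeats = 1) {
  g <- validate_genotypes(genotypes)
  n <- nrow(g)
  n_hna1a <- rbinom(n, g$cn_b, hna1a_freq)
  c733 <- layout$c733
  c147t <- layout$c147t
  peak <- function(assay, size, copies) {
    tibble(sample_id = g$sample_id, assay = assay, size_bp = size,
           area = base_area * copies *
             lognormal_factor_mean(n, noise$area_cv, repeats))
  }
  out <- bind_rows(
    peak("REDVR_C733", c733$size_bp[c733$role == "fcgr3a"], g$cn_a),
    peak("REDVR_C733", c733$size_bp[c733$role == "fcgr3b"], g$cn_b),
    peak("REDVR_C147T", c147t$size_bp[c147t$role == "hna1a"], n_hna1a),
    peak("REDVR_C147T", c147t$size_bp[c147t$role == "hna1b"], g$cn_b - n_hna1a))
  out$height <- out$area / 10
  out <- out[, c("sample_id", "assay", "size_bp", "height", "area")]
  attr(out, "n_hna1a") <- setNames(n_hna1a, g$sample_id)
  arrange(out, .data$sample_id, .data$assay, .data$size_bp)
}

#' Assign microsatellite allele lengths to genotype copies
#'
#' Gives every FCGR3 copy of every sample a distinct dinucleotide-spaced
#' MSAT1 allele length drawn without replacement from `ladder`.  Distinct
#' per-copy lengths make each electropherogram peak carry exactly one
#' copy, the configuration under which the published normalizer-peak
#' dosage rules are exact (see the methods vignette for what this does
#' and does not emulate about real homozygosity).
#'
#' @param genotypes genotype tibble.
#' @param ladder admissible allele lengths, bp (dinucleotide spacing).
#' @return tibble with columns `sample_id`, `length_bp`, one row per copy.
#' @export
assign_str_alleles <- function(genotypes,
                               ladder = seq(140, 162, by = 2)) {
  g <- validate_genotypes(genotypes)
  if (max(g$cn_total) > length(ladder)) {
    abort("allele ladder shorter than the largest total copy number")
  }
  rows <- purrr::map(seq_len(nrow(g)), function(i) {
    k <- g$cn_total[i]
    if (k == 0) return(NULL)
    tibble(sample_id = g$sample_id[i],
           length_bp = sort(sample(ladder, k, replace = FALSE)))
  })
  list_rbind(rows)
}

#' Simulate MSAT1 microsatellite peak tables with polymerase stutter
#'
#' One true peak per distinct allele length, with expected area
#' proportional to the number of copies of that length; each true allele
#' additionally generates a slippage (stutter) peak 2 bp smaller with
#' area `slippage_alpha * (length - slippage_offset)` times the parent
#' area.  A stutter peak coinciding with a true allele 2 bp below its
#' parent is summed into that peak — the overlap the length-dependent
#' correction in [correct_slippage()] later undoes.  Lognormal noise is
#' applied to each emitted peak.
#'
#' @param alleles allele table from [assign_str_alleles()] (one row per
#'   copy, columns `sample_id`, `length_bp`).
#' @inheritParams simulate_prt
#' @return peak tibble with `assay = "STR"`.
#' @export
simulate_str <- function(alleles, noise = noise_model(), base_area = 5000,
                         repeats = 1) {
  assert_columns(alleles, c("sample_id", "length_bp"), "allele table")
  if (any(alleles$length_bp <= 0)) abort("non-positive allele length")
  frac_max <- noise$slippage_alpha *
    (max(alleles$length_bp) - noise$slippage_offset)
  if (frac_max >= 1) abort("stutter fraction reaches 1 on the size range")
  rows <- alleles |>
    group_by(.data$sample_id, .data$length_bp) |>
    summarise(copies = n(), .groups = "drop")
  out <- rows |>
    group_by(.data$sample_id) |>
    group_modify_str(noise, base_area, repeats)
  out$height <- out$area / 10
  arrange(out[, c("sample_id", "assay", "size_bp", "height", "area")],
          .data$sample_id, .data$size_bp)
}

## Per-sample expected peak construction (true + stutter, coincidence
## summed), then per-peak noise.
group_modify_str <- function(grouped, noise, base_area, repeats = 1) {
  dplyr::group_modify(grouped, function(df, key) {
    true_area <- setNames(base_area * df$copies, df$length_bp)
    stutter_len <- df$length_bp - 2
    stutter_area <- noise$slippage_alpha *
      pmax(df$length_bp - noise$slippage_offset, 0) * true_area
    areas <- true_area
    for (j in seq_along(stutter_len)) {
      key_j <- as.character(stutter_len[j])
      if (stutter_area[j] <= 0) next
      if (key_j %in% names(areas)) {
        areas[key_j] <- areas[key_j] + stutter_area[j]
      } else {
        areas[key_j] <- stutter_area[j]
      }
    }
    sizes <- as.numeric(names(areas))
    obs <- as.numeric(areas) *
      lognormal_factor_mean(length(areas), noise$area_cv, repeats)
    tibble(assay = "STR", size_bp = sizes, area = obs)
  }) |> ungroup()
}

#' Simulate a complete multi-assay cohort
#'
#' One call produces everything the downstream pipeline consumes for a
#' cohort of `n` diploid individuals: the truth genotypes, TaqMan-style
#' duplex qPCR measurements for both genes, SYBR-style qPCR measurements
#' for FCGR3B plus target/reference dilution series, PRT and REDVR and
#' STR peak tables, a continuous array-style dosage reference
#' (`cn_total` with multiplicative lognormal noise of CV `dosage_cv`),
#' and the ids of `n_calibration` samples earmarked as known-truth
#' calibration standards.  Fully deterministic under `seed`.
#'
#' @param n cohort size (the emulated reference cohort has 90).
#' @param pop a [population_model()].
#' @param noise a [noise_model()].
#' @param seed integer seed.
#' @param dosage_cv lognormal CV of the continuous dosage reference.
#' @param hna1a_freq HNA1a allele frequency for the C147T digest.
#' @param n_calibration number of leading samples reserved as
#'   known-truth calibration standards.
#' @param assay_repeats independent repeats of every assay (default 3,
#'   the emulated study protocol): qPCR samples get
#'   `3 * assay_repeats` pooled replicate wells, and each
#'   electrophoresis assay's peak areas are averaged over
#'   `assay_repeats` repeats.
#' @return a list of class `fcgr_cohort`; see Details for components.
#' @details Components: `truth` (genotypes), `qpcr_taqman` (both loci),
#'   `qpcr_sybr` (FCGR3B), `dilution_target`/`dilution_reference`,
#'   `peaks` (PRT + REDVR + STR), `str_alleles`, `dosage`,
#'   `calibration_ids`, `params`.
#' @export
simulate_cohort <- function(n = 90, pop = population_model(),
                            noise = noise_model(), seed = 1,
                            dosage_cv = 0.2, hna1a_freq = 0.5,
                            n_calibration = 12, assay_repeats = 3) {
  set.seed(seed)
  truth <- sample_genotypes(pop, n)
  wells <- 3 * assay_repeats
  qpcr_a <- simulate_taqman(truth, "FCGR3A", noise, run_id = "taqman_A",
                            replicates = wells)
  qpcr_b <- simulate_taqman(truth, "FCGR3B", noise, run_id = "taqman_B",
                            replicates = wells)
  qpcr_sybr <- simulate_taqman(truth, "FCGR3B", noise, run_id = "sybr_B",
                               replicates = wells)
  dil_t <- simulate_dilution_series(noise = noise, replicates = wells)
  dil_r <- simulate_dilution_series(noise = noise, replicates = wells)
  prt <- simulate_prt(truth, noise, repeats = assay_repeats)
  redvr <- simulate_redvr(truth, noise, hna1a_freq = hna1a_freq,
                          repeats = assay_repeats)
  alleles <- assign_str_alleles(truth)
  str_peaks <- simulate_str(alleles, noise, repeats = assay_repeats)
  dosage <- tibble(sample_id = truth$sample_id,
                   dosage = truth$cn_total * lognormal_factor(n, dosage_cv))
  structure(list(
    truth = truth,
    qpcr_taqman = bind_rows(qpcr_a, qpcr_b),
    qpcr_sybr = qpcr_sybr,
    dilution_target = dil_t,
    dilution_reference = dil_r,
    peaks = bind_rows(prt, redvr, str_peaks),
    str_alleles = alleles,
    dosage = dosage,
    calibration_ids = head(truth$sample_id, n_calibration),
    params = list(n = n, seed = seed, noise = noise, dosage_cv = dosage_cv,
                  hna1a_freq = hna1a_freq, assay_repeats = assay_repeats)),
    class = "fcgr_cohort")
}

#' @export
print.fcgr_cohort <- function(x, ...) {
  cat(sprintf("<fcgr_cohort> n = %d, seed = %d\n",
              x$params$n, x$params$seed))
  cat(sprintf("  noise: ct_sd = %g, area_cv = %g, slippage_alpha = %g\n",
              x$params$noise$ct_sd, x$params$noise$area_cv,
              x$params$noise$slippage_alpha))
  invisible(x)
}
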