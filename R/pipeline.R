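#' Run every caller on a simulated cohort
#'
#' Convenience wrapper chaining the four callers over the outputs of
#' [simulate_cohort()]: TaqMan duplex calls for FCGR3A and FCGR3B (with
#' the FCGR3 total as the sum of gene-level calls), SYBR standard-curve
#' calls for FCGR3B, PRT+REDVR maximum-likelihood calls for all three
#' loci (calibrated on the cohort's reserved known-truth samples), and
#' STR calls for the FCGR3 total using the stutter parameters of the
#' cohort's noise model (an assay property established by calibration).
#'
#' @param cohort an `fcgr_cohort` from [simulate_cohort()].
#' @param integrate if `TRUE`, majority-consensus calls
#'   (`method = "integrated"`) are appended via [integrate_calls()].
#' @param policy [integration_policy()] used when `integrate = TRUE`.
#' @param anchor_mode if `TRUE` (default), qPCR estimates are rescaled to
#'   the diploid modal cluster with [anchor_diploid_mode()] before
#'   rounding — the refined-assay calibration appropriate for cohorts
#'   whose modal per-gene copy number is 2.
#' @return long call tibble over all methods.
#' @export
call_all_methods <- function(cohort, integrate = FALSE,
                             policy = integration_policy(),
                             anchor_mode = TRUE) {
  if (!inherits(cohort, "fcgr_cohort")) abort("not an fcgr_cohort")
  noise <- cohort$params$noise

  taqman <- call_taqman(cohort$qpcr_taqman)
  if (anchor_mode) taqman <- anchor_diploid_mode(taqman)
  taqman <- sum_locus_calls(taqman)

  curve_t <- fit_standard_curve(cohort$dilution_target)
  curve_r <- fit_standard_curve(cohort$dilution_reference)
  sybr <- call_sybr(cohort$qpcr_sybr, curve_t, curve_r)
  if (anchor_mode) sybr <- anchor_diploid_mode(sybr)

  prt_obs <- compute_prt_ratio(cohort$peaks)
  redvr_obs <- redvr_fractions(cohort$peaks)
  cal_truth <- cohort$truth[cohort$truth$sample_id %in%
                              cohort$calibration_ids, ]
  calibration <- calibrate_prt(prt_obs, cal_truth, redvr_obs)
  prt_calls <- call_prt_redvr(prt_obs, redvr_obs, calibration)

  stutter <- stutter_model(alpha = noise$slippage_alpha,
                           offset_bp = noise$slippage_offset)
  str_calls <- call_str(cohort$peaks, stutter,
                        samples = cohort$truth$sample_id) |>
    select(-"n_peaks")

  calls <- bind_rows(taqman, sybr, prt_calls, str_calls)
  if (integrate) {
    calls <- bind_rows(calls,
                       integrate_calls(calls, policy) |> select(-"votes", -"tie"))
  }
  calls
}
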