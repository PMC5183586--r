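#' Fit a qPCR standard curve
#'
#' Least-squares line of Ct on log10 relative input quantity over a
#' dilution series.  The amplification efficiency follows from the slope
#' as `E = 10^(-1/slope)`: a perfectly doubling assay loses 3.3219 cycles
#' per 10-fold dilution.  At least three dilution points spanning at
#' least two logs are required; a positive slope (swapped axes) is an
#' error.
#'
#' @param dilution_points data frame with columns `log10_quantity` and
#'   `ct` (replicate-mean Ct per dilution point).
#' @return object of class `standard_curve` with fields `slope`,
#'   `intercept`, `efficiency`, `r_squared`, `n`, `log10_range`.
#' @seealso [simulate_dilution_series()], [call_sybr()]
#' @export
fit_standard_curve <- function(dilution_points) {
  assert_columns(dilution_points, c("log10_quantity", "ct"),
                 "dilution series")
  d <- as_tibble(dilution_points)
  if (nrow(d) < 3) abort("at least 3 dilution points are required")
  if (diff(range(d$log10_quantity)) < 2) {
    abort("dilution points must span at least 2 logs")
  }
  fit <- lm(ct ~ log10_quantity, data = d)
  slope <- unname(coef(fit)[2])
  if (slope >= 0) abort("positive slope: check that axes are not swapped")
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((d$ct - mean(d$ct))^2)
  structure(list(
    slope = slope,
    intercept = unname(coef(fit)[1]),
    efficiency = 10^(-1 / slope),
    r_squared = 1 - ss_res / ss_tot,
    n = nrow(d),
    log10_range = range(d$log10_quantity),
    fit = fit), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve> slope = %.4f cycles/log10, efficiency = %.4f, R^2 = %.4f (n = %d)\n",
    x$slope, x$efficiency, x$r_squared, x$n))
  invisible(x)
}

#' @method tidy standard_curve
#' @export
tidy.standard_curve <- function(x, ...) {
  # suppressed: summary.lm warns on an exactly collinear (noise-free) fit
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble(term = c("intercept", "slope"),
         estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' @method glance standard_curve
#' @export
glance.standard_curve <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         efficiency = x$efficiency, r_squared = x$r_squared, n = x$n)
}

## Interpolate a relative quantity from a fitted curve.
curve_quantity <- function(curve, ct) 10^((ct - curve$intercept) / curve$slope)

## Replicate aggregation: drop replicates > outlier_cycles from the
## median, then mean; NULL if the surviving spread still exceeds
## spread_max (the call is then flagged missing, never guessed).
aggregate_cts <- function(cts, outlier_cycles = 0.5, spread_max = 1) {
  cts <- cts[!is.na(cts)]
  if (length(cts) == 0) return(list(mean = NA_real_, ok = FALSE))
  if (all(cts >= CT_NO_AMP)) return(list(mean = CT_NO_AMP, ok = TRUE))
  keep <- cts[abs(cts - median(cts)) <= outlier_cycles]
  if (length(keep) == 0) keep <- cts
  if (diff(range(keep)) > spread_max) {
    return(list(mean = NA_real_, ok = FALSE))
  }
  list(mean = mean(keep), ok = TRUE)
}

qpcr_sample_means <- function(measurements, outlier_cycles, spread_max) {
  measurements |>
    group_by(.data$sample_id, .data$locus, .data$role) |>
    summarise(agg = list(aggregate_cts(.data$ct, outlier_cycles, spread_max)),
              .groups = "drop") |>
    mutate(mean_ct = map_dbl(.data$agg, "mean"),
           ok = purrr::map_lgl(.data$agg, "ok")) |>
    select(-"agg") |>
    pivot_wider(names_from = "role", values_from = c("mean_ct", "ok"))
}

#' Call copy numbers from duplex TaqMan-style qPCR
#'
#' Comparative quantification against a calibrator of known copy number:
#' with per-amplicon efficiencies `E_t` and `E_r`, the continuous dosage
#' estimate is
#' `calibrator_cn * E_t^(dCt_t) / E_r^(dCt_r)` where `dCt` is
#' (calibrator mean Ct − sample mean Ct) for that amplicon.  Replicates
#' are screened (any replicate more than `outlier_cycles` from the median
#' is discarded) and averaged; if the surviving spread exceeds
#' `spread_max` cycles the call is flagged missing rather than guessed.
#' A no-amplification sentinel on the target yields a zero call.  Integer
#' calls use half-up rounding ([round_half_up()]).
#'
#' @param measurements long qPCR tibble (`sample_id`, `locus`, `role`,
#'   `replicate`, `ct`), e.g. from [simulate_taqman()].
#' @param calibrator_id sample id of the calibrator.
#' @param calibrator_cn its known copy number (default diploid 2).
#' @param efficiency_target,efficiency_reference amplification factors
#'   per cycle; default perfect doubling, override with values from
#'   [fit_standard_curve()].
#' @param outlier_cycles replicate-outlier screen threshold, cycles.
#' @param spread_max maximum allowed post-screen replicate range, cycles.
#' @return call tibble (`sample_id`, `method`, `locus`,
#'   `continuous_estimate`, `integer_call`, `flag`).
#' @export
call_taqman <- function(measurements, calibrator_id = "CAL",
                        calibrator_cn = 2,
                        efficiency_target = 2, efficiency_reference = 2,
                        outlier_cycles = 0.5, spread_max = 1) {
  assert_columns(measurements, c("sample_id", "locus", "role", "ct"),
                 "qPCR measurements")
  means <- qpcr_sample_means(measurements, outlier_cycles, spread_max)
  out <- means |>
    group_by(.data$locus) |>
    dplyr::group_modify(function(df, key) {
      cal <- df[df$sample_id == calibrator_id, ]
      if (nrow(cal) != 1) {
        abort(sprintf("calibrator '%s' not found for locus %s",
                      calibrator_id, key$locus))
      }
      df <- df[df$sample_id != calibrator_id, ]
      dct_t <- cal$mean_ct_target - df$mean_ct_target
      dct_r <- cal$mean_ct_reference - df$mean_ct_reference
      est <- calibrator_cn * efficiency_target^dct_t /
        efficiency_reference^dct_r
      no_amp <- !is.na(df$mean_ct_target) & df$mean_ct_target >= CT_NO_AMP
      est[no_amp] <- 0
      bad <- !df$ok_target | !df$ok_reference
      est[bad] <- NA_real_
      tibble(sample_id = df$sample_id,
             continuous_estimate = est,
             integer_call = round_half_up(est),
             flag = ifelse(bad, "high_replicate_spread", NA_character_))
    }) |>
    ungroup() |>
    mutate(method = "taqman") |>
    select("sample_id", "method", "locus",
           "continuous_estimate", "integer_call", "flag")
  arrange(out, .data$locus, .data$sample_id)
}

#' Call copy numbers by the relative standard-curve method
#'
#' SYBR Green-style quantification: target and reference Cts are
#' interpolated to relative quantities on their fitted standard curves;
#' the dosage estimate is `calibrator_cn` times the sample's
#' target/reference quantity ratio normalized to the calibrator's ratio.
#' Curves must fit with `r_squared` at or above `min_r_squared`; samples
#' whose interpolated quantity falls more than one log outside the fitted
#' dilution range are flagged as extrapolated (but still called).
#'
#' @inheritParams call_taqman
#' @param curve_target,curve_reference fitted [fit_standard_curve()]
#'   objects for the two amplicons.
#' @param min_r_squared minimum acceptable curve fit quality.
#' @return call tibble as for [call_taqman()] with `method = "sybr"`.
#' @export
call_sybr <- function(measurements, curve_target, curve_reference,
                      calibrator_id = "CAL", calibrator_cn = 2,
                      min_r_squared = 0.98,
                      outlier_cycles = 0.5, spread_max = 1) {
  for (cv in list(curve_target, curve_reference)) {
    if (!inherits(cv, "standard_curve")) abort("not a standard_curve")
    if (cv$r_squared < min_r_squared) {
      abort(sprintf("standard curve r_squared %.4f below %.2f",
                    cv$r_squared, min_r_squared))
    }
  }
  means <- qpcr_sample_means(measurements, outlier_cycles, spread_max)
  out <- means |>
    group_by(.data$locus) |>
    dplyr::group_modify(function(df, key) {
      cal <- df[df$sample_id == calibrator_id, ]
      if (nrow(cal) != 1) {
        abort(sprintf("calibrator '%s' not found for locus %s",
                      calibrator_id, key$locus))
      }
      df <- df[df$sample_id != calibrator_id, ]
      q_t <- curve_quantity(curve_target, df$mean_ct_target)
      q_r <- curve_quantity(curve_reference, df$mean_ct_reference)
      cal_ratio <- curve_quantity(curve_target, cal$mean_ct_target) /
        curve_quantity(curve_reference, cal$mean_ct_reference)
      est <- calibrator_cn * (q_t / q_r) / cal_ratio
      no_amp <- !is.na(df$mean_ct_target) & df$mean_ct_target >= CT_NO_AMP
      est[no_amp] <- 0
      extrap <- log10(q_t) < curve_target$log10_range[1] - 1 |
        log10(q_t) > curve_target$log10_range[2] + 1
      extrap[no_amp] <- FALSE
      bad <- !df$ok_target | !df$ok_reference
      est[bad] <- NA_real_
      flag <- dplyr::case_when(bad ~ "high_replicate_spread",
                               extrap ~ "extrapolated",
                               TRUE ~ NA_character_)
      tibble(sample_id = df$sample_id,
             continuous_estimate = est,
             integer_call = round_half_up(est),
             flag = flag)
    }) |>
    ungroup() |>
    mutate(method = "sybr") |>
    select("sample_id", "method", "locus",
           "continuous_estimate", "integer_call", "flag")
  arrange(out, .data$locus, .data$sample_id)
}

#' Anchor continuous qPCR estimates to the diploid modal cluster
#'
#' A comparative qPCR scale inherits the calibrator's own measurement
#' error as a cohort-wide multiplicative systematic.  The usual
#' refinement in copy-number typing removes it by anchoring the scale to
#' the cohort's modal cluster: in a population whose modal copy number
#' per gene is the diploid two, the per-locus median continuous estimate
#' is rescaled to `target_cn` and integer calls re-derived.  Requires a
#' cohort-scale call table (dozens of samples) and a population with its
#' mode at `target_cn`; zero (no-amplification) calls are left untouched.
#'
#' @param calls call tibble from [call_taqman()] or [call_sybr()].
#' @param target_cn copy number of the modal cluster (default diploid 2).
#' @return the call tibble with rescaled `continuous_estimate` and
#'   re-rounded `integer_call`.
#' @export
anchor_diploid_mode <- function(calls, target_cn = 2) {
  assert_columns(calls, c("sample_id", "method", "locus",
                          "continuous_estimate", "integer_call"), "calls")
  calls |>
    group_by(.data$method, .data$locus) |>
    dplyr::group_modify(function(df, key) {
      est <- df$continuous_estimate
      med <- median(est[!is.na(est) & est > 0])
      if (is.finite(med) && med > 0) {
        factor <- target_cn / med
        scaled <- ifelse(!is.na(est) & est > 0, est * factor, est)
        df$continuous_estimate <- scaled
        df$integer_call <- round_half_up(scaled)
      }
      df
    }) |>
    ungroup() |>
    select(all_of(names(calls)))
}

#' Derive whole-locus calls by summing gene-level calls
#'
#' For methods that genotype FCGR3A and FCGR3B separately (TaqMan), the
#' FCGR3 total is the sum of the two gene-level calls — integer calls are
#' summed, never re-rounded from the summed continuous estimate.
#'
#' @param calls call tibble containing FCGR3A and FCGR3B rows for one
#'   method.
#' @return the input with FCGR3 rows appended.
#' @export
sum_locus_calls <- function(calls) {
  assert_columns(calls, c("sample_id", "method", "locus",
                          "continuous_estimate", "integer_call"), "calls")
  wide <- calls |>
    filter(.data$locus %in% c("FCGR3A", "FCGR3B")) |>
    group_by(.data$sample_id, .data$method) |>
    summarise(
      continuous_estimate = ifelse(any(is.na(.data$continuous_estimate)),
                                   NA_real_,
                                   sum(.data$continuous_estimate)),
      integer_call = ifelse(any(is.na(.data$integer_call)), NA_integer_,
                            as.integer(sum(.data$integer_call))),
      n_genes = n(), .groups = "drop")
  if (any(wide$n_genes != 2)) {
    wide$continuous_estimate[wide$n_genes != 2] <- NA_real_
    wide$integer_call[wide$n_genes != 2] <- NA_integer_
  }
  total <- wide |>
    mutate(locus = "FCGR3", flag = NA_character_) |>
    select("sample_id", "method", "locus",
           "continuous_estimate", "integer_call", "flag")
  bind_rows(as_tibble(calls), total)
}
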