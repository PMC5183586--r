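#' Extract paralog-ratio-test observations from a peak table
#'
#' Matches the combined FCGR3A+FCGR3B product peak and the chromosome-18
#' reference peak by size within the layout's tolerance window and
#' records their raw areas and ratio.  Exactly one peak may fall in each
#' window: extra peaks are a hard error listing the offending sizes;
#' a missing or zero-area reference peak makes the observation unusable
#' (flagged, never guessed).
#'
#' @param peaks peak tibble (rows with `assay == "PRT"` are used).
#' @param layout a [prt_layout()].
#' @return tibble with columns `sample_id`, `target_area`,
#'   `reference_area`, `ratio_raw`, `usable`.
#' @export
compute_prt_ratio <- function(peaks, layout = prt_layout()) {
  assert_columns(peaks, c("sample_id", "assay", "size_bp", "area"), "peaks")
  tol <- attr(layout, "tol_bp")
  prt <- filter(as_tibble(peaks), .data$assay == "PRT")
  pick <- function(df, size, role) {
    hit <- df[abs(df$size_bp - size) <= tol, ]
    if (nrow(hit) > 1) {
      abort(sprintf("sample %s: %d peaks in the %s window (sizes: %s)",
                    df$sample_id[1], nrow(hit), role,
                    paste(hit$size_bp, collapse = ", ")))
    }
    if (nrow(hit) == 0) return(NA_real_)
    hit$area
  }
  stray_check <- function(df) {
    windows <- purrr::map_lgl(df$size_bp, function(s) {
      any(abs(s - layout$size_bp) <= tol)
    })
    if (!all(windows)) {
      abort(sprintf("sample %s: peak(s) outside expected size windows: %s",
                    df$sample_id[1],
                    paste(df$size_bp[!windows], collapse = ", ")))
    }
  }
  prt |>
    group_by(.data$sample_id) |>
    dplyr::group_modify(function(df, key) {
      df$sample_id <- key$sample_id
      stray_check(df)
      tgt <- pick(df, layout$size_bp[layout$role == "target"], "target")
      ref <- pick(df, layout$size_bp[layout$role == "reference"], "reference")
      usable <- !is.na(ref) && ref > 0 && !is.na(tgt)
      tibble(target_area = tgt, reference_area = ref,
             ratio_raw = if (usable) tgt / ref else NA_real_,
             usable = usable)
    }) |>
    ungroup()
}

#' Extract digest-variant-ratio fractions from a peak table
#'
#' From the C733 digest, the FCGR3A share of total FCGR3 signal
#' (`fraction_a`); from the C147T digest, the HNA1a share within FCGR3B
#' signal (`fraction_hna1a`).  A fraction is absent (`NA`) when the
#' corresponding peak pair is missing or sums to zero area.
#'
#' @param peaks peak tibble.
#' @param layout a [redvr_layout()].
#' @return tibble with columns `sample_id`, `fraction_a`,
#'   `fraction_hna1a`.
#' @export
redvr_fractions <- function(peaks, layout = redvr_layout()) {
  assert_columns(peaks, c("sample_id", "assay", "size_bp", "area"), "peaks")
  tol <- attr(layout, "tol_bp")
  frac <- function(df, lay) {
    a1 <- df$area[abs(df$size_bp - lay$size_bp[1]) <= tol]
    a2 <- df$area[abs(df$size_bp - lay$size_bp[2]) <= tol]
    if (length(a1) != 1 || length(a2) != 1) return(NA_real_)
    if (a1 + a2 <= 0) return(NA_real_)
    a1 / (a1 + a2)
  }
  p <- as_tibble(peaks)
  ids <- unique(p$sample_id[p$assay %in% c("REDVR_C733", "REDVR_C147T")])
  rows <- purrr::map(ids, function(id) {
    c733 <- p[p$sample_id == id & p$assay == "REDVR_C733", ]
    c147 <- p[p$sample_id == id & p$assay == "REDVR_C147T", ]
    tibble(sample_id = id,
           fraction_a = frac(c733, layout$c733),
           fraction_hna1a = frac(c147, layout$c147t))
  })
  list_rbind(rows)
}

#' Calibrate the paralog ratio test against known-truth samples
#'
#' Reference standards of known copy number anchor the area-ratio scale:
#' the calibration factor is the mean of (raw ratio) / (true total / 2)
#' over the calibrators, and the error-model sigmas are the empirical
#' standard deviations of the calibrated residuals (ratio residuals
#' against `true_total/2`; digest-fraction residuals against
#' `cn_a/cn_total` when REDVR observations are supplied).  Degenerate
#' calibrator sets (zero residual variance) fall back to `sigma_floor`
#' with a warning.
#'
#' @param prt_obs observations from [compute_prt_ratio()].
#' @param truth genotype tibble restricted to the calibrator samples.
#' @param redvr_obs optional fractions from [redvr_fractions()].
#' @param sigma_floor minimum admissible sigma (default 0.05).
#' @return list of class `prt_calibration`: `factor`, `sigma_ratio`,
#'   `sigma_fraction`, `n`.
#' @export
calibrate_prt <- function(prt_obs, truth, redvr_obs = NULL,
                          sigma_floor = 0.05) {
  g <- validate_genotypes(truth)
  obs <- inner_join(filter(prt_obs, .data$usable), g, by = "sample_id")
  if (nrow(obs) < 3) abort("at least 3 usable known-CN calibrators required")
  per_pair <- obs$ratio_raw / (obs$cn_total / 2)
  factor <- mean(per_pair)
  resid <- obs$ratio_raw / factor - obs$cn_total / 2
  sigma_ratio <- sd(resid)
  if (!is.finite(sigma_ratio) || sigma_ratio < 1e-9) {
    warn(sprintf(
      "degenerate calibrator set (zero ratio variance); using sigma_floor = %g",
      sigma_floor))
    sigma_ratio <- sigma_floor
  }
  sigma_fraction <- NA_real_
  if (!is.null(redvr_obs)) {
    fr <- inner_join(redvr_obs, g, by = "sample_id") |>
      filter(!is.na(.data$fraction_a), .data$cn_total > 0)
    if (nrow(fr) >= 3) {
      fresid <- fr$fraction_a - fr$cn_a / fr$cn_total
      sigma_fraction <- sd(fresid)
      if (!is.finite(sigma_fraction) || sigma_fraction < 1e-9) {
        warn(sprintf(
          "degenerate calibrator set (zero fraction variance); using sigma_floor = %g",
          sigma_floor))
        sigma_fraction <- sigma_floor
      }
    }
  }
  structure(list(factor = factor, sigma_ratio = sigma_ratio,
                 sigma_fraction = sigma_fraction, n = nrow(obs)),
            class = "prt_calibration")
}

#' @export
print.prt_calibration <- function(x, ...) {
  cat(sprintf(
    "<prt_calibration> factor = %.4f, sigma_ratio = %.4f, sigma_fraction = %s (n = %d)\n",
    x$factor, x$sigma_ratio,
    ifelse(is.na(x$sigma_fraction), "NA", sprintf("%.4f", x$sigma_fraction)),
    x$n))
  invisible(x)
}

#' Gaussian error model for the joint PRT/REDVR likelihood
#'
#' @param sigma_ratio sd of the calibrated PRT dosage ratio.
#' @param sigma_fraction sd of the digest fractions.
#' @param cn_ceiling maximum total copy number scored (default 8).
#' @param prior optional data frame (`cn_a`, `cn_b`, `prior`) over
#'   hypotheses; default uniform over all pairs with total <= ceiling.
#' @param use_hna if `TRUE`, the HNA1a/HNA1b fraction adds a third
#'   likelihood term given a configured allele-split hypothesis grid
#'   (off by default: the digest types HNA alleles, its coupling to CN
#'   likelihood is a modelling extension).
#' @param margin_threshold log-likelihood margin below which a call is
#'   flagged low-confidence.
#' @return object of class `cn_error_model`.
#' @export
error_model <- function(sigma_ratio = 0.1, sigma_fraction = 0.05,
                        cn_ceiling = 8, prior = NULL, use_hna = FALSE,
                        margin_threshold = 1) {
  if (sigma_ratio <= 0 || sigma_fraction <= 0) abort("sigmas must be > 0")
  grid <- expand_cn_grid(cn_ceiling)
  if (is.null(prior)) {
    grid$prior <- 1 / nrow(grid)
  } else {
    assert_columns(prior, c("cn_a", "cn_b", "prior"), "prior")
    grid <- left_join(grid, as_tibble(prior), by = c("cn_a", "cn_b"))
    grid$prior[is.na(grid$prior)] <- 0
    if (abs(sum(grid$prior) - 1) > 1e-9) abort("prior must sum to 1")
  }
  structure(list(sigma_ratio = sigma_ratio, sigma_fraction = sigma_fraction,
                 cn_ceiling = cn_ceiling, grid = grid, use_hna = use_hna,
                 margin_threshold = margin_threshold),
            class = "cn_error_model")
}

## All (cn_a, cn_b) hypotheses with total <= ceiling, ordered so that the
## documented tie-break (smaller total, then smaller cn_a) is "first match".
expand_cn_grid <- function(cn_ceiling) {
  g <- tidyr::expand_grid(cn_a = 0:cn_ceiling, cn_b = 0:cn_ceiling) |>
    mutate(total = .data$cn_a + .data$cn_b) |>
    filter(.data$total <= cn_ceiling) |>
    arrange(.data$total, .data$cn_a)
  g
}

#' Maximum-likelihood joint copy-number call from PRT and REDVR
#'
#' Scores every hypothesis (cn_a, cn_b) with total 0..ceiling:
#' `log L = log prior + logN(ratio; total/2, sigma_ratio)` plus, when the
#' C733 fraction is observed and the hypothesis total is positive,
#' `logN(fraction_a; cn_a/total, sigma_fraction)` — the (0,0) hypothesis
#' is scored with the fraction term omitted.  The argmax is returned
#' together with the log-likelihood margin to the runner-up; exact ties
#' are broken toward the smaller total, then the smaller cn_a, and
#' flagged.  Every input yields a call: confidence lives in the margin,
#' with margins below the model's threshold flagged `low_confidence`.
#'
#' @param ratio calibrated PRT dosage ratio (raw ratio divided by the
#'   calibration factor; expectation `total/2`).
#' @param fraction_a C733 FCGR3A fraction in `[0,1]`, or `NA` if absent.
#' @param model a [error_model()].
#' @return one-row tibble: `cn_a`, `cn_b`, `cn_total`, `log_lik`,
#'   `margin`, `tie`, `flag`.
#' @export
ml_call <- function(ratio, fraction_a = NA_real_, model = error_model()) {
  grid <- model$grid
  ll <- log(grid$prior) +
    dnorm(ratio, mean = grid$total / 2, sd = model$sigma_ratio, log = TRUE)
  if (!is.na(fraction_a)) {
    with_frac <- grid$total > 0
    ll[with_frac] <- ll[with_frac] +
      dnorm(fraction_a, mean = grid$cn_a[with_frac] / grid$total[with_frac],
            sd = model$sigma_fraction, log = TRUE)
  }
  ord <- order(ll, decreasing = TRUE)
  best_ll <- ll[ord[1]]
  tied <- which(abs(ll - best_ll) <= 1e-9)
  best <- tied[1]  # grid is pre-ordered by (total, cn_a)
  others <- ll[-best]
  margin <- best_ll - max(others)
  tie <- length(tied) > 1
  flag <- dplyr::case_when(tie ~ "tie",
                           margin < model$margin_threshold ~ "low_confidence",
                           TRUE ~ NA_character_)
  tibble(cn_a = grid$cn_a[best], cn_b = grid$cn_b[best],
         cn_total = grid$total[best], log_lik = best_ll,
         margin = margin, tie = tie, flag = flag)
}

#' Call a cohort jointly from PRT and REDVR observations
#'
#' Joins observations by sample, applies the calibration, runs
#' [ml_call()] per sample and reports three call sets: FCGR3A, FCGR3B
#' and FCGR3, where the FCGR3 call is always `cn_a + cn_b` of the joint
#' call (never independently re-rounded).  Samples with a missing or
#' unusable PRT observation are reported as missing calls.  Continuous
#' estimates are the calibrated dosages: `2*ratio` for the locus total,
#' apportioned by `fraction_a` for the genes.
#'
#' @param prt_obs from [compute_prt_ratio()].
#' @param redvr_obs from [redvr_fractions()]; may be missing samples.
#' @param calibration a [calibrate_prt()] result.
#' @param model a [error_model()]; when `NULL`, one is built from the
#'   calibration sigmas.
#' @return call tibble with rows for the three loci,
#'   `method = "prt_redvr"`.
#' @export
call_prt_redvr <- function(prt_obs, redvr_obs, calibration, model = NULL) {
  if (!inherits(calibration, "prt_calibration")) abort("not a prt_calibration")
  if (is.null(model)) {
    sf <- calibration$sigma_fraction
    model <- error_model(
      sigma_ratio = calibration$sigma_ratio,
      sigma_fraction = if (is.finite(sf)) sf else 0.05)
  }
  obs <- left_join(prt_obs, redvr_obs, by = "sample_id")
  rows <- purrr::map(seq_len(nrow(obs)), function(i) {
    o <- obs[i, ]
    if (!isTRUE(o$usable)) {
      return(tibble(sample_id = o$sample_id,
                    locus = c("FCGR3A", "FCGR3B", "FCGR3"),
                    continuous_estimate = NA_real_,
                    integer_call = NA_integer_,
                    flag = "unusable_prt"))
    }
    ratio <- o$ratio_raw / calibration$factor
    fa <- if ("fraction_a" %in% names(o)) o$fraction_a else NA_real_
    call <- ml_call(ratio, fa, model)
    dose_total <- 2 * ratio
    tibble(sample_id = o$sample_id,
           locus = c("FCGR3A", "FCGR3B", "FCGR3"),
           continuous_estimate = c(
             if (is.na(fa)) NA_real_ else dose_total * fa,
             if (is.na(fa)) NA_real_ else dose_total * (1 - fa),
             dose_total),
           integer_call = c(call$cn_a, call$cn_b, call$cn_total),
           flag = call$flag)
  })
  out <- list_rbind(rows) |> mutate(method = "prt_redvr") |>
    select("sample_id", "method", "locus",
           "continuous_estimate", "integer_call", "flag")
  arrange(out, .data$locus, .data$sample_id)
}
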