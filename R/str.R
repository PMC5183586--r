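#' Stutter model for microsatellite slippage correction
#'
#' Polymerase slippage during MSAT1 amplification generates an artifact
#' peak one repeat unit (2 bp) below each true allele, with magnitude
#' growing with allele length.  The model is linear in length: the
#' stutter area is `alpha * (length_bp - offset_bp)` times the parent
#' peak area, zero at or below the offset.
#'
#' @param alpha stutter fraction per bp above the offset (>= 0).
#' @param offset_bp allele length at which stutter vanishes.
#' @return object of class `stutter_model`.
#' @export
stutter_model <- function(alpha = 0.002, offset_bp = 130) {
  if (alpha < 0) abort("alpha must be >= 0")
  structure(list(alpha = alpha, offset_bp = offset_bp),
            class = "stutter_model")
}

stutter_fraction <- function(model, size_bp) {
  pmax(model$alpha * (size_bp - model$offset_bp), 0)
}

#' Correct electropherogram peaks for polymerase stutter
#'
#' Processes one sample's STR peaks from largest to smallest: each
#' peak's predicted stutter contribution (`alpha * (size - offset)` of
#' its corrected area) is subtracted from the peak exactly 2 bp smaller,
#' if present — so a stutter artifact riding on a true allele is removed
#' and the cascade through runs of 2 bp-spaced alleles is handled in one
#' pass.  Corrected areas are floored at zero, and peaks falling below
#' `noise_floor` times the largest corrected area are dropped (these are
#' stutter-only artifact peaks).  With `alpha = 0` the correction is the
#' identity.
#'
#' @param peaks one sample's STR peak tibble (columns `size_bp`, `area`;
#'   extra columns carried through).
#' @param model a [stutter_model()].
#' @param noise_floor fraction of the largest corrected area below which
#'   a peak is discarded (default 0.02).
#' @return tibble of retained peaks with columns `size_bp`,
#'   `area_observed`, `area` (corrected), sorted by size.
#' @export
correct_slippage <- function(peaks, model = stutter_model(),
                             noise_floor = 0.02) {
  assert_columns(peaks, c("size_bp", "area"), "peaks")
  p <- arrange(as_tibble(peaks), dplyr::desc(.data$size_bp))
  if (nrow(p) == 0) {
    return(tibble(size_bp = numeric(), area_observed = numeric(),
                  area = numeric()))
  }
  corrected <- p$area
  for (j in seq_len(nrow(p))) {
    pred <- stutter_fraction(model, p$size_bp[j]) * corrected[j]
    if (pred <= 0) next
    k <- which(abs(p$size_bp - (p$size_bp[j] - 2)) < 0.5)
    if (length(k) == 1) {
      corrected[k] <- max(corrected[k] - pred, 0)
    }
  }
  out <- tibble(size_bp = p$size_bp, area_observed = p$area,
                area = corrected)
  floor_abs <- noise_floor * max(out$area)
  out <- out[out$area >= floor_abs & out$area > 0, ]
  arrange(out, .data$size_bp)
}

#' Select the dosage normalizer peak
#'
#' The per-copy unit area is taken from a rank-ordered peak: with more
#' than four peaks, the third-smallest-area peak divides every area;
#' with more than two (three or four), the second-smallest; with one or
#' two peaks, the smallest-area peak (the two-allele heterozygote then
#' defaults to dosage 1 per allele — a declared extension, the published
#' rules start at three peaks).  Area ties are broken toward the smaller
#' fragment size.
#'
#' @param peaks corrected peak tibble (>= 1 row).
#' @return the selected normalizer row (one-row tibble).
#' @export
select_normalizer <- function(peaks) {
  assert_columns(peaks, c("size_bp", "area"), "peaks")
  p <- as_tibble(peaks)
  if (nrow(p) == 0) abort("no peaks to select a normalizer from")
  p <- arrange(p, .data$area, .data$size_bp)
  rank <- if (nrow(p) > 4) 3L else if (nrow(p) > 2) 2L else 1L
  p[rank, ]
}

#' Call total FCGR3 copy number from MSAT1 peaks
#'
#' After stutter correction and normalizer selection, each retained
#' peak's dosage is its area divided by the normalizer area, rounded
#' half-up with a floor of 1 (a surviving real allele cannot carry zero
#' copies); the integer call is the dosage sum and the continuous
#' estimate the sum of unrounded ratios.  No surviving peaks means a
#' zero call.  Operates per sample when given a multi-sample peak table.
#'
#' @param peaks peak tibble (rows with `assay == "STR"` are used when an
#'   `assay` column is present).
#' @param model a [stutter_model()].
#' @param noise_floor see [correct_slippage()].
#' @param samples optional character vector of expected sample ids; ids
#'   with no peaks in the table (a zero-copy electropherogram is empty)
#'   are then reported as zero calls instead of being absent.
#' @return call tibble with `method = "str"`, `locus = "FCGR3"`, plus a
#'   `n_peaks` audit column.
#' @export
call_str <- function(peaks, model = stutter_model(), noise_floor = 0.02,
                     samples = NULL) {
  p <- as_tibble(peaks)
  if ("assay" %in% names(p)) p <- filter(p, .data$assay == "STR")
  if (!"sample_id" %in% names(p)) p$sample_id <- "sample"
  ids <- union(unique(p$sample_id), samples %||% character())
  rows <- purrr::map(ids, function(id) {
    corr <- correct_slippage(p[p$sample_id == id, c("size_bp", "area")],
                             model, noise_floor)
    if (nrow(corr) == 0) {
      return(tibble(sample_id = id, continuous_estimate = 0,
                    integer_call = 0L, n_peaks = 0L))
    }
    norm <- select_normalizer(corr)
    ratio <- corr$area / norm$area
    dosage <- pmax(round_half_up(ratio), 1L)
    tibble(sample_id = id,
           continuous_estimate = sum(ratio),
           integer_call = as.integer(sum(dosage)),
           n_peaks = nrow(corr))
  })
  out <- list_rbind(rows) |>
    mutate(method = "str", locus = "FCGR3", flag = NA_character_) |>
    select("sample_id", "method", "locus",
           "continuous_estimate", "integer_call", "flag", "n_peaks")
  arrange(out, .data$sample_id)
}

#' Calibrate the stutter model from single-allele control runs
#'
#' Controls carrying one true allele each show an isolated stutter peak
#' 2 bp below the allele; the observed stutter/parent area fractions are
#' regressed on allele length by least squares, giving
#' `alpha` (slope) and `offset_bp` (x-intercept) of the linear stutter
#' law.
#'
#' @param control_peaks peak tibble of single-allele controls (each
#'   sample: one parent peak, one stutter peak 2 bp below).
#' @return a fitted [stutter_model()].
#' @export
calibrate_stutter <- function(control_peaks) {
  p <- as_tibble(control_peaks)
  if ("assay" %in% names(p)) p <- filter(p, .data$assay == "STR")
  obs <- p |>
    group_by(.data$sample_id) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) != 2) {
        abort(sprintf("control %s must show exactly 2 peaks", key$sample_id))
      }
      df <- arrange(df, .data$size_bp)
      if (abs(diff(df$size_bp) - 2) > 0.5) {
        abort(sprintf("control %s: peaks are not 2 bp apart", key$sample_id))
      }
      tibble(length_bp = df$size_bp[2],
             stutter_frac = df$area[1] / df$area[2])
    }) |>
    ungroup()
  if (nrow(obs) < 2) abort("need >= 2 distinct control lengths")
  fit <- lm(stutter_frac ~ length_bp, data = obs)
  alpha <- unname(coef(fit)[2])
  if (alpha <= 0) abort("fitted stutter slope is not positive")
  stutter_model(alpha = alpha, offset_bp = -unname(coef(fit)[1]) / alpha)
}
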