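#' Pairwise and multiway concordance between call sets
#'
#' The concordance rate between methods is the percentage of paired
#' samples whose integer calls are identical — exact integer equality,
#' reported to two decimals (half-up).  Pairing is pairwise-complete:
#' samples missing in any compared method are excluded and the
#' denominator `n_paired` is always reported beside the rate.
#' `concordance_pairwise()` compares exactly two methods;
#' `concordance_multiway()` requires all of >= 3 methods to agree on a
#' sample, which can only lower the rate.
#'
#' @param calls long call tibble.
#' @param methods character vector of method ids to compare (2 for
#'   pairwise, >= 3 for multiway).
#' @param locus optional locus filter; default: every locus at which
#'   all compared methods have calls.
#' @return object of class `cn_concordance`: a tibble with columns
#'   `locus`, `comparison`, `n_paired`, `n_agree`, `rate`, plus a
#'   per-copy-number breakdown in `attr(, "breakdown")`.
#' @export
concordance_pairwise <- function(calls, methods, locus = NULL) {
  if (length(methods) != 2) abort("concordance_pairwise compares 2 methods")
  concordance_multi_impl(calls, methods, locus)
}

#' @rdname concordance_pairwise
#' @export
concordance_multiway <- function(calls, methods, locus = NULL) {
  if (length(methods) < 3) abort("concordance_multiway needs >= 3 methods")
  concordance_multi_impl(calls, methods, locus)
}

concordance_multi_impl <- function(calls, methods, locus) {
  assert_columns(calls, c("sample_id", "method", "locus", "integer_call"),
                 "calls")
  x <- as_tibble(calls) |> filter(.data$method %in% methods)
  missing_m <- setdiff(methods, unique(x$method))
  if (length(missing_m) > 0) {
    abort(sprintf("no calls for method(s): %s",
                  paste(missing_m, collapse = ", ")))
  }
  if (!is.null(locus)) x <- x[x$locus %in% locus, ]
  wide <- x |>
    select("sample_id", "locus", "method", "integer_call") |>
    pivot_wider(names_from = "method", values_from = "integer_call")
  have_all <- methods[methods %in% names(wide)]
  wide <- wide[, c("sample_id", "locus", have_all)]
  wide <- wide[stats::complete.cases(wide[have_all]), ]
  loci_here <- intersect(FCGR_LOCI, unique(wide$locus))
  rows <- purrr::map(loci_here, function(lc) {
    w <- wide[wide$locus == lc, ]
    if (nrow(w) == 0) return(NULL)
    vals <- as.matrix(w[have_all])
    agree <- apply(vals, 1, function(v) all(v == v[1]))
    tibble(locus = lc,
           comparison = paste(methods, collapse = " vs "),
           n_paired = nrow(w), n_agree = sum(agree),
           rate = round2(100 * sum(agree) / nrow(w)))
  })
  res <- list_rbind(rows)
  if (nrow(res) == 0) abort("zero paired samples for the requested comparison")
  breakdown <- purrr::map(loci_here, function(lc) {
    w <- wide[wide$locus == lc, ]
    vals <- as.matrix(w[have_all])
    agree <- apply(vals, 1, function(v) all(v == v[1]))
    tibble(locus = lc, cn = vals[, 1]) |>
      mutate(agree = agree) |>
      group_by(.data$locus, .data$cn) |>
      summarise(n = n(), n_agree = sum(.data$agree), .groups = "drop")
  }) |> list_rbind()
  new_cn_concordance(res, breakdown)
}

new_cn_concordance <- function(tbl, breakdown) {
  structure(tbl, breakdown = breakdown,
            class = c("cn_concordance", class(tbl)))
}

#' @export
print.cn_concordance <- function(x, ...) {
  cat("<cn_concordance>\n")
  df <- as_tibble(unclass_keep(x))
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-7s %s: %.2f%% (%d/%d)\n", df$locus[i],
                df$comparison[i], df$rate[i], df$n_agree[i], df$n_paired[i]))
  }
  invisible(x)
}

unclass_keep <- function(x) {
  attr(x, "breakdown") <- NULL
  class(x) <- setdiff(class(x), c("cn_concordance", "cn_error_profile"))
  x
}

#' @method tidy cn_concordance
#' @export
tidy.cn_concordance <- function(x, ...) as_tibble(unclass_keep(x))

#' @method glance cn_concordance
#' @export
glance.cn_concordance <- function(x, ...) {
  df <- as_tibble(unclass_keep(x))
  tibble(n_comparisons = nrow(df),
         min_rate = min(df$rate), max_rate = max(df$rate),
         n_paired_total = sum(df$n_paired))
}

#' Concordance of calls with an integer reference
#'
#' Compares a call set with a sequencing-style integer truth table (the
#' role played by a phase-3 structural-variant reference panel).
#' Samples absent from the reference are dropped from the denominator
#' and reported, never silently imputed.
#'
#' @param calls long call tibble (one or more methods).
#' @param reference integer reference tibble (`sample_id`, `locus`,
#'   `truth_cn`), e.g. from [read_reference_table()] or a genotype
#'   table via truth columns.
#' @param locus optional locus filter.
#' @return `cn_concordance` tibble with one row per (method, locus);
#'   dropped sample ids in `attr(, "dropped")`.
#' @export
concordance_with_reference <- function(calls, reference, locus = NULL) {
  assert_columns(calls, c("sample_id", "method", "locus", "integer_call"),
                 "calls")
  if (all(c("cn_a", "cn_b", "cn_total") %in% names(reference))) {
    reference <- truth_as_reference(reference)
  }
  assert_columns(reference, c("sample_id", "locus", "truth_cn"), "reference")
  x <- as_tibble(calls) |> filter(.data$method != "truth")
  if (!is.null(locus)) x <- x[x$locus %in% locus, ]
  joined <- inner_join(x, as_tibble(reference),
                       by = c("sample_id", "locus"))
  dropped <- setdiff(unique(x$sample_id), unique(joined$sample_id))
  joined <- joined[!is.na(joined$integer_call) & !is.na(joined$truth_cn), ]
  if (nrow(joined) == 0) abort("zero paired samples against the reference")
  res <- joined |>
    group_by(.data$method, .data$locus) |>
    summarise(n_paired = n(),
              n_agree = sum(.data$integer_call == .data$truth_cn),
              .groups = "drop") |>
    mutate(rate = round2(100 * .data$n_agree / .data$n_paired),
           comparison = paste(.data$method, "vs reference")) |>
    select("locus", "comparison", "n_paired", "n_agree", "rate",
           method = "method")
  breakdown <- joined |>
    group_by(.data$method, .data$locus, cn = .data$truth_cn) |>
    summarise(n = n(),
              n_agree = sum(.data$integer_call == .data$truth_cn),
              .groups = "drop")
  out <- new_cn_concordance(res, breakdown)
  attr(out, "dropped") <- dropped
  out
}

#' Correlate calls with a continuous dosage reference
#'
#' Pearson correlation between per-sample copy-number estimates and an
#' array-style continuous dosage reference, with the two-sided p-value
#' from [stats::cor.test()].  Continuous estimates are used when
#' available, integer calls otherwise; which was used is recorded.
#'
#' @param calls long call tibble for one method/locus (or filtered via
#'   `method`/`locus`).
#' @param dosage dosage tibble (`sample_id`, `dosage`).
#' @param method,locus optional filters when `calls` is a multi-method
#'   table.
#' @param use `"auto"` (continuous when present), `"continuous"` or
#'   `"integer"`.
#' @return object of class `cn_correlation`.
#' @export
correlate_with_dosage <- function(calls, dosage, method = NULL,
                                  locus = NULL,
                                  use = c("auto", "continuous", "integer")) {
  use <- arg_match(use)
  assert_columns(dosage, c("sample_id", "dosage"), "dosage table")
  x <- as_tibble(calls)
  if (!is.null(method)) x <- x[x$method %in% method, ]
  if (!is.null(locus)) x <- x[x$locus %in% locus, ]
  if (dplyr::n_distinct(x$method) != 1 || dplyr::n_distinct(x$locus) != 1) {
    abort("correlate_with_dosage needs exactly one method and one locus")
  }
  joined <- inner_join(x, as_tibble(dosage), by = "sample_id")
  if (use == "auto") {
    use <- if (any(!is.na(joined$continuous_estimate)))
      "continuous" else "integer"
  }
  est <- if (use == "continuous") joined$continuous_estimate
         else as.numeric(joined$integer_call)
  used <- use
  keep <- !is.na(est) & !is.na(joined$dosage)
  est <- est[keep]; dos <- joined$dosage[keep]
  if (length(est) < 3) abort("need >= 3 paired values")
  if (sd(est) == 0 || sd(dos) == 0) abort("zero variance on one side")
  ct <- cor.test(est, dos, method = "pearson")
  structure(list(
    method = x$method[1], locus = x$locus[1],
    r = unname(ct$estimate), n = length(est), p_value = ct$p.value,
    used = used,
    data = tibble(sample_id = joined$sample_id[keep],
                  estimate = est, dosage = dos)),
    class = "cn_correlation")
}

#' @export
print.cn_correlation <- function(x, ...) {
  cat(sprintf("<cn_correlation> %s / %s: r = %.3f (n = %d, p = %.3g, %s estimates)\n",
              x$method, x$locus, x$r, x$n, x$p_value, x$used))
  invisible(x)
}

#' @method tidy cn_correlation
#' @export
tidy.cn_correlation <- function(x, ...) {
  tibble(method = x$method, locus = x$locus, r = x$r, n = x$n,
         p_value = x$p_value, used = x$used)
}

#' @method glance cn_correlation
#' @export
glance.cn_correlation <- function(x, ...) tidy(x)

#' Per-copy-number error-direction profile
#'
#' For each method, locus and true copy-number class, counts calls above
#' truth, below truth and equal to it, with percentages — the
#' red (over-call) / green (under-call) split used to characterise which
#' classes a method over- or under-estimates.
#'
#' @inheritParams concordance_with_reference
#' @return object of class `cn_error_profile`: tibble with columns
#'   `method`, `locus`, `truth_cn`, `n`, `n_above`, `n_below`,
#'   `n_equal`, `pct_above`, `pct_below`, `pct_equal`.
#' @export
error_direction_profile <- function(calls, reference, locus = NULL) {
  if (all(c("cn_a", "cn_b", "cn_total") %in% names(reference))) {
    reference <- truth_as_reference(reference)
  }
  assert_columns(reference, c("sample_id", "locus", "truth_cn"), "reference")
  x <- as_tibble(calls) |> filter(.data$method != "truth")
  if (!is.null(locus)) x <- x[x$locus %in% locus, ]
  joined <- inner_join(x, as_tibble(reference),
                       by = c("sample_id", "locus")) |>
    filter(!is.na(.data$integer_call), !is.na(.data$truth_cn))
  if (nrow(joined) == 0) abort("no paired samples")
  prof <- joined |>
    group_by(.data$method, .data$locus, truth_cn = .data$truth_cn) |>
    summarise(n = n(),
              n_above = sum(.data$integer_call > .data$truth_cn),
              n_below = sum(.data$integer_call < .data$truth_cn),
              n_equal = sum(.data$integer_call == .data$truth_cn),
              .groups = "drop") |>
    mutate(pct_above = round2(100 * .data$n_above / .data$n),
           pct_below = round2(100 * .data$n_below / .data$n),
           pct_equal = round2(100 * .data$n_equal / .data$n))
  structure(prof, class = c("cn_error_profile", class(prof)))
}

#' @export
print.cn_error_profile <- function(x, ...) {
  cat("<cn_error_profile>\n")
  print(as_tibble(unclass_keep(x)), n = Inf)
  invisible(x)
}

#' @method tidy cn_error_profile
#' @export
tidy.cn_error_profile <- function(x, ...) as_tibble(unclass_keep(x))

#' @method glance cn_error_profile
#' @export
glance.cn_error_profile <- function(x, ...) {
  df <- as_tibble(unclass_keep(x))
  df |>
    group_by(.data$method, .data$locus) |>
    summarise(n = sum(.data$n), n_above = sum(.data$n_above),
              n_below = sum(.data$n_below), n_equal = sum(.data$n_equal),
              .groups = "drop") |>
    mutate(pct_above = round2(100 * .data$n_above / .data$n),
           pct_below = round2(100 * .data$n_below / .data$n))
}
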