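#' Plot methods for evaluation results
#'
#' `autoplot.cn_concordance()` draws concordance rates as a bar panel
#' per locus; `autoplot.cn_correlation()` the estimate-vs-dosage scatter
#' with the least-squares line and the Pearson r in the subtitle;
#' `autoplot.cn_error_profile()` the per-true-copy-number miscall
#' columns, over-calls in red and under-calls in green (the convention
#' used for error-direction figures in the CNV-typing literature).
#'
#' @param object an evaluation result object.
#' @param ... unused.
#' @return a ggplot object.
#' @name autoplot-fcgr3cnv
NULL

#' @rdname autoplot-fcgr3cnv
#' @method autoplot cn_concordance
#' @export
autoplot.cn_concordance <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$comparison, y = .data$rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f%% (%d/%d)", .data$rate, .data$n_agree,
                      .data$n_paired)), vjust = -0.4, size = 3) +
    ggplot2::facet_wrap(~locus) +
    ggplot2::coord_cartesian(ylim = c(0, 105)) +
    ggplot2::labs(x = NULL, y = "concordance rate (%)") +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @rdname autoplot-fcgr3cnv
#' @method autoplot cn_correlation
#' @export
autoplot.cn_correlation <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$dosage, y = .data$estimate)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x,
                         se = FALSE, colour = "firebrick") +
    ggplot2::labs(
      x = "reference dosage", y = sprintf("%s estimate", object$method),
      title = sprintf("%s / %s", object$method, object$locus),
      subtitle = sprintf("r = %.3f, n = %d, p = %.2g",
                         object$r, object$n, object$p_value)) +
    ggplot2::theme_bw()
}

#' @rdname autoplot-fcgr3cnv
#' @method autoplot cn_error_profile
#' @export
autoplot.cn_error_profile <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("pct_above", "pct_below"),
                        names_to = "direction", values_to = "pct") |>
    mutate(direction = ifelse(.data$direction == "pct_above",
                              "called above truth", "called below truth"))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$truth_cn),
                                   y = .data$pct, fill = .data$direction)) +
    ggplot2::geom_col(position = "stack") +
    ggplot2::scale_fill_manual(values = c(
      "called above truth" = "firebrick",
      "called below truth" = "forestgreen")) +
    ggplot2::facet_grid(method ~ locus) +
    ggplot2::labs(x = "true copy number", y = "miscalled samples (%)",
                  fill = NULL) +
    ggplot2::theme_bw()
}
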