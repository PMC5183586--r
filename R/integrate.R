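#' Consensus policy for integrating calls from several methods
#'
#' @param strategy `"majority"` (modal integer call across non-missing
#'   methods) or `"precision_weighted"` (argmax of summed per-method
#'   weights over candidate copy numbers).
#' @param tiebreak_method method whose vote settles ties (default
#'   `"taqman"`, the most accurate single method); if absent from the
#'   supplied methods, or its vote is not among the tied values, the
#'   smallest tied call wins and the record is flagged.
#' @param weights named numeric vector of per-method weights (required
#'   for `"precision_weighted"`).
#' @return object of class `integration_policy`.
#' @export
integration_policy <- function(strategy = c("majority", "precision_weighted"),
                               tiebreak_method = "taqman", weights = NULL) {
  strategy <- arg_match(strategy)
  if (strategy == "precision_weighted" && is.null(weights)) {
    abort("precision_weighted integration needs per-method weights")
  }
  structure(list(strategy = strategy, tiebreak_method = tiebreak_method,
                 weights = weights),
            class = "integration_policy")
}

## Resolve one sample's votes (named int vector: method -> call) to a
## consensus call under the policy.
resolve_votes <- function(votes, policy) {
  if (length(votes) == 0) return(NULL)
  score <- if (policy$strategy == "majority") {
    tapply(rep(1, length(votes)), votes, sum)
  } else {
    w <- policy$weights[names(votes)]
    w[is.na(w)] <- 0
    tapply(w, votes, sum)
  }
  top <- as.integer(names(score)[score == max(score)])
  tie <- length(top) > 1
  if (!tie) {
    return(list(call = top, tie = FALSE, tiebreak_used = FALSE))
  }
  tb <- policy$tiebreak_method
  if (!is.null(tb) && tb %in% names(votes) && votes[[tb]] %in% top) {
    return(list(call = votes[[tb]], tie = TRUE, tiebreak_used = TRUE))
  }
  list(call = min(top), tie = TRUE, tiebreak_used = FALSE)
}

#' Integrate calls from multiple methods into a consensus call set
#'
#' Combines the integer calls of two or more methods into an
#' "integrated" copy number per sample and locus.  Missing calls do not
#' vote; a sample missing in every method is missing from the output.
#' Every consensus record carries the per-method votes as an audit
#' column and a tie flag.
#'
#' @param calls long call tibble holding >= 2 methods (integrated and
#'   truth rows are ignored).
#' @param policy an [integration_policy()].
#' @param locus optional locus filter; default integrates every locus
#'   present.
#' @return call tibble with `method = "integrated"` and extra columns
#'   `votes` and `tie`.
#' @export
integrate_calls <- function(calls, policy = integration_policy(),
                            locus = NULL) {
  assert_columns(calls, c("sample_id", "method", "locus", "integer_call"),
                 "calls")
  x <- as_tibble(calls) |>
    filter(!.data$method %in% c("integrated", "truth"))
  if (!is.null(locus)) x <- x[x$locus %in% locus, ]
  if (dplyr::n_distinct(x$method) < 2) {
    abort("integration needs calls from at least 2 methods")
  }
  out <- x |>
    group_by(.data$sample_id, .data$locus) |>
    dplyr::group_modify(function(df, key) {
      votes <- setNames(df$integer_call, df$method)
      votes <- votes[!is.na(votes)]
      res <- resolve_votes(votes, policy)
      if (is.null(res)) {
        return(tibble(continuous_estimate = NA_real_,
                      integer_call = NA_integer_,
                      votes = NA_character_, tie = NA))
      }
      tibble(continuous_estimate = NA_real_,
             integer_call = as.integer(res$call),
             votes = paste(names(votes), votes, sep = "=", collapse = ";"),
             tie = res$tie)
    }) |>
    ungroup() |>
    filter(!is.na(.data$integer_call) | !is.na(.data$votes)) |>
    mutate(method = "integrated",
           flag = ifelse(.data$tie, "tie", NA_character_)) |>
    select("sample_id", "method", "locus", "continuous_estimate",
           "integer_call", "flag", "votes", "tie")
  arrange(out, .data$locus, .data$sample_id)
}
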