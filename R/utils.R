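#' Round half away from zero
#'
#' Integer copy-number calls use commercial ("half-up") rounding: 2.5 becomes
#' 3, not 2 as under [base::round()]'s banker's rounding.  The boundary choice
#' is a declared convention of this package; it is applied everywhere a
#' continuous dosage estimate is converted to an integer call.
#'
#' @param x numeric vector.
#' @return integer vector, `NA` preserved.
#' @examples
#' round_half_up(c(1.4, 1.5, 2.5))
#' @export
round_half_up <- function(x) {
  out <- ifelse(is.na(x), NA_integer_, as.integer(floor(x + 0.5)))
  out
}

## Two-decimal percentage formatting used for all concordance rates
## (half-up, so 91.115 -> 91.12).
round2 <- function(x) floor(x * 100 + 0.5) / 100

## Multiplicative lognormal noise with median 1 and coefficient of
## variation `cv` on the natural scale; cv = 0 is the identity.
lognormal_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sigma <- sqrt(log(1 + cv^2))
  exp(rnorm(n, 0, sigma))
}

## sd of log(area) implied by a lognormal coefficient of variation.
lognormal_sigma <- function(cv) sqrt(log(1 + cv^2))

## Mean of `repeats` independent median-one lognormal factors per element
## (the noise seen when an assay is repeated and its signals averaged).
lognormal_factor_mean <- function(n, cv, repeats = 1) {
  if (cv <= 0) return(rep(1, n))
  rowMeans(matrix(lognormal_factor(n * repeats, cv), nrow = n))
}

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

## Coerce a character/numeric vector to integer, accepting lossless forms
## like "2.0"; anything else is a hard error naming the offender.
coerce_integer <- function(x, what = "value", na_token = "NA") {
  x_chr <- as.character(x)
  x_chr[x_chr == na_token] <- NA_character_
  num <- suppressWarnings(as.numeric(x_chr))
  bad <- !is.na(x_chr) & (is.na(num) | abs(num - round(num)) > 1e-9)
  if (any(bad)) {
    abort(sprintf("non-integer %s: %s", what,
                  paste(unique(x_chr[bad]), collapse = ", ")))
  }
  as.integer(round(num))
}
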