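#' Validate a table of copy-number genotypes
#'
#' A genotype table records, per sample, the integer copy number of FCGR3A
#' (`cn_a`), of FCGR3B (`cn_b`) and of the whole FCGR3 locus (`cn_total`).
#' Values must be non-negative integers, `cn_total` must equal
#' `cn_a + cn_b` whenever both gene-level values are present, and totals
#' above `cn_ceiling` are rejected (diploid FCGR3 totals observed in East
#' Asian reference panels span roughly 2-7 copies).
#'
#' @param genotypes data frame with columns `sample_id`, `cn_a`, `cn_b`,
#'   `cn_total`.
#' @param cn_ceiling maximum admissible total copy number (default 8).
#' @return the validated genotypes as a tibble (invisibly usable in pipes).
#' @export
validate_genotypes <- function(genotypes, cn_ceiling = 8) {
  assert_columns(genotypes, c("sample_id", "cn_a", "cn_b", "cn_total"),
                 "genotype table")
  g <- as_tibble(genotypes)
  for (col in c("cn_a", "cn_b", "cn_total")) {
    g[[col]] <- coerce_integer(g[[col]], col)
    if (any(g[[col]] < 0, na.rm = TRUE)) {
      abort(sprintf("negative copy number in column %s", col))
    }
  }
  both <- !is.na(g$cn_a) & !is.na(g$cn_b)
  bad <- both & !is.na(g$cn_total) & g$cn_total != g$cn_a + g$cn_b
  if (any(bad)) {
    abort(sprintf("cn_total != cn_a + cn_b for sample(s): %s",
                  paste(g$sample_id[bad], collapse = ", ")))
  }
  over <- !is.na(g$cn_total) & g$cn_total > cn_ceiling
  if (any(over)) {
    abort(sprintf("total copy number above ceiling %d for sample(s): %s",
                  cn_ceiling, paste(g$sample_id[over], collapse = ", ")))
  }
  g
}

#' Read and write integer copy-number call tables
#'
#' Call tables are the central tabular exchange format of the package: one
#' row per (sample, method, locus) with the continuous pre-rounding dosage
#' estimate and the integer call.  Files are UTF-8 delimited text with a
#' header, `#` comment lines allowed; missing calls are encoded by
#' `na_token`.  `read_call_table()` validates on the way in: duplicate
#' (sample, method, locus) rows and non-integer values in `integer_call`
#' are hard errors (a value such as "2.0" is accepted as 2).
#'
#' @param path file path.
#' @param delim field delimiter; tab by default, `","` also supported.
#' @param na_token string encoding a missing call (default `"NA"`).
#' @param methods admissible method identifiers.
#' @param loci admissible locus names.
#' @return a tibble with columns `sample_id`, `method`, `locus`,
#'   `continuous_estimate`, `integer_call` (plus any extra columns, e.g.
#'   `flag`, carried through verbatim).
#' @export
read_call_table <- function(path, delim = "\t", na_token = "NA",
                            methods = FCGR_METHODS, loci = FCGR_LOCI) {
  df <- readr::read_delim(path, delim = delim, na = na_token,
                          comment = "#", show_col_types = FALSE,
                          col_types = readr::cols(.default = readr::col_character()))
  assert_columns(df, c("sample_id", "method", "locus",
                       "continuous_estimate", "integer_call"),
                 sprintf("call table '%s'", path))
  df$continuous_estimate <- suppressWarnings(as.numeric(df$continuous_estimate))
  df$integer_call <- coerce_integer(df$integer_call, "integer_call", na_token)
  bad_method <- setdiff(unique(df$method), methods)
  if (length(bad_method) > 0) {
    abort(sprintf("unknown method id(s): %s", paste(bad_method, collapse = ", ")))
  }
  bad_locus <- setdiff(unique(df$locus), loci)
  if (length(bad_locus) > 0) {
    abort(sprintf("unknown locus name(s): %s", paste(bad_locus, collapse = ", ")))
  }
  dup <- duplicated(df[c("sample_id", "method", "locus")])
  if (any(dup)) {
    i <- which(dup)[1]
    abort(sprintf(
      "duplicate (sample, method, locus) row %d: %s / %s / %s",
      i, df$sample_id[i], df$method[i], df$locus[i]))
  }
  if (any(df$integer_call < 0, na.rm = TRUE)) abort("negative integer_call")
  as_tibble(df)
}

#' @param calls call tibble as returned by the callers or `read_call_table()`.
#' @param comment optional character vector written as `#` header lines
#'   (e.g. the simulation seed).
#' @rdname read_call_table
#' @export
write_call_table <- function(calls, path, delim = "\t", na_token = "NA",
                             comment = NULL) {
  assert_columns(calls, c("sample_id", "method", "locus",
                          "continuous_estimate", "integer_call"),
                 "call table")
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(comment)) {
    writeLines(paste0("# ", comment), con)
  }
  readr::write_delim(as_tibble(calls), con, delim = delim, na = na_token)
  invisible(path)
}

#' Read an electropherogram peak table
#'
#' Peak tables carry capillary-electrophoresis peaks the way a GeneMapper
#' text export does: one row per peak with the sample, an assay tag (e.g.
#' `PRT`, `REDVR_C733`, `REDVR_C147T`, `STR`), the fragment size in base
#' pairs, and the peak height and area.  Rows with a negative area or a
#' missing size are rejected with a warning naming the row; a zero area is
#' valid (an absent paralog yields a zero-area digest peak).  Peaks are
#' returned sorted by sample, assay and ascending size.
#'
#' @inheritParams read_call_table
#' @return tibble with columns `sample_id`, `assay`, `size_bp`, `height`,
#'   `area`.
#' @export
read_peak_table <- function(path, delim = "\t", na_token = "NA") {
  df <- readr::read_delim(path, delim = delim, na = na_token,
                          comment = "#", show_col_types = FALSE)
  assert_columns(df, c("sample_id", "assay", "size_bp", "height", "area"),
                 sprintf("peak table '%s'", path))
  df <- as_tibble(df)
  df$size_bp <- as.numeric(df$size_bp)
  df$height <- as.numeric(df$height)
  df$area <- as.numeric(df$area)
  drop <- is.na(df$size_bp) | (!is.na(df$area) & df$area < 0) | is.na(df$area)
  if (any(drop)) {
    warn(sprintf("rejected %d peak row(s) with missing size or negative area (rows: %s)",
                 sum(drop), paste(which(drop), collapse = ", ")))
    df <- df[!drop, ]
  }
  arrange(df, .data$sample_id, .data$assay, .data$size_bp)
}

#' @param peaks peak tibble.
#' @rdname read_peak_table
#' @export
write_peak_table <- function(peaks, path, delim = "\t", comment = NULL) {
  assert_columns(peaks, c("sample_id", "assay", "size_bp", "height", "area"),
                 "peak table")
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  readr::write_delim(as_tibble(peaks), con, delim = delim)
  invisible(path)
}

#' Read reference truth and dosage tables
#'
#' Two reference formats mirror the two public gold standards the package
#' evaluates against: an integer truth table (sequencing-style calls;
#' columns `sample_id`, `locus`, `truth_cn`) and a continuous dosage table
#' (array-style relative dosage; columns `sample_id`, `dosage`).  Integer
#' truths above the copy-number ceiling are rejected on read.
#'
#' @inheritParams read_call_table
#' @param cn_ceiling maximum admissible copy number (default 8).
#' @return a tibble.
#' @export
read_reference_table <- function(path, delim = "\t", na_token = "NA",
                                 cn_ceiling = 8) {
  df <- readr::read_delim(path, delim = delim, na = na_token,
                          comment = "#", show_col_types = FALSE)
  assert_columns(df, c("sample_id", "locus", "truth_cn"),
                 sprintf("reference table '%s'", path))
  df <- as_tibble(df)
  df$truth_cn <- coerce_integer(df$truth_cn, "truth_cn", na_token)
  if (any(df$truth_cn < 0, na.rm = TRUE)) abort("negative truth_cn")
  over <- !is.na(df$truth_cn) & df$truth_cn > cn_ceiling
  if (any(over)) {
    abort(sprintf("truth_cn above ceiling %d in row(s): %s", cn_ceiling,
                  paste(which(over), collapse = ", ")))
  }
  dup <- duplicated(df[c("sample_id", "locus")])
  if (any(dup)) abort("duplicate (sample_id, locus) in reference table")
  df
}

#' @rdname read_reference_table
#' @export
read_genotype_table <- function(path, delim = "\t", na_token = "NA",
                                cn_ceiling = 8) {
  df <- readr::read_delim(path, delim = delim, na = na_token,
                          comment = "#", show_col_types = FALSE)
  validate_genotypes(df, cn_ceiling)
}

#' @rdname read_reference_table
#' @export
read_dosage_table <- function(path, delim = "\t", na_token = "NA") {
  df <- readr::read_delim(path, delim = delim, na = na_token,
                          comment = "#", show_col_types = FALSE)
  assert_columns(df, c("sample_id", "dosage"),
                 sprintf("dosage table '%s'", path))
  df <- as_tibble(df)
  df$dosage <- as.numeric(df$dosage)
  if (anyDuplicated(df$sample_id)) abort("duplicate sample_id in dosage table")
  df
}

## Truth genotypes reshaped to the long call-table convention, so the
## evaluation layer can treat "truth" like any other method.
truth_as_reference <- function(genotypes) {
  g <- validate_genotypes(genotypes)
  bind_rows(
    tibble(sample_id = g$sample_id, locus = "FCGR3A", truth_cn = g$cn_a),
    tibble(sample_id = g$sample_id, locus = "FCGR3B", truth_cn = g$cn_b),
    tibble(sample_id = g$sample_id, locus = "FCGR3", truth_cn = g$cn_total)
  )
}
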