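#' Cohort tables: validation and delimited-text I/O
#'
#' A cohort is a data frame with one row per subject.  Required columns:
#' `subject_id`, `cohort` (one of derivation/validation/volunteer), `sex`
#' (male/female), `age` (years), `hematocrit` (%), `t1_myo` (ms),
#' `t1_blood_lv`, `t1_blood_rv` (ms), `t1star_blood_lv`, `t1star_blood_rv`
#' (ms), `wall_thickness` (mm).  The synthetic-only latent columns
#' `t1_tissue_true` (ms) and `mbv` (fraction) are optional, as are the T1*
#' columns on read (flagged absent as `NA`).
#'
#' Files are comma-separated with a header row of exactly these column
#' names, decimal points and no thousands separators.
#'
#' @param x A data frame to validate or coerce.
#' @return `as_t1_cohort()` returns a validated `t1_cohort`.
#' @name cohort_table
NULL

cohort_required_cols <- c("subject_id", "cohort", "sex", "age", "hematocrit",
                          "t1_myo", "t1_blood_lv", "t1_blood_rv",
                          "t1star_blood_lv", "t1star_blood_rv",
                          "wall_thickness")
cohort_latent_cols <- c("t1_tissue_true", "mbv")
cohort_numeric_cols <- setdiff(c(cohort_required_cols, cohort_latent_cols),
                               c("subject_id", "cohort", "sex"))

#' @rdname cohort_table
#' @export
as_t1_cohort <- function(x) {
  stopifnot(is.data.frame(x))
  missing_cols <- setdiff(setdiff(cohort_required_cols,
                                  c("t1star_blood_lv", "t1star_blood_rv")),
                          names(x))
  if (length(missing_cols))
    stop("cohort table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in c("t1star_blood_lv", "t1star_blood_rv"))
    if (!col %in% names(x)) x[[col]] <- NA_real_
  validate_cohort_values(x)
  class(x) <- c("t1_cohort", "data.frame")
  x
}

validate_cohort_values <- function(x) {
  # NA is tolerated only in the optional T1* columns; rows failing a check
  # are reported by number so bad input files are diagnosable.
  bad_row <- function(ok, what) {
    rows <- which(!ok)
    if (length(rows))
      stop(sprintf("invalid cohort value (%s) in row(s): %s", what,
                   paste(utils::head(rows, 5), collapse = ", ")),
           call. = FALSE)
  }
  for (col in cohort_numeric_cols) {
    if (!col %in% names(x)) next
    if (!is.numeric(x[[col]]))
      stop("column `", col, "` must be numeric", call. = FALSE)
  }
  bad_row(x$cohort %in% cohort_labels, "unknown cohort label")
  bad_row(x$sex %in% c("male", "female"), "sex must be male/female")
  bad_row(!is.na(x$hematocrit) & x$hematocrit > 0 & x$hematocrit < 100,
          "hematocrit outside (0, 100)")
  for (col in c("t1_myo", "t1_blood_lv", "t1_blood_rv"))
    bad_row(!is.na(x[[col]]) & x[[col]] > 0, paste0(col, " must be > 0"))
  for (col in c("t1star_blood_lv", "t1star_blood_rv"))
    bad_row(is.na(x[[col]]) | x[[col]] > 0, paste0(col, " must be > 0"))
  bad_row(!is.na(x$wall_thickness) & x$wall_thickness > 0,
          "wall_thickness must be > 0")
  invisible(x)
}

#' Write or read a cohort table
#'
#' @param cohort A `t1_cohort` (or compatible data frame).
#' @param path File path for the comma-separated table.
#' @return `read_cohort()` returns a `t1_cohort`; `write_cohort()` returns
#'   `path` invisibly.  Numeric fields round-trip at full double precision.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- as_t1_cohort(cohort)
  df <- as.data.frame(cohort)
  # full-precision text so write -> read is a field-for-field identity
  for (col in cohort_numeric_cols)
    if (col %in% names(df)) df[[col]] <- sprintf("%.17g", df[[col]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path))
    stop("no such cohort file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  present_numeric <- intersect(cohort_numeric_cols, names(df))
  for (col in present_numeric) {
    v <- df[[col]]
    if (is.character(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(parsed) & !is.na(v) & nzchar(trimws(v)))
      if (length(bad))
        stop(sprintf("non-numeric value in column `%s`, row(s): %s", col,
                     paste(utils::head(bad, 5), collapse = ", ")),
             call. = FALSE)
      v <- parsed
    }
    df[[col]] <- as.numeric(v)
  }
  as_t1_cohort(df)
}

#' @export
print.t1_cohort <- function(x, ...) {
  cat(sprintf("<t1_cohort> %d subjects (%s)\n", nrow(x),
              paste(unique(x$cohort), collapse = ", ")))
  NextMethod()
}
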