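# cohort file I/O: comma-separated UTF-8 with header, one respondent per row.
# The column dictionary ships as inst/extdata/cohort-schema.tsv and is also
# available programmatically via cohort_schema().

.cohort_columns <- c("srh", "income_initial", "premium", "oop_spend",
                     "reimbursement", "outpatient_visits",
                     "inpatient_episodes", "gender", "age",
                     "education_years", "education_group", "marital",
                     "urban", "region")

.region_levels <- c("east", "central", "west")
.education_levels <- c("below_middle_school", "middle_school",
                       "high_school", "above_high_school")

#' Column dictionary of the cohort file format
#'
#' @return a `data.frame` with one row per mandatory column: name, type and
#'   a short definition. Matches `inst/extdata/cohort-schema.tsv`.
#' @export
cohort_schema <- function() {
  path <- system.file("extdata", "cohort-schema.tsv", package = "hequity",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Validate a participant table against the cohort schema
#'
#' Checks mandatory columns, SRH range 1..5, non-negative incomes, premiums,
#' spending and counts, and that reimbursement never exceeds out-of-pocket
#' spending. Errors name the offending column (and first offending row).
#'
#' @param cohort a data.frame.
#' @return the cohort, invisibly, with `education_group` and `region`
#'   coerced to their canonical factor levels.
#' @export
validate_cohort <- function(cohort) {
  missing_cols <- setdiff(.cohort_columns, names(cohort))
  if (length(missing_cols)) {
    stop("cohort schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_row <- function(ok, col, why) {
    if (!all(ok)) {
      stop(sprintf("cohort schema error in column '%s' (row %d): %s",
                   col, which(!ok)[1L], why), call. = FALSE)
    }
  }
  srh <- cohort$srh
  bad_row(!is.na(srh) & srh %in% 1:5, "srh",
          "self-rated health must be an integer in 1..5")
  bad_row(!is.na(cohort$income_initial) & cohort$income_initial >= 0,
          "income_initial", "initial income must be non-negative")
  for (col in c("premium", "oop_spend", "reimbursement",
                "outpatient_visits", "inpatient_episodes")) {
    bad_row(!is.na(cohort[[col]]) & cohort[[col]] >= 0, col,
            "must be non-negative")
  }
  bad_row(cohort$reimbursement <= cohort$oop_spend + 1e-8, "reimbursement",
          "reimbursement cannot exceed out-of-pocket spending")
  for (col in c("gender", "marital", "urban")) {
    bad_row(cohort[[col]] %in% c(0, 1), col, "must be binary 0/1")
  }
  cohort$region <- factor(as.character(cohort$region),
                          levels = .region_levels)
  bad_row(!is.na(cohort$region), "region",
          paste("must be one of", paste(.region_levels, collapse = "/")))
  cohort$education_group <- factor(as.character(cohort$education_group),
                                   levels = .education_levels)
  bad_row(!is.na(cohort$education_group), "education_group",
          paste("must be one of", paste(.education_levels, collapse = "/")))
  invisible(cohort)
}

#' Write / read a cohort table
#'
#' Lossless round-trip of the participant table as UTF-8 comma-separated
#' text with a header row (schema version 1; see [cohort_schema()]).
#'
#' @param cohort a validated participant table.
#' @param path file path.
#' @return `write_cohort` returns `path` invisibly; `read_cohort` returns a
#'   validated cohort `data.frame`.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  utils::write.csv(cohort, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       fileEncoding = "UTF-8")
  x <- validate_cohort(x)
  for (col in c("srh", "outpatient_visits", "inpatient_episodes", "gender",
                "age", "education_years", "marital", "urban")) {
    x[[col]] <- as.integer(x[[col]])
  }
  x
}
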