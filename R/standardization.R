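# Indirect need-standardization of medical service utilization.
#
# A linear model Y = a + b X_need + g Z_nonneed + e is fitted by least
# squares; "need-expected" utilization evaluates need factors at observed
# values and every non-need factor at its sample mean; standardized
# utilization is Y - Yhat_expected + mean(Y), which preserves the grand
# mean exactly.

.need_vars <- c("gender", "age", "srh")
.nonneed_vars <- c("log1p_income", "education_years", "marital", "urban",
                   "region")

# design frame for the utilization model; SRH enters as its 1-5 ordinal
# code, income as log(1 + income)
.util_frame <- function(cohort) {
  data.frame(gender = cohort$gender, age = cohort$age, srh = cohort$srh,
             log1p_income = log1p(cohort$income_initial),
             education_years = cohort$education_years,
             marital = cohort$marital, urban = cohort$urban,
             region = cohort$region)
}

#' Fit the utilization need model
#'
#' Least-squares regression of an annual utilization count (outpatient
#' visits or inpatient episodes) on need factors (gender, age, SRH coded
#' 1-5) and non-need factors (log(1+income), education years, marital
#' status, urban/rural status, region).
#'
#' @param cohort participant table.
#' @param outcome `"outpatient"` or `"inpatient"`.
#' @return object of class `need_model`: list with `fit` (`lm`),
#'   `outcome`, `need_vars`, `nonneed_vars`, coefficient split.
#' @export
fit_need_model <- function(cohort, outcome = c("outpatient", "inpatient")) {
  outcome <- match.arg(outcome)
  y <- if (outcome == "outpatient") cohort$outpatient_visits else
    cohort$inpatient_episodes
  df <- .util_frame(cohort)
  df$y <- y
  fit <- stats::lm(y ~ gender + age + srh + log1p_income +
                     education_years + marital + urban + region, data = df)
  cf <- stats::coef(fit)
  if (any(is.na(cf))) {
    stop("rank-deficient utilization model; collinear column(s): ",
         paste(names(cf)[is.na(cf)], collapse = ", "), call. = FALSE)
  }
  structure(list(fit = fit, outcome = outcome,
                 need_vars = .need_vars, nonneed_vars = .nonneed_vars,
                 coefficients = cf,
                 sigma = suppressWarnings(summary(fit)$sigma),
                 n = length(y)),
            class = "need_model")
}

#' @export
print.need_model <- function(x, digits = 4, ...) {
  cat(sprintf("Utilization need model (%s), n = %d\n", x$outcome, x$n))
  print(round(x$coefficients, digits))
  cat(sprintf("residual SD %.3f\n", x$sigma))
  invisible(x)
}

#' Need-expected utilization
#'
#' Prediction from a [fit_need_model()] fit with the need factors at their
#' observed values and every non-need factor fixed at its sample mean (the
#' means of the fitting sample's design columns). Two participants with
#' identical need factors get identical expected utilization regardless of
#' income.
#'
#' @param fit a `need_model`.
#' @param cohort participant table to predict for (defaults to the fitting
#'   data via its stored model frame when omitted).
#' @return numeric vector of expected utilization.
#' @export
expected_utilization <- function(fit, cohort = NULL) {
  mm_fit <- stats::model.matrix(fit$fit)
  mm <- if (is.null(cohort)) mm_fit else {
    df <- .util_frame(validate_cohort(cohort))
    stats::model.matrix(stats::delete.response(stats::terms(fit$fit)), df)
  }
  # non-need columns (including region dummies) -> fitting-sample means
  nonneed_cols <- grep(paste0("^(", paste(fit$nonneed_vars, collapse = "|"),
                              ")"), colnames(mm), value = TRUE)
  col_means <- colMeans(mm_fit)[nonneed_cols]
  mm[, nonneed_cols] <- rep(col_means, each = nrow(mm))
  unname(drop(mm %*% fit$coefficients))
}

#' Standardized utilization
#'
#' `Y_s = Y - Yhat_expected + mean(Y)`; the grand mean of the standardized
#' utilization equals the grand mean of actual utilization exactly (a
#' least-squares identity when the expected values come from a model with
#' an intercept fitted to the same sample).
#'
#' @param actual observed utilization vector.
#' @param expected need-expected utilization from
#'   [expected_utilization()].
#' @return numeric vector, same length.
#' @export
standardize_utilization <- function(actual, expected) {
  if (length(actual) != length(expected)) {
    stop("length mismatch", call. = FALSE)
  }
  actual - expected + mean(actual)
}

#' Per-quintile utilization table with coverage ratios
#'
#' For each income quintile and each outcome (outpatient, inpatient):
#' mean actual, mean need-expected, and mean standardized utilization,
#' plus the coverage ratio `100 * actual / expected` (percent; undefined
#' when expected <= 0, reported as `NA`).
#'
#' @param cohort participant table.
#' @param quintiles optional factor from [quintile_assign()]; computed on
#'   initial income when omitted.
#' @return object of class `utilization_table`: data.frame with columns
#'   `group`, `outcome`, `actual_mean`, `expected_mean`,
#'   `standardized_mean`, `coverage_ratio_pct`, `n`; the fitted need
#'   models are attached as an attribute.
#' @export
utilization_table <- function(cohort, quintiles = NULL) {
  cohort <- validate_cohort(cohort)
  if (is.null(quintiles)) quintiles <- quintile_assign(cohort$income_initial)
  fits <- list(outpatient = fit_need_model(cohort, "outpatient"),
               inpatient = fit_need_model(cohort, "inpatient"))
  rows <- lapply(names(fits), function(oc) {
    actual <- if (oc == "outpatient") cohort$outpatient_visits else
      cohort$inpatient_episodes
    expected <- expected_utilization(fits[[oc]])
    standardized <- standardize_utilization(actual, expected)
    agg <- lapply(levels(quintiles), function(lv) {
      i <- quintiles == lv
      am <- mean(actual[i]); em <- mean(expected[i])
      data.frame(group = lv, outcome = oc,
                 actual_mean = am, expected_mean = em,
                 standardized_mean = mean(standardized[i]),
                 coverage_ratio_pct = if (em > 0)
                   round_half_up(100 * am / em, 2) else NA_real_,
                 n = sum(i), stringsAsFactors = FALSE)
    })
    do.call(rbind, agg)
  })
  out <- do.call(rbind, rows)
  attr(out, "need_models") <- fits
  class(out) <- c("utilization_table", "data.frame")
  out
}

#' @export
print.utilization_table <- function(x, digits = 3, ...) {
  cat("Medical service utilization by income quintile\n")
  y <- as.data.frame(x)
  for (cl in c("actual_mean", "expected_mean", "standardized_mean")) {
    y[[cl]] <- round(y[[cl]], digits)
  }
  print(y, row.names = FALSE)
  invisible(x)
}
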