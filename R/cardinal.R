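#' Min-max rescale a latent health index to the unit interval
#'
#' Maps the predicted latent health index onto \[0, 1\] using the in-sample
#' extrema: `sah_i = (latent_i - min) / (max - min)`. The extrema used are
#' stored so the mapping is reportable. At least one participant attains 0
#' and one attains 1 by construction.
#'
#' @param latent numeric vector with at least two distinct values.
#' @return object of class `cardinal_health`: list with `sah` (in \[0,1\]),
#'   `latent`, `latent_min`, `latent_max`.
#' @export
rescale_unit <- function(latent) {
  if (!is.numeric(latent) || length(latent) < 2L || anyNA(latent)) {
    stop("'latent' must be a numeric vector of length >= 2 without NAs",
         call. = FALSE)
  }
  lo <- min(latent)
  hi <- max(latent)
  if (hi - lo <= 0) {
    stop("degenerate latent index: all values equal, cannot rescale to [0, 1]",
         call. = FALSE)
  }
  structure(list(sah = (latent - lo) / (hi - lo),
                 latent = latent, latent_min = lo, latent_max = hi),
            class = "cardinal_health")
}

#' @export
print.cardinal_health <- function(x, ...) {
  cat(sprintf(
    "Cardinalized health: n = %d, latent range [%.4g, %.4g] mapped to [0, 1]\n",
    length(x$sah), x$latent_min, x$latent_max))
  cat(sprintf("  mean score %.4f\n", mean(x$sah)))
  invisible(x)
}

# control-variable set used throughout (gender, age, education years,
# marital status, region)
.control_frame <- function(cohort) {
  data.frame(gender = cohort$gender, age = cohort$age,
             education_years = cohort$education_years,
             marital = cohort$marital, region = cohort$region)
}

#' Cardinalize self-rated health against a stage income
#'
#' Convenience wrapper: fits the ordered probit of SRH on the given stage
#' income plus the standard control set (gender, age, education years,
#' marital status, region), predicts the latent linear index at observed
#' covariate values, and min-max rescales it to \[0, 1\].
#'
#' @param cohort a participant table (see [generate_cohort()]).
#' @param income stage-income vector; defaults to `cohort$income_initial`.
#' @param fit optionally, a pre-computed [fit_ordered_probit()] object to
#'   predict from instead of refitting (used by the `fixed` stage mode).
#' @return a list with the `cardinal_health` object (`health`) and the
#'   `oprobit` fit used (`fit`).
#' @export
cardinalize <- function(cohort, income = cohort$income_initial, fit = NULL) {
  ctrl <- .control_frame(cohort)
  if (is.null(fit)) {
    fit <- fit_ordered_probit(cohort$srh, income, ctrl)
  }
  latent <- predict(fit, income = income, controls = ctrl)
  list(health = rescale_unit(latent), fit = fit)
}
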