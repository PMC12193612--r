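#' Configuration for the synthetic insurance cohort generator
#'
#' Builds and validates the parameter set from which [generate_cohort()]
#' draws a survey-like cohort of resident medical-insurance participants.
#' The defaults emulate the statistical structure the analysis assumes:
#' right-skewed per-capita household income, a latent health process with a
#' positive income gradient thresholded into five self-rated-health (SRH)
#' levels, a flat annual premium with a waiver for a low-income tail,
#' need- and income-graded utilization counts, out-of-pocket spending tied
#' to utilization, and partial reimbursement of that spending.
#'
#' @param n_individuals number of participants (>= 2).
#' @param seed integer RNG seed; generation is fully deterministic given
#'   the configuration and seed.
#' @param income_log_mean,income_log_sd lognormal parameters of annual
#'   per-capita household income (currency units).
#' @param health_income_slope effect of log(1+income) on latent health.
#' @param health_income_slope_gender_gap additional slope for participants
#'   with `gender == 1` (female); 0 by default.
#' @param health_intercept intercept of the latent health index.
#' @param covariate_effects named list of latent-health effects for the
#'   control variables (`gender`, `age`, `education_years`, `marital`,
#'   `urban`, `region_central`, `region_west`). Missing names default to 0.
#' @param srh_cutpoints four strictly increasing thresholds partitioning the
#'   latent scale into SRH levels 1..5.
#' @param premium_flat flat annual premium (currency units).
#' @param subsidy_fraction_bottom fraction of the lowest-income tail whose
#'   premium is (partially) waived.
#' @param subsidy_rate fraction of the premium waived for that tail, in
#'   \[0, 1\].
#' @param oop_model list with `unit_cost_outpatient`, `unit_cost_inpatient`,
#'   `income_elasticity` and `noise_sd` governing out-of-pocket spending.
#' @param reimbursement_rate fraction of out-of-pocket spending returned,
#'   in \[0, 1\].
#' @param utilization_model per-outcome (`outpatient`, `inpatient`) lists of
#'   linear-mean coefficients (`intercept`, `need`, `age`, `gender`,
#'   `income`, `education`) and a negative-binomial `size` (dispersion).
#'   The mean is linear in a need score derived from SRH (5 - srh), age,
#'   gender, centred log income, and centred education years.
#'
#' @return an object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()]
#' @export
cohort_config <- function(n_individuals = 20000L,
                          seed = 1L,
                          income_log_mean = 9.5,
                          income_log_sd = 0.8,
                          health_income_slope = 0.3,
                          health_income_slope_gender_gap = 0,
                          health_intercept = -2.33,
                          covariate_effects = list(
                            gender = -0.10, age = -0.015,
                            education_years = 0.03, marital = 0.10,
                            urban = 0.05, region_central = -0.05,
                            region_west = -0.10),
                          srh_cutpoints = c(-1.74, -0.79, 0.36, 1.33),
                          premium_flat = 250,
                          subsidy_fraction_bottom = 0.05,
                          subsidy_rate = 1,
                          oop_model = list(unit_cost_outpatient = 150,
                                           unit_cost_inpatient = 2500,
                                           income_elasticity = 0.15,
                                           noise_sd = 0.4),
                          reimbursement_rate = 0.5,
                          utilization_model = list(
                            outpatient = list(intercept = 3.0, need = 0.8,
                                              age = 0.03, gender = 0.2,
                                              income = 0.5, education = 0,
                                              size = 1.2),
                            inpatient = list(intercept = 0.25, need = 0.25,
                                             age = 0.01, gender = 0.0,
                                             income = 0.12, education = 0,
                                             size = 0.8))) {
  if (!is.numeric(n_individuals) || length(n_individuals) != 1L ||
      n_individuals < 2 || n_individuals != round(n_individuals)) {
    stop("'n_individuals' must be a whole number >= 2", call. = FALSE)
  }
  stopifnot_scalar_num(seed, "seed")
  stopifnot_scalar_num(income_log_mean, "income_log_mean")
  if (!is.numeric(income_log_sd) || income_log_sd <= 0) {
    stop("'income_log_sd' must be > 0", call. = FALSE)
  }
  stopifnot_scalar_num(health_income_slope, "health_income_slope")
  if (!is.numeric(srh_cutpoints) || length(srh_cutpoints) != 4L ||
      any(diff(srh_cutpoints) <= 0)) {
    stop("'srh_cutpoints' must be 4 strictly increasing thresholds",
         call. = FALSE)
  }
  stopifnot_scalar_num(premium_flat, "premium_flat", lo = 0)
  stopifnot_scalar_num(subsidy_fraction_bottom, "subsidy_fraction_bottom",
                       lo = 0, hi = 1)
  stopifnot_scalar_num(subsidy_rate, "subsidy_rate", lo = 0, hi = 1)
  stopifnot_scalar_num(reimbursement_rate, "reimbursement_rate",
                       lo = 0, hi = 1)
  known <- c("gender", "age", "education_years", "marital", "urban",
             "region_central", "region_west")
  if (length(covariate_effects) &&
      !all(names(covariate_effects) %in% known)) {
    stop("unknown names in 'covariate_effects': ",
         paste(setdiff(names(covariate_effects), known), collapse = ", "),
         call. = FALSE)
  }
  eff <- stats::setNames(as.list(rep(0, length(known))), known)
  eff[names(covariate_effects)] <- covariate_effects
  cfg <- list(n_individuals = as.integer(n_individuals),
              seed = as.integer(seed),
              income_log_mean = income_log_mean,
              income_log_sd = income_log_sd,
              health_income_slope = health_income_slope,
              health_income_slope_gender_gap = health_income_slope_gender_gap,
              health_intercept = health_intercept,
              covariate_effects = eff,
              srh_cutpoints = srh_cutpoints,
              premium_flat = premium_flat,
              subsidy_fraction_bottom = subsidy_fraction_bottom,
              subsidy_rate = subsidy_rate,
              oop_model = oop_model,
              reimbursement_rate = reimbursement_rate,
              utilization_model = utilization_model)
  class(cfg) <- "cohort_config"
  cfg
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  n = %d, seed = %d\n", x$n_individuals, x$seed))
  cat(sprintf("  income ~ lognormal(meanlog = %.3g, sdlog = %.3g)\n",
              x$income_log_mean, x$income_log_sd))
  cat(sprintf("  latent-health slope on log income: %.3g\n",
              x$health_income_slope))
  cat(sprintf("  premium %.0f (bottom %.0f%% waived at rate %.0f%%), reimbursement rate %.0f%%\n",
              x$premium_flat, 100 * x$subsidy_fraction_bottom,
              100 * x$subsidy_rate, 100 * x$reimbursement_rate))
  invisible(x)
}

# linear negative-binomial mean for one utilization outcome; `need` is the
# SRH-derived need score (5 - srh), higher = sicker
.util_mu <- function(m, need, age, gender, loginc, edu, income_log_mean) {
  mu <- m$intercept +
    m$need * need +
    m$age * (age - 50) / 10 +
    m$gender * gender +
    m$income * (loginc - income_log_mean) +
    m$education * (edu - 8)
  pmax(mu, 0.01)
}

#' Generate a synthetic insurance cohort
#'
#' Draws one participant-level table under the process described in
#' [cohort_config()]: latent health is
#' `intercept + slope * log(1 + income) + covariate effects + N(0,1)` noise,
#' thresholded at the configured cutpoints into SRH 1..5; the flat premium
#' is reduced by `subsidy_rate` for the bottom `subsidy_fraction_bottom`
#' income tail; outpatient/inpatient counts are overdispersed
#' (negative-binomial) with a mean linear in need (SRH, age, gender) and
#' non-need (income, education) factors; out-of-pocket spending scales with
#' utilization and income; reimbursement is a fixed fraction of spending.
#'
#' @param config a [cohort_config()] object.
#' @return a `data.frame` with one row per participant and columns
#'   `srh`, `income_initial`, `premium`, `oop_spend`, `reimbursement`,
#'   `outpatient_visits`, `inpatient_episodes`, `gender`, `age`,
#'   `education_years`, `education_group`, `marital`, `urban`, `region`.
#'   The realized generator state (configuration, true latent health, need
#'   score) is attached as `attr(, "ground_truth")`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    config <- do.call(cohort_config, as.list(config))
  }
  n <- config$n_individuals
  with_seed(config$seed, {
    income <- stats::rlnorm(n, config$income_log_mean, config$income_log_sd)
    gender <- stats::rbinom(n, 1L, 0.5)                 # 1 = female
    age <- pmin(pmax(round(stats::rnorm(n, 50, 16)), 18L), 90L)
    education_years <- sample(c(0L, 3L, 6L, 9L, 12L, 16L), n, replace = TRUE,
                              prob = c(0.08, 0.12, 0.30, 0.28, 0.15, 0.07))
    marital <- stats::rbinom(n, 1L, 0.8)
    urban <- stats::rbinom(n, 1L, 0.35)
    region <- factor(sample(c("east", "central", "west"), n, replace = TRUE,
                            prob = c(0.35, 0.35, 0.30)),
                     levels = c("east", "central", "west"))

    eff <- config$covariate_effects
    slope <- config$health_income_slope +
      config$health_income_slope_gender_gap * gender
    latent_systematic <- config$health_intercept +
      slope * log1p(income) +
      eff$gender * gender +
      eff$age * age +
      eff$education_years * education_years +
      eff$marital * marital +
      eff$urban * urban +
      eff$region_central * (region == "central") +
      eff$region_west * (region == "west")
    latent <- latent_systematic + stats::rnorm(n)
    srh <- findInterval(latent, config$srh_cutpoints) + 1L

    # premium: flat, waived (at subsidy_rate) for the poorest tail
    premium <- rep(config$premium_flat, n)
    n_sub <- floor(config$subsidy_fraction_bottom * n)
    if (n_sub > 0) {
      poorest <- order(income)[seq_len(n_sub)]
      premium[poorest] <- premium[poorest] * (1 - config$subsidy_rate)
    }

    need <- 5 - srh                                     # higher = sicker
    loginc <- log1p(income)
    um <- config$utilization_model
    mu_out <- .util_mu(um$outpatient, need, age, gender, loginc,
                       education_years, config$income_log_mean)
    mu_in <- .util_mu(um$inpatient, need, age, gender, loginc,
                      education_years, config$income_log_mean)
    outpatient <- stats::rnbinom(n, size = um$outpatient$size, mu = mu_out)
    inpatient <- stats::rnbinom(n, size = um$inpatient$size, mu = mu_in)

    om <- config$oop_model
    base_cost <- om$unit_cost_outpatient * outpatient +
      om$unit_cost_inpatient * inpatient
    oop <- base_cost * exp(om$income_elasticity *
                             (loginc - config$income_log_mean) +
                           stats::rnorm(n, 0, om$noise_sd) -
                           om$noise_sd^2 / 2)
    reimbursement <- config$reimbursement_rate * oop

    edu_breaks <- c(-Inf, 9, 12, 15, Inf)
    education_group <- cut(education_years, edu_breaks, right = FALSE,
                           labels = c("below_middle_school", "middle_school",
                                      "high_school", "above_high_school"))

    cohort <- data.frame(
      srh = srh,
      income_initial = income,
      premium = premium,
      oop_spend = oop,
      reimbursement = reimbursement,
      outpatient_visits = outpatient,
      inpatient_episodes = inpatient,
      gender = gender,
      age = age,
      education_years = education_years,
      education_group = education_group,
      marital = marital,
      urban = urban,
      region = region,
      stringsAsFactors = FALSE
    )
    attr(cohort, "ground_truth") <- list(
      config = config,
      latent_health = latent,
      latent_systematic = latent_systematic,
      need_score = need,
      expected_ci_sign = sign(config$health_income_slope)
    )
    cohort
  })
}
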