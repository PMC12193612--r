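# Stage-wise decomposition of income-related health inequality across the
# four income states induced by the insurance scheme: initial income, after
# premium contribution, after out-of-pocket treatment spending, and after
# reimbursement.

.stage_names <- c("initial", "contribution", "treatment", "reimbursement")

#' Per-participant incomes at the four insurance stages
#'
#' `initial` is per-capita household income; `contribution = initial -
#' premium`; `treatment = contribution - oop_spend`; `reimbursement =
#' treatment + reimbursement`. Negative post-treatment incomes are kept
#' as-is (ranks remain defined).
#'
#' @param cohort participant table with `income_initial`, `premium`,
#'   `oop_spend`, `reimbursement` columns.
#' @return a `data.frame` with columns `initial`, `contribution`,
#'   `treatment`, `reimbursement`.
#' @export
build_stage_incomes <- function(cohort) {
  needed <- c("income_initial", "premium", "oop_spend", "reimbursement")
  missing_cols <- setdiff(needed, names(cohort))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (any(cohort$reimbursement > cohort$oop_spend + 1e-8)) {
    stop("reimbursement exceeds out-of-pocket spending for some participants",
         call. = FALSE)
  }
  initial <- cohort$income_initial
  contribution <- initial - cohort$premium
  treatment <- contribution - cohort$oop_spend
  reimbursement <- treatment + cohort$reimbursement
  data.frame(initial = initial, contribution = contribution,
             treatment = treatment, reimbursement = reimbursement)
}

#' Nonparametric bootstrap standard error of a cohort statistic
#'
#' Resamples participants (rows) with replacement, recomputes the
#' statistic, and returns the bootstrap SE together with a two-sided
#' percentile p-value against zero. Degenerate resamples (statistic errors
#' or is non-finite, e.g. constant health) are redrawn and counted.
#'
#' @param statistic function of a data.frame returning one number.
#' @param cohort the participant table (any data.frame).
#' @param B number of bootstrap replicates (>= 2; B < 50 is flagged
#'   low-precision).
#' @param seed RNG seed; same seed gives identical results.
#' @return list with `se`, `p_value`, `replicates`, `n_degenerate`,
#'   `low_precision`.
#' @export
bootstrap_se <- function(statistic, cohort, B = 200L, seed = 1L) {
  if (B < 2L) stop("'B' must be at least 2", call. = FALSE)
  n <- nrow(cohort)
  with_seed(seed, {
    reps <- numeric(B)
    n_degenerate <- 0L
    for (b in seq_len(B)) {
      val <- NA_real_
      tries <- 0L
      while (!is.finite(val) && tries < 25L) {
        idx <- sample.int(n, n, replace = TRUE)
        val <- tryCatch(statistic(cohort[idx, , drop = FALSE]),
                        error = function(e) NA_real_)
        tries <- tries + 1L
        if (!is.finite(val)) n_degenerate <- n_degenerate + 1L
      }
      if (!is.finite(val)) {
        stop("bootstrap: statistic degenerate on 25 consecutive resamples",
             call. = FALSE)
      }
      reps[b] <- val
    }
    # two-sided percentile p against 0 (add-one correction keeps p > 0)
    p <- 2 * min((sum(reps <= 0) + 1) / (B + 1),
                 (sum(reps >= 0) + 1) / (B + 1))
    list(se = stats::sd(reps), p_value = min(p, 1), replicates = reps,
         n_degenerate = n_degenerate, low_precision = B < 50L)
  })
}

# one stage's CI + EI on already-cardinalized health
.stage_indices <- function(sah, stage_income, stage, group = "total") {
  r <- fractional_rank(stage_income)
  list(ci = concentration_index(sah, r, stage = stage, group = group),
       ei = erreygers_index(sah, r, stage = stage, group = group))
}

# cardinalized [0,1] health per stage under the requested mode
.stage_health <- function(cohort, stages, mode) {
  if (mode == "fixed") {
    card <- cardinalize(cohort, income = stages$initial)
    sah <- replicate(4, card$health$sah, simplify = FALSE)
    names(sah) <- .stage_names
    list(sah = sah, fits = list(initial = card$fit))
  } else {
    fits <- list()
    sah <- lapply(.stage_names, function(s) {
      card <- cardinalize(cohort, income = stages[[s]])
      fits[[s]] <<- card$fit
      card$health$sah
    })
    names(sah) <- .stage_names
    list(sah = sah, fits = fits)
  }
}

#' Stage-wise health-inequality analysis
#'
#' The package's central estimator: cardinalizes self-rated health via the
#' ordered probit, ranks participants by income at each of the four
#' insurance stages, and computes the concentration index (CI) and
#' Erreygers index (EI) per stage, plus the stage-to-stage changes and the
#' total change `delta_total = CI_initial - CI_reimbursement` (negative
#' means the scheme widened inequality).
#'
#' Two cardinalization modes are supported: `per_stage` (default) refits
#' the ordered probit with each stage's income as the income regressor and
#' re-predicts the health score per stage; `fixed` fits once on initial
#' income and holds the score constant across stages so that only income
#' ranks change.
#'
#' @param cohort participant table (see [generate_cohort()] /
#'   [read_cohort()]).
#' @param mode `"per_stage"` or `"fixed"`.
#' @param boot_B bootstrap replicates for SEs of each stage index
#'   (0 = skip).
#' @param seed bootstrap seed.
#' @return object of class `health_inequality`: list with `indices` (a
#'   data.frame: stage, ci, ei, mean_health, se/p if bootstrapped),
#'   `deltas` (stage-to-stage CI changes and `delta_total`), `mode`,
#'   `fits`, `n`.
#' @export
health_inequality <- function(cohort, mode = c("per_stage", "fixed"),
                              boot_B = 0L, seed = 1L) {
  mode <- match.arg(mode)
  cohort <- validate_cohort(cohort)
  stages <- build_stage_incomes(cohort)
  sh <- .stage_health(cohort, stages, mode)

  res <- lapply(.stage_names, function(s) {
    .stage_indices(sh$sah[[s]], stages[[s]], s)
  })
  names(res) <- .stage_names
  indices <- data.frame(
    stage = .stage_names,
    ci = vapply(res, function(r) r$ci$index_value, numeric(1)),
    ei = vapply(res, function(r) r$ei$index_value, numeric(1)),
    mean_health = vapply(res, function(r) r$ci$mean_health, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )

  if (boot_B >= 2L) {
    boot <- lapply(seq_along(.stage_names), function(k) {
      s <- .stage_names[k]
      df <- data.frame(sah = sh$sah[[s]], stage_income = stages[[s]])
      bootstrap_se(function(d) {
        concentration_index(d$sah, fractional_rank(d$stage_income))$index_value
      }, df, B = boot_B, seed = seed + k)
    })
    indices$ci_se_boot <- vapply(boot, `[[`, numeric(1), "se")
    indices$ci_p_boot <- vapply(boot, `[[`, numeric(1), "p_value")
  }

  ci <- stats::setNames(indices$ci, indices$stage)
  deltas <- list(
    delta_contribution = unname(ci["initial"] - ci["contribution"]),
    delta_treatment = unname(ci["contribution"] - ci["treatment"]),
    delta_reimbursement = unname(ci["treatment"] - ci["reimbursement"]),
    delta_total = unname(ci["initial"] - ci["reimbursement"])
  )

  structure(list(indices = indices, deltas = deltas, mode = mode,
                 fits = sh$fits, sah = sh$sah, stage_incomes = stages,
                 n = nrow(cohort), boot_B = boot_B, seed = seed),
            class = "health_inequality")
}

#' @export
print.health_inequality <- function(x, digits = 4, ...) {
  cat(sprintf(
    "Stage-wise income-related health inequality (n = %d, mode = %s)\n\n",
    x$n, x$mode))
  print(cbind(stage = x$indices$stage,
              round(x$indices[, -1, drop = FALSE], digits)),
        row.names = FALSE)
  cat(sprintf(
    "\nDeltas (CI): contribution %+.*f, treatment %+.*f, reimbursement %+.*f\n",
    digits, x$deltas$delta_contribution, digits, x$deltas$delta_treatment,
    digits, x$deltas$delta_reimbursement))
  cat(sprintf("delta_total = %+.*f  (%s)\n", digits, x$deltas$delta_total,
              if (x$deltas$delta_total < 0)
                "inequality widened post-reimbursement"
              else "inequality narrowed post-reimbursement"))
  invisible(x)
}

#' @export
summary.health_inequality <- function(object, ...) {
  object
}

#' @export
plot.health_inequality <- function(x, ...) {
  ci <- x$indices$ci
  plot(seq_along(.stage_names), ci, type = "b", pch = 19, xaxt = "n",
       xlab = "insurance stage", ylab = "concentration index",
       main = "Health inequality across insurance stages", ...)
  graphics::axis(1, at = seq_along(.stage_names), labels = .stage_names)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Subgroup concentration indices at one stage
#'
#' Recomputes fractional income ranks *within* each subgroup and returns
#' one CI per subgroup. By default health is also cardinalized within each
#' subgroup (the ordered probit is refit on that subgroup's members), so
#' a subgroup-specific income-health gradient is measurable; supplying a
#' pre-computed full-sample `sah` vector instead puts all subgroups on a
#' common pooled health scale. Income quintile groups are formed on
#' initial income and held fixed across stages. Subgroups with fewer than
#' 2 members are skipped with a warning.
#'
#' @param cohort participant table.
#' @param grouping one of `"income_quintile"`, `"gender"`,
#'   `"education_group"`.
#' @param stage one of `"initial"`, `"contribution"`, `"treatment"`,
#'   `"reimbursement"`.
#' @param mode cardinalization mode, as in [health_inequality()].
#' @param sah optionally, a pre-computed \[0,1\] health vector for this
#'   stage (skips refitting).
#' @return data.frame: group, ci, ei, mean_health, n.
#' @export
subgroup_ci <- function(cohort,
                        grouping = c("income_quintile", "gender",
                                     "education_group"),
                        stage = .stage_names, mode = c("per_stage", "fixed"),
                        sah = NULL) {
  grouping <- match.arg(grouping)
  stage <- match.arg(stage)
  mode <- match.arg(mode)
  cohort <- validate_cohort(cohort)
  stages <- build_stage_incomes(cohort)
  within_fit <- is.null(sah)
  card_inc <- if (mode == "fixed") stages$initial else stages[[stage]]
  g <- switch(grouping,
              income_quintile = quintile_assign(cohort$income_initial),
              gender = factor(ifelse(cohort$gender == 1, "female", "male"),
                              levels = c("male", "female")),
              education_group = cohort$education_group)
  out <- lapply(levels(g), function(lv) {
    i <- which(g == lv)
    if (length(i) < 2L) {
      warning(sprintf("subgroup '%s' has < 2 members; skipped", lv),
              call. = FALSE)
      return(NULL)
    }
    r <- fractional_rank(stages[[stage]][i])
    h <- if (within_fit) {
      cardinalize(cohort[i, , drop = FALSE],
                  income = card_inc[i])$health$sah
    } else sah[i]
    data.frame(group = lv,
               ci = concentration_index(h, r)$index_value,
               ei = erreygers_index(h, r)$index_value,
               mean_health = mean(h), n = length(i),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out$stage <- stage
  out
}
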