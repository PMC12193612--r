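# Concentration and Erreygers indices over fractional income ranks.

#' Fractional ranks of a ranking variable
#'
#' Ascending fractional ranks `(i - 0.5)/n`; tied values share the average
#' of their positional ranks, so the mean rank is exactly 0.5 for any
#' input (a constant vector yields all ranks 0.5).
#'
#' @param values numeric vector (typically a stage income).
#' @return numeric vector of ranks in (0, 1).
#' @export
fractional_rank <- function(values) {
  if (length(values) == 0L || anyNA(values)) {
    stop("'values' must be a non-empty numeric vector without NAs",
         call. = FALSE)
  }
  (rank(values, ties.method = "average") - 0.5) / length(values)
}

.new_ci_result <- function(value, kind, health, n, stage = NA_character_,
                           group = "total") {
  structure(list(index_value = value, index_kind = kind, stage = stage,
                 group = group, mean_health = mean(health), n = n,
                 se_boot = NA_real_, p_boot = NA_real_),
            class = "ci_result")
}

#' @export
print.ci_result <- function(x, ...) {
  lbl <- if (x$index_kind == "erreygers") "Erreygers index" else
    "Concentration index"
  cat(sprintf("%s: %.4f", lbl, x$index_value))
  if (!is.na(x$stage)) cat(sprintf("  [stage: %s]", x$stage))
  if (!identical(x$group, "total")) cat(sprintf("  [group: %s]", x$group))
  cat(sprintf("\n  mean health %.4f, n = %d", x$mean_health, x$n))
  if (!is.na(x$se_boot)) {
    cat(sprintf(", bootstrap SE %.4f, p = %.3g", x$se_boot, x$p_boot))
  }
  cat("\n")
  invisible(x)
}

#' Concentration index of health over income ranks
#'
#' `CI = 2 cov(h, r) / mean(h)` with the population (1/n) covariance; for
#' untied ranks this equals the summation form
#' `2/(n * mean(h)) * sum(h_i * r_i) - 1`. Positive values indicate health
#' concentrated among the rich (pro-rich inequality); the index lies in
#' \[-1, 1\].
#'
#' @param health numeric health vector with positive mean (e.g. the
#'   cardinalized \[0,1\] score).
#' @param ranks fractional ranks from [fractional_rank()] (same length).
#' @param stage,group optional labels carried into the result.
#' @return a `ci_result` object; the index itself is `$index_value`.
#' @export
concentration_index <- function(health, ranks, stage = NA_character_,
                                group = "total") {
  n <- length(health)
  if (n != length(ranks)) stop("length mismatch", call. = FALSE)
  h_bar <- mean(health)
  if (h_bar <= 0) {
    stop("concentration index undefined: mean health must be > 0",
         call. = FALSE)
  }
  # population covariance
  ci <- 2 * mean((health - h_bar) * (ranks - mean(ranks))) / h_bar
  .new_ci_result(ci, "standard", health, n, stage, group)
}

#' Erreygers corrected concentration index
#'
#' `EI = (1/n) * sum( 4 * h_i / (h_max - h_min) * (2 r_i - 1) )` for a
#' bounded health variable. For health bounded in \[0, 1\] this equals
#' `4 * mean(h) * CI` when ranks are untied. Lies in \[-1, 1\]; positive
#' values favour the rich.
#'
#' @param health numeric vector within \[`h_min`, `h_max`\].
#' @param ranks fractional ranks from [fractional_rank()].
#' @param h_min,h_max attainable bounds of the health variable (defaults
#'   0 and 1, the bounds of the cardinalized score).
#' @inheritParams concentration_index
#' @return a `ci_result` object with `index_kind = "erreygers"`.
#' @export
erreygers_index <- function(health, ranks, h_min = 0, h_max = 1,
                            stage = NA_character_, group = "total") {
  n <- length(health)
  if (n != length(ranks)) stop("length mismatch", call. = FALSE)
  if (h_min >= h_max) stop("'h_min' must be < 'h_max'", call. = FALSE)
  if (any(health < h_min - 1e-12 | health > h_max + 1e-12)) {
    stop("health values outside [h_min, h_max]", call. = FALSE)
  }
  ei <- mean(4 * (health - h_min) / (h_max - h_min) * (2 * ranks - 1))
  .new_ci_result(ei, "erreygers", health, n, stage, group)
}

#' Assign income quintile groups
#'
#' Cuts at the 20/40/60/80th percentiles of income; ties at a boundary are
#' all assigned to the lower group. If all incomes are equal everyone falls
#' in the lowest group (with a warning).
#'
#' @param income numeric vector, length >= 5.
#' @return a factor with levels `low`, `lower_middle`, `middle`,
#'   `upper_middle`, `high`.
#' @export
quintile_assign <- function(income) {
  if (length(income) < 5L) stop("need at least 5 observations", call. = FALSE)
  labs <- c("low", "lower_middle", "middle", "upper_middle", "high")
  q <- stats::quantile(income, c(0.2, 0.4, 0.6, 0.8), names = FALSE)
  if (length(unique(q)) < 4L) {
    # degenerate percentiles: collapse duplicated boundaries; anything at or
    # below a boundary goes to the lowest group that boundary closes
    warning("tied quintile boundaries: income groups are unbalanced",
            call. = FALSE)
    q <- q + cumsum(c(0, diff(q) == 0)) * 0  # keep values; handle via unique
    breaks <- unique(c(-Inf, q, Inf))
    g <- cut(income, breaks, labels = FALSE, right = TRUE)
    return(factor(labs[g], levels = labs))
  }
  cut(income, c(-Inf, q, Inf), labels = labs, right = TRUE)
}
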