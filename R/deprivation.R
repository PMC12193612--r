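# Relative deprivation of health (Yitzhaki/Kakwani style): each
# participant's mean shortfall relative to all healthier participants,
# normalized by mean health. The population mean of the index equals the
# Gini coefficient of health.

#' Mean-normalized relative deprivation of health
#'
#' For participant i with health `x_i`,
#' `rd_i = 1/(n * u) * sum_j max(x_j - x_i, 0)` where `u` is mean health.
#' Computed via the decomposition `rd_i = (1/u) * r_plus_i * (u_plus_i -
#' x_i)` with `r_plus_i` the share of participants strictly healthier than
#' i and `u_plus_i` their mean health — O(n log n) by sorting and suffix
#' sums. Optionally computed within groups.
#'
#' @param health numeric vector (raw 1-5 SRH scores by default in the
#'   pipeline; any positive-mean health measure works).
#' @param group optional factor: compute the index within each group
#'   separately (each group is its own reference population).
#' @return object of class `rd_result`: list with `rd` (>= 0, 0 for every
#'   participant attaining the group maximum), `mean_health`,
#'   `count_above`, `share_above`, `mean_above`.
#' @export
relative_deprivation <- function(health, group = NULL) {
  if (anyNA(health)) stop("missing health values", call. = FALSE)
  if (is.null(group)) group <- factor(rep("all", length(health)))
  group <- droplevels(as.factor(group))
  n_tot <- length(health)
  rd <- count_above <- share_above <- mean_above <- numeric(n_tot)
  u_store <- numeric(n_tot)
  for (lv in levels(group)) {
    i <- which(group == lv)
    x <- health[i]
    n <- length(x)
    u <- mean(x)
    if (u <= 0) {
      stop("relative deprivation undefined: mean health must be > 0",
           call. = FALSE)
    }
    o <- order(x, decreasing = TRUE)
    xs <- x[o]
    # suffix -> prefix over the descending sort: participants strictly
    # healthier than x are those sorted before the first occurrence of x
    csum <- cumsum(xs)
    first_idx <- match(xs, xs)              # first position of each value
    n_above <- first_idx - 1L
    s_above <- ifelse(n_above > 0L, csum[pmax(first_idx - 1L, 1L)], 0)
    m_above <- ifelse(n_above > 0L, s_above / n_above, NA_real_)
    r_above <- n_above / n
    rd_g <- ifelse(n_above > 0L, (1 / u) * r_above * (m_above - xs), 0)
    # undo the sort
    inv <- order(o)
    rd[i] <- rd_g[inv]
    count_above[i] <- n_above[inv]
    share_above[i] <- r_above[inv]
    mean_above[i] <- m_above[inv]
    u_store[i] <- u
  }
  structure(list(rd = rd, mean_health = if (nlevels(group) == 1L)
                   u_store[1L] else u_store,
                 count_above = count_above, share_above = share_above,
                 mean_above = mean_above, group = group),
            class = "rd_result")
}

#' @export
print.rd_result <- function(x, ...) {
  cat(sprintf(
    "Relative health deprivation: n = %d, mean RD = %.4f (= Gini of health)\n",
    length(x$rd), mean(x$rd)))
  invisible(x)
}

#' Regression of relative deprivation on income-quintile membership
#'
#' Ordinary least squares of the per-participant relative-deprivation
#' index on four income-quintile dummies (lowest quintile as reference),
#' optionally adding the standard control set (gender, age, education
#' years, marital status, region). Conventional (non-robust) standard
#' errors.
#'
#' @param rd numeric relative-deprivation vector (e.g. `$rd` of
#'   [relative_deprivation()]).
#' @param quintiles factor from [quintile_assign()] on initial income.
#' @param controls optional control covariate data.frame.
#' @param with_controls include the controls?
#' @return object of class `rd_regression`: list with `coefficients`
#'   data.frame (term, estimate, se, p_value), the underlying `lm` fit,
#'   and `with_controls`.
#' @export
rd_regression <- function(rd, quintiles, controls = NULL,
                          with_controls = !is.null(controls)) {
  quintiles <- as.factor(quintiles)
  if (nlevels(droplevels(quintiles)) < 2L) {
    stop("need at least two income groups", call. = FALSE)
  }
  df <- data.frame(rd = rd, quintile = quintiles)
  form <- rd ~ quintile
  if (with_controls) {
    if (is.null(controls)) stop("'controls' required", call. = FALSE)
    df <- cbind(df, as.data.frame(controls))
    form <- stats::reformulate(c("quintile", colnames(controls)),
                               response = "rd")
  }
  fit <- stats::lm(form, data = df)
  if (any(is.na(stats::coef(fit)))) {
    stop("collinear regressors: ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  structure(list(coefficients = data.frame(term = rownames(sm),
                                           estimate = sm[, 1],
                                           se = sm[, 2],
                                           p_value = sm[, 4],
                                           row.names = NULL,
                                           stringsAsFactors = FALSE),
                 fit = fit, with_controls = with_controls,
                 n = length(rd)),
            class = "rd_regression")
}

#' @export
print.rd_regression <- function(x, digits = 4, ...) {
  cat(sprintf("RD on income quintiles (%s controls), n = %d\n",
              if (x$with_controls) "with" else "without", x$n))
  tab <- x$coefficients
  tab$estimate <- round(tab$estimate, digits)
  tab$se <- round(tab$se, digits)
  tab$stars <- ifelse(tab$p_value < 0.01, "***", "")
  print(tab[, c("term", "estimate", "se", "stars")], row.names = FALSE)
  invisible(x)
}
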