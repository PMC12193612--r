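# Ordered-probit fitting for the cardinalization of self-rated health.
#
# Latent model: H* = X b + e, e ~ N(0, 1); observed category k iff
# tau_{k-1} < H* <= tau_k with tau_0 = -Inf, tau_K = +Inf. No separate
# intercept (absorbed by the cutpoints, the standard identification).
# Maximized by BFGS with an analytic gradient; cutpoints kept ascending by
# optimizing (tau_1, log-gaps).

.oprobit_nll <- function(theta, y, X, K) {
  p <- ncol(X)
  beta <- theta[seq_len(p)]
  tau <- if (K == 2L) theta[p + 1L] else
    cumsum(c(theta[p + 1L], exp(theta[(p + 2L):(p + K - 1L)])))
  eta <- drop(X %*% beta)
  hi <- c(tau, Inf)[y] - eta
  lo <- c(-Inf, tau)[y] - eta
  pr <- pmax(stats::pnorm(hi) - stats::pnorm(lo), 1e-300)
  -sum(log(pr))
}

.oprobit_grad <- function(theta, y, X, K) {
  p <- ncol(X)
  beta <- theta[seq_len(p)]
  tau <- if (K == 2L) theta[p + 1L] else
    cumsum(c(theta[p + 1L], exp(theta[(p + 2L):(p + K - 1L)])))
  eta <- drop(X %*% beta)
  hi <- c(tau, Inf)[y] - eta
  lo <- c(-Inf, tau)[y] - eta
  pr <- pmax(stats::pnorm(hi) - stats::pnorm(lo), 1e-300)
  dhi <- stats::dnorm(hi)
  dlo <- stats::dnorm(lo)
  # d nll / d eta_i
  g_eta <- (dhi - dlo) / pr
  g_beta <- drop(crossprod(X, g_eta))
  # d nll / d tau_j: tau_j is the upper bound for category j and the lower
  # bound for category j + 1
  g_tau <- vapply(seq_len(K - 1L), function(j) {
    -sum(dhi[y == j] / pr[y == j]) + sum(dlo[y == j + 1L] / pr[y == j + 1L])
  }, numeric(1))
  if (K == 2L) return(c(g_beta, g_tau))
  g_a <- sum(g_tau)
  g_d <- vapply(seq_len(K - 2L), function(j) {
    exp(theta[p + 1L + j]) * sum(g_tau[(j + 1L):(K - 1L)])
  }, numeric(1))
  c(g_beta, g_a, g_d)
}

#' Fit an ordered probit of self-rated health on stage income and controls
#'
#' Maximum-likelihood ordered probit of an ordinal outcome (SRH, 2 or more
#' observed levels; the 2-level case reduces to a plain binary probit) on a
#' stage-income regressor and a table of control covariates. Income enters
#' as the signed log transform `sign(x) * log(1 + |x|)`, which equals
#' `log(1 + income)` for the non-negative initial income and remains
#' defined for negative post-treatment stage incomes.
#'
#' @param srh integer/ordinal outcome vector with at least 2 observed
#'   levels.
#' @param income stage-income vector (currency units), same length.
#' @param controls optional `data.frame` of control covariates (entered via
#'   `model.matrix`, factors expanded to dummies).
#' @param maxit,gtol optimizer settings: BFGS iteration cap and the
#'   mean-gradient convergence tolerance.
#' @return an object of class `oprobit`: list with `coefficients` (named,
#'   income term `log1p_income` first), `cutpoints` (ascending), `se`,
#'   `vcov`, `logLik`, `converged`, `n_obs`, `levels`, plus the design
#'   recipe used by [predict.oprobit()].
#' @export
fit_ordered_probit <- function(srh, income, controls = NULL,
                               maxit = 200L, gtol = 1e-6) {
  if (length(srh) != length(income)) {
    stop("'srh' and 'income' lengths differ", call. = FALSE)
  }
  lev <- sort(unique(srh))
  K <- length(lev)
  if (K < 2L) {
    stop("degenerate outcome: self-rated health has a single observed level",
         call. = FALSE)
  }
  y <- match(srh, lev)
  X <- cbind(log1p_income = signed_log1p(income))
  xlevels <- NULL
  ctrl_terms <- NULL
  if (!is.null(controls)) {
    controls <- as.data.frame(controls)
    if (anyNA(controls)) stop("missing values in 'controls'", call. = FALSE)
    ctrl_terms <- stats::terms(~., data = controls)
    mf <- stats::model.frame(ctrl_terms, controls)
    xlevels <- stats::.getXlevels(ctrl_terms, mf)
    Xc <- stats::model.matrix(ctrl_terms, mf)
    X <- cbind(X, Xc[, colnames(Xc) != "(Intercept)", drop = FALSE])
  }
  storage.mode(X) <- "double"
  # constant columns (e.g. a control that does not vary in a subgroup, or
  # an unobserved factor level's dummy) are unidentified: drop them
  varying <- apply(X, 2L, function(cl) diff(range(cl)) > 0)
  if (!varying[1L]) {
    stop("stage income is constant; the probit index is unidentified",
         call. = FALSE)
  }
  dropped <- colnames(X)[!varying]
  X <- X[, varying, drop = FALSE]
  n <- nrow(X)

  # start values: cutpoints from marginal category frequencies, beta = 0
  cum <- cumsum(tabulate(y, K) / n)[seq_len(K - 1L)]
  tau0 <- stats::qnorm(pmin(pmax(cum, 1e-6), 1 - 1e-6))
  theta0 <- c(rep(0, ncol(X)),
              if (K == 2L) tau0 else
                c(tau0[1L], log(pmax(diff(tau0), 1e-4))))

  # BFGS to near the optimum, then Newton polish (numeric Hessian of the
  # analytic gradient) until the mean-gradient tolerance is met
  opt <- stats::optim(theta0, .oprobit_nll, .oprobit_grad,
                      y = y, X = X, K = K, method = "BFGS",
                      control = list(maxit = maxit, reltol = 1e-13))
  par <- opt$par
  g <- .oprobit_grad(par, y, X, K)
  newton_it <- 0L
  while (opt$convergence == 0L && max(abs(g)) / n >= gtol &&
         newton_it < 10L) {
    Ht <- try(stats::optimHess(par, .oprobit_nll, .oprobit_grad,
                               y = y, X = X, K = K), silent = TRUE)
    if (inherits(Ht, "try-error")) break
    step <- try(solve(Ht, g), silent = TRUE)
    if (inherits(step, "try-error")) break
    f0 <- .oprobit_nll(par, y, X, K)
    lambda <- 1
    repeat {
      cand <- par - lambda * step
      if (.oprobit_nll(cand, y, X, K) <= f0 + 1e-12 * abs(f0)) break
      lambda <- lambda / 2
      if (lambda < 1e-4) break
    }
    par <- par - lambda * step
    g <- .oprobit_grad(par, y, X, K)
    newton_it <- newton_it + 1L
  }
  opt$par <- par
  opt$value <- .oprobit_nll(par, y, X, K)
  converged <- opt$convergence == 0L && max(abs(g)) / n < gtol
  if (!converged) {
    warning(sprintf(
      "ordered probit did not converge (optim code %d, mean |gradient| %.2e, %d iterations); converged = FALSE",
      opt$convergence, max(abs(g)) / n, opt$counts[["function"]]),
      call. = FALSE)
  }

  p <- ncol(X)
  beta <- opt$par[seq_len(p)]
  tau <- if (K == 2L) opt$par[p + 1L] else
    cumsum(c(opt$par[p + 1L], exp(opt$par[(p + 2L):(p + K - 1L)])))

  # observed-information vcov in the natural (beta, tau) parameterization
  nll_nat <- function(th) {
    th2 <- th
    if (K > 2L) {
      th2[(p + 2L):(p + K - 1L)] <- log(pmax(diff(th[(p + 1L):(p + K - 1L)]),
                                             1e-12))
    }
    .oprobit_nll(th2, y, X, K)
  }
  H <- try(stats::optimHess(c(beta, tau), nll_nat), silent = TRUE)
  vc <- NULL
  se <- rep(NA_real_, p)
  if (!inherits(H, "try-error")) {
    vc <- try(solve(H), silent = TRUE)
    if (!inherits(vc, "try-error") && all(diag(vc)[seq_len(p)] > 0)) {
      se <- sqrt(diag(vc)[seq_len(p)])
    } else vc <- NULL
  }
  names(beta) <- colnames(X)
  names(se) <- colnames(X)

  structure(list(coefficients = beta,
                 cutpoints = tau,
                 se = se,
                 vcov = vc,
                 logLik = -opt$value,
                 converged = converged,
                 n_obs = n,
                 levels = lev,
                 optim_diagnostics = list(code = opt$convergence,
                                          counts = opt$counts,
                                          max_abs_gradient = max(abs(g))),
                 ctrl_terms = ctrl_terms,
                 xlevels = xlevels,
                 design_columns = colnames(X),
                 dropped_columns = dropped),
            class = "oprobit")
}

#' @export
print.oprobit <- function(x, ...) {
  cat(sprintf("Ordered probit (%d obs, %d outcome levels)%s\n", x$n_obs,
              length(x$levels),
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat("Coefficients:\n")
  print(round(rbind(estimate = x$coefficients, se = x$se), 4))
  cat("Cutpoints:", paste(round(x$cutpoints, 4), collapse = ", "), "\n")
  cat(sprintf("log-likelihood: %.2f\n", x$logLik))
  invisible(x)
}

#' @export
summary.oprobit <- function(object, ...) {
  z <- object$coefficients / object$se
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `z value` = z,
               `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  structure(list(coefficients = tab, cutpoints = object$cutpoints,
                 logLik = object$logLik, n_obs = object$n_obs,
                 converged = object$converged),
            class = "summary.oprobit")
}

#' @export
print.summary.oprobit <- function(x, ...) {
  cat("Ordered probit fit\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat("Cutpoints:", paste(round(x$cutpoints, 4), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.oprobit <- function(object, ...) object$coefficients

#' @export
vcov.oprobit <- function(object, ...) object$vcov

#' @export
logLik.oprobit <- function(object, ...) {
  structure(object$logLik, df = length(object$coefficients) +
              length(object$cutpoints), nobs = object$n_obs,
            class = "logLik")
}

# rebuild the design matrix for new data, erroring on unseen factor levels
.oprobit_design <- function(object, income, controls) {
  X <- cbind(log1p_income = signed_log1p(income))
  if (!is.null(object$ctrl_terms)) {
    if (is.null(controls)) {
      stop("model was fitted with controls; 'controls' must be supplied",
           call. = FALSE)
    }
    controls <- as.data.frame(controls)
    for (v in names(object$xlevels)) {
      seen <- object$xlevels[[v]]
      new <- setdiff(unique(as.character(controls[[v]])), seen)
      if (length(new)) {
        stop(sprintf("unseen level(s) in '%s': %s", v,
                     paste(new, collapse = ", ")), call. = FALSE)
      }
      controls[[v]] <- factor(as.character(controls[[v]]), levels = seen)
    }
    mf <- stats::model.frame(object$ctrl_terms, controls,
                             xlev = object$xlevels)
    Xc <- stats::model.matrix(object$ctrl_terms, mf)
    X <- cbind(X, Xc[, colnames(Xc) != "(Intercept)", drop = FALSE])
  }
  X[, object$design_columns, drop = FALSE]
}

#' Predict the latent health index from an ordered-probit fit
#'
#' Returns the linear index `X b` per participant (cutpoints excluded), an
#' unbounded continuous health score suitable for min-max rescaling.
#'
#' @param object an [fit_ordered_probit()] fit with `converged = TRUE`.
#' @param income stage-income vector.
#' @param controls control covariates matching the fit (unseen factor
#'   levels raise an error).
#' @param type `"latent"` (default) for the linear index; `"probs"` for the
#'   matrix of category probabilities.
#' @param ... unused.
#' @return numeric vector (latent) or matrix (probs).
#' @export
predict.oprobit <- function(object, income, controls = NULL,
                            type = c("latent", "probs"), ...) {
  type <- match.arg(type)
  if (!isTRUE(object$converged)) {
    stop("refusing to predict from a non-converged ordered-probit fit",
         call. = FALSE)
  }
  X <- .oprobit_design(object, income, controls)
  eta <- unname(drop(X %*% object$coefficients))
  if (type == "latent") return(eta)
  K <- length(object$levels)
  cuts <- c(-Inf, object$cutpoints, Inf)
  pr <- vapply(seq_len(K), function(k) {
    stats::pnorm(cuts[k + 1L] - eta) - stats::pnorm(cuts[k] - eta)
  }, numeric(length(eta)))
  pr <- matrix(pr, ncol = K,
               dimnames = list(NULL, paste0("level_", object$levels)))
  pr
}
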