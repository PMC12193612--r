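# internal helpers shared across modules

# signed log transform: equals log1p(x) for x >= 0, odd in x, defined on all
# of R so that post-treatment stage incomes (which may be negative) can enter
# the probit index
signed_log1p <- function(x) sign(x) * log1p(abs(x))

# round-half-up for display percentages (base round() is half-to-even)
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate `code` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stopifnot_scalar_num <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    stop(sprintf("'%s' must be a finite numeric scalar in [%s, %s]", name, lo, hi),
         call. = FALSE)
  }
  invisible(x)
}
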