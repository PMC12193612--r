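# Independent brute-force oracles used to freeze expected values. These
# deliberately avoid the package's own computational paths.

# summation form of the concentration index (valid for untied ranks)
ci_summation_oracle <- function(health, ranks) {
  n <- length(health)
  2 / (n * mean(health)) * sum(health * ranks) - 1
}

# Erreygers index straight from its defining sum
ei_oracle <- function(health, ranks, h_min = 0, h_max = 1) {
  mean(4 * (health - h_min) / (h_max - h_min) * (2 * ranks - 1))
}

# O(n^2) pairwise relative deprivation: rd_i = sum_j max(x_j - x_i, 0) /
# (n * mean(x))
rd_pairwise_oracle <- function(x) {
  n <- length(x)
  u <- mean(x)
  vapply(x, function(xi) sum(pmax(x - xi, 0)) / (n * u), numeric(1))
}

# Gini coefficient by full pairwise enumeration
gini_oracle <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

# small default synthetic cohort for unit tests
test_cohort <- function(n = 3000, seed = 42, ...) {
  generate_cohort(cohort_config(n_individuals = n, seed = seed, ...))
}

# a tiny hand-built cohort that passes validation
manual_cohort <- function(n = 12) {
  set.seed(99)
  data.frame(
    srh = rep(1:5, length.out = n),
    income_initial = seq(1000, 1000 * n, length.out = n),
    premium = rep(100, n),
    oop_spend = rep(50, n),
    reimbursement = rep(25, n),
    outpatient_visits = rep(2L, n),
    inpatient_episodes = rep(0L, n),
    gender = rep(c(0L, 1L), length.out = n),
    age = rep(c(30L, 50L, 70L), length.out = n),
    education_years = rep(c(6L, 9L, 12L), length.out = n),
    education_group = rep(c("below_middle_school", "middle_school",
                            "high_school"), length.out = n),
    marital = rep(1L, n),
    urban = rep(c(0L, 1L), length.out = n),
    region = rep(c("east", "central", "west"), length.out = n),
    stringsAsFactors = FALSE
  )
}
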