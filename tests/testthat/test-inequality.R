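test_that("fractional ranks follow (i - 0.5)/n with tie-averaging", {
  expect_equal(fractional_rank(c(10, 20, 30)), c(1, 3, 5) / 6)
  expect_equal(fractional_rank(c(5, 5)), c(0.5, 0.5))
  expect_equal(fractional_rank(rep(7, 9)), rep(0.5, 9))
  # permutation equivariance: same value always gets the same rank
  v <- c(3, 9, 1, 7, 5)
  base <- setNames(fractional_rank(v), v)
  perms <- matrix(c(1:5, 5:1, c(2, 4, 1, 5, 3), c(3, 1, 5, 2, 4)),
                  ncol = 5, byrow = TRUE)
  for (k in seq_len(nrow(perms))) {
    p <- perms[k, ]
    expect_equal(setNames(fractional_rank(v[p]), v[p])[as.character(v)],
                 base)
  }
  # mean rank is exactly 0.5 even under heavy ties
  set.seed(1)
  for (i in 1:20) {
    x <- sample(1:4, 30, replace = TRUE)
    expect_equal(mean(fractional_rank(x)), 0.5, tolerance = 1e-14)
  }
})

test_that("CI covariance form equals the summation form on untied ranks", {
  set.seed(2)
  for (i in 1:50) {
    n <- sample(3:8, 1)
    h <- runif(n, 0.1, 1)
    inc <- sample(seq_len(100), n)        # untied
    r <- fractional_rank(inc)
    expect_equal(concentration_index(h, r)$index_value,
                 ci_summation_oracle(h, r), tolerance = 1e-12)
  }
})

test_that("CI limits: zero for constant health, antisymmetric, scale invariant, bounded", {
  r <- fractional_rank(1:100)
  expect_equal(concentration_index(rep(0.4, 100), r)$index_value, 0)
  set.seed(3)
  for (i in 1:25) {
    h <- runif(60)
    inc <- rnorm(60)
    r1 <- fractional_rank(inc)
    r2 <- fractional_rank(-inc)
    ci <- concentration_index(h, r1)$index_value
    expect_equal(concentration_index(h, r2)$index_value, -ci,
                 tolerance = 1e-12)
    expect_equal(concentration_index(3.7 * h, r1)$index_value, ci,
                 tolerance = 1e-12)
    expect_lt(abs(ci), 1)
    ei <- erreygers_index(h, r1)$index_value
    expect_lt(abs(ei), 1)
    expect_equal(erreygers_index(h, r2)$index_value, -ei, tolerance = 1e-12)
  }
  # perfectly pro-rich health has positive CI; reversal flips exactly
  h_incr <- (1:100) / 100
  expect_gt(concentration_index(h_incr, r)$index_value, 0)
  expect_error(concentration_index(rep(0, 10), fractional_rank(1:10)),
               "mean health")
})

test_that("Erreygers index matches its oracle, the 4*mean*CI identity, and the rank limit", {
  set.seed(4)
  for (i in 1:40) {
    n <- sample(5:50, 1)
    h <- runif(n)
    r <- fractional_rank(sample(seq_len(1000), n))
    ei <- erreygers_index(h, r)$index_value
    expect_equal(ei, ei_oracle(h, r), tolerance = 1e-12)
    ci <- concentration_index(h, r)$index_value
    expect_equal(ei, 4 * mean(h) * ci, tolerance = 1e-12)
  }
  expect_equal(erreygers_index(rep(0.3, 50),
                               fractional_rank(1:50))$index_value, 0)
  # health equal to the income rank itself: CI -> 1/3, EI -> 2/3
  r <- fractional_rank(seq_len(1000))
  expect_equal(concentration_index(r, r)$index_value,
               ci_summation_oracle(r, r), tolerance = 1e-12)
  expect_equal(concentration_index(r, r)$index_value, 1 / 3,
               tolerance = 1e-3)
  expect_equal(erreygers_index(r, r)$index_value, ei_oracle(r, r),
               tolerance = 1e-12)
  expect_equal(erreygers_index(r, r)$index_value, 2 / 3, tolerance = 1e-3)
  expect_error(erreygers_index(c(0.5, 1.2), fractional_rank(1:2)),
               "outside")
})

test_that("stage incomes follow the contribution/treatment/reimbursement arithmetic", {
  co <- manual_cohort(4)
  co$income_initial <- c(100, 200, 300, 400)
  co$premium <- rep(10, 4)
  co$oop_spend <- rep(30, 4)
  co$reimbursement <- rep(20, 4)
  st <- build_stage_incomes(co)
  expect_equal(st$initial[1], 100)
  expect_equal(st$contribution[1], 90)
  expect_equal(st$treatment[1], 60)
  expect_equal(st$reimbursement[1], 80)

  zero <- co
  zero$premium <- zero$oop_spend <- zero$reimbursement <- rep(0, 4)
  stz <- build_stage_incomes(zero)
  expect_equal(stz$contribution, stz$initial)
  expect_equal(stz$reimbursement, stz$initial)

  bad <- co
  bad$reimbursement <- bad$oop_spend + 1
  expect_error(build_stage_incomes(bad), "exceeds")

  # elementwise monotonicity on a generated cohort
  gen <- test_cohort(n = 2000, seed = 19)
  stg <- build_stage_incomes(gen)
  expect_true(all(stg$contribution <= stg$initial))
  expect_true(all(stg$treatment <= stg$contribution))
  expect_true(all(stg$reimbursement >= stg$treatment))
})

test_that("quintile assignment balances groups and handles ties", {
  q <- quintile_assign(1:10)
  expect_equal(as.vector(table(q)), rep(2L, 5))
  expect_warning(q2 <- quintile_assign(rep(3, 20)), "tied")
  expect_true(all(q2 == "low"))
  set.seed(5)
  for (i in 1:20) {
    x <- sample(1:15, 100, replace = TRUE)
    qq <- quintile_assign(x)
    # group sizes deviate from n/5 by at most the tie mass at a boundary
    max_tie <- max(table(x))
    expect_lte(max(abs(table(qq) - 20)), max_tie)
  }
})

test_that("stage pipeline: no monetary flows leave all four indices identical", {
  co <- as.data.frame(test_cohort(n = 1500, seed = 23))
  co$premium <- co$oop_spend <- co$reimbursement <- rep(0, nrow(co))
  hi <- health_inequality(co, mode = "fixed")
  expect_equal(hi$indices$ci, rep(hi$indices$ci[1], 4), tolerance = 1e-12)
  expect_equal(unlist(hi$deltas), rep(0, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("deltas telescope and a pro-poor transfer narrows inequality", {
  hi <- health_inequality(test_cohort(n = 2500, seed = 29))
  d <- hi$deltas
  expect_equal(d$delta_total,
               d$delta_contribution + d$delta_treatment +
                 d$delta_reimbursement, tolerance = 1e-12)

  # rank-preserving levy on everyone, fully rebated to the poorest decile:
  # with health fixed, the post-reimbursement ranking favours the poor and
  # measured inequality must fall (delta_total > 0)
  co <- as.data.frame(test_cohort(n = 2500, seed = 37))
  levy <- median(co$income_initial) * 0.5
  co$premium <- rep(0, nrow(co))
  co$oop_spend <- rep(levy, nrow(co))
  poorest <- co$income_initial <= quantile(co$income_initial, 0.1)
  co$reimbursement <- ifelse(poorest, levy, 0)
  hi2 <- health_inequality(co, mode = "fixed")
  expect_gt(hi2$deltas$delta_total, 0)
})

test_that("subgroup CIs recompute ranks within groups", {
  co <- test_cohort(n = 3000, seed = 41)
  sah <- cardinalize(co)$health$sah
  # within-quintile ranks have mean 0.5 in every quintile
  q <- quintile_assign(co$income_initial)
  for (lv in levels(q)) {
    expect_equal(mean(fractional_rank(co$income_initial[q == lv])), 0.5,
                 tolerance = 1e-14)
  }
  tab <- subgroup_ci(co, "income_quintile", stage = "initial", sah = sah)
  expect_identical(tab$group, levels(q))
  expect_equal(sum(tab$n), nrow(co))

  # a label independent of income and health: subgroup CIs straddle the
  # total CI within a Monte-Carlo band
  set.seed(101)
  co$education_group <- sample(levels(co$education_group), nrow(co),
                               replace = TRUE)
  total_ci <- concentration_index(sah,
                                  fractional_rank(co$income_initial))$index_value
  tab2 <- subgroup_ci(co, "education_group", stage = "initial", sah = sah)
  band <- 4 * 2 * sd(sah) * sqrt(1 / 12) / (mean(sah) * sqrt(min(tab2$n)))
  expect_true(all(abs(tab2$ci - total_ci) < band))
})

test_that("a stronger female income-health gradient yields larger female CIs", {
  hits <- 0L
  for (s in 1:30) {
    co <- generate_cohort(cohort_config(
      n_individuals = 4000, seed = 1000 + s,
      health_income_slope_gender_gap = 0.3))
    tab <- subgroup_ci(co, "gender", stage = "initial")
    if (tab$ci[tab$group == "female"] > tab$ci[tab$group == "male"]) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, 28L)
})

test_that("bootstrap SE is calibrated, seeded, and flags tiny B", {
  set.seed(6)
  df <- data.frame(x = rnorm(1000, mean = 2, sd = 3))
  bs <- bootstrap_se(function(d) mean(d$x), df, B = 500, seed = 77)
  expect_lt(abs(bs$se - 3 / sqrt(1000)) / (3 / sqrt(1000)), 0.2)
  expect_lt(bs$p_value, 0.02)
  bs2 <- bootstrap_se(function(d) mean(d$x), df, B = 500, seed = 77)
  expect_identical(bs$se, bs2$se)
  tiny <- bootstrap_se(function(d) mean(d$x), df, B = 2, seed = 1)
  expect_true(tiny$low_precision)
  expect_error(bootstrap_se(function(d) mean(d$x), df, B = 1), "at least 2")
})
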