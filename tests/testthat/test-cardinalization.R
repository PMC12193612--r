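test_that("ordered probit recovers generator coefficients and matches an independent fit", {
  co <- generate_cohort(cohort_config(n_individuals = 20000, seed = 3))
  ctrl <- data.frame(gender = co$gender, age = co$age,
                     education_years = co$education_years,
                     marital = co$marital, region = co$region)
  fit <- fit_ordered_probit(co$srh, co$income_initial, ctrl)
  expect_true(fit$converged)

  truth <- attr(co, "ground_truth")$config
  est <- fit$coefficients
  se <- fit$se
  expect_lt(abs(est["log1p_income"] - truth$health_income_slope),
            3 * se["log1p_income"])
  expect_lt(abs(est["age"] - truth$covariate_effects$age), 3 * se["age"])
  expect_lt(abs(est["gender"] - truth$covariate_effects$gender),
            3 * se["gender"])

  skip_if_not_installed("MASS")
  sub <- co[1:4000, ]
  f2 <- fit_ordered_probit(sub$srh, sub$income_initial,
                           data.frame(gender = sub$gender, age = sub$age))
  df <- data.frame(srh = factor(sub$srh, ordered = TRUE),
                   log1p_income = log1p(sub$income_initial),
                   gender = sub$gender, age = sub$age)
  polr_fit <- MASS::polr(srh ~ log1p_income + gender + age, data = df,
                         method = "probit")
  expect_equal(unname(f2$coefficients), unname(coef(polr_fit)),
               tolerance = 1e-3)
  expect_equal(unname(f2$cutpoints), unname(polr_fit$zeta), tolerance = 1e-3)
})

test_that("controls orthogonal to health get near-zero coefficients", {
  co <- generate_cohort(cohort_config(n_individuals = 10000, seed = 17))
  set.seed(123)
  ctrl <- data.frame(noise1 = rnorm(nrow(co)), noise2 = rnorm(nrow(co)))
  fit <- fit_ordered_probit(co$srh, co$income_initial, ctrl)
  expect_lt(abs(fit$coefficients["noise1"]), 3 * fit$se["noise1"])
  expect_lt(abs(fit$coefficients["noise2"]), 3 * fit$se["noise2"])
})

test_that("two-level outcome reduces to a binary probit", {
  co <- test_cohort(n = 4000, seed = 21)
  y2 <- as.integer(co$srh >= 4) + 1L
  fit <- fit_ordered_probit(y2, co$income_initial,
                            data.frame(age = co$age))
  glm_fit <- glm(I(y2 == 2L) ~ log1p(co$income_initial) + co$age,
                 family = binomial("probit"))
  expect_equal(unname(fit$coefficients),
               unname(coef(glm_fit)[-1]), tolerance = 1e-4)
  # same latent ordering as the plain probit's linear predictor
  lat <- predict(fit, co$income_initial, data.frame(age = co$age))
  expect_equal(order(lat), order(predict(glm_fit)))
})

test_that("degenerate outcomes and unseen levels error explicitly", {
  expect_error(fit_ordered_probit(rep(3L, 100), runif(100)),
               "single observed level")
  co <- test_cohort(n = 1000, seed = 4)
  fit <- fit_ordered_probit(co$srh, co$income_initial,
                            data.frame(region = co$region))
  newctrl <- data.frame(region = rep("north", 3))
  expect_error(predict(fit, c(1, 2, 3) * 1000, newctrl), "unseen level")
})

test_that("latent prediction is the linear index: linearity and ground-truth correlation", {
  co <- test_cohort(n = 2000, seed = 6)
  ctrl <- data.frame(age = co$age)
  fit <- fit_ordered_probit(co$srh, co$income_initial, ctrl)
  lat <- predict(fit, co$income_initial, ctrl)
  ctrl2 <- ctrl
  ctrl2$age <- ctrl$age + 10
  lat2 <- predict(fit, co$income_initial, ctrl2)
  expect_equal(lat2 - lat, rep(10 * fit$coefficients[["age"]], nrow(co)),
               tolerance = 1e-10)

  big <- generate_cohort(cohort_config(n_individuals = 20000, seed = 9))
  card <- cardinalize(big)
  truth <- attr(big, "ground_truth")$latent_systematic
  expect_gt(cor(card$health$latent, truth), 0.5)
})

test_that("monotone link: higher latent raises upper-category probabilities", {
  co <- test_cohort(n = 2000, seed = 13)
  ctrl <- data.frame(age = co$age)
  fit <- fit_ordered_probit(co$srh, co$income_initial, ctrl)
  inc <- c(500, 5000, 50000, 500000)
  pr <- predict(fit, inc, data.frame(age = rep(50, 4)), type = "probs")
  expect_true(all(abs(rowSums(pr) - 1) < 1e-12))
  cum_upper <- t(apply(pr[, 5:1], 1, cumsum))  # P(srh >= k), k = 5..1
  expect_true(all(diff(cum_upper[, 1]) > 0))   # P(srh = 5) rises in latent
})

test_that("unit rescaling contracts hold and are affine invariant", {
  x <- c(-1, 0, 1)
  expect_equal(rescale_unit(x)$sah, c(0, 0.5, 1))
  set.seed(7)
  for (i in 1:20) {
    v <- rnorm(sample(5:50, 1))
    s <- rescale_unit(v)
    expect_equal(min(s$sah), 0)
    expect_equal(max(s$sah), 1)
    expect_identical(order(s$sah), order(v))          # rank preservation
    a <- runif(1, 0.1, 5); b <- rnorm(1)
    expect_equal(rescale_unit(a * v + b)$sah, s$sah, tolerance = 1e-10)
  }
  expect_error(rescale_unit(rep(2, 10)), "degenerate")
})

test_that("mean cardinalized score rises strictly with true SRH level", {
  co <- generate_cohort(cohort_config(n_individuals = 20000, seed = 31))
  sah <- cardinalize(co)$health$sah
  m <- tapply(sah, co$srh, mean)
  expect_true(all(diff(m) > 0))
})
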