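test_that("Kaplan-Meier estimates follow closed forms on simple inputs", {
  # no events: survival stays at 1
  df <- data.frame(time = c(5, 8, 12), event = 0, grade_2tier = "low")
  km <- km_estimate(df)$low
  expect_true(all(km$surv == 1))

  # single event at t0 among n = 4, no censoring: S(t0) = 1 - 1/4
  df2 <- data.frame(time = c(3, 10, 10, 10), event = c(1, 0, 0, 0),
                    grade_2tier = "high")
  km2 <- km_estimate(df2)$high
  expect_equal(km2$surv[km2$time == 3], 0.75)

  # estimator is non-increasing and starts at S <= 1
  co <- generate_cohort(n_cases = 300, censor_rate = 0.3, n_features = 2,
                        seed = 14)
  km3 <- km_estimate(co, group_by = "grade_true")
  for (g in km3) {
    expect_true(all(diff(g$surv) <= 1e-12))
    expect_lte(max(g$surv), 1)
  }
  expect_error(km_estimate(data.frame(time = -1, event = 1,
                                      grade_2tier = "low")), ">= 0")
})

test_that("the KM estimator converges to the exponential closed form", {
  co <- generate_cohort(n_cases = 2000, hazard_ratio = 1, censor_rate = 0.3,
                        n_features = 2, baseline_median_months = 60,
                        seed = 17)
  lam <- log(2) / 60
  km <- km_estimate(co, group_by = "grade_true")
  for (g in km) {
    horizon <- quantile(co$time, 0.9)
    keep <- g$time <= horizon
    expect_lt(max(abs(g$surv[keep] - exp(-lam * g$time[keep]))), 0.05)
  }
})

test_that("Cox fits recover known hazard structure", {
  # identical survival in both groups -> HR ~ 1
  base <- data.frame(time = rep(c(2, 5, 9, 14, 20), 2),
                     event = rep(c(1, 1, 0, 1, 0), 2),
                     grade_2tier = rep(c("low", "high"), each = 5))
  hr <- cox_fit(base, covariates = "grade")$hr
  expect_equal(hr, 1, tolerance = 1e-6)

  # true HR 2 recovered at n = 2000 with 30% censoring
  co <- generate_cohort(n_cases = 2000, hazard_ratio = 2, censor_rate = 0.3,
                        n_features = 2, seed = 1)
  fit <- cox_fit(co, covariates = "grade", grade_col = "grade_true")
  expect_gt(fit$hr, 1.8); expect_lt(fit$hr, 2.2)
  expect_true(fit$ci_lower < 2 && fit$ci_upper > 2)

  # duplicated cohort: identical Breslow estimating equation root,
  # narrower CI (duplication creates ties, so Breslow is the exact case)
  dup <- rbind(co, co)
  fitb <- cox_fit(co, covariates = "grade", grade_col = "grade_true",
                  ties = "breslow")
  fit2 <- cox_fit(dup, covariates = "grade", grade_col = "grade_true",
                  ties = "breslow")
  expect_equal(fit2$hr, fitb$hr, tolerance = 1e-6)
  expect_lt(fit2$ci_upper - fit2$ci_lower, fitb$ci_upper - fitb$ci_lower)

  expect_error(cox_fit(data.frame(time = 1:3, event = c(1, 0, 0),
                                  grade_2tier = c("low", "high", "low")),
                       covariates = "grade"), "2 events")
  expect_error(cox_fit(data.frame(time = 1:4, event = 1,
                                  grade_2tier = "low"),
                       covariates = "grade"), "constant")
})

test_that("Cox CIs cover the true hazard ratio at the nominal rate", {
  covered <- 0L
  for (rep in 1:200) {
    co <- generate_cohort(n_cases = 300, hazard_ratio = 2, censor_rate = 0.3,
                          n_features = 2, seed = 1000L + rep)
    fit <- cox_fit(co, covariates = "grade", grade_col = "grade_true")
    if (fit$ci_lower < 2 && fit$ci_upper > 2) covered <- covered + 1L
  }
  expect_gte(covered / 200, 0.9)
})

test_that("crude and adjusted fits agree when covariates are grade-independent", {
  co <- generate_cohort(n_cases = 2000, hazard_ratio = 2, censor_rate = 0.3,
                        n_features = 2, seed = 23)
  co$grade_2tier <- co$grade_true
  rep_tab <- grade_prognosis_report(co, "grade_2tier")
  expect_equal(nrow(rep_tab), 3)
  expect_equal(rep_tab$model, c("A", "B", "C"))
  hrs <- rep_tab$hr
  expect_lt(max(abs(log(hrs) - log(hrs[1]))), 0.15)

  # identical sources -> identical rows
  co$grade_copy <- co$grade_2tier
  both <- grade_prognosis_report(co, c("grade_2tier", "grade_copy"))
  expect_equal(both$hr[1:3], both$hr[4:6])
  expect_equal(nrow(both), 6)
})

test_that("misclassified manual grades attenuate the hazard ratio", {
  log_true <- numeric(25); log_noisy <- numeric(25)
  for (r in 1:25) {
    co <- generate_cohort(n_cases = 400, hazard_ratio = 2, censor_rate = 0.3,
                          n_features = 2, seed = 3000L + r)
    co$grade_model <- co$grade_true
    flip <- withr::with_seed(4000L + r,
                             runif(nrow(co)) < 0.3)
    co$grade_manual <- ifelse(flip,
                              ifelse(co$grade_true == "high", "low", "high"),
                              co$grade_true)
    log_true[r] <- log(cox_fit(co, "grade", grade_col = "grade_model")$hr)
    log_noisy[r] <- log(cox_fit(co, "grade", grade_col = "grade_manual")$hr)
  }
  expect_gt(mean(log_true), mean(log_noisy))
})
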