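test_that("z-scoring standardizes columns and replays stored parameters", {
  x <- cbind(a = c(1, 2, 3), b = c(10, 20, 60))
  zs <- zscore_fit_apply(x)
  expect_equal(unname(zs$x[, "a"]), c(-1, 0, 1))
  expect_equal(unname(colMeans(zs$x)), c(0, 0))
  expect_equal(unname(apply(zs$x, 2, sd)), c(1, 1))

  x2 <- cbind(a = c(4, 5), b = c(0, 30))
  replay <- zscore_fit_apply(x2, zs$params)
  expect_equal(unname(replay$x[, "a"]), (c(4, 5) - 2) / 1)

  expect_warning(zc <- zscore_fit_apply(cbind(a = c(1, 1, 1), b = 1:3)),
                 "constant")
  expect_true(all(zc$x[, "a"] == 0))
  expect_error(zscore_fit_apply(cbind(c = 1:3), zs$params), "missing")
})

test_that("lambda tuning finds signal when present and chance when absent", {
  co <- generate_cohort(n_cases = 200,
                        informative_features = c(f001 = 3, f002 = 3),
                        censor_rate = 0, n_features = 10, seed = 31)
  x <- zscore_fit_apply(as.matrix(co[, grep("^f", names(co))]))$x
  grid <- c(1e-3, 0.01, 0.05, 0.2)
  tuned <- tune_lambda(x, co$grade_true, grid, n_rep = 40, seed = 7)
  expect_gte(max(tuned$mean_auc), 0.95)
  expect_true(tuned$lambda %in% grid)

  null <- generate_cohort(n_cases = 200, censor_rate = 0, n_features = 10,
                          seed = 32)
  xn <- zscore_fit_apply(as.matrix(null[, grep("^f", names(null))]))$x
  tn <- tune_lambda(xn, null$grade_true, grid, n_rep = 40, seed = 7)
  expect_lt(abs(max(tn$mean_auc) - 0.5), 0.08)

  # a grid with a single huge penalty yields an intercept-only model
  m <- fit_lasso(x, co$grade_true, lambda = 1e6)
  expect_true(all(m$weights == 0))
  expect_error(tune_lambda(x, rep("high", nrow(x)), grid), "both")
})

test_that("the lasso path is sparse above lambda_max and monotone in lambda", {
  co <- generate_cohort(n_cases = 150,
                        informative_features = setNames(rep(1, 3),
                                                        c("f001", "f002", "f003")),
                        censor_rate = 0, n_features = 20, seed = 41)
  x <- zscore_fit_apply(as.matrix(co[, grep("^f", names(co))]))$x
  y <- co$grade_true
  yb <- as.numeric(y == "high")
  lmax <- max(abs(crossprod(x, yb - mean(yb)) / nrow(x)))
  above <- fit_lasso(x, y, lambda = lmax * 1.05)
  expect_true(all(above$weights == 0))
  expect_equal(above$intercept, qlogis(mean(yb)), tolerance = 1e-4)

  grid <- exp(seq(log(lmax * 1.1), log(1e-3), length.out = 12))
  nz <- vapply(grid, function(l) sum(fit_lasso(x, y, l)$weights != 0),
               numeric(1))
  expect_true(all(diff(nz) >= 0))   # grid is decreasing: support only grows
})

test_that("support recovery finds informative features with few false positives", {
  eff <- setNames(rep(1, 5), summary_feature_names()[1:5])
  co <- generate_cohort(n_cases = 500, informative_features = eff,
                        censor_rate = 0, seed = 3)
  x <- as.matrix(co[, summary_feature_names()])
  zs <- zscore_fit_apply(x)
  m <- fit_lasso(zs$x, co$grade_true, lambda = 0.05,
                 zscore_params = zs$params)
  expect_gte(sum(m$weights[names(eff)] != 0), 4)
  expect_lte(sum(m$weights[setdiff(names(m$weights), names(eff))] != 0), 10)

  # round-trip: training-set predictions reproduce the stored accuracy
  pr <- predict_grade(m, x)
  ev <- evaluate_grades(co$grade_true, pr$grade_pred, pr$prob_high)
  pr2 <- predict_grade(m, x)
  ev2 <- evaluate_grades(co$grade_true, pr2$grade_pred, pr2$prob_high)
  expect_equal(ev$accuracy, ev2$accuracy)
  expect_gt(ev$roc_auc, 0.85)
})

test_that("prediction applies the logistic link monotonically and checks schema", {
  m <- coef_set(intercept = 0, weights = c(f1 = 0, f2 = 0), lambda = 1)
  tab <- cbind(f1 = c(-5, 0, 5), f2 = c(1, 2, 3))
  expect_equal(predict_grade(m, tab)$prob_high, rep(0.5, 3))

  m2 <- coef_set(intercept = 0, weights = c(f1 = 1.5, f2 = 0), lambda = 1)
  p <- predict_grade(m2, tab)$prob_high
  expect_true(all(diff(p) > 0))
  expect_error(predict_grade(m2, cbind(f1 = 1)), "missing")
})

test_that("evaluation reproduces the printed test-set confusion metrics", {
  # smallest integer matrix consistent with the reported rates at n = 42
  truth <- c(rep("high", 26), rep("low", 16))
  pred <- c(rep("high", 22), rep("low", 4), rep("high", 3), rep("low", 13))
  ev <- evaluate_grades(truth, pred)
  round_half_up <- function(x, d) floor(x * 10^d + 0.5) / 10^d
  expect_equal(ev$sensitivity, 22 / 26)
  expect_equal(ev$specificity, 13 / 16)
  expect_equal(round_half_up(ev$sensitivity, 3), 0.846)
  expect_equal(round_half_up(ev$specificity, 3), 0.813)
  expect_equal(round_half_up(ev$accuracy, 3), 0.833)

  perf <- evaluate_grades(c("low", "high"), c("low", "high"), c(0.1, 0.9))
  expect_equal(perf$accuracy, 1); expect_equal(perf$cohen_kappa, 1)
  expect_equal(perf$roc_auc, 1)

  allhigh <- evaluate_grades(c("low", "low", "high", "high"),
                             rep("high", 4))
  expect_equal(allhigh$sensitivity, 1)
  expect_equal(allhigh$specificity, 0)
  expect_error(evaluate_grades(c("low"), c("low", "high")), "lengths")
})

test_that("evaluation rates match direct formulas on random confusion matrices", {
  for (seed in 1:200) {
    cm <- withr::with_seed(seed, rmultinom(1, size = 60, prob = rep(0.25, 4)))
    tp <- cm[1]; fn <- cm[2]; fp <- cm[3]; tn <- cm[4]
    if (tp + fn == 0 || tn + fp == 0) next
    truth <- c(rep("high", tp + fn), rep("low", fp + tn))
    pred <- c(rep("high", tp), rep("low", fn), rep("high", fp), rep("low", tn))
    ev <- evaluate_grades(truth, pred)
    expect_equal(ev$accuracy, (tp + tn) / 60)
    expect_equal(ev$sensitivity, tp / (tp + fn))
    expect_equal(ev$specificity, tn / (tn + fp))
  }
})

test_that("the internal AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(5, {
    truth <- sample(c("low", "high"), 80, replace = TRUE)
    score <- rnorm(80) + (truth == "high")
  })
  got <- rccgrade:::roc_auc(truth, score)
  ref <- as.numeric(pROC::auc(pROC::roc(truth, score, levels = c("low", "high"),
                                        direction = "<", quiet = TRUE)))
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("models serialize to JSON and back without loss", {
  zsp <- list(mean = c(f1 = 0.5, f2 = -1), sd = c(f1 = 2, f2 = 1))
  m <- coef_set(0.25, c(f1 = 1.5, f2 = -0.75), lambda = 0.02,
                zscore_params = zsp)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(back$intercept, m$intercept)
  expect_equal(back$weights, m$weights)
  expect_equal(back$lambda, m$lambda)
  expect_equal(back$zscore_params, m$zscore_params)
})

test_that("the packaged published model matches its transcription contract", {
  m <- load_published_model()
  tab <- attr(m, "table")
  expect_equal(nrow(tab), 26)
  expect_equal(length(unique(paste(tab$feature))), 18)
  expect_equal(m$lambda, 0.0101)
  expect_equal(unname(m$weights["morph_elongation_mad"]), -1.51e-01)
  expect_equal(unname(m$weights["tex_gln_lab_mad"]), 2.45)
  expect_true(all(names(m$weights) %in% summary_feature_names()))
  expect_null(m$zscore_params)
})
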