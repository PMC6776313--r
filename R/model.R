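# L1-penalized logistic grade classifier. glmnet's binomial objective,
# mean negative log-likelihood + lambda * ||w||_1 with an unpenalized
# intercept, matches the model contract; features are z-scored by this
# module, so glmnet's own standardization is disabled.

#' Z-score a feature table
#'
#' Fits per-column mean/SD (sample SD, n - 1) and applies them, or applies
#' precomputed parameters without refitting. Zero-variance columns are
#' passed through as 0 with a warning.
#'
#' @param table numeric matrix or data.frame of features
#' @param params optional list with numeric vectors `mean` and `sd` (named
#'   by column) from a previous fit
#' @return list with `x` (standardized matrix) and `params`
#' @export
zscore_fit_apply <- function(table, params = NULL) {
  x <- as.matrix(table)
  if (is.null(params)) {
    if (nrow(x) < 2L) stopf("need >= 2 rows to fit z-score parameters")
    mu <- colMeans(x)
    sdev <- apply(x, 2L, sd)
    if (any(sdev == 0))
      warning(sprintf("%d constant column(s) passed through as 0",
                      sum(sdev == 0)))
    params <- list(mean = mu, sd = sdev)
  } else {
    missing_cols <- setdiff(names(params$mean), colnames(x))
    if (length(missing_cols))
      stopf("table is missing z-score columns: %s",
            paste(missing_cols, collapse = ", "))
    x <- x[, names(params$mean), drop = FALSE]
  }
  sdev <- params$sd
  z <- sweep(x, 2L, params$mean)
  ok <- sdev > 0
  z[, ok] <- sweep(z[, ok, drop = FALSE], 2L, sdev[ok], `/`)
  z[, !ok] <- 0
  list(x = z, params = params)
}

# Rank-based ROC AUC (equals the trapezoidal area with tie correction);
# positive class = "high".
roc_auc <- function(truth, scores) {
  pos <- truth == "high"
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0L || nn == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
}

#' Construct a coefficient set
#'
#' @param intercept model intercept
#' @param weights named numeric vector of feature weights
#' @param lambda L1 penalty used at fit time
#' @param zscore_params z-score parameters stored for prediction (may be
#'   `NULL` when unknown)
#' @return object of class `coef_set`
#' @export
coef_set <- function(intercept, weights, lambda, zscore_params = NULL) {
  structure(list(intercept = as.numeric(intercept),
                 weights = weights, lambda = lambda,
                 zscore_params = zscore_params),
            class = "coef_set")
}

#' @export
print.coef_set <- function(x, ...) {
  nz <- sum(x$weights != 0)
  cat(sprintf("L1-logistic grade model: %d nonzero of %d weights, lambda = %g\n",
              nz, length(x$weights), x$lambda))
  cat(sprintf("intercept = %.4f\n", x$intercept))
  invisible(x)
}

#' Tune the L1 penalty by repeated random holdout
#'
#' For each candidate penalty, fits the lasso path on 100 (by default)
#' stratified random 90/10 splits of the training data and averages the
#' validation ROC AUC. The winning penalty maximizes mean AUC; exact ties
#' go to the larger (sparser) penalty.
#'
#' @param x standardized feature matrix
#' @param y grade labels ("low"/"high" or 0/1 with 1 = high)
#' @param grid numeric vector of candidate lambda values
#' @param n_rep number of random holdout iterations
#' @param holdout validation fraction
#' @param seed integer seed controlling the splits
#' @return list with `lambda` (the winner), `grid`, and `mean_auc`
#' @export
tune_lambda <- function(x, y, grid, n_rep = 100L, holdout = 0.1, seed = 1L) {
  y <- normalize_labels(y)
  if (length(unique(y)) < 2L) stopf("both grade classes must be present")
  if (!length(grid)) stopf("lambda grid is empty")
  grid <- sort(unique(grid), decreasing = TRUE)
  withr::with_seed(seed, {
    aucs <- matrix(NA_real_, n_rep, length(grid))
    idx_hi <- which(y == "high"); idx_lo <- which(y == "low")
    n_hi <- max(1L, round(length(idx_hi) * holdout))
    n_lo <- max(1L, round(length(idx_lo) * holdout))
    for (r in seq_len(n_rep)) {
      val <- c(sample(idx_hi, n_hi), sample(idx_lo, n_lo))
      fit <- glmnet::glmnet(x[-val, , drop = FALSE],
                            factor(y[-val], levels = c("low", "high")),
                            family = "binomial", lambda = grid,
                            standardize = FALSE)
      pr <- predict(fit, x[val, , drop = FALSE], s = grid, type = "link")
      aucs[r, ] <- apply(pr, 2L, function(sc) roc_auc(y[val], sc))
    }
    mean_auc <- colMeans(aucs, na.rm = TRUE)
    best <- max(mean_auc)
    lambda <- max(grid[mean_auc == best])   # ties -> sparser model
    list(lambda = lambda, grid = grid, mean_auc = setNames(mean_auc, grid))
  })
}

normalize_labels <- function(y) {
  if (is.numeric(y)) return(ifelse(y > 0, "high", "low"))
  y <- as.character(y)
  if (!all(y %in% c("low", "high"))) stopf("labels must be low/high (or 0/1)")
  y
}

#' Fit the L1-penalized logistic grade model
#'
#' Minimizes the mean binomial negative log-likelihood plus
#' `lambda * sum(|w|)` with an unpenalized intercept, on an already
#' standardized feature matrix. The coefficient at the requested penalty is
#' taken from a warm-started path ending exactly at `lambda`.
#'
#' @param x standardized feature matrix (rows = cases)
#' @param y grade labels ("low"/"high" or 0/1 with 1 = high)
#' @param lambda L1 penalty (>= 0)
#' @param zscore_params z-score parameters to store with the model
#' @return a [coef_set()]
#' @export
fit_lasso <- function(x, y, lambda, zscore_params = NULL) {
  y <- normalize_labels(y)
  if (length(unique(y)) < 2L) stopf("both grade classes must be present")
  yf <- factor(y, levels = c("low", "high"))
  ybar <- mean(yf == "high")
  lmax <- max(abs(crossprod(x, (yf == "high") - ybar)) / nrow(x))
  path <- exp(seq(log(max(lmax, lambda) * 1.05), log(max(lambda, 1e-8)),
                  length.out = 60L))
  path <- sort(unique(c(path, lambda)), decreasing = TRUE)
  path <- path[path >= lambda - 1e-15]
  fit <- glmnet::glmnet(x, yf, family = "binomial", lambda = path,
                        standardize = FALSE, thresh = 1e-9, maxit = 1e5)
  cf <- coef(fit, s = lambda)
  w <- setNames(as.numeric(cf[-1L]), rownames(cf)[-1L])
  coef_set(intercept = as.numeric(cf[1L]), weights = w, lambda = lambda,
           zscore_params = zscore_params)
}

#' Predict two-tier grade for new cases
#'
#' Applies the model's stored z-score parameters (when present), the linear
#' predictor and the logistic link. Cases with probability >= `threshold`
#' are labeled high grade.
#'
#' @param model a [coef_set()]
#' @param table data.frame or matrix containing at least the model's
#'   feature columns
#' @param threshold classification threshold on the high-grade probability
#' @return data.frame with columns `prob_high` and `grade_pred`
#' @export
predict_grade <- function(model, table, threshold = 0.5) {
  x <- as.matrix(table)
  need <- names(model$weights)
  miss <- setdiff(need, colnames(x))
  if (length(miss))
    stopf("table is missing model features: %s", paste(miss, collapse = ", "))
  if (!is.null(model$zscore_params))
    x <- zscore_fit_apply(x, model$zscore_params)$x
  x <- x[, need, drop = FALSE]
  eta <- model$intercept + as.vector(x %*% model$weights)
  p <- 1 / (1 + exp(-eta))
  data.frame(prob_high = p,
             grade_pred = ifelse(p >= threshold, "high", "low"),
             stringsAsFactors = FALSE)
}

#' Evaluate grade predictions
#'
#' Confusion counts (high = positive class), accuracy, sensitivity,
#' specificity, ROC AUC (trapezoidal/rank form) and Cohen's kappa.
#'
#' @param truth true labels ("low"/"high")
#' @param pred predicted labels
#' @param prob optional high-grade probabilities for the AUC
#' @return list of class `evaluation_report`
#' @export
evaluate_grades <- function(truth, pred, prob = NULL) {
  truth <- normalize_labels(truth); pred <- normalize_labels(pred)
  if (length(truth) != length(pred)) stopf("truth and pred lengths differ")
  tp <- sum(truth == "high" & pred == "high")
  tn <- sum(truth == "low" & pred == "low")
  fp <- sum(truth == "low" & pred == "high")
  fn <- sum(truth == "high" & pred == "low")
  n <- length(truth)
  tab <- cross_tabulate(pred, truth, levels = c("low", "high"))
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn, n = n,
    accuracy = (tp + tn) / n,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    roc_auc = if (!is.null(prob)) roc_auc(truth, prob) else NA_real_,
    cohen_kappa = cohen_kappa(tab)), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("n = %d | TP %d FP %d TN %d FN %d\n", x$n, x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("accuracy %.3f | sensitivity %.3f | specificity %.3f\n",
              x$accuracy, x$sensitivity, x$specificity))
  cat(sprintf("ROC AUC %.3f | Cohen's kappa %.3f\n", x$roc_auc, x$cohen_kappa))
  invisible(x)
}

#' Serialize a model to JSON
#'
#' @param model a [coef_set()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_model <- function(model, path) {
  obj <- list(intercept = model$intercept,
              weights = as.list(model$weights),
              lambda = model$lambda,
              zscore_params = if (is.null(model$zscore_params)) NULL else
                list(mean = as.list(model$zscore_params$mean),
                     sd = as.list(model$zscore_params$sd)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model serialized by [write_model()]
#'
#' @param path JSON model path
#' @return a [coef_set()]
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  zp <- NULL
  if (!is.null(obj$zscore_params))
    zp <- list(mean = unlist(obj$zscore_params$mean),
               sd = unlist(obj$zscore_params$sd))
  coef_set(obj$intercept, unlist(obj$weights), obj$lambda, zp)
}
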