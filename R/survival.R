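# Survival evaluation of grades: Kaplan-Meier estimation and crude /
# adjusted Cox proportional-hazards models (Efron ties), via the survival
# package. Grade is coded high vs low so HR > 1 means worse survival for
# high-grade cases; stage enters as a factor with stage I as reference.

check_survival_cols <- function(records, cols) {
  miss <- setdiff(cols, names(records))
  if (length(miss)) stopf("missing columns: %s", paste(miss, collapse = ", "))
  if (any(records$time < 0)) stopf("survival times must be >= 0")
  if (!all(records$event %in% c(0, 1))) stopf("event must be 0/1")
  invisible(records)
}

#' Kaplan-Meier estimate per grade group
#'
#' Product-limit estimator with right censoring and Greenwood-based 95%
#' confidence bands, computed per level of the grouping column.
#'
#' @param records data.frame with `time`, `event` and the grouping column
#' @param group_by name of the grouping column (default `grade_2tier`)
#' @return named list (one element per group) of data.frames with columns
#'   `time`, `n_risk`, `n_event`, `surv`, `lower`, `upper`
#' @export
km_estimate <- function(records, group_by = "grade_2tier") {
  check_survival_cols(records, c("time", "event", group_by))
  groups <- split(records, records[[group_by]], drop = TRUE)
  if (any(vapply(groups, nrow, 1L) == 0L)) stopf("empty group")
  lapply(groups, function(g) {
    fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = g,
                             conf.type = "log")
    data.frame(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
               surv = fit$surv, lower = fit$lower, upper = fit$upper)
  })
}

#' Cox proportional-hazards fit for grade and covariates
#'
#' Partial-likelihood estimation with Efron tie handling. Grade is a factor
#' with low as reference; gender and stage are factors (stage I reference);
#' age is continuous.
#'
#' @param records data.frame with `time`, `event` and the requested
#'   covariate columns
#' @param covariates character subset of `c("grade", "age", "gender",
#'   "stage")`; `"grade"` is resolved through `grade_col`
#' @param grade_col name of the grade column to use for the `grade` term
#' @param ties tie-handling method, `"efron"` (default) or `"breslow"`
#' @return data.frame with one row per coefficient: `term`, `hr`,
#'   `ci_lower`, `ci_upper`, `p`; attribute `separation` flags monotone
#'   likelihood
#' @export
cox_fit <- function(records, covariates = c("grade", "age", "gender", "stage"),
                    grade_col = "grade_2tier", ties = c("efron", "breslow")) {
  covariates <- match.arg(covariates, several.ok = TRUE)
  ties <- match.arg(ties)
  df <- as.data.frame(records)
  check_survival_cols(df, c("time", "event"))
  if (sum(df$event) < 2L) stopf("need at least 2 events")
  terms <- character(0)
  if ("grade" %in% covariates) {
    df$.grade <- factor(df[[grade_col]], levels = c("low", "high"))
    terms <- c(terms, ".grade")
  }
  if ("age" %in% covariates) terms <- c(terms, "age")
  if ("gender" %in% covariates) {
    df$gender <- factor(df$gender)
    terms <- c(terms, "gender")
  }
  if ("stage" %in% covariates) {
    df$stage <- factor(df$stage, levels = c("I", "II", "III", "IV"))
    terms <- c(terms, "stage")
  }
  for (tm in terms)
    if (length(unique(df[[tm]])) < 2L)
      stopf("covariate '%s' is constant across cases", sub("^\\.", "", tm))
  fml <- as.formula(paste("survival::Surv(time, event) ~",
                          paste(terms, collapse = " + ")))
  separation <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = df, ties = ties),
    warning = function(w) {
      if (grepl("infinite|did not converge", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  s <- summary(fit)
  out <- data.frame(term = sub("^\\.grade", "grade", rownames(s$coefficients)),
                    hr = s$coefficients[, "exp(coef)"],
                    ci_lower = s$conf.int[, "lower .95"],
                    ci_upper = s$conf.int[, "upper .95"],
                    p = s$coefficients[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  out$term <- sub("^gradehigh$", "grade_high", out$term)
  attr(out, "separation") <- separation
  out
}

#' Side-by-side prognosis report for several grade sources
#'
#' For each grade source (e.g. a pathologist's column and the model's
#' column), fits three Cox models: A crude (grade only), B adjusted for age
#' and gender, and C additionally adjusted for stage, and tabulates the
#' grade hazard ratios.
#'
#' @param records data.frame with `time`, `event`, `age`, `gender`,
#'   `stage`, and one low/high column per grade source
#' @param grade_sources character vector of grade column names
#' @return data.frame with columns `source`, `model` (A/B/C), `hr`,
#'   `ci_lower`, `ci_upper`, `p` (3 rows per source)
#' @export
grade_prognosis_report <- function(records, grade_sources) {
  miss <- setdiff(grade_sources, names(records))
  if (length(miss)) stopf("missing grade columns: %s", paste(miss, collapse = ", "))
  models <- list(A = "grade", B = c("grade", "age", "gender"),
                 C = c("grade", "age", "gender", "stage"))
  rows <- list()
  for (src in grade_sources) {
    for (mn in names(models)) {
      fit <- cox_fit(records, covariates = models[[mn]], grade_col = src)
      g <- fit[fit$term == "grade_high", , drop = FALSE]
      rows[[length(rows) + 1L]] <-
        data.frame(source = src, model = mn, hr = g$hr,
                   ci_lower = g$ci_lower, ci_upper = g$ci_upper, p = g$p,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
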