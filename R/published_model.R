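# The published final grade classifier: 26 weighted entries over 18
# unique base features, fitted at lambda = 0.0101. The training cohort's
# z-score means/SDs were never released, so the set supports transcription
# checks and relative ranking, not calibrated probabilities on new data.

published_lambda <- 0.0101

#' Load the published grade-model coefficient set
#'
#' Returns the transcribed coefficients of the final L1-logistic grade
#' classifier (26 entries over 18 unique base features, optimal lambda
#' 0.0101) as a [coef_set()]. `zscore_params` is `NULL` because the
#' original training standardization parameters are not public; see the
#' package vignette for the implications.
#'
#' @return a [coef_set()] with attribute `table`, the transcription
#'   data.frame (feature, type, color_space, summary, coefficient,
#'   canonical_name)
#' @export
load_published_model <- function() {
  path <- system.file("extdata", "published_model_coefficients.csv",
                      package = "rccgrade", mustWork = TRUE)
  md5 <- as.character(tools::md5sum(path))
  expected <- published_model_md5
  if (!is.na(expected) && md5 != expected)
    stopf("packaged coefficient file is corrupted (md5 %s)", md5)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) != 26L)
    stopf("packaged coefficient table must have 26 rows, found %d", nrow(tab))
  w <- setNames(tab$coefficient, tab$canonical_name)
  model <- coef_set(intercept = 0, weights = w, lambda = published_lambda,
                    zscore_params = NULL)
  attr(model, "table") <- tab
  model
}

# md5 of the shipped CSV, fixed at packaging time.
published_model_md5 <- "36c5134b0829b7b5eb01d319ad382d9b"
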