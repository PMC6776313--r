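#' Cross-tabulate two raters' grades
#'
#' @param ratings_a,ratings_b equal-length grade vectors
#' @param levels ordered grade levels (e.g. `c("low", "high")` or `1:4`)
#' @return square integer count matrix (rows = rater A, cols = rater B)
#' @export
cross_tabulate <- function(ratings_a, ratings_b, levels) {
  if (length(ratings_a) != length(ratings_b))
    stopf("rating vectors must have equal length")
  bad <- setdiff(unique(c(ratings_a, ratings_b)), levels)
  if (length(bad))
    stopf("ratings outside the declared levels: %s", paste(bad, collapse = ", "))
  a <- factor(ratings_a, levels = levels)
  b <- factor(ratings_b, levels = levels)
  unclass(table(a, b, dnn = NULL))
}

#' Frequency of agreement between two raters
#'
#' @param tab square count matrix from [cross_tabulate()]
#' @return trace / total, in `[0, 1]`
#' @export
agreement_frequency <- function(tab) {
  n <- sum(tab)
  if (n == 0) stopf("empty cross-tabulation")
  sum(diag(tab)) / n
}

#' Cohen's kappa for two raters
#'
#' Unweighted kappa: `(p_o - p_e) / (1 - p_e)` with chance agreement from
#' the product of row and column marginals. When chance agreement is 1
#' (degenerate marginals), kappa is defined as 1 for perfect agreement and
#' 0 otherwise, with a warning.
#'
#' @param tab square count matrix from [cross_tabulate()]
#' @return kappa
#' @export
cohen_kappa <- function(tab) {
  n <- sum(tab)
  if (n == 0) stopf("empty cross-tabulation")
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (1 - pe < .Machine$double.eps) {
    warning("chance agreement is 1; kappa set by convention")
    return(if (po >= 1) 1 else 0)
  }
  (po - pe) / (1 - pe)
}

#' Fleiss' kappa for three or more raters
#'
#' Standard Fleiss formula over category proportions, requiring a fixed
#' number of raters per case.
#'
#' @param ratings cases x raters matrix (or data.frame) of categorical
#'   grades
#' @return kappa
#' @export
fleiss_kappa <- function(ratings) {
  m <- as.matrix(ratings)
  if (ncol(m) < 2L) stopf("need at least 2 raters")
  if (nrow(m) < 2L) stopf("need at least 2 cases")
  if (any(is.na(m))) stopf("all cases must be rated by every rater")
  cats <- sort(unique(as.vector(m)))
  r <- ncol(m)
  counts <- t(apply(m, 1L, function(row) tabulate(match(row, cats),
                                                  nbins = length(cats))))
  p_i <- (rowSums(counts^2) - r) / (r * (r - 1))
  p_j <- colSums(counts) / (nrow(m) * r)
  pbar <- mean(p_i)
  pe <- sum(p_j^2)
  if (1 - pe < .Machine$double.eps) {
    warning("chance agreement is 1; kappa set by convention")
    return(if (pbar >= 1) 1 else 0)
  }
  (pbar - pe) / (1 - pe)
}

#' Consensus grade by majority vote
#'
#' Re-assigns each case the most frequent grade among its raters (designed
#' for an odd rater count; even-count ties raise an error).
#'
#' @param ratings cases x raters matrix or data.frame of two-tier grades
#' @return character vector of per-case consensus grades
#' @export
consensus_reassign <- function(ratings) {
  m <- as.matrix(ratings)
  apply(m, 1L, function(row) {
    tab <- sort(table(row), decreasing = TRUE)
    if (length(tab) > 1L && tab[1L] == tab[2L])
      stopf("tied vote with an even rater count; majority is undefined")
    names(tab)[1L]
  })
}
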