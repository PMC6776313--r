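#' Tile a region-of-interest image into analysis patches
#'
#' Cuts non-overlapping `tile` x `tile` patches from the top-left grid in
#' row-major order. A right/bottom remainder strip is kept (padded to full
#' size by reflection) when it spans at least half a tile, and dropped
#' otherwise.
#'
#' @param roi_image integer H x W x 3 RGB array
#' @param tile tile edge in pixels (the pipeline's native size is 2000)
#' @return list of RGB patches; each carries attribute `origin`, the
#'   (row, col) of its top-left pixel in the ROI
#' @export
tile_roi <- function(roi_image, tile = 2000L) {
  check_patch(roi_image)
  d <- dim(roi_image)[1:2]
  starts <- function(n) {
    full <- n %/% tile
    rem <- n - full * tile
    s <- if (full > 0L) seq(1L, by = tile, length.out = full) else integer(0)
    if (rem >= tile / 2 || full == 0L) s <- c(s, full * tile + 1L)
    s
  }
  reflect_idx <- function(from, n) {
    idx <- from:(from + tile - 1L)
    over <- idx > n
    idx[over] <- n - (idx[over] - n) + 1L   # reflect about the edge
    pmax(idx, 1L)
  }
  out <- list()
  for (r0 in starts(d[1L])) {
    ri <- reflect_idx(r0, d[1L])
    for (c0 in starts(d[2L])) {
      ci <- reflect_idx(c0, d[2L])
      p <- roi_image[ri, ci, , drop = FALSE]
      attr(p, "origin") <- c(r0, c0)
      out[[length(out) + 1L]] <- p
    }
  }
  out
}

#' Summarize patch features to the ROI level
#'
#' For each of the 72 per-patch features, computes the median and the raw
#' (unscaled) median absolute deviation across the ROI's patches, yielding
#' the 144 summarized features.
#'
#' @param patch_vectors list of named 72-feature vectors (from
#'   [patch_features()]), or a patches x 72 matrix
#' @return named numeric vector of length 144 (`<feature>_median`,
#'   `<feature>_mad` pairs, see [summary_feature_names()])
#' @export
summarize_roi <- function(patch_vectors) {
  if (is.list(patch_vectors)) {
    patch_vectors <- patch_vectors[!vapply(patch_vectors, is.null, logical(1L))]
    if (length(patch_vectors) == 0L) stopf("ROI has no non-empty patches")
    m <- do.call(rbind, patch_vectors)
  } else m <- patch_vectors
  if (is.null(dim(m)) || nrow(m) == 0L) stopf("ROI has no patch vectors")
  med <- apply(m, 2L, median)
  mad_raw <- apply(m, 2L, function(x) median(abs(x - median(x))))
  out <- as.vector(rbind(med, mad_raw))
  names(out) <- as.vector(rbind(paste0(colnames(m), "_median"),
                                paste0(colnames(m), "_mad")))
  out
}

#' Select the representative ROI of a case
#'
#' Restricts to the ROIs carrying the case's maximal grade, computes their
#' per-feature median vector, and returns the restricted ROI whose
#' summarized features minimize Euclidean distance to that median. Ties go
#' to the smallest `roi_id`.
#'
#' @param summaries ROIs x features numeric matrix of summarized features
#' @param grades integer ROI grades (1-4), one per row
#' @param roi_ids ROI identifiers (default row order)
#' @return the selected element of `roi_ids`
#' @export
select_representative_roi <- function(summaries, grades,
                                      roi_ids = seq_len(nrow(summaries))) {
  if (is.null(dim(summaries)) || nrow(summaries) == 0L)
    stopf("no ROI summaries given")
  if (length(grades) != nrow(summaries))
    stopf("one grade per ROI is required")
  top <- which(grades == max(grades))
  sub <- summaries[top, , drop = FALSE]
  ctr <- apply(sub, 2L, median)
  d2 <- rowSums(sweep(sub, 2L, ctr)^2)
  ord <- order(d2, roi_ids[top])
  roi_ids[top][ord[1L]]
}

#' Designate the case-level grade from its ROI grades
#'
#' The designated 4-tier grade is the highest grade among the case's ROIs;
#' the 2-tier grade maps grades 1-2 to low and 3-4 to high.
#'
#' @param roi_grades integer vector of ROI grades in 1..4
#' @return list with `grade_4tier` and `grade_2tier` ("low"/"high")
#' @export
designate_grade <- function(roi_grades) {
  if (length(roi_grades) == 0L) stopf("at least one ROI grade is required")
  if (!all(roi_grades %in% 1:4))
    stopf("ROI grades must be integers in 1..4")
  g4 <- max(roi_grades)
  list(grade_4tier = g4, grade_2tier = if (g4 <= 2L) "low" else "high")
}
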