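#' Segmentation parameters
#'
#' Bundles the tunable parameters of the nuclei segmentation stage. The
#' defaults are declared, logged choices rather than values claimed
#' faithful to any particular slide scanner.
#'
#' @param window odd local-mean window in pixels for adaptive thresholding
#' @param offset_v value-channel offset: foreground is darker than the
#'   local mean by more than this
#' @param offset_s saturation offset: foreground is more saturated than the
#'   local mean by more than this
#' @param hue_band numeric (lo, hi) hue interval (scaled to `[0, 1)`)
#'   accepted as hematoxylin-like
#' @param vote_k number of channel masks (of 3) that must agree
#' @param h_min h-maxima depth on the distance transform for watershed
#'   markers
#' @param min_area,max_area nucleus area filter in pixels
#' @return list of class `segmentation_params`
#' @export
segmentation_params <- function(window = 101L, offset_v = 0.02,
                                offset_s = 0.01, hue_band = c(0.5, 0.8),
                                vote_k = 2L, h_min = 2, min_area = 200L,
                                max_area = 2000L) {
  if (window %% 2L == 0L || window < 3L) stopf("window must be odd and >= 3")
  if (vote_k < 1L || vote_k > 3L) stopf("vote_k must be in 1..3")
  if (!(min_area > 0L && min_area < max_area))
    stopf("need 0 < min_area < max_area")
  structure(list(window = as.integer(window), offset_v = offset_v,
                 offset_s = offset_s, hue_band = hue_band,
                 vote_k = as.integer(vote_k), h_min = h_min,
                 min_area = as.integer(min_area),
                 max_area = as.integer(max_area)),
            class = "segmentation_params")
}

#' Adaptive thresholding of nuclei in HSV space
#'
#' Per-channel rules fused by a k-of-3 vote: the value channel flags pixels
#' darker than their local mean (nuclei are dark on a light background),
#' the saturation channel flags pixels more saturated than their local
#' mean, and the hue channel flags pixels within the hematoxylin
#' (blue-violet) hue band.
#'
#' @param hsv list with matrices `h`, `s`, `v` (from [to_hsv()])
#' @param params a [segmentation_params()] object
#' @return logical foreground matrix
#' @export
threshold_nuclei <- function(hsv, params = segmentation_params()) {
  stopifnot(all(c("h", "s", "v") %in% names(hsv)))
  d <- dim(hsv$v)
  if (!all(dim(hsv$h) == d) || !all(dim(hsv$s) == d))
    stopf("HSV planes must share one shape")
  if (params$window > min(d))
    stopf("window (%d) exceeds image extent", params$window)
  mv <- hsv$v < local_mean(hsv$v, params$window) - params$offset_v
  ms <- hsv$s > local_mean(hsv$s, params$window) + params$offset_s
  mh <- hsv$h >= params$hue_band[1L] & hsv$h <= params$hue_band[2L]
  (mv + ms + mh) >= params$vote_k
}

#' Separate touching nuclei by marker-controlled watershed
#'
#' Markers are the h-maxima (depth `h_min`) of the Euclidean distance
#' transform of the foreground mask; flooding of the negated distance map
#' is restricted to the mask, so no foreground pixel is ever assigned to
#' background.
#'
#' @param mask logical foreground matrix
#' @param params a [segmentation_params()] object
#' @return integer label matrix (0 = background)
#' @export
split_touching <- function(mask, params = segmentation_params()) {
  if (!any(mask)) return(matrix(0L, nrow(mask), ncol(mask)))
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  labs <- EBImage::watershed(dm, tolerance = params$h_min, ext = 1L)
  out <- EBImage::imageData(labs)
  storage.mode(out) <- "integer"
  out
}

#' Morphological refinement and area filtering of nuclei labels
#'
#' Fills holes and applies a binary opening (3 x 3 disk) to each label,
#' then removes labels whose refined area lies outside
#' `[min_area, max_area]` pixels. Survivors are renumbered 1..n in the
#' original label order.
#'
#' @param labels integer label matrix
#' @param params a [segmentation_params()] object
#' @return integer label matrix
#' @export
refine_and_filter <- function(labels, params = segmentation_params()) {
  labs <- sort(unique(labels[labels > 0L]))
  out <- matrix(0L, nrow(labels), ncol(labels))
  kern <- matrix(1, 3L, 3L)
  nxt <- 0L
  for (lab in labs) {
    coords <- which(labels == lab, arr.ind = TRUE)
    r1 <- max(min(coords[, 1L]) - 2L, 1L); r2 <- min(max(coords[, 1L]) + 2L, nrow(labels))
    c1 <- max(min(coords[, 2L]) - 2L, 1L); c2 <- min(max(coords[, 2L]) + 2L, ncol(labels))
    sub <- labels[r1:r2, c1:c2] == lab
    sub <- EBImage::fillHull(EBImage::Image(sub * 1))
    sub <- EBImage::opening(sub, kern)
    keep <- EBImage::imageData(sub) > 0
    area <- sum(keep)
    if (area < params$min_area || area > params$max_area) next
    nxt <- nxt + 1L
    blk <- out[r1:r2, c1:c2]
    blk[keep] <- nxt
    out[r1:r2, c1:c2] <- blk
  }
  out
}

#' Segment nuclei in an H&E patch
#'
#' Runs the full two-step procedure: optional stain normalization against a
#' reference patch, HSV conversion, channel-voted adaptive thresholding,
#' marker-controlled watershed splitting of touching nuclei, and
#' morphological refinement with the 200-2000 px area filter.
#'
#' @param patch integer H x W x 3 RGB array
#' @param params a [segmentation_params()] object
#' @param reference optional reference patch for [normalize_stain()]
#' @return integer label matrix aligned to the patch
#' @export
segment_patch <- function(patch, params = segmentation_params(),
                          reference = NULL) {
  check_patch(patch)
  if (!is.null(reference)) patch <- normalize_stain(patch, reference)
  fg <- threshold_nuclei(to_hsv(patch), params)
  labels <- split_touching(fg, params)
  refine_and_filter(labels, params)
}
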