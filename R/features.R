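# Per-nucleus histomics: 9 morphology + 5 intensity and 16 texture
# statistics per analysis channel. Texture statistics use min-max
# quantization to Q gray levels within each nucleus, distance-1
# co-occurrence over the four principal directions (symmetrized), and
# maximal-run accumulation over the same four directions.

region_coords <- function(region) {
  if (is.logical(region)) {
    coords <- which(region, arr.ind = TRUE)
  } else if (is.matrix(region) && ncol(region) == 2L) {
    coords <- region
  } else stopf("region must be a logical matrix or a 2-column (row, col) matrix")
  if (nrow(coords) == 0L) stopf("region is empty")
  coords
}

coords_to_mask <- function(coords) {
  r0 <- min(coords[, 1L]); c0 <- min(coords[, 2L])
  m <- matrix(FALSE, max(coords[, 1L]) - r0 + 1L, max(coords[, 2L]) - c0 + 1L)
  m[cbind(coords[, 1L] - r0 + 1L, coords[, 2L] - c0 + 1L)] <- TRUE
  m
}

# Crofton perimeter estimate: run starts counted along the four principal
# directions; diagonal counts are rescaled by the line spacing.
crofton_perimeter <- function(mask) {
  pad <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  pad[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  nr <- nrow(pad); nc <- ncol(pad)
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nr, nc)
    rs <- seq_len(nr - abs(dr)); cs <- seq_len(nc - abs(dc))
    out[rs + max(dr, 0), cs + max(dc, 0)] <- m[rs + max(-dr, 0), cs + max(-dc, 0)]
    out
  }
  runs <- function(dr, dc) sum(pad & !shift(pad, dr, dc))
  r_h <- runs(0L, 1L)   # runs along rows
  r_v <- runs(1L, 0L)   # runs along columns
  r_d <- runs(1L, 1L)   # down-right diagonals
  r_a <- runs(1L, -1L)  # down-left diagonals
  pi * (r_h + r_v + r_d / sqrt(2) + r_a / sqrt(2)) / 4
}

#' Morphological features of one nucleus
#'
#' Computes the nine shape descriptors: area (pixel count), roundness,
#' elongation, flatness, Crofton perimeter, equivalent spherical perimeter
#' and radius, and the minor/major axes of the moment-matched ellipse
#' (4 * sqrt of the pixel-covariance eigenvalues). Flatness duplicates
#' elongation in 2D, where the three-axis definition degenerates.
#'
#' @param region logical matrix or 2-column (row, col) coordinate matrix of
#'   the nucleus pixels
#' @return named numeric vector of length 9 (`morph_*` names)
#' @export
shape_features <- function(region) {
  coords <- region_coords(region)
  n <- nrow(coords)
  mu <- colMeans(coords)
  dd <- sweep(coords, 2L, mu)
  covm <- crossprod(dd) / n
  ev <- sort(pmax(eigen(covm, symmetric = TRUE, only.values = TRUE)$values, 0),
             decreasing = TRUE)
  major <- 4 * sqrt(ev[1L]); minor <- 4 * sqrt(ev[2L])
  elong <- if (minor > 0) major / minor else Inf
  perim <- crofton_perimeter(coords_to_mask(coords))
  r_eq <- sqrt(n / pi)
  esp <- 2 * pi * r_eq
  c(morph_area = n,
    morph_roundness = esp / perim,
    morph_elongation = elong,
    morph_flatness = elong,
    morph_perimeter = perim,
    morph_equivalent_spherical_perimeter = esp,
    morph_equivalent_spherical_radius = r_eq,
    morph_ellipse_minor_axis = minor,
    morph_ellipse_major_axis = major)
}

#' First-order intensity statistics of a nucleus region
#'
#' Mean, median, standard deviation (n - 1), skewness (g1) and excess
#' kurtosis of the channel values inside the region. Constant regions
#' return 0 for sd, skewness and kurtosis.
#'
#' @param plane numeric matrix (one analysis channel)
#' @param region logical matrix (same shape) or coordinate matrix
#' @return named numeric vector of length 5
#' @export
intensity_features <- function(plane, region) {
  coords <- region_coords(region)
  x <- plane[cbind(coords[, 1L], coords[, 2L])]
  n <- length(x)
  m <- mean(x)
  s <- if (n > 1L) sd(x) else 0
  if (s > 0) {
    z <- (x - m)
    m2 <- mean(z^2); m3 <- mean(z^3); m4 <- mean(z^4)
    skew <- m3 / m2^1.5
    kurt <- m4 / m2^2 - 3
  } else {
    s <- 0; skew <- 0; kurt <- 0
  }
  c(mean = m, median = median(x), sd = s, skewness = skew, kurtosis = kurt)
}

# Min-max quantization of region values to 1..Q (constant region -> 1).
quantize_region <- function(plane, coords, Q) {
  x <- plane[cbind(coords[, 1L], coords[, 2L])]
  mn <- min(x); mx <- max(x)
  if (mx > mn) pmin(as.integer(floor((x - mn) / (mx - mn) * Q)) + 1L, Q)
  else rep(1L, length(x))
}

# Cropped level matrix with NA outside the region.
level_matrix <- function(plane, region, Q) {
  coords <- region_coords(region)
  lev <- quantize_region(plane, coords, Q)
  r0 <- min(coords[, 1L]); c0 <- min(coords[, 2L])
  m <- matrix(NA_integer_, max(coords[, 1L]) - r0 + 1L,
              max(coords[, 2L]) - c0 + 1L)
  m[cbind(coords[, 1L] - r0 + 1L, coords[, 2L] - c0 + 1L)] <- lev
  m
}

glcm_offsets <- list(c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))

# Symmetric, normalized gray-level co-occurrence matrix, distance 1,
# four directions accumulated.
glcm_matrix <- function(plane, region, Q = 32L) {
  lev <- level_matrix(plane, region, Q)
  nr <- nrow(lev); nc <- ncol(lev)
  counts <- matrix(0, Q, Q)
  for (off in glcm_offsets) {
    dr <- off[1L]; dc <- off[2L]
    rs <- seq_len(nr - dr)
    cs <- if (dc >= 0) seq_len(nc - dc) else seq.int(1L - dc, nc)
    if (!length(rs) || !length(cs)) next
    a <- lev[rs, cs, drop = FALSE]
    b <- lev[rs + dr, cs + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    ia <- a[ok]; ib <- b[ok]
    tab <- tabulate((ia - 1L) * Q + ib, nbins = Q * Q) +
           tabulate((ib - 1L) * Q + ia, nbins = Q * Q)
    counts <- counts + matrix(tab, Q, Q, byrow = TRUE)
  }
  tot <- sum(counts)
  if (tot == 0) stopf("region admits no distance-1 pixel pairs")
  counts / tot
}

glcm_stats <- function(p) {
  Q <- nrow(p)
  i <- seq_len(Q)
  px <- rowSums(p)                      # symmetric: both marginals equal
  mu <- sum(i * px)
  sig2 <- sum((i - mu)^2 * px)
  ii <- matrix(i, Q, Q); jj <- t(ii)
  energy <- sum(p^2)
  entropy <- -sum(p[p > 0] * log(p[p > 0]))
  inertia <- sum((ii - jj)^2 * p)
  idm <- sum(p / (1 + (ii - jj)^2))
  if (sig2 > 0) {
    correlation <- sum((ii - mu) * (jj - mu) * p) / sig2
    haralick_correlation <- (sum(ii * jj * p) - mu^2) / sig2
  } else {
    correlation <- 0; haralick_correlation <- 0
  }
  shade <- sum((ii + jj - 2 * mu)^3 * p)
  prom <- sum((ii + jj - 2 * mu)^4 * p)
  c(correlation = correlation, cluster_shade = shade,
    cluster_prominence = prom, energy = energy, entropy = entropy,
    haralick_correlation = haralick_correlation, inertia = inertia,
    inverse_difference_moment = idm)
}

#' Gray-level co-occurrence texture features of a nucleus region
#'
#' Builds a symmetric distance-1 co-occurrence matrix over the four
#' principal directions from pixel pairs lying entirely inside the region,
#' after min-max quantization to `Q` levels, and evaluates the eight
#' Haralick statistics: correlation, cluster shade, cluster prominence,
#' energy, entropy (natural log), Haralick correlation, inertia and inverse
#' difference moment. Zero-variance regions return 0 for the two
#' correlation statistics.
#'
#' @param plane numeric matrix (one analysis channel)
#' @param region logical matrix or coordinate matrix of the nucleus pixels
#' @param Q number of quantization levels
#' @return named numeric vector of length 8
#' @export
glcm_features <- function(plane, region, Q = 32L) {
  glcm_stats(glcm_matrix(plane, region, Q))
}

rlm_direction_codes <- c(horizontal = 1L, vertical = 2L,
                         diag_down = 3L, diag_up = 4L)

# Runs of identical quantized levels within the region along the requested
# directions. Returns integer levels `i` and run lengths `j`, one entry per
# maximal run.
region_runs <- function(lev, directions = names(rlm_direction_codes)) {
  lines <- list()
  idx_rows <- row(lev); idx_cols <- col(lev)
  if ("horizontal" %in% directions)
    lines <- c(lines, split(as.vector(t(lev)), as.vector(t(idx_rows))))
  if ("vertical" %in% directions)
    lines <- c(lines, split(as.vector(lev), as.vector(idx_cols)))
  if ("diag_down" %in% directions)
    lines <- c(lines, split(as.vector(lev), as.vector(idx_cols - idx_rows)))
  if ("diag_up" %in% directions)
    lines <- c(lines, split(as.vector(lev), as.vector(idx_cols + idx_rows)))
  lv <- integer(0); ln <- integer(0)
  for (line in lines) {
    r <- rle(line)
    keep <- !is.na(r$values)
    lv <- c(lv, r$values[keep])
    ln <- c(ln, r$lengths[keep])
  }
  list(i = lv, j = ln)
}

#' Gray-level run-length texture features of a nucleus region
#'
#' Accumulates maximal same-level runs (after min-max quantization to `Q`
#' levels, indexed 1..Q) along the chosen directions into one run-length
#' matrix and evaluates the eight Galloway/Chu statistics, normalized by
#' the total run count: gray-level and run-length non-uniformity, low/high
#' gray-level run emphasis, and the four short/long-run low/high
#' gray-level emphases.
#'
#' @param plane numeric matrix (one analysis channel)
#' @param region logical matrix or coordinate matrix of the nucleus pixels
#' @param Q number of quantization levels
#' @param directions subset of `"horizontal"`, `"vertical"`, `"diag_down"`,
#'   `"diag_up"` (default all four)
#' @return named numeric vector of length 8
#' @export
rlm_features <- function(plane, region, Q = 32L,
                         directions = names(rlm_direction_codes)) {
  directions <- match.arg(directions, names(rlm_direction_codes),
                          several.ok = TRUE)
  lev <- level_matrix(plane, region, Q)
  rr <- region_runs(lev, directions)
  i <- rr$i; j <- rr$j
  n_r <- length(i)
  if (n_r == 0L) stopf("region has no runs")
  c(gln = sum(tapply(rep(1, n_r), i, sum)^2) / n_r,
    rln = sum(tapply(rep(1, n_r), j, sum)^2) / n_r,
    lgre = sum(1 / i^2) / n_r,
    hgre = sum(i^2) / n_r,
    srlge = sum(1 / (i^2 * j^2)) / n_r,
    srhge = sum(i^2 / j^2) / n_r,
    lrlge = sum(j^2 / i^2) / n_r,
    lrhge = sum(i^2 * j^2) / n_r)
}

#' Extract the 72 histomics features for one patch
#'
#' Computes all morphology, intensity and texture features per nucleus on
#' the three analysis channels from [extract_channels()], then aggregates
#' nucleus-level values to a single patch-level vector (mean by default;
#' median available).
#'
#' @param patch integer H x W x 3 RGB array
#' @param mask integer label matrix aligned to the patch (0 = background)
#' @param Q texture quantization levels
#' @param aggregate `"mean"` (default) or `"median"` nucleus-to-patch
#'   aggregator
#' @param channels optional precomputed result of [extract_channels()]
#' @return named numeric vector of length 72 (see [feature_names()]), with
#'   attribute `n_nuclei`; `NULL` (with a warning) when the mask holds no
#'   labels, signalling an empty patch to be skipped upstream
#' @export
patch_features <- function(patch, mask, Q = 32L,
                           aggregate = c("mean", "median"),
                           channels = NULL) {
  aggregate <- match.arg(aggregate)
  check_patch(patch)
  if (!all(dim(mask) == dim(patch)[1:2]))
    stopf("mask (%d x %d) is not aligned to the patch", nrow(mask), ncol(mask))
  labs <- sort(unique(mask[mask > 0L]))
  if (length(labs) == 0L) {
    warning("patch contains no segmented nuclei; skipping")
    return(NULL)
  }
  if (is.null(channels)) channels <- extract_channels(patch)
  per_nuc <- matrix(NA_real_, length(labs), 72L,
                    dimnames = list(NULL, feature_names()))
  for (k in seq_along(labs)) {
    coords <- which(mask == labs[k], arr.ind = TRUE)
    vals <- shape_features(coords)
    for (ch in names(channel_codes)) {
      plane <- channels[[channel_codes[[ch]]]]
      it <- intensity_features(plane, coords)
      names(it) <- paste0("int_", names(it), "_", ch)
      gl <- glcm_stats(glcm_matrix(plane, coords, Q))
      rl <- rlm_features(plane, coords, Q)
      tx <- c(gl, rl)[texture_stat_names]
      names(tx) <- paste0("tex_", texture_stat_names, "_", ch)
      vals <- c(vals, it, tx)
    }
    per_nuc[k, names(vals)] <- vals
  }
  agg <- if (aggregate == "mean") colMeans(per_nuc) else
    apply(per_nuc, 2L, median)
  structure(agg, n_nuclei = length(labs))
}
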