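# Ruifrok & Johnston optical-density unit vectors for hematoxylin and
# eosin; the third row is the normalized residual (cross product), giving
# an invertible 3x3 stain basis.
#' Standard H&E stain matrix
#'
#' Rows are unit optical-density vectors (R, G, B) for hematoxylin, eosin,
#' and a residual channel completing the basis.
#'
#' @return 3 x 3 numeric matrix with rownames hematoxylin, eosin, residual
#' @export
he_stain_matrix <- function() {
  h <- c(0.650, 0.704, 0.286)
  e <- c(0.072, 0.990, 0.105)
  h <- h / sqrt(sum(h^2))
  e <- e / sqrt(sum(e^2))
  r <- c(h[2] * e[3] - h[3] * e[2],
         h[3] * e[1] - h[1] * e[3],
         h[1] * e[2] - h[2] * e[1])
  r <- r / sqrt(sum(r^2))
  m <- rbind(hematoxylin = h, eosin = e, residual = r)
  colnames(m) <- c("R", "G", "B")
  m
}

# Beer-Lambert transforms. Optical density uses log10 with a +1 offset so
# a zero pixel stays finite; OD is clipped at 0 so white maps to zero
# absorbance exactly.
rgb_to_od <- function(patch) {
  check_patch(patch)
  od <- -log10((patch + 1) / 255)
  od[od < 0] <- 0
  od
}

od_to_rgb <- function(od) {
  out <- round(255 * 10^(-od))
  storage.mode(out) <- "integer"
  clamp(out, 0L, 255L)
}

#' Convert an RGB patch to HSV planes
#'
#' Standard hexcone conversion. Hue is scaled to `[0, 1)`, saturation and
#' value to `[0, 1]`.
#'
#' @param patch integer H x W x 3 array, 0..255
#' @return list with matrices `h`, `s`, `v`
#' @export
to_hsv <- function(patch) {
  check_patch(patch)
  d <- dim(patch)
  flat <- rbind(as.vector(patch[, , 1L]), as.vector(patch[, , 2L]),
                as.vector(patch[, , 3L]))
  hsv <- grDevices::rgb2hsv(flat, maxColorValue = 255)
  list(h = matrix(hsv[1L, ], d[1L], d[2L]),
       s = matrix(hsv[2L, ], d[1L], d[2L]),
       v = matrix(hsv[3L, ], d[1L], d[2L]))
}

#' H&E color deconvolution
#'
#' Projects per-pixel optical density onto the inverse of a stain basis,
#' separating the image into per-stain optical-density planes. Negative
#' projections (pixels outside the stain cone) are clipped to zero.
#'
#' @param patch integer H x W x 3 array, 0..255
#' @param stain_matrix 3 x 3 matrix of stain OD row vectors; defaults to
#'   [he_stain_matrix()]
#' @return list of H x W OD matrices named after the stain rows
#' @export
deconvolve_stains <- function(patch, stain_matrix = he_stain_matrix()) {
  check_patch(patch)
  if (nrow(stain_matrix) != 3L || ncol(stain_matrix) != 3L)
    stopf("stain_matrix must be 3 x 3")
  if (abs(det(stain_matrix)) < 1e-8) stopf("stain matrix is singular")
  d <- dim(patch)
  od <- rgb_to_od(patch)
  flat <- cbind(as.vector(od[, , 1L]), as.vector(od[, , 2L]),
                as.vector(od[, , 3L]))
  conc <- flat %*% solve(stain_matrix)   # pixel OD row = conc row %*% stains
  conc[conc < 0] <- 0
  out <- lapply(seq_len(3L), function(i) matrix(conc[, i], d[1L], d[2L]))
  names(out) <- rownames(stain_matrix) %||% paste0("stain", 1:3)
  out
}

# Re-render RGB from per-stain OD planes under the same basis.
reconstruct_stains <- function(stain_planes, stain_matrix = he_stain_matrix()) {
  d <- dim(stain_planes[[1L]])
  conc <- vapply(stain_planes, as.vector, numeric(prod(d)))
  od_flat <- conc %*% stain_matrix[seq_along(stain_planes), , drop = FALSE]
  od <- array(0, c(d, 3L))
  for (k in 1:3) od[, , k] <- matrix(od_flat[, k], d[1L], d[2L])
  od_to_rgb(od)
}

#' Normalize H&E staining against a reference patch
#'
#' Handles staining variation across slides by monotone quantile mapping:
#' the patch is deconvolved into hematoxylin and eosin optical densities,
#' each stain channel's distribution is mapped onto the reference patch's,
#' and the result is re-rendered to RGB. The map is monotone, so pixel
#' ordering within each stain channel is preserved.
#'
#' @param patch integer H x W x 3 array to normalize
#' @param reference integer H x W x 3 reference patch; must contain at
#'   least 100 tissue pixels (total OD > 0.15)
#' @param stain_matrix stain basis, as in [deconvolve_stains()]
#' @return normalized RGB patch (integer H x W x 3)
#' @export
normalize_stain <- function(patch, reference, stain_matrix = he_stain_matrix()) {
  check_patch(patch); check_patch(reference)
  ref_od <- rgb_to_od(reference)
  tissue <- rowSums(cbind(as.vector(ref_od[, , 1]), as.vector(ref_od[, , 2]),
                          as.vector(ref_od[, , 3]))) > 0.15
  if (sum(tissue) < 100L)
    stopf("reference patch has fewer than 100 tissue pixels (%d)", sum(tissue))
  src <- deconvolve_stains(patch, stain_matrix)
  ref <- deconvolve_stains(reference, stain_matrix)
  mapped <- src
  for (s in c("hematoxylin", "eosin")) {
    m <- quantile_map(as.vector(src[[s]]), as.vector(ref[[s]]))
    mapped[[s]] <- matrix(pmax(m, 0), nrow(src[[s]]), ncol(src[[s]]))
  }
  reconstruct_stains(mapped[c("hematoxylin", "eosin", "residual")], stain_matrix)
}

#' Extract the three analysis channels from a patch
#'
#' The feature-extraction stage works on three planes: lightness from HSV
#' (the V channel), lightness from Lab (L*, rescaled to `[0, 1]`, D65 white
#' point), and the hematoxylin optical density from H&E color
#' deconvolution.
#'
#' @param patch integer H x W x 3 array, 0..255
#' @param stain_matrix stain basis for the hematoxylin plane
#' @return list of H x W matrices: `hsv_value`, `lab_lightness`,
#'   `hematoxylin`
#' @export
extract_channels <- function(patch, stain_matrix = he_stain_matrix()) {
  check_patch(patch)
  d <- dim(patch)
  v <- to_hsv(patch)$v
  flat <- cbind(as.vector(patch[, , 1L]), as.vector(patch[, , 2L]),
                as.vector(patch[, , 3L])) / 255
  lab <- grDevices::convertColor(flat, from = "sRGB", to = "Lab")
  l <- matrix(lab[, 1L] / 100, d[1L], d[2L])
  hem <- deconvolve_stains(patch, stain_matrix)$hematoxylin
  list(hsv_value = v, lab_lightness = l, hematoxylin = hem)
}
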