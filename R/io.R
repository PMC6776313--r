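#' Read an RGB patch from PNG or TIFF
#'
#' Returns an 8-bit integer array of shape H x W x 3 (top-left origin,
#' row-major). Grayscale images are replicated across channels; an alpha
#' channel, if present, is dropped.
#'
#' @param path file path ending in .png, .tif or .tiff
#' @return integer array H x W x 3 with values in 0..255
#' @export
read_patch <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stopf("unsupported image format: %s", ext))
  if (is.matrix(img)) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
  if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
  out <- array(as.integer(round(img * 255)), dim = dim(img))
  check_patch(out)
}

#' Write an RGB patch to PNG or TIFF
#'
#' @param patch integer array H x W x 3, values 0..255
#' @param path output path (.png, .tif, .tiff)
#' @return `path`, invisibly
#' @export
write_patch <- function(patch, path) {
  check_patch(patch)
  x <- clamp(patch, 0L, 255L) / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(x, path),
    tif = ,
    tiff = tiff::writeTIFF(x, path, bits.per.sample = 8L),
    stopf("unsupported image format: %s", ext))
  invisible(path)
}

#' Read a label mask from a 16-bit TIFF
#'
#' @param path mask file path
#' @return integer matrix of labels (0 = background)
#' @export
read_mask <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}

#' Write a label mask as a 16-bit TIFF
#'
#' @param mask integer matrix of labels (0 = background, labels < 65536)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_mask <- function(mask, path) {
  if (max(mask) > 65535L) stopf("label values exceed 16-bit range")
  tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16L)
  invisible(path)
}
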