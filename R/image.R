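#' Image container conventions
#'
#' Throughout anakit an image is a base-R numeric matrix (grayscale) or a
#' `height x width x 3` array (RGB), with intensities in `[0, 255]`. These
#' helpers validate that contract and convert to/from [EBImage::Image]
#' objects (which are `x, y(, c)`-indexed and scaled to `[0, 1]`).
#'
#' @param img matrix or 3-d array of intensities in `[0, 255]`.
#' @return `check_image()` returns `img` invisibly after validation.
#' @keywords internal
check_image <- function(img) {
  if (!(is.matrix(img) || (is.array(img) && length(dim(img)) == 3L)))
    stop("image must be a matrix (grayscale) or height x width x 3 array (RGB)")
  if (is.array(img) && !is.matrix(img) && dim(img)[3] != 3L)
    stop("a multi-channel image must have exactly 3 channels, got ", dim(img)[3])
  if (anyNA(img)) stop("image contains NA intensities")
  rng <- range(img)
  if (rng[1] < 0 || rng[2] > 255)
    stop("intensities must lie in [0, 255]; observed range [",
         rng[1], ", ", rng[2], "]")
  invisible(img)
}

n_channels <- function(img) if (is.matrix(img)) 1L else dim(img)[3]

#' @rdname check_image
#' @keywords internal
as_ebimage <- function(img) {
  check_image(img)
  if (is.matrix(img)) {
    EBImage::Image(t(img) / 255)
  } else {
    EBImage::Image(aperm(img, c(2, 1, 3)) / 255, colormode = "Color")
  }
}

#' @rdname check_image
#' @param eb an `EBImage::Image`.
#' @keywords internal
from_ebimage <- function(eb) {
  d <- dim(eb)
  x <- EBImage::imageData(eb) * 255
  x[x < 0] <- 0
  x[x > 255] <- 255
  if (length(d) == 2L) t(x) else aperm(x, c(2, 1, 3))[, , 1:3]
}

#' Read and write images
#'
#' Thin wrappers over [EBImage::readImage()]/[EBImage::writeImage()] that
#' convert between files (PNG/TIFF) and anakit's 0-255 matrix/array
#' convention. Multi-channel files are returned as RGB arrays (any alpha
#' channel is dropped).
#'
#' @param path file path (`.png`, `.tif`/`.tiff`).
#' @return `read_image()`: a matrix or `H x W x 3` array in `[0, 255]`.
#' @export
read_image <- function(path) {
  eb <- EBImage::readImage(path)
  d <- dim(eb)
  if (length(d) == 3L && d[3] > 3L) eb <- eb[, , 1:3]  # drop alpha
  if (length(d) == 3L && d[3] == 2L) eb <- eb[, , 1]   # gray + alpha
  img <- from_ebimage(eb)
  round(img)
}

#' @rdname read_image
#' @param img image matrix/array in `[0, 255]`.
#' @param bits bit depth for PNG output (8 or 16).
#' @export
write_image <- function(img, path, bits = 8L) {
  eb <- as_ebimage(img)
  EBImage::writeImage(eb, path, bits.per.sample = as.integer(bits))
  invisible(path)
}

# round-half-away-from-zero; intensities are non-negative so floor(x + .5)
round_half_up <- function(x) floor(x + 0.5)
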