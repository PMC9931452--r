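#' Cut an IIF image into four quadrants
#'
#' Raw IIF fields are divided into four sub-images (top-left, top-right,
#' bottom-left, bottom-right) before further processing; cutting augments
#' the data set and keeps downstream images small. Rows are split at
#' `floor(height / 2)` and columns at `floor(width / 2)`; for odd
#' dimensions the extra row/column goes to the bottom/right pieces.
#'
#' @param img grayscale matrix or RGB array in `[0, 255]`, at least 2 x 2.
#' @return list of 4 images in order top-left, top-right, bottom-left,
#'   bottom-right. Together they contain every input pixel exactly once.
#' @examples
#' q <- cut_quadrants(matrix(0:24, 5, 5))
#' sapply(q, nrow)  # 2 2 3 3
#' @export
cut_quadrants <- function(img) {
  check_image(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  if (h < 2) stop("image height (", h, ") must be at least 2 to cut quadrants")
  if (w < 2) stop("image width (", w, ") must be at least 2 to cut quadrants")
  hr <- h %/% 2L; wc <- w %/% 2L
  top <- seq_len(hr); bottom <- (hr + 1L):h
  left <- seq_len(wc); right <- (wc + 1L):w
  take <- if (is.matrix(img)) {
    function(r, c) img[r, c, drop = FALSE]
  } else {
    function(r, c) img[r, c, , drop = FALSE]
  }
  list(take(top, left), take(top, right), take(bottom, left), take(bottom, right))
}

#' Extract the green fluorescence channel
#'
#' The antibody signal of an IIF image lives in the green channel; red and
#' blue carry mostly noise and are removed. Grayscale input passes through
#' unchanged.
#'
#' @param img RGB array (`H x W x 3`) or grayscale matrix in `[0, 255]`.
#' @return grayscale matrix equal to the green plane.
#' @export
extract_green <- function(img) {
  check_image(img)
  nc <- n_channels(img)
  if (nc == 1L) return(img)
  if (nc != 3L) stop("expected 1 or 3 channels, got ", nc)
  img[, , 2]
}

#' Min-max normalize to the 0-255 scale
#'
#' Rescales a grayscale image so its minimum maps to 0 and its maximum to
#' 255: `round(255 * (x - min) / (max - min))`, rounding half away from
#' zero. A constant image has no contrast to stretch; it is returned as all
#' zeros with a warning.
#'
#' @param img grayscale matrix in `[0, 255]`.
#' @return integer-valued matrix with range `{0, ..., 255}`.
#' @export
minmax_normalize <- function(img) {
  check_image(img)
  if (!is.matrix(img)) stop("minmax_normalize expects a single-channel image")
  lo <- min(img); hi <- max(img)
  if (hi == lo) {
    warning("constant image (all intensities ", lo, "): returning all zeros")
    return(matrix(0, nrow(img), ncol(img)))
  }
  round_half_up(255 * (img - lo) / (hi - lo))
}

#' Preprocess one IIF image
#'
#' Applies the standard preprocessing chain: green-channel extraction,
#' optional quadrant cutting, and per-piece min-max normalization
#' (normalization follows cutting, so each quadrant is stretched to its own
#' full 0-255 range).
#'
#' @param img RGB array or grayscale matrix in `[0, 255]`.
#' @param cut cut into quadrants first? (default `TRUE`)
#' @return list of normalized grayscale matrices (length 4 if `cut`, else 1).
#' @export
preprocess_image <- function(img, cut = TRUE) {
  g <- extract_green(img)
  pieces <- if (cut) cut_quadrants(g) else list(g)
  lapply(pieces, minmax_normalize)
}

#' Preprocess a directory of images
#'
#' Reads every PNG/TIFF under `in_dir` (recursively), preprocesses it with
#' [preprocess_image()], and writes the resulting grayscale PNGs to
#' `out_dir`, mirroring the relative paths. Quadrants get suffixes
#' `_q1`..`_q4` (top-left, top-right, bottom-left, bottom-right).
#'
#' @param in_dir,out_dir input and output directories.
#' @param cut cut into quadrants? (default `TRUE`)
#' @return invisibly, a data.frame mapping input to output files.
#' @export
preprocess_dir <- function(in_dir, out_dir, cut = TRUE) {
  files <- list.files(in_dir, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                      recursive = TRUE)
  if (!length(files)) stop("no PNG/TIFF images found under ", in_dir)
  out <- vector("list", length(files))
  for (i in seq_along(files)) {
    f <- files[i]
    img <- read_image(file.path(in_dir, f))
    pieces <- preprocess_image(img, cut = cut)
    stem <- sub("\\.[^.]+$", "", f)
    paths <- if (length(pieces) == 1L) paste0(stem, ".png")
             else paste0(stem, "_q", seq_along(pieces), ".png")
    for (j in seq_along(pieces)) {
      dest <- file.path(out_dir, paths[j])
      dir.create(dirname(dest), recursive = TRUE, showWarnings = FALSE)
      write_image(pieces[[j]], dest)
    }
    out[[i]] <- data.frame(input = f, output = paths, piece = seq_along(pieces))
  }
  invisible(do.call(rbind, out))
}
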