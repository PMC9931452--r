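#' Segmentation configuration
#'
#' Collects the tunable parameters of the cell-segmentation stage. Defaults
#' follow the published recipe where it states values (the three region
#' filters) and common practice where it does not (blur kernel, marker
#' thresholds); see the methods vignette for the rationale behind each.
#'
#' @param blur_kernel Gaussian blur kernel size in pixels (odd integer).
#' @param blur_sigma Gaussian sigma; default derived from the kernel size as
#'   `0.3 * ((k - 1) / 2 - 1) + 0.8`.
#' @param clean_kernel square structuring-element size for morphological
#'   opening (odd integer).
#' @param fg_fraction sure-foreground distance threshold as a fraction of
#'   the maximum distance-transform value.
#' @param bg_dilate_iter dilation iterations delimiting sure background.
#' @param diameter_range accepted equivalent-diameter interval in pixels.
#' @param margin minimum centroid distance from the image edge in pixels.
#' @param min_brightness centre brightness must exceed this intensity.
#' @return a list of class `segment_config`.
#' @export
segment_config <- function(blur_kernel = 5L,
                           blur_sigma = NULL,
                           clean_kernel = 3L,
                           fg_fraction = 0.4,
                           bg_dilate_iter = 3L,
                           diameter_range = c(30, 120),
                           margin = 20,
                           min_brightness = 50) {
  if (is.null(blur_sigma)) blur_sigma <- 0.3 * ((blur_kernel - 1) / 2 - 1) + 0.8
  stopifnot(blur_kernel >= 1, blur_kernel %% 2 == 1,
            clean_kernel >= 1, clean_kernel %% 2 == 1,
            fg_fraction > 0, fg_fraction < 1,
            bg_dilate_iter >= 1,
            length(diameter_range) == 2, diameter_range[1] <= diameter_range[2])
  structure(list(blur_kernel = as.integer(blur_kernel), blur_sigma = blur_sigma,
                 clean_kernel = as.integer(clean_kernel),
                 fg_fraction = fg_fraction,
                 bg_dilate_iter = as.integer(bg_dilate_iter),
                 diameter_range = diameter_range, margin = margin,
                 min_brightness = min_brightness),
            class = "segment_config")
}

check_mask <- function(mask) {
  if (!is.matrix(mask)) stop("mask must be a matrix")
  if (!all(mask %in% c(0, 1))) stop("mask values must be 0 or 1")
  invisible(mask)
}

mask_as_eb <- function(mask) EBImage::Image(t(mask))
mask_from_eb <- function(eb) (t(EBImage::imageData(eb)) > 0) * 1

#' Otsu threshold of a grayscale image
#'
#' Picks the intensity threshold maximizing the between-class variance of
#' the 256-bin intensity histogram (background = intensities at or below
#' the threshold, foreground above). This splits cells from the dark slide
#' background without manual tuning.
#'
#' @param img single-channel matrix in `[0, 255]`; must not be constant.
#' @return list with `threshold` (integer in 0..254) and `mask`
#'   (binary matrix, 1 where `img > threshold`).
#' @export
otsu_threshold <- function(img) {
  check_image(img)
  if (!is.matrix(img)) stop("otsu_threshold expects a single-channel image")
  v <- as.integer(round_half_up(img))
  if (min(v) == max(v))
    stop("constant image: no foreground/background separation possible")
  counts <- tabulate(v + 1L, nbins = 256L)
  n <- sum(counts)
  p <- counts / n
  omega <- cumsum(p)                      # class-0 weight up to level t
  mu <- cumsum(p * (0:255))               # first moment up to level t
  mu_t <- mu[256]
  # between-class variance for thresholds t = 0..254
  w0 <- omega[1:255]; m0 <- mu[1:255]
  sigma_b <- (mu_t * w0 - m0)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- -Inf    # empty classes carry no split
  t_star <- which.max(sigma_b) - 1L       # smallest maximizer
  list(threshold = t_star, mask = (img > t_star) * 1)
}

#' Morphological opening of a binary mask
#'
#' Erosion followed by dilation with a square structuring element, removing
#' foreground specks smaller than the element (imaging noise surviving the
#' threshold).
#'
#' @param mask binary 0/1 matrix.
#' @param kernel_size side of the square structuring element (odd integer).
#' @return cleaned binary matrix.
#' @export
clean_mask <- function(mask, kernel_size = 3L) {
  check_mask(mask)
  if (kernel_size > nrow(mask) || kernel_size > ncol(mask))
    stop("kernel (", kernel_size, ") larger than image ",
         nrow(mask), "x", ncol(mask))
  kern <- EBImage::makeBrush(kernel_size, shape = "box")
  eb <- mask_as_eb(mask)
  mask_from_eb(EBImage::dilate(EBImage::erode(eb, kern), kern))
}

#' Build watershed markers from a cleaned mask
#'
#' Standard marker construction for seeded watershed: sure background is
#' the complement of a dilated mask; sure foreground is the set of pixels
#' whose exact Euclidean distance to the background is at least
#' `fg_fraction` of the maximum distance (cell cores); everything between
#' is the unknown region the watershed must apportion. Each 8-connected
#' sure-foreground component receives its own label starting at 2.
#'
#' @param mask cleaned binary 0/1 matrix.
#' @param fg_fraction distance-transform fraction defining sure foreground.
#' @param dilate_iter iterations of 3x3 dilation bounding sure background.
#' @return integer matrix: 0 unknown, 1 sure background, >= 2 seed labels.
#' @export
build_markers <- function(mask, fg_fraction = 0.4, dilate_iter = 3L) {
  check_mask(mask)
  if (sum(mask) == 0) {
    message("empty mask: marker map is all sure background")
    return(matrix(1L, nrow(mask), ncol(mask)))
  }
  kern <- EBImage::makeBrush(3L, shape = "box")
  dil <- mask_as_eb(mask)
  for (i in seq_len(dilate_iter)) dil <- EBImage::dilate(dil, kern)
  dil <- mask_from_eb(dil)
  dist <- t(EBImage::imageData(EBImage::distmap(mask_as_eb(mask))))
  sure_fg <- (dist >= fg_fraction * max(dist)) * 1
  comp <- cc_label8(sure_fg)
  markers <- matrix(0L, nrow(mask), ncol(mask))
  markers[dil == 0] <- 1L
  sel <- comp > 0
  markers[sel] <- comp[sel] + 1L
  markers
}

#' Marker-based watershed segmentation
#'
#' Floods the image's gradient-magnitude landscape from the marker seeds:
#' flat cell interiors and flat background are basins, intensity edges are
#' the ridges, so the watershed line settles on the steepest part of a
#' cell's rim rather than somewhere inside its faint halo. Every unknown
#' pixel is assigned to the background or to one of the foreground seeds;
#' pixels where two basins meet form the watershed lines and carry the
#' sentinel value -1.
#'
#' @param img grayscale matrix in `[0, 255]` (same shape as `markers`).
#' @param markers marker map from [build_markers()].
#' @return integer matrix: -1 watershed line, 1 background, >= 2 cell labels.
#' @export
watershed_cells <- function(img, markers) {
  check_image(img)
  if (!is.matrix(img)) stop("watershed_cells expects a single-channel image")
  if (!identical(dim(img), dim(markers)))
    stop("image and marker shapes differ: ", paste(dim(img), collapse = "x"),
         " vs ", paste(dim(markers), collapse = "x"))
  storage.mode(markers) <- "integer"
  h <- nrow(img); w <- ncol(img)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (img[, 3:w] - img[, 1:(w - 2)]) / 2
  gy[2:(h - 1), ] <- (img[3:h, ] - img[1:(h - 2), ]) / 2
  ws_flood(sqrt(gx^2 + gy^2), markers)
}

region_stats <- function(lab, img, id) {
  sel <- which(lab == id, arr.ind = TRUE)
  rows <- sel[, 1] - 1L; cols <- sel[, 2] - 1L  # 0-based
  area <- nrow(sel)
  centroid <- c(mean(rows), mean(cols))
  bbox <- c(min(rows), min(cols), max(rows) + 1L, max(cols) + 1L)
  mask <- matrix(0, bbox[3] - bbox[1], bbox[4] - bbox[2])
  mask[cbind(rows - bbox[1] + 1L, cols - bbox[2] + 1L)] <- 1
  cr <- round_half_up(centroid[1]); cc <- round_half_up(centroid[2])
  rr <- pmax(0, cr - 1):pmin(nrow(img) - 1, cr + 1)
  cw <- pmax(0, cc - 1):pmin(ncol(img) - 1, cc + 1)
  brightness <- mean(img[rr + 1, cw + 1])
  structure(list(label = id, mask = mask, bbox = bbox, centroid = centroid,
                 area = area, equivalent_diameter = 2 * sqrt(area / pi),
                 centre_brightness = brightness),
            class = "cell_region")
}

#' Filter watershed regions with the published acceptance rules
#'
#' A segmented region is kept as a cell only when it looks like one:
#' equivalent diameter (diameter of the equal-area circle) within
#' `diameter_range`, centroid at least `margin` pixels from every image
#' edge, and centre brightness (mean intensity over the 3x3 neighbourhood
#' of the rounded centroid) above `min_brightness`. Defaults are
#' 30-120 px, 20 px and 50 intensity units.
#'
#' @param lab labelled grid from [watershed_cells()].
#' @param img the intensity image the labels refer to.
#' @param diameter_range,margin,min_brightness filter parameters.
#' @return list of `cell_region` objects (possibly empty), ordered by label.
#' @export
filter_regions <- function(lab, img, diameter_range = c(30, 120),
                           margin = 20, min_brightness = 50) {
  check_image(img)
  ids <- sort(unique(lab[lab >= 2L]))
  h <- nrow(img); w <- ncol(img)
  keep <- list()
  for (id in ids) {
    reg <- region_stats(lab, img, id)
    d <- reg$equivalent_diameter
    edge_dist <- min(reg$centroid[1], reg$centroid[2],
                     h - 1 - reg$centroid[1], w - 1 - reg$centroid[2])
    if (d >= diameter_range[1] && d <= diameter_range[2] &&
        edge_dist >= margin &&
        reg$centre_brightness > min_brightness)
      keep[[length(keep) + 1L]] <- reg
  }
  keep
}

#' Summarize cell regions as a data frame
#'
#' @param regions list of `cell_region` objects from [filter_regions()].
#' @return data.frame with one row per region (label, bbox, centroid,
#'   area, equivalent diameter, centre brightness).
#' @export
regions_table <- function(regions) {
  if (!length(regions))
    return(data.frame(label = integer(), row0 = integer(), col0 = integer(),
                      row1 = integer(), col1 = integer(),
                      centroid_row = numeric(), centroid_col = numeric(),
                      area = integer(), equivalent_diameter = numeric(),
                      centre_brightness = numeric()))
  do.call(rbind, lapply(regions, function(r)
    data.frame(label = r$label, row0 = r$bbox[1], col0 = r$bbox[2],
               row1 = r$bbox[3], col1 = r$bbox[4],
               centroid_row = r$centroid[1], centroid_col = r$centroid[2],
               area = r$area, equivalent_diameter = r$equivalent_diameter,
               centre_brightness = r$centre_brightness)))
}

#' Crop cell rectangles from an image
#'
#' @param regions list of `cell_region` objects.
#' @param img source intensity image.
#' @return list of rectangular crops (matrices), one per region, in order.
#' @export
crop_cells <- function(regions, img) {
  check_image(img)
  lapply(regions, function(r) {
    b <- r$bbox
    if (b[1] < 0 || b[2] < 0 || b[3] > nrow(img) || b[4] > ncol(img))
      stop("region bbox (", paste(b, collapse = ","),
           ") outside image bounds ", nrow(img), "x", ncol(img))
    img[(b[1] + 1):b[3], (b[2] + 1):b[4], drop = FALSE]
  })
}

#' Segment all cells in a preprocessed image
#'
#' Runs the full chain: Gaussian blur, Otsu threshold, morphological
#' opening, marker construction, marker-based watershed, region filtering
#' and rectangular cropping. Brightness filtering and crops use the
#' original (unblurred) intensities.
#'
#' @param img preprocessed grayscale matrix in `[0, 255]`.
#' @param config a [segment_config()].
#' @return list with `threshold`, `mask`, `markers`, `labels` (watershed
#'   grid), `regions` (filtered `cell_region` list) and `crops`.
#' @export
segment_cells <- function(img, config = segment_config()) {
  check_image(img)
  blurred <- from_ebimage(EBImage::gblur(as_ebimage(img),
                                         sigma = config$blur_sigma))
  ot <- otsu_threshold(blurred)
  mask <- clean_mask(ot$mask, config$clean_kernel)
  markers <- build_markers(mask, config$fg_fraction, config$bg_dilate_iter)
  labels <- watershed_cells(blurred, markers)
  regions <- filter_regions(labels, img, config$diameter_range,
                            config$margin, config$min_brightness)
  list(threshold = ot$threshold, mask = mask, markers = markers,
       labels = labels, regions = regions, crops = crop_cells(regions, img))
}
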