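#' Local binary pattern configuration
#'
#' An LBP code compares a pixel with `N` neighbours equally spaced on a
#' circle of radius `s`: bit `i` is set when the neighbour at angle
#' `(360/N) * i` is at least as bright as the centre. `sign_at_zero`
#' controls the bit assigned to an exact tie (default 1, so constant
#' regions give the all-ones code and the descriptor is stable under flat
#' patches).
#'
#' @param N neighbour count, 4 or 8.
#' @param s circle radius in pixels (> 0).
#' @param sign_at_zero bit for a zero intensity difference, 0 or 1.
#' @return a list of class `lbp_config`.
#' @export
lbp_config <- function(N = 8L, s = 1, sign_at_zero = 1L) {
  if (!N %in% c(4L, 8L)) stop("N must be 4 or 8, got ", N)
  if (s <= 0) stop("radius s must be positive")
  if (!sign_at_zero %in% c(0L, 1L)) stop("sign_at_zero must be 0 or 1")
  structure(list(N = as.integer(N), s = s,
                 sign_at_zero = as.integer(sign_at_zero)),
            class = "lbp_config")
}

# Neighbour displacements (dr, dc) for angles theta_i = (360/N) * i,
# measured with the column axis as x and the row axis as y. Values within
# 1e-9 of an integer are snapped so axis-aligned samples need no
# interpolation.
lbp_offsets <- function(cfg) {
  i <- seq_len(cfg$N) - 1
  theta <- 2 * pi * i / cfg$N
  dc <- cfg$s * cos(theta)
  dr <- cfg$s * sin(theta)
  snap <- function(x) ifelse(abs(x - round(x)) < 1e-9, round(x), x)
  cbind(dr = snap(dr), dc = snap(dc))
}

# bilinear sample of img at 0-based fractional position (r, c)
bilinear_at <- function(img, r, c) {
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  r1 <- min(r0 + 1, nrow(img) - 1); c1 <- min(c0 + 1, ncol(img) - 1)
  (1 - fr) * (1 - fc) * img[r0 + 1, c0 + 1] +
    (1 - fr) * fc * img[r0 + 1, c1 + 1] +
    fr * (1 - fc) * img[r1 + 1, c0 + 1] +
    fr * fc * img[r1 + 1, c1 + 1]
}

#' LBP code at one position
#'
#' @param img grayscale matrix in `[0, 255]`.
#' @param r 0-based position `c(row, col)`, at least `s` pixels from every
#'   border (diagonal samples use bilinear interpolation).
#' @param cfg an [lbp_config()].
#' @return integer code in `[0, 2^N - 1]`.
#' @export
lbp_code <- function(img, r, cfg = lbp_config()) {
  check_image(img)
  s <- ceiling(cfg$s - 1e-9)
  if (r[1] < s || r[2] < s || r[1] > nrow(img) - 1 - s || r[2] > ncol(img) - 1 - s)
    stop("position (", r[1], ",", r[2], ") closer than s=", cfg$s,
         " to the image border")
  off <- lbp_offsets(cfg)
  centre <- img[r[1] + 1, r[2] + 1]
  code <- 0L
  for (i in seq_len(cfg$N)) {
    v <- bilinear_at(img, r[1] + off[i, 1], r[2] + off[i, 2])
    d <- v - centre
    # 8-bit intensities differ by >= 1, so sub-1e-6 residue is bilinear
    # round-off on an exact tie
    bit <- if (d > 1e-6) 1L else if (d < -1e-6) 0L else cfg$sign_at_zero
    code <- code + bit * bitwShiftL(1L, i - 1L)
  }
  code
}

# shifted copy of the interior block: value at (r + dr, c + dc) for every
# interior position (r, c); dr/dc may be fractional (bilinear).
shift_block <- function(img, rows, cols, dr, dc) {
  if (dr == round(dr) && dc == round(dc)) {
    img[rows + dr, cols + dc, drop = FALSE]
  } else {
    r0 <- floor(dr); c0 <- floor(dc)
    fr <- dr - r0; fc <- dc - c0
    (1 - fr) * (1 - fc) * img[rows + r0, cols + c0, drop = FALSE] +
      (1 - fr) * fc * img[rows + r0, cols + c0 + 1, drop = FALSE] +
      fr * (1 - fc) * img[rows + r0 + 1, cols + c0, drop = FALSE] +
      fr * fc * img[rows + r0 + 1, cols + c0 + 1, drop = FALSE]
  }
}

# matrix of LBP codes over the interior (margin s); vectorized
lbp_code_map <- function(img, cfg) {
  s <- ceiling(cfg$s - 1e-9)
  h <- nrow(img); w <- ncol(img)
  if (h <= 2 * s + 1 || w <= 2 * s + 1)
    stop("image ", h, "x", w, " too small for LBP radius s=", cfg$s)
  rows <- (s + 1):(h - s); cols <- (s + 1):(w - s)
  centre <- img[rows, cols, drop = FALSE]
  off <- lbp_offsets(cfg)
  code <- matrix(0L, length(rows), length(cols))
  for (i in seq_len(cfg$N)) {
    d <- shift_block(img, rows, cols, off[i, 1], off[i, 2]) - centre
    bit <- (d > 1e-6) | (abs(d) <= 1e-6 & cfg$sign_at_zero == 1L)
    code <- code + bit * bitwShiftL(1L, i - 1L)
  }
  code
}

new_feature <- function(values, descriptor, label = NA_character_) {
  structure(as.numeric(values), descriptor = descriptor, label = label,
            class = "ana_feature")
}

#' @export
print.ana_feature <- function(x, ...) {
  cat("<ana_feature> ", attr(x, "descriptor"), ", length ", length(x),
      if (!is.na(attr(x, "label"))) paste0(", label ", attr(x, "label")), "\n",
      sep = "")
  invisible(x)
}

#' LBP histogram of an image
#'
#' Histogram of LBP codes over all interior positions (those at least `s`
#' pixels from the border). The histogram length is `2^N` and its total
#' equals the number of interior positions, `(H - 2s)(W - 2s)`.
#'
#' @inheritParams lbp_code
#' @return `ana_feature` vector of length `2^N`.
#' @export
lbp_histogram <- function(img, cfg = lbp_config()) {
  check_image(img)
  codes <- lbp_code_map(img, cfg)
  new_feature(tabulate(codes + 1L, nbins = 2L^cfg$N), "LBP")
}

#' Co-occurrence pair configuration
#'
#' CoALBP pairs the LBP codes of two pixels separated by a displacement of
#' length `r` along each of the four orientations 0, 45, 90 and 135
#' degrees. Displacements are lattice vectors — `(0,r)`, `(r,r)`, `(r,0)`,
#' `(r,-r)` in `(row, col)` form — so all samples fall on pixel centres and
#' 90-degree image rotations permute the configuration set exactly.
#'
#' @param r displacement distance in pixels (positive integer).
#' @return a list of class `pair_config`.
#' @export
pair_config <- function(r = 2L) {
  if (r <= 0 || r != round(r)) stop("pair interval r must be a positive integer")
  structure(list(r = as.integer(r), phis = c(0L, 45L, 90L, 135L)),
            class = "pair_config")
}

pair_displacements <- function(pair) {
  r <- pair$r
  list(`0` = c(0L, r), `45` = c(r, r), `90` = c(r, 0L), `135` = c(r, -r))
}

# per-orientation (code_at_base, code_at_displaced) vectors from a code map
pair_codes <- function(codes, disp) {
  h <- nrow(codes); w <- ncol(codes)
  dr <- disp[1]; dc <- disp[2]
  if (h - abs(dr) < 1 || w - abs(dc) < 1)
    stop("image too small for pair displacement (", dr, ",", dc, ")")
  rows_a <- (max(0, -dr) + 1):(h - max(0, dr))
  cols_a <- (max(0, -dc) + 1):(w - max(0, dc))
  a <- codes[rows_a, cols_a, drop = FALSE]
  b <- codes[rows_a + dr, cols_a + dc, drop = FALSE]
  list(a = as.vector(a), b = as.vector(b))
}

#' CoALBP histogram of an image
#'
#' For each of the four orientations, the 2-D co-occurrence histogram of
#' LBP code pairs at displacement `r` is accumulated and flattened; the
#' four blocks are concatenated into a vector of length `4 * (2^N)^2`.
#' Each block's total equals the number of valid pair positions for its
#' orientation.
#'
#' @inheritParams lbp_code
#' @param pair a [pair_config()].
#' @return `ana_feature` vector of length `4 * (2^N)^2`.
#' @export
coalbp_histogram <- function(img, cfg = lbp_config(N = 4L, s = 1),
                             pair = pair_config(r = 2L)) {
  check_image(img)
  codes <- lbp_code_map(img, cfg)
  nc <- 2L^cfg$N
  blocks <- lapply(pair_displacements(pair), function(disp) {
    p <- pair_codes(codes, disp)
    tabulate(p$a * nc + p$b + 1L, nbins = nc * nc)
  })
  new_feature(unlist(blocks, use.names = FALSE), "CoALBP")
}

# rotate a 4-bit code left by k neighbour steps (one step = 90 degrees)
rot4 <- function(code, k) {
  k <- k %% 4L
  bitwAnd(bitwOr(bitwShiftL(code, k), bitwShiftR(code, 4L - k)), 15L)
}

#' Rotation-invariant label table for LBP pairs
#'
#' Builds the lookup assigning every (code_a, code_b, orientation) triple a
#' rotation-invariant label. Two pair configurations share a label when a
#' rotation of the whole image maps one onto the other: rotating by 90
#' degrees advances the orientation and cyclically shifts both 4-bit
#' codes, and rotating by 180 degrees additionally swaps the pair order
#' (the displacement reverses). For `N = 4` this partitions the
#' `4 * 256` triples into `(16^2 + 16) / 2 = 136` classes.
#'
#' @param cfg an [lbp_config()] with `N = 4` (the only neighbour count for
#'   which the 136-class table arises).
#' @return object of class `ric_label_table`: `n_labels`, and `maps`, a
#'   list of four length-256 integer vectors (one per orientation) mapping
#'   the flat pair index `16 * code_a + code_b` to a label in `0..135`.
#' @export
build_label_table <- function(cfg = lbp_config(N = 4L, s = 1)) {
  if (cfg$N != 4L)
    stop("rotation-invariant pair labels are defined for N = 4 (got N = ",
         cfg$N, ")")
  ab <- expand.grid(b = 0:15, a = 0:15)   # flat index = 16 a + b
  a <- ab$a; b <- ab$b
  # canonical representative under the 180-degree flip (a,b) -> (s2 b, s2 a)
  enc <- function(x, y) 16L * x + y
  flip <- enc(rot4(b, 2L), rot4(a, 2L))
  canon <- pmin(enc(a, b), flip)
  classes <- sort(unique(canon))
  pairclass <- match(canon, classes) - 1L          # 0..135 per ordered pair
  # orientation k-steps: 0 and 45 degrees share the identity alignment,
  # 90 and 135 are one 90-degree step on; codes are counter-rotated first
  ksteps <- c(`0` = 0L, `45` = 0L, `90` = 1L, `135` = 1L)
  maps <- lapply(ksteps, function(k) {
    a2 <- rot4(a, (4L - k) %% 4L)
    b2 <- rot4(b, (4L - k) %% 4L)
    pairclass[enc(a2, b2) + 1L]
  })
  structure(list(n_labels = length(classes), maps = maps, N = 4L,
                 phis = c(0L, 45L, 90L, 135L)),
            class = "ric_label_table")
}

#' RIC-LBP histogram of an image
#'
#' The rotation-invariant co-occurrence LBP descriptor: at each of the
#' configured `(s, r)` scales — LBP radius `s`, pair interval `r` — LBP
#' pairs over all four orientations are mapped through the rotation-
#' invariant label table and accumulated into one 136-bin histogram, which
#' is L1-normalized. The per-scale histograms are concatenated; with the
#' default three scales `(1,2), (2,4), (4,8)` the descriptor has length
#' `136 * 3 = 408`.
#'
#' @param img grayscale matrix in `[0, 255]`.
#' @param scales list of `c(s, r)` pairs.
#' @param table label table from [build_label_table()]; rebuilt if `NULL`.
#' @return `ana_feature` vector of length `136 * length(scales)`.
#' @export
riclbp_histogram <- function(img,
                             scales = list(c(1, 2), c(2, 4), c(4, 8)),
                             table = NULL) {
  check_image(img)
  if (is.null(table)) table <- build_label_table()
  blocks <- lapply(scales, function(sr) {
    cfg <- lbp_config(N = 4L, s = sr[1])
    codes <- lbp_code_map(img, cfg)
    disp <- pair_displacements(pair_config(r = sr[2]))
    h <- numeric(table$n_labels)
    for (phi in names(disp)) {
      p <- pair_codes(codes, disp[[phi]])
      lab <- table$maps[[phi]][16L * p$a + p$b + 1L]
      h <- h + tabulate(lab + 1L, nbins = table$n_labels)
    }
    tot <- sum(h)
    if (tot > 0) h <- h / tot
    h
  })
  new_feature(unlist(blocks, use.names = FALSE), "RIC-LBP")
}

#' Fuse SIFT and RIC-LBP descriptors
#'
#' Concatenates the pooled 128-dim SIFT descriptor with the 408-dim
#' RIC-LBP descriptor into the 536-dim FUS vector — the fused feature that
#' achieved the best classification accuracy among the classical
#' descriptors.
#'
#' @param sift length-128 SIFT feature.
#' @param riclbp length-408 RIC-LBP feature.
#' @return `ana_feature` vector of length 536, descriptor `"FUS"`.
#' @export
fuse_features <- function(sift, riclbp) {
  if (length(sift) != 128L)
    stop("SIFT part must have length 128, got ", length(sift))
  if (length(riclbp) != 408L)
    stop("RIC-LBP part must have length 408, got ", length(riclbp))
  new_feature(c(as.numeric(sift), as.numeric(riclbp)), "FUS")
}

#' Extract a named descriptor from cell crops
#'
#' Convenience dispatcher running one descriptor over a list of crops and
#' assembling the feature matrix the classifiers consume.
#'
#' @param crops list of grayscale matrices.
#' @param descriptor one of `"lbp"`, `"coalbp"`, `"riclbp"`, `"sift"`,
#'   `"fus"`.
#' @param labels optional class labels, recycled onto the result.
#' @return data.frame with columns `label` and `v1..vd`.
#' @export
extract_features <- function(crops,
                             descriptor = c("riclbp", "lbp", "coalbp",
                                            "sift", "fus"),
                             labels = NULL) {
  descriptor <- match.arg(descriptor)
  table <- if (descriptor %in% c("riclbp", "fus")) build_label_table() else NULL
  fv <- lapply(crops, function(crop) {
    switch(descriptor,
           lbp = lbp_histogram(crop),
           coalbp = coalbp_histogram(crop),
           riclbp = riclbp_histogram(crop, table = table),
           sift = sift_descriptor(crop),
           fus = fuse_features(sift_descriptor(crop),
                               riclbp_histogram(crop, table = table)))
  })
  X <- do.call(rbind, lapply(fv, as.numeric))
  colnames(X) <- paste0("v", seq_len(ncol(X)))
  out <- data.frame(label = if (is.null(labels)) NA_character_ else labels,
                    X, check.names = FALSE)
  attr(out, "descriptor") <- attr(fv[[1]], "descriptor")
  out
}
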