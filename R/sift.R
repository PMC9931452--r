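# Scale-invariant feature transform, self-contained.
#
# Cell crops are resized to 128 x 128 and described by a difference-of-
# Gaussians keypoint detector plus the standard 4x4-cell, 8-orientation-bin
# gradient descriptor. Per-keypoint descriptors are mean-pooled into a
# single 128-vector per crop. Everything is deterministic.

SIFT_SIZE <- 128L       # working image side after resize
SIFT_OCTAVES <- 3L
SIFT_NSPO <- 2L         # DoG intervals per octave
SIFT_SIGMA0 <- 1.6
SIFT_CONTRAST <- 0.015  # |DoG| threshold on [0,1] intensities
SIFT_EDGE_R <- 10       # principal-curvature ratio limit
SIFT_MAX_KP <- 40L      # strongest keypoints kept per crop

gblur_mat <- function(m, sigma) {
  from_ebimage(EBImage::gblur(as_ebimage(m * 255), sigma = sigma)) / 255
}

grad_xy <- function(m) {
  h <- nrow(m); w <- ncol(m)
  gx <- matrix(0, h, w); gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (m[, 3:w] - m[, 1:(w - 2)]) / 2
  gy[2:(h - 1), ] <- (m[3:h, ] - m[1:(h - 2), ]) / 2
  list(gx = gx, gy = gy)
}

# Gaussian/DoG pyramid over octaves; each octave holds NSPO + 3 blur levels
sift_pyramid <- function(base) {
  k <- 2^(1 / SIFT_NSPO)
  octaves <- vector("list", SIFT_OCTAVES)
  cur <- gblur_mat(base, sqrt(SIFT_SIGMA0^2 - 0.5^2))  # assume sigma 0.5 input
  for (o in seq_len(SIFT_OCTAVES)) {
    n_lev <- SIFT_NSPO + 3L
    gauss <- vector("list", n_lev)
    gauss[[1]] <- cur
    for (i in 2:n_lev) {
      sig_prev <- SIFT_SIGMA0 * k^(i - 2)
      gauss[[i]] <- gblur_mat(gauss[[i - 1]], sig_prev * sqrt(k^2 - 1))
    }
    dog <- lapply(seq_len(n_lev - 1L), function(i) gauss[[i + 1]] - gauss[[i]])
    octaves[[o]] <- list(gauss = gauss, dog = dog)
    nxt <- gauss[[SIFT_NSPO + 1L]]
    cur <- nxt[seq(1, nrow(nxt), by = 2), seq(1, ncol(nxt), by = 2), drop = FALSE]
  }
  octaves
}

# strict 26-neighbourhood extrema of the middle DoG levels of one octave
dog_extrema <- function(dog, level) {
  d <- dog[[level]]
  h <- nrow(d); w <- ncol(d)
  if (h < 3 || w < 3) return(NULL)
  ri <- 2:(h - 1); ci <- 2:(w - 1)
  centre <- d[ri, ci]
  strong <- abs(centre) >= SIFT_CONTRAST
  if (!any(strong)) return(NULL)
  is_max <- strong & TRUE; is_min <- strong & TRUE
  for (lev in (level - 1L):(level + 1L)) {
    dd <- dog[[lev]]
    for (dr in -1:1) for (dc in -1:1) {
      if (lev == level && dr == 0 && dc == 0) next
      nb <- dd[ri + dr, ci + dc]
      is_max <- is_max & (centre > nb)
      is_min <- is_min & (centre < nb)
    }
  }
  sel <- which(is_max | is_min, arr.ind = TRUE)
  if (!nrow(sel)) return(NULL)
  r <- sel[, 1] + 1L; c <- sel[, 2] + 1L
  # principal-curvature (edge) rejection from the 2x2 Hessian of D
  idx <- cbind(r, c)
  dxx <- d[cbind(r, c + 1L)] + d[cbind(r, c - 1L)] - 2 * d[idx]
  dyy <- d[cbind(r + 1L, c)] + d[cbind(r - 1L, c)] - 2 * d[idx]
  dxy <- (d[cbind(r + 1L, c + 1L)] + d[cbind(r - 1L, c - 1L)] -
          d[cbind(r + 1L, c - 1L)] - d[cbind(r - 1L, c + 1L)]) / 4
  tr <- dxx + dyy; det <- dxx * dyy - dxy^2
  er <- SIFT_EDGE_R
  ok <- det > 0 & tr^2 / det < (er + 1)^2 / er
  if (!any(ok)) return(NULL)
  data.frame(row = r[ok], col = c[ok], level = level,
             response = abs(d[idx])[ok])
}

# dominant gradient orientation at a keypoint (36-bin weighted histogram,
# smoothed, parabolic peak interpolation)
kp_orientation <- function(gr, row, col, sigma) {
  h <- nrow(gr$gx); w <- ncol(gr$gx)
  sw <- 1.5 * sigma
  rad <- max(1L, round(3 * sw))
  rr <- max(1, row - rad):min(h, row + rad)
  cc <- max(1, col - rad):min(w, col + rad)
  dx <- outer(rep(1, length(rr)), cc - col)
  dy <- outer(rr - row, rep(1, length(cc)))
  wgt <- exp(-(dx^2 + dy^2) / (2 * sw^2))
  gx <- gr$gx[rr, cc]; gy <- gr$gy[rr, cc]
  mag <- sqrt(gx^2 + gy^2)
  ang <- atan2(gy, gx) %% (2 * pi)
  bin <- floor(ang / (2 * pi) * 36) %% 36
  hist <- numeric(36)
  acc <- rowsum(as.vector(mag * wgt), as.vector(bin))
  hist[as.integer(rownames(acc)) + 1L] <- acc
  for (i in 1:2) hist <- (hist + c(hist[-1], hist[1]) + c(hist[36], hist[-36])) / 3
  b <- which.max(hist)
  lo <- hist[if (b == 1) 36 else b - 1]; hi <- hist[if (b == 36) 1 else b + 1]
  denom <- lo - 2 * hist[b] + hi
  off <- if (abs(denom) > 1e-12) 0.5 * (lo - hi) / denom else 0
  ((b - 1 + off) * 2 * pi / 36) %% (2 * pi)
}

# 4x4x8 gradient descriptor at (row, col) with scale sigma and the given
# orientation, computed on one Gaussian level; trilinear soft binning.
kp_descriptor <- function(gr, row, col, sigma, ori) {
  d <- 4L; nb <- 8L
  cell <- 3 * sigma
  h <- nrow(gr$gx); w <- ncol(gr$gx)
  rad <- min(round(cell * (d + 1) / 2 * sqrt(2)) + 1, max(h, w))
  rr <- max(1, row - rad):min(h, row + rad)
  cc <- max(1, col - rad):min(w, col + rad)
  dx <- as.vector(outer(rep(1, length(rr)), cc - col))
  dy <- as.vector(outer(rr - row, rep(1, length(cc))))
  ct <- cos(ori); st <- sin(ori)
  xr <- (ct * dx + st * dy) / cell
  yr <- (-st * dx + ct * dy) / cell
  u <- xr + d / 2 - 0.5; v <- yr + d / 2 - 0.5
  keep <- u > -1 & u < d & v > -1 & v < d
  if (!any(keep)) return(numeric(d * d * nb))
  u <- u[keep]; v <- v[keep]
  gx <- gr$gx[rr, cc][keep]; gy <- gr$gy[rr, cc][keep]
  mag <- sqrt(gx^2 + gy^2)
  wgt <- mag * exp(-(xr[keep]^2 + yr[keep]^2) / (2 * (0.5 * d)^2))
  ang <- (atan2(gy, gx) - ori) %% (2 * pi)
  ob <- ang / (2 * pi) * nb
  u0 <- floor(u); v0 <- floor(v); o0 <- floor(ob)
  fu <- u - u0; fv <- v - v0; fo <- ob - o0
  acc <- numeric(d * d * nb)
  for (du in 0:1) for (dv in 0:1) for (do in 0:1) {
    ui <- u0 + du; vi <- v0 + dv
    ok <- ui >= 0 & ui < d & vi >= 0 & vi < d
    if (!any(ok)) next
    oi <- (o0[ok] + do) %% nb
    wcomb <- wgt[ok] *
      (if (du) fu[ok] else 1 - fu[ok]) *
      (if (dv) fv[ok] else 1 - fv[ok]) *
      (if (do) fo[ok] else 1 - fo[ok])
    idx <- (vi[ok] * d + ui[ok]) * nb + oi + 1
    s <- rowsum(wcomb, idx)
    acc[as.integer(rownames(s))] <- acc[as.integer(rownames(s))] + s
  }
  nrm <- sqrt(sum(acc^2))
  if (nrm < 1e-12) return(acc)
  acc <- pmin(acc / nrm, 0.2)
  acc / sqrt(sum(acc^2))
}

#' SIFT keypoints and descriptors of a cell crop
#'
#' Resizes the crop to 128 x 128 (bilinear), detects difference-of-Gaussian
#' extrema over 3 octaves, assigns each surviving keypoint its dominant
#' gradient orientation, and computes the 128-dimensional gradient
#' descriptor. At most 40 keypoints (strongest DoG response) are kept.
#'
#' @param img grayscale matrix in `[0, 255]`.
#' @return list with `descriptors` (matrix, one row per keypoint, 128
#'   columns; zero rows when no keypoint passes the tests) and `keypoints`
#'   (data.frame: row, col, octave, sigma, orientation, response; 0-based
#'   coordinates in the 128 x 128 frame).
#' @export
sift_keypoints <- function(img) {
  check_image(img)
  if (!is.matrix(img)) stop("sift expects a single-channel crop")
  base <- from_ebimage(EBImage::resize(as_ebimage(img), w = SIFT_SIZE,
                                       h = SIFT_SIZE)) / 255
  pyr <- sift_pyramid(base)
  k <- 2^(1 / SIFT_NSPO)
  cand <- list()
  for (o in seq_along(pyr)) {
    for (lev in 2:(length(pyr[[o]]$dog) - 1L)) {
      e <- dog_extrema(pyr[[o]]$dog, lev)
      if (!is.null(e)) { e$octave <- o; cand[[length(cand) + 1L]] <- e }
    }
  }
  empty <- list(descriptors = matrix(numeric(), 0, 128),
                keypoints = data.frame())
  if (!length(cand)) return(empty)
  cand <- do.call(rbind, cand)
  ord <- order(-cand$response, cand$octave, cand$level, cand$row, cand$col)
  cand <- cand[ord, , drop = FALSE][seq_len(min(nrow(cand), SIFT_MAX_KP)), ]
  desc <- matrix(0, nrow(cand), 128)
  info <- data.frame(row = numeric(0), col = numeric(0), octave = integer(0),
                     sigma = numeric(0), orientation = numeric(0),
                     response = numeric(0))
  grads <- list()  # gradient cache per (octave, level)
  for (i in seq_len(nrow(cand))) {
    o <- cand$octave[i]; lev <- cand$level[i]
    key <- paste0(o, "_", lev)
    if (is.null(grads[[key]])) grads[[key]] <- grad_xy(pyr[[o]]$gauss[[lev]])
    gr <- grads[[key]]
    sigma <- SIFT_SIGMA0 * k^(lev - 1)
    ori <- kp_orientation(gr, cand$row[i], cand$col[i], sigma)
    desc[i, ] <- kp_descriptor(gr, cand$row[i], cand$col[i], sigma, ori)
    info <- rbind(info, data.frame(
      row = (cand$row[i] - 1) * 2^(o - 1), col = (cand$col[i] - 1) * 2^(o - 1),
      octave = o, sigma = sigma * 2^(o - 1), orientation = ori,
      response = cand$response[i]))
  }
  nz <- rowSums(desc^2) > 0
  if (!any(nz)) return(empty)
  list(descriptors = desc[nz, , drop = FALSE],
       keypoints = info[nz, , drop = FALSE])
}

#' Pooled SIFT descriptor of a cell crop
#'
#' Mean-pools the per-keypoint descriptors of [sift_keypoints()] into one
#' 128-dimensional vector. When no keypoint is found (e.g. a flat crop), a
#' single descriptor is computed at the image centre with fixed scale
#' (sigma 16) and orientation 0, so the output is always a finite
#' 128-vector.
#'
#' @param img grayscale matrix in `[0, 255]`.
#' @return `ana_feature` vector of length 128, descriptor `"SIFT"`.
#' @export
sift_descriptor <- function(img) {
  kp <- sift_keypoints(img)
  if (nrow(kp$descriptors) > 0)
    return(new_feature(colMeans(kp$descriptors), "SIFT"))
  base <- from_ebimage(EBImage::resize(as_ebimage(img), w = SIFT_SIZE,
                                       h = SIFT_SIZE)) / 255
  gr <- grad_xy(gblur_mat(base, sqrt(SIFT_SIGMA0^2 - 0.5^2)))
  centre <- SIFT_SIZE / 2
  new_feature(kp_descriptor(gr, centre, centre, sigma = 16, ori = 0), "SIFT")
}
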