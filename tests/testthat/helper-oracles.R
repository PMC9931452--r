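# Independent brute-force oracles and small fixture builders. These
# deliberately re-derive each quantity from its definition with plain
# loops, sharing no code with the package implementation.

rot90cw <- function(m) t(m[nrow(m):1, , drop = FALSE])

random_gray <- function(h, w, seed) {
  set.seed(seed)
  matrix(sample(0:255, h * w, replace = TRUE), h, w)
}

disk_image <- function(h, w, cy, cx, r, fg = 200, bg = 0) {
  dy <- outer((0:(h - 1)) - cy, rep(1, w))
  dx <- outer(rep(1, h), (0:(w - 1)) - cx)
  ifelse(dy^2 + dx^2 <= r^2, fg, bg)
}

# --- LBP (per-bit literal evaluation of the code definition) -------------

oracle_bilinear <- function(img, r, c) {
  r0 <- floor(r); c0 <- floor(c); fr <- r - r0; fc <- c - c0
  r1 <- min(r0 + 1, nrow(img) - 1); c1 <- min(c0 + 1, ncol(img) - 1)
  (1 - fr) * (1 - fc) * img[r0 + 1, c0 + 1] +
    (1 - fr) * fc * img[r0 + 1, c1 + 1] +
    fr * (1 - fc) * img[r1 + 1, c0 + 1] +
    fr * fc * img[r1 + 1, c1 + 1]
}

oracle_lbp_code <- function(img, row, col, N = 8, s = 1, sign_at_zero = 1) {
  code <- 0
  for (i in 0:(N - 1)) {
    theta <- 2 * pi * i / N
    dc <- s * cos(theta); dr <- s * sin(theta)
    if (abs(dc - round(dc)) < 1e-9) dc <- round(dc)
    if (abs(dr - round(dr)) < 1e-9) dr <- round(dr)
    v <- oracle_bilinear(img, row + dr, col + dc)
    d <- v - img[row + 1, col + 1]
    bit <- if (d > 1e-6) 1 else if (d < -1e-6) 0 else sign_at_zero
    code <- code + bit * 2^i
  }
  code
}

oracle_lbp_hist <- function(img, N = 8, s = 1) {
  h <- nrow(img); w <- ncol(img)
  out <- numeric(2^N)
  for (row in s:(h - 1 - s)) for (col in s:(w - 1 - s)) {
    cd <- oracle_lbp_code(img, row, col, N, s)
    out[cd + 1] <- out[cd + 1] + 1
  }
  out
}

# CoALBP: double loop over every base position and orientation, using the
# documented lattice displacements (0,r),(r,r),(r,0),(r,-r) in (row, col)
oracle_coalbp <- function(img, N = 4, s = 1, r = 2) {
  h <- nrow(img); w <- ncol(img)
  nc <- 2^N
  disp <- list(c(0, r), c(r, r), c(r, 0), c(r, -r))
  out <- numeric(0)
  for (dp in disp) {
    block <- numeric(nc * nc)
    for (row in s:(h - 1 - s)) for (col in s:(w - 1 - s)) {
      r2 <- row + dp[1]; c2 <- col + dp[2]
      if (r2 < s || r2 > h - 1 - s || c2 < s || c2 > w - 1 - s) next
      a <- oracle_lbp_code(img, row, col, N, s)
      b <- oracle_lbp_code(img, r2, c2, N, s)
      block[a * nc + b + 1] <- block[a * nc + b + 1] + 1
    }
    out <- c(out, block)
  }
  out
}

# orbit enumeration over all 256 ordered 4-bit code pairs under the
# 180-degree rotate-and-swap involution
oracle_pair_orbits <- function() {
  rotl <- function(code, k) {
    k <- k %% 4
    bitwAnd(bitwOr(bitwShiftL(code, k), bitwShiftR(code, 4 - k)), 15)
  }
  seen <- rep(FALSE, 256)
  n_orbits <- 0
  for (a in 0:15) for (b in 0:15) {
    i <- a * 16 + b
    if (seen[i + 1]) next
    j <- rotl(b, 2) * 16 + rotl(a, 2)
    seen[i + 1] <- TRUE
    seen[j + 1] <- TRUE
    n_orbits <- n_orbits + 1
  }
  n_orbits
}

# --- Otsu: exhaustive search over all 255 candidate thresholds ----------

oracle_otsu <- function(img) {
  v <- round(as.vector(img))
  best_t <- NA; best_s <- -Inf
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    s <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (s > best_s) { best_s <- s; best_t <- t }
  }
  best_t
}

# --- morphology with in-bounds-only (border-ignoring) semantics ----------

oracle_erode <- function(mask, k = 3) {
  h <- nrow(mask); w <- ncol(mask); half <- (k - 1) / 2
  out <- matrix(0, h, w)
  for (r in 1:h) for (c in 1:w) {
    rr <- max(1, r - half):min(h, r + half)
    cc <- max(1, c - half):min(w, c + half)
    out[r, c] <- as.numeric(all(mask[rr, cc] == 1))
  }
  out
}

oracle_dilate <- function(mask, k = 3) {
  h <- nrow(mask); w <- ncol(mask); half <- (k - 1) / 2
  out <- matrix(0, h, w)
  for (r in 1:h) for (c in 1:w) {
    rr <- max(1, r - half):min(h, r + half)
    cc <- max(1, c - half):min(w, c + half)
    out[r, c] <- as.numeric(any(mask[rr, cc] == 1))
  }
  out
}

# exact Euclidean distance transform by all-pairs search (tiny grids only)
oracle_distmap <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  bg <- which(mask == 0, arr.ind = TRUE)
  out <- matrix(0, h, w)
  for (r in 1:h) for (c in 1:w) {
    if (mask[r, c] == 0) next
    out[r, c] <- sqrt(min((bg[, 1] - r)^2 + (bg[, 2] - c)^2))
  }
  out
}

# paste a region's bbox-restricted mask back onto a full-size canvas
crop_to_full <- function(region, h, w) {
  m <- matrix(0, h, w)
  b <- region$bbox
  m[(b[1] + 1):b[3], (b[2] + 1):b[4]] <- region$mask
  m
}
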