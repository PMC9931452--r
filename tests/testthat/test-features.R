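test_that("LBP codes follow the per-bit definition", {
  # constant image: every difference is an exact tie, sign(0) = 1
  expect_identical(lbp_code(matrix(7, 5, 5), c(2, 2)), 255L)

  # bright centre, dark neighbours: all bits clear
  m <- matrix(0, 5, 5); m[3, 3] <- 100
  expect_identical(lbp_code(m, c(2, 2)), 0L)

  # brute-force oracle over random images, N = 4, s = 1
  for (seed in 1:16) {
    img <- random_gray(5, 5, seed = seed)
    cfg <- lbp_config(N = 4, s = 1)
    for (pos in list(c(1, 1), c(2, 2), c(3, 1))) {
      expect_identical(lbp_code(img, pos, cfg),
                       as.integer(oracle_lbp_code(img, pos[1], pos[2],
                                                  N = 4, s = 1)))
    }
  }

  expect_error(lbp_code(matrix(0, 5, 5), c(0, 2)), "border")
})

test_that("LBP histogram counts interior codes", {
  h <- lbp_histogram(matrix(10, 10, 10))
  expect_identical(as.numeric(h[256]), 64)  # all mass at code 255
  expect_identical(sum(h), 64)

  # step edge against the literal double-loop oracle
  img <- matrix(0, 8, 12); img[, 7:12] <- 200
  expect_equal(as.numeric(lbp_histogram(img)), oracle_lbp_hist(img))

  # counting identity over assorted sizes and radii
  set.seed(99)
  for (i in 1:20) {
    hh <- sample(5:17, 1); ww <- sample(5:17, 1)
    s <- sample(1:2, 1)
    if (hh <= 2 * s + 1 || ww <= 2 * s + 1) next
    img <- random_gray(hh, ww, seed = 100 + i)
    cfg <- lbp_config(N = 4, s = s)
    expect_identical(sum(lbp_histogram(img, cfg)), (hh - 2 * s) * (ww - 2 * s))
  }

  expect_error(lbp_histogram(matrix(0, 3, 3), lbp_config(N = 8, s = 1)),
               "too small")
})

test_that("CoALBP concatenates four orientation co-occurrence histograms", {
  cfg <- lbp_config(N = 4, s = 1)
  h <- coalbp_histogram(matrix(9, 12, 12), cfg, pair_config(2))
  expect_length(h, 1024)  # 4 blocks of 16^2
  for (blk in 0:3) {
    block <- h[blk * 256 + 1:256]
    expect_identical(which(block > 0), 256L)  # all mass at pair (15, 15)
  }

  # each block total = valid pair positions for its displacement
  img <- random_gray(12, 12, seed = 50)
  h <- coalbp_histogram(img, cfg, pair_config(2))
  expect_equal(as.numeric(h), oracle_coalbp(img, N = 4, s = 1, r = 2))

  expect_error(coalbp_histogram(matrix(0, 4, 4), cfg, pair_config(8)),
               "too small")
})

test_that("rotation-invariant label table partitions pairs into 136 classes", {
  tab <- build_label_table()
  expect_identical(tab$n_labels, 136L)
  expect_identical(tab$n_labels, as.integer((16^2 + 16) / 2))
  expect_identical(oracle_pair_orbits(), 136)

  # a true partition: every (a, b, phi) triple has exactly one label and
  # all 136 labels are hit
  for (m in tab$maps) {
    expect_length(m, 256)
    expect_true(all(m %in% 0:135))
  }
  expect_setequal(unique(unlist(tab$maps)), 0:135)

  # the all-zeros pair is rotation symmetric: same label at every phi
  lab00 <- vapply(tab$maps, function(m) m[1], integer(1))
  expect_identical(unname(unique(lab00)), lab00[[1]])

  expect_error(build_label_table(lbp_config(N = 8, s = 1)), "N = 4")
})

test_that("RIC-LBP has length 408 and exact 90-degree rotation invariance", {
  img <- random_gray(64, 64, seed = 12)
  h <- riclbp_histogram(img)
  expect_length(h, 408)

  # constant image: each scale block concentrates on the all-ones pair
  hc <- riclbp_histogram(matrix(120, 40, 40))
  for (blk in 0:2) {
    block <- hc[blk * 136 + 1:136]
    expect_identical(sum(block > 0), 1L)
    expect_equal(sum(block), 1)  # L1-normalized
  }

  # exact equality under image rotation (square frame)
  for (seed in c(4, 17)) {
    m <- random_gray(48, 48, seed = seed)
    r0 <- as.numeric(riclbp_histogram(m))
    r90 <- as.numeric(riclbp_histogram(rot90cw(m)))
    r180 <- as.numeric(riclbp_histogram(rot90cw(rot90cw(m))))
    expect_identical(r0, r90)
    expect_identical(r0, r180)
  }

  expect_error(riclbp_histogram(matrix(0, 10, 10)), "too small")
})

test_that("descriptor fusion concatenates SIFT and RIC-LBP into 536", {
  s <- seq_len(128) / 128
  r <- seq_len(408) / 408
  f <- fuse_features(s, r)
  expect_length(f, 536)
  expect_identical(attr(f, "descriptor"), "FUS")
  expect_identical(as.numeric(f[1:128]), s)
  expect_identical(as.numeric(f[129:536]), r)
  expect_identical(as.numeric(fuse_features(rep(0, 128), rep(0, 408))),
                   rep(0, 536))
  expect_error(fuse_features(rep(0, 100), rep(0, 408)), "128")
})

test_that("descriptors are deterministic", {
  crop <- generate_cell_crops(1, seed = 77)$crops[[1]]
  expect_identical(riclbp_histogram(crop), riclbp_histogram(crop))
  expect_identical(sift_descriptor(crop), sift_descriptor(crop))
  expect_identical(coalbp_histogram(crop), coalbp_histogram(crop))
})
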