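test_that("Otsu threshold maximizes between-class variance", {
  # perfectly bimodal image
  img <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  res <- otsu_threshold(img)
  expect_gte(res$threshold, 10)
  expect_lt(res$threshold, 200)
  expect_identical(res$mask, (img > res$threshold) * 1)
  expect_identical(sum(res$mask), 50)

  # two-Gaussian mixture against the exhaustive-search oracle
  set.seed(33)
  v <- pmin(pmax(c(rnorm(300, 40, 10), rnorm(300, 180, 10)), 0), 255)
  img <- matrix(round(v), 20, 30)
  expect_identical(otsu_threshold(img)$threshold, oracle_otsu(img))

  # single bright pixel
  img <- matrix(0, 9, 9); img[5, 5] <- 255
  expect_identical(sum(otsu_threshold(img)$mask), 1)

  expect_error(otsu_threshold(matrix(7, 4, 4)), "constant")
})

test_that("mask opening removes specks, keeps solids, matches the set oracle", {
  m <- matrix(0, 9, 9); m[5, 5] <- 1
  expect_identical(clean_mask(m, 3), matrix(0, 9, 9))

  sq <- matrix(0, 30, 30); sq[6:25, 6:25] <- 1
  expect_identical(clean_mask(sq, 3), sq)

  set.seed(5)
  rnd <- matrix(rbinom(12 * 14, 1, 0.5), 12, 14)
  expect_identical(clean_mask(rnd, 3), oracle_dilate(oracle_erode(rnd, 3), 3))

  expect_error(clean_mask(matrix(1, 2, 2), 3), "larger than image")
})

test_that("marker construction labels cores via the distance transform", {
  # one solid disk: a single foreground component labelled 2
  m <- disk_image(80, 80, 40, 40, 30, fg = 1, bg = 0)
  mk <- build_markers(m)
  expect_setequal(unique(as.vector(mk)), c(0, 1, 2))

  # two disks joined by a thin bridge split at fg_fraction = 0.4
  m <- disk_image(60, 110, 30, 28, 20, fg = 1) +
       disk_image(60, 110, 30, 80, 20, fg = 1)
  m[30:31, 48:60] <- 1
  m <- (m > 0) * 1
  mk <- build_markers(m, fg_fraction = 0.4)
  expect_identical(max(mk), 3L)  # labels 2 and 3: bridge did not merge cores

  # the exact Euclidean distance transform the markers rely on
  small <- disk_image(25, 25, 12, 12, 8, fg = 1)
  dist_pkg <- t(EBImage::imageData(EBImage::distmap(EBImage::Image(t(small)))))
  expect_equal(dist_pkg, oracle_distmap(small), tolerance = 1e-6)

  expect_message(mk <- build_markers(matrix(0, 10, 10)), "all sure background")
  expect_identical(unique(as.vector(mk)), 1L)
})

test_that("watershed partitions unknown pixels and respects marker labels", {
  img <- disk_image(60, 60, 30, 30, 20)
  res <- segment_cells(img, segment_config(min_brightness = 10,
                                           diameter_range = c(10, 120),
                                           margin = 5))
  expect_length(res$regions, 1)
  iou <- mask_iou(crop_to_full(res$regions[[1]], 60, 60),
                  disk_image(60, 60, 30, 30, 20, fg = 1))
  expect_gt(iou, 0.8)

  # two touching disks, two markers: disjoint regions separated by a line
  img <- pmax(disk_image(70, 110, 35, 34, 20), disk_image(70, 110, 35, 72, 20))
  mk <- build_markers((img > 100) * 1)
  expect_identical(max(mk), 3L)
  lab <- watershed_cells(img, mk)
  expect_setequal(sort(unique(as.vector(lab))), c(-1L, 1L, 2L, 3L))
  # partition: every pixel carries exactly one of {background, region, line}
  expect_identical(sum(lab == 0), 0L)
  # the two basins are 8-separated by the watershed line
  expect_gt(sum(lab == -1), 0)

  # markers without foreground labels give pure background
  mk0 <- matrix(1L, 20, 20); mk0[8:12, 8:12] <- 0L
  lab0 <- watershed_cells(matrix(50, 20, 20), mk0)
  expect_setequal(unique(as.vector(lab0)), 1L)

  expect_error(watershed_cells(matrix(0, 5, 5), matrix(1L, 6, 6)), "shapes differ")
})

test_that("region filters enforce diameter, margin and centre brightness", {
  # diameter 25 disk (below the 30 px floor): rejected even though bright
  lab <- (disk_image(100, 100, 50, 50, 12.5, fg = 1) == 1) * 2
  img <- disk_image(100, 100, 50, 50, 12.5, fg = 200)
  expect_length(filter_regions(lab, img), 0)

  # diameter 50, centroid 10 px from the left edge: rejected by margin
  lab <- (disk_image(200, 200, 100, 10, 25, fg = 1) == 1) * 2
  img <- disk_image(200, 200, 100, 10, 25, fg = 200)
  expect_length(filter_regions(lab, img), 0)

  # same geometry centred: brightness 40 rejected, 60 accepted
  lab <- (disk_image(200, 200, 100, 100, 25, fg = 1) == 1) * 2
  expect_length(filter_regions(lab, disk_image(200, 200, 100, 100, 25, fg = 40)), 0)
  kept <- filter_regions(lab, disk_image(200, 200, 100, 100, 25, fg = 60))
  expect_length(kept, 1)
  expect_equal(kept[[1]]$equivalent_diameter, 50, tolerance = 0.05)
  expect_equal(kept[[1]]$centre_brightness, 60)

  # monotonicity: shrinking the diameter interval never adds regions
  sc <- generate_scene(scene_spec(n_cells = 5, seed = 21))
  res <- segment_cells(extract_green(sc$image))
  n_narrow <- length(filter_regions(res$labels, extract_green(sc$image),
                                    diameter_range = c(45, 70)))
  expect_lte(n_narrow, length(res$regions))
})

test_that("crops copy bbox rectangles from the source image", {
  img <- random_gray(60, 70, seed = 8)
  reg <- structure(list(label = 2L, bbox = c(10L, 10L, 40L, 50L),
                        mask = matrix(1, 30, 40), centroid = c(24, 29),
                        area = 1200L, equivalent_diameter = 39,
                        centre_brightness = 100), class = "cell_region")
  cr <- crop_cells(list(reg), img)
  expect_identical(dim(cr[[1]]), c(30L, 40L))
  expect_identical(cr[[1]], img[11:40, 11:50])

  bad <- reg; bad$bbox <- c(40L, 50L, 70L, 80L)
  expect_error(crop_cells(list(bad), img), "outside image bounds")
})

test_that("segmentation is deterministic for a fixed input and config", {
  sc <- generate_scene(scene_spec(n_cells = 4, seed = 31))
  g <- extract_green(sc$image)
  r1 <- segment_cells(g)
  r2 <- segment_cells(g)
  expect_identical(r1, r2)
})

test_that("bright non-touching planted cells are recovered with IoU >= 0.7", {
  for (seed in c(101, 104)) {
    sc <- generate_scene(scene_spec(n_cells = 6, seed = seed))
    g <- extract_green(sc$image)
    scr <- score_segmentation(sc, segment_cells(g))
    brightness <- vapply(seq_len(nrow(sc$cells)), function(i) {
      r <- round(sc$cells$row[i]); c <- round(sc$cells$col[i])
      mean(g[(r - 1):(r + 1) + 1, (c - 1):(c + 1) + 1])
    }, numeric(1))
    expect_true(all(scr$best_iou[brightness > 100] >= 0.7))
  }
})
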