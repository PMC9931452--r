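#' Synthetic fluorescence scene specification
#'
#' Parameters of the generator that emulates IIF fields: bright,
#' roughly circular cells on a dark noisy background, with the antibody
#' signal on the green channel. Two texture classes are produced:
#' `"homogeneous"` (smooth disk interior) and `"speckled"` (dimmer disk
#' carrying bright punctate dots), mirroring the two ANA staining patterns
#' the classical pipeline separates.
#'
#' Defaults keep planted cells inside the segmentation acceptance window:
#' diameters 40-80 px (within the 30-120 px size filter) and cell
#' intensities 120-200 (well above the brightness-50 filter) on a
#' background of mean 10.
#'
#' @param height,width scene size in pixels.
#' @param n_cells number of cells to place.
#' @param diameter_range cell diameter interval in pixels.
#' @param base_intensity mean background intensity.
#' @param cell_intensity_range uniform range of the per-cell peak intensity.
#' @param noise_sd Gaussian noise standard deviation (intensity units).
#' @param class_mix probability that a cell is speckled.
#' @param speckle_density speckle dots per 100 square pixels of cell area.
#' @param seed integer RNG seed.
#' @return list of class `scene_spec`.
#' @export
scene_spec <- function(height = 512L, width = 512L, n_cells = 8L,
                       diameter_range = c(40, 80), base_intensity = 10,
                       cell_intensity_range = c(120, 200), noise_sd = 5,
                       class_mix = 0.5, speckle_density = 1.2, seed = 1L) {
  stopifnot(height >= 32, width >= 32, n_cells >= 0,
            diameter_range[1] <= diameter_range[2],
            class_mix >= 0, class_mix <= 1, speckle_density > 0)
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_cells = as.integer(n_cells),
                 diameter_range = diameter_range,
                 base_intensity = base_intensity,
                 cell_intensity_range = cell_intensity_range,
                 noise_sd = noise_sd, class_mix = class_mix,
                 speckle_density = speckle_density, seed = as.integer(seed)),
            class = "scene_spec")
}

# non-overlapping circle placement by bounded rejection sampling
place_cells <- function(spec) {
  if (spec$n_cells == 0) return(data.frame())
  rows <- cols <- radii <- numeric(0)
  for (i in seq_len(spec$n_cells)) {
    placed <- FALSE
    for (try in 1:200) {
      r <- runif(1, spec$diameter_range[1], spec$diameter_range[2]) / 2
      margin <- r + 4
      if (spec$height - margin <= margin || spec$width - margin <= margin) next
      cy <- runif(1, margin, spec$height - 1 - margin)
      cx <- runif(1, margin, spec$width - 1 - margin)
      if (!length(rows) ||
          all(sqrt((rows - cy)^2 + (cols - cx)^2) > radii + r + 4)) {
        rows <- c(rows, cy); cols <- c(cols, cx); radii <- c(radii, r)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place ", spec$n_cells, " non-overlapping cells of ",
           "diameter ", spec$diameter_range[1], "-", spec$diameter_range[2],
           " in a ", spec$height, "x", spec$width, " scene")
  }
  data.frame(row = rows, col = cols, radius = radii)
}

disk_mask <- function(h, w, cy, cx, r) {
  dr <- outer((0:(h - 1)) - cy, rep(1, w))
  dc <- outer(rep(1, h), (0:(w - 1)) - cx)
  (dr^2 + dc^2 <= r^2) * 1
}

#' Generate one synthetic fluorescence scene
#'
#' Draws an RGB scene according to `spec`: Gaussian background, per-cell
#' disks (homogeneous at full intensity, speckled at half intensity plus
#' Poisson-many bright 2-4 px dots), mild optical blur on the green
#' channel, and low-level noise on red/blue. Ground-truth per-cell binary
#' masks and class labels are returned alongside. Fully reproducible from
#' `spec$seed`.
#'
#' @param spec a [scene_spec()].
#' @return list with `image` (`H x W x 3` array in `[0, 255]`), `masks`
#'   (list of per-cell full-size 0/1 matrices), `labels` (character),
#'   `cells` (data.frame: id, row, col, radius, label, bbox columns).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  h <- spec$height; w <- spec$width
  green <- matrix(rnorm(h * w, spec$base_intensity, spec$noise_sd), h, w)
  cells <- place_cells(spec)
  masks <- list(); labels <- character(0)
  if (nrow(cells)) {
    speckled <- runif(nrow(cells)) < spec$class_mix
    for (i in seq_len(nrow(cells))) {
      cy <- cells$row[i]; cx <- cells$col[i]; r <- cells$radius[i]
      m <- disk_mask(h, w, cy, cx, r)
      amp <- runif(1, spec$cell_intensity_range[1], spec$cell_intensity_range[2])
      sel <- m == 1
      if (!speckled[i]) {
        green[sel] <- amp + rnorm(sum(sel), 0, spec$noise_sd)
      } else {
        green[sel] <- 0.5 * amp + rnorm(sum(sel), 0, spec$noise_sd)
        area <- sum(sel)
        n_dots <- rpois(1, spec$speckle_density * area / 100)
        if (n_dots > 0) {
          # dot centres uniform in the disk (polar sampling); dots drawn
          # inside the cell's bounding window only
          rho <- r * sqrt(runif(n_dots)); phi <- runif(n_dots, 0, 2 * pi)
          dry <- cy + rho * sin(phi); dcx <- cx + rho * cos(phi)
          drad <- runif(n_dots, 1, 2)  # dot diameter 2-4 px
          rr <- max(1, floor(cy - r)):min(h, ceiling(cy + r) + 1)
          cc <- max(1, floor(cx - r)):min(w, ceiling(cx + r) + 1)
          py <- outer(rr - 1, rep(1, length(cc)))
          px <- outer(rep(1, length(rr)), cc - 1)
          inside <- sel[rr, cc]
          for (j in seq_len(n_dots)) {
            dm <- ((py - dry[j])^2 + (px - dcx[j])^2 <= drad[j]^2) & inside
            sub <- green[rr, cc]
            sub[dm] <- amp
            green[rr, cc] <- sub
          }
        }
      }
      masks[[i]] <- m
      labels <- c(labels, if (speckled[i]) "speckled" else "homogeneous")
    }
  }
  green <- pmin(pmax(green, 0), 255)
  green <- from_ebimage(EBImage::gblur(as_ebimage(green), sigma = 1))
  img <- array(0, dim = c(h, w, 3))
  img[, , 1] <- pmin(pmax(matrix(rnorm(h * w, 8, 3), h, w), 0), 255)
  img[, , 2] <- green
  img[, , 3] <- pmin(pmax(matrix(rnorm(h * w, 8, 3), h, w), 0), 255)
  img <- round_half_up(img)
  cells_df <- if (nrow(cells)) {
    data.frame(id = seq_len(nrow(cells)), row = cells$row, col = cells$col,
               radius = cells$radius, label = labels,
               row0 = pmax(0, floor(cells$row - cells$radius)),
               col0 = pmax(0, floor(cells$col - cells$radius)),
               row1 = pmin(h, ceiling(cells$row + cells$radius) + 1),
               col1 = pmin(w, ceiling(cells$col + cells$radius) + 1))
  } else {
    data.frame(id = integer(), row = numeric(), col = numeric(),
               radius = numeric(), label = character(), row0 = integer(),
               col0 = integer(), row1 = integer(), col1 = integer())
  }
  list(image = img, masks = masks, labels = labels, cells = cells_df)
}

scene_seed <- function(master, index) {
  as.integer((as.numeric(master) * 7919 + index * 104729) %% 2147483647)
}

#' Generate a benchmark directory of synthetic scenes
#'
#' Writes `n_scenes` reproducible scenes (RGB PNGs), per-scene ground-truth
#' label grids (16-bit PNGs where pixel value = cell id) and a truth CSV
#' (`scene, cell_id, row0, col0, row1, col1, class`) in the layout the
#' preprocessing stage consumes. Each scene uses its own RNG stream derived
#' from `(seed, scene index)`.
#'
#' @param n_scenes number of scenes.
#' @param template a [scene_spec()] used for every scene (its `seed` is
#'   replaced per scene).
#' @param seed master seed.
#' @param out_dir output directory (created if missing).
#' @return invisibly, the truth data.frame.
#' @export
generate_benchmark <- function(n_scenes, template = scene_spec(),
                               seed = 1L, out_dir) {
  stopifnot(n_scenes >= 1, inherits(template, "scene_spec"))
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "masks"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  truth <- list()
  for (i in seq_len(n_scenes)) {
    sp <- template
    sp$seed <- scene_seed(seed, i)
    sc <- generate_scene(sp)
    name <- sprintf("scene_%03d", i)
    write_image(sc$image, file.path(out_dir, "images", paste0(name, ".png")))
    lab_grid <- matrix(0, sp$height, sp$width)
    for (j in seq_along(sc$masks)) lab_grid[sc$masks[[j]] == 1] <- j
    write_image(lab_grid, file.path(out_dir, "masks", paste0(name, ".png")),
                bits = 16L)
    if (nrow(sc$cells))
      truth[[length(truth) + 1L]] <-
        data.frame(scene = name, cell_id = sc$cells$id,
                   row0 = sc$cells$row0, col0 = sc$cells$col0,
                   row1 = sc$cells$row1, col1 = sc$cells$col1,
                   row = sc$cells$row, col = sc$cells$col,
                   radius = sc$cells$radius, class = sc$cells$label)
  }
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(scene = character(), cell_id = integer())
  write.csv(truth, file.path(out_dir, "truth.csv"), row.names = FALSE)
  invisible(truth)
}

#' Generate standalone cell crops
#'
#' Draws single-cell images (one disk centred in a tight canvas, same
#' texture model as [generate_scene()]) for training and testing the
#' descriptor + classifier stages without running segmentation. Each crop
#' has its own RNG stream derived from `(seed, crop index)`.
#'
#' @param n number of crops.
#' @param class_mix probability of the speckled class.
#' @param diameter_range cell diameter interval in pixels.
#' @param seed master seed.
#' @return list with `crops` (list of grayscale matrices) and `labels`.
#' @export
generate_cell_crops <- function(n, class_mix = 0.5, diameter_range = c(40, 80),
                                seed = 1L) {
  crops <- vector("list", n)
  labels <- character(n)
  for (i in seq_len(n)) {
    d <- ceiling(diameter_range[2]) + 16L
    sp <- scene_spec(height = d, width = d, n_cells = 1L,
                     diameter_range = diameter_range, class_mix = class_mix,
                     seed = scene_seed(seed, i))
    sc <- generate_scene(sp)
    b <- sc$cells[1, ]
    crops[[i]] <- extract_green(sc$image)[(b$row0 + 1):b$row1,
                                          (b$col0 + 1):b$col1]
    labels[i] <- sc$labels[1]
  }
  list(crops = crops, labels = labels)
}
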