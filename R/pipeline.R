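#' Pipeline configuration
#'
#' One flat record of every tunable parameter across the stages, with
#' defaults matching the published recipe where it states values. The
#' configuration serializes losslessly to YAML ([save_config()] /
#' [load_config()]) and each pipeline run writes its resolved configuration
#' beside its outputs, so a run is reproducible from its manifest.
#'
#' @param cut cut raw images into quadrants before preprocessing?
#' @param blur_kernel,blur_sigma,clean_kernel,fg_fraction,bg_dilate_iter,diameter_range,margin,min_brightness
#'   segmentation parameters; see [segment_config()].
#' @param descriptor feature descriptor: `"fus"`, `"riclbp"`, `"lbp"`,
#'   `"coalbp"` or `"sift"`.
#' @param split_ratio train fraction of the source-image-level split.
#' @param knn_k,ntree,svm_cost,svm_gamma classifier parameters; see
#'   [train_members()].
#' @param seed global seed for every randomized component.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cut = TRUE,
                            blur_kernel = 5L, blur_sigma = NULL,
                            clean_kernel = 3L, fg_fraction = 0.4,
                            bg_dilate_iter = 3L,
                            diameter_range = c(30, 120), margin = 20,
                            min_brightness = 50,
                            descriptor = "fus", split_ratio = 0.8,
                            knn_k = 5L, ntree = 1000L, svm_cost = 1,
                            svm_gamma = NULL, seed = 1L) {
  seg <- segment_config(blur_kernel, blur_sigma, clean_kernel, fg_fraction,
                        bg_dilate_iter, diameter_range, margin, min_brightness)
  descriptor <- match.arg(descriptor, c("fus", "riclbp", "lbp", "coalbp",
                                        "sift"))
  structure(c(unclass(seg),
              list(cut = isTRUE(cut), descriptor = descriptor,
                   split_ratio = split_ratio, knn_k = as.integer(knn_k),
                   ntree = as.integer(ntree), svm_cost = svm_cost,
                   svm_gamma = svm_gamma, seed = as.integer(seed))),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @param path YAML file path.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
load_config <- function(path) {
  vals <- yaml::yaml.load_file(path)
  keep <- intersect(names(vals), names(formals(pipeline_config)))
  do.call(pipeline_config, vals[keep])
}

as_segment_config <- function(cfg) {
  segment_config(cfg$blur_kernel, cfg$blur_sigma, cfg$clean_kernel,
                 cfg$fg_fraction, cfg$bg_dilate_iter, cfg$diameter_range,
                 cfg$margin, cfg$min_brightness)
}

quadrant_offsets <- function(h, w, cut) {
  if (!cut) return(list(c(0L, 0L)))
  list(c(0L, 0L), c(0L, w %/% 2L), c(h %/% 2L, 0L), c(h %/% 2L, w %/% 2L))
}

#' Intersection-over-union of two binary masks
#'
#' @param a,b 0/1 matrices of equal shape.
#' @return IoU in `[0, 1]` (0 when both masks are empty).
#' @export
mask_iou <- function(a, b) {
  inter <- sum(a == 1 & b == 1)
  uni <- sum(a == 1 | b == 1)
  if (uni == 0) 0 else inter / uni
}

#' Score segmentation against a scene's ground truth
#'
#' Matches every planted cell to the recovered region of maximal mask IoU
#' and reports the per-cell best IoU, so recovery rates at any IoU cutoff
#' can be read off directly.
#'
#' @param scene output of [generate_scene()].
#' @param result output of [segment_cells()] on the scene's preprocessed
#'   green channel.
#' @return data.frame with one row per planted cell: `cell_id`, `label`,
#'   `best_iou`, `matched_region` (region label or NA).
#' @export
score_segmentation <- function(scene, result) {
  h <- dim(scene$image)[1]; w <- dim(scene$image)[2]
  region_masks <- lapply(result$regions, function(r) {
    m <- matrix(0, h, w)
    b <- r$bbox
    m[(b[1] + 1):b[3], (b[2] + 1):b[4]] <- r$mask
    m
  })
  rows <- lapply(seq_along(scene$masks), function(i) {
    ious <- vapply(region_masks, mask_iou, numeric(1), b = scene$masks[[i]])
    best <- if (length(ious)) which.max(ious) else NA_integer_
    data.frame(cell_id = i, label = scene$labels[i],
               best_iou = if (length(ious)) max(ious) else 0,
               matched_region = if (length(ious))
                 result$regions[[best]]$label else NA_integer_)
  })
  if (!length(rows))
    return(data.frame(cell_id = integer(), label = character(),
                      best_iou = numeric(), matched_region = integer()))
  do.call(rbind, rows)
}

#' Run the full segmentation + classification pipeline
#'
#' Executes the complete chain on a directory of scenes: green-channel
#' preprocessing (with optional quadrant cutting), cell segmentation,
#' descriptor extraction, a stratified source-image-level train/test
#' split, ensemble training and evaluation. Cell labels come from a
#' `truth.csv` ground-truth file (benchmark layout, cells matched by
#' centroid containment in the truth bounding boxes) or, absent that, from
#' the class-named parent directory of each image.
#'
#' Outputs under `out_dir`: `features.csv`, `report.json`, `manifest.yaml`
#' (resolved configuration, seed, versions) and a `crops/` folder.
#'
#' @param cfg a [pipeline_config()].
#' @param in_dir input directory: either `images/*.png` + `truth.csv`, or
#'   `<class>/<image>.png` trees.
#' @param out_dir output directory (created).
#' @param write_crops write individual crop PNGs? (default `FALSE`)
#' @return list of class `ana_pipeline_result`: `report` (an `ana_eval`),
#'   `items` (per-cell table), `feature_dim`, `n_train`, `n_test`,
#'   `ensemble`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), in_dir, out_dir,
                         write_crops = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  truth_path <- file.path(in_dir, "truth.csv")
  truth <- if (file.exists(truth_path)) read.csv(truth_path) else NULL
  img_dir <- if (!is.null(truth)) file.path(in_dir, "images") else in_dir
  files <- list.files(img_dir, pattern = "\\.(png|tif|tiff)$",
                      ignore.case = TRUE, recursive = TRUE)
  if (!length(files)) stop("stage preprocess: no images found under ", img_dir)
  seg_cfg <- as_segment_config(cfg)
  crops <- list(); labels <- character(0); sources <- character(0)
  for (f in files) {
    scene_id <- sub("\\.[^.]+$", "", basename(f))
    img <- tryCatch(read_image(file.path(img_dir, f)),
                    error = function(e) stop("stage preprocess failed on ", f,
                                             ": ", conditionMessage(e)))
    h <- dim(img)[1]; w <- dim(img)[2]
    pieces <- preprocess_image(img, cut = cfg$cut)
    offs <- quadrant_offsets(h, w, cfg$cut)
    for (q in seq_along(pieces)) {
      res <- tryCatch(segment_cells(pieces[[q]], seg_cfg),
                      error = function(e) stop("stage segment failed on ", f,
                                               ": ", conditionMessage(e)))
      for (j in seq_along(res$regions)) {
        reg <- res$regions[[j]]
        gr <- reg$centroid[1] + offs[[q]][1]
        gc <- reg$centroid[2] + offs[[q]][2]
        lab <- if (!is.null(truth)) {
          hit <- truth[truth$scene == scene_id & truth$row0 <= gr &
                         truth$row1 > gr & truth$col0 <= gc &
                         truth$col1 > gc, , drop = FALSE]
          if (nrow(hit)) as.character(hit$class[1]) else NA_character_
        } else {
          d <- dirname(f)
          if (d == ".") NA_character_ else basename(d)
        }
        if (is.na(lab)) next  # unmatched region: no ground truth, drop
        crops[[length(crops) + 1L]] <- res$crops[[j]]
        labels <- c(labels, lab)
        sources <- c(sources, scene_id)
      }
    }
  }
  if (length(crops) < 4)
    stop("stage segment: only ", length(crops), " labelled cells recovered")
  feats <- extract_features(crops, cfg$descriptor, labels)
  X <- as.matrix(feats[, -1, drop = FALSE])
  items <- data.frame(image = sources, label = labels)
  sp <- split_train_test(cbind(items, idx = seq_len(nrow(items))),
                         ratio = cfg$split_ratio, seed = cfg$seed)
  ens <- train_members(X[sp$train$idx, , drop = FALSE], sp$train$label,
                       k = cfg$knn_k, ntree = cfg$ntree, cost = cfg$svm_cost,
                       gamma = cfg$svm_gamma, seed = cfg$seed)
  report <- evaluate_model(ens, X[sp$test$idx, , drop = FALSE], sp$test$label)
  # artefacts
  write.csv(cbind(data.frame(source = sources, label = labels),
                  as.data.frame(X)),
            file.path(out_dir, "features.csv"), row.names = FALSE)
  if (write_crops) {
    dir.create(file.path(out_dir, "crops"), showWarnings = FALSE)
    for (i in seq_along(crops))
      write_image(crops[[i]],
                  file.path(out_dir, "crops", sprintf("cell_%05d.png", i)))
  }
  jsonlite::write_json(
    list(descriptor = cfg$descriptor, feature_dim = ncol(X),
         n_cells = nrow(items), n_train = nrow(sp$train),
         n_test = nrow(sp$test), accuracy = report$accuracy,
         confusion = report$confusion, per_class = report$per_class),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
  manifest <- c(unclass(cfg),
                list(package_version = as.character(utils::packageVersion("anakit")),
                     r_version = R.version.string))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  structure(list(report = report, items = items, feature_dim = ncol(X),
                 n_train = nrow(sp$train), n_test = nrow(sp$test),
                 ensemble = ens),
            class = "ana_pipeline_result")
}
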