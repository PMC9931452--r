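#' Stratified source-image-level train/test split
#'
#' Splits labelled cells so that all cells coming from the same source IIF
#' image land on the same side (cells from one field are correlated;
#' splitting them across sets would leak information), stratified by class
#' and reproducible from a seed. The per-class number of training images is
#' `round(ratio * n_images)`, clamped so both sides stay non-empty.
#'
#' @param items data.frame with columns `image` (source-image id) and
#'   `label` (class); one row per cell.
#' @param ratio training fraction in (0, 1); the published split is 8:2.
#' @param seed integer RNG seed.
#' @return list with `train` and `test` (row subsets of `items`),
#'   `train_images` and `test_images` (the image ids).
#' @export
split_train_test <- function(items, ratio = 0.8, seed = 1L) {
  stopifnot(is.data.frame(items), all(c("image", "label") %in% names(items)),
            ratio > 0, ratio < 1)
  # image-level class = majority vote over its cells
  img_label <- vapply(split(as.character(items$label), items$image),
                      function(l) names(sort(table(l), decreasing = TRUE))[1],
                      character(1))
  train_imgs <- character(0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (cl in sort(unique(img_label))) {
    imgs <- sort(names(img_label)[img_label == cl])
    if (length(imgs) < 2)
      stop("class '", cl, "' has a single source image; ",
           "stratified image-level split impossible")
    n_tr <- min(max(round(ratio * length(imgs)), 1L), length(imgs) - 1L)
    train_imgs <- c(train_imgs, sample(imgs, n_tr))
  }
  in_train <- items$image %in% train_imgs
  list(train = items[in_train, , drop = FALSE],
       test = items[!in_train, , drop = FALSE],
       train_images = sort(train_imgs),
       test_images = sort(setdiff(unique(as.character(items$image)),
                                  train_imgs)))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Train the three base classifiers
#'
#' Fits the ensemble members on a feature matrix: an RBF-kernel SVM with
#' Platt-calibrated probability outputs, a k-nearest-neighbour classifier
#' weighting votes by inverse distance, and a random forest with 1000
#' trees. Features are standardized once (centre/scale from the training
#' set) and the same transform is applied at prediction time.
#'
#' @param X numeric matrix, one row per training cell.
#' @param y class labels (coerced to factor); at least two classes.
#' @param k KNN neighbour count.
#' @param ntree random-forest size.
#' @param cost SVM soft-margin cost C.
#' @param gamma RBF width; default `1 / (d * var(X))` on the standardized
#'   features.
#' @param seed integer seed controlling the SVM probability calibration and
#'   the forest's bootstrap.
#' @return object of class `ana_ensemble` holding the three fitted members,
#'   the class order and the standardization transform.
#' @export
train_members <- function(X, y, k = 5L, ntree = 1000L, cost = 1,
                          gamma = NULL, seed = 1L) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(y) < 2) stop("training data contains a single class")
  if (nrow(X) < 2 * nlevels(y)) stop("too few training samples")
  centre <- colMeans(X)
  scale_ <- apply(X, 2, stats::sd)
  scale_[scale_ < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, centre), 2, scale_, "/")
  if (is.null(gamma)) gamma <- 1 / (ncol(Xs) * stats::var(as.vector(Xs)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  svm_fit <- e1071::svm(Xs, y, kernel = "radial", cost = cost, gamma = gamma,
                        probability = TRUE, scale = FALSE)
  set.seed(seed)
  rf_fit <- randomForest::randomForest(Xs, y, ntree = ntree)
  structure(list(
    members = list(
      svm = structure(list(fit = svm_fit), class = "ana_member_svm"),
      knn = structure(list(X = Xs, y = y, k = as.integer(k)),
                      class = "ana_member_knn"),
      rf = structure(list(fit = rf_fit), class = "ana_member_rf")),
    class_names = levels(y), centre = centre, scale = scale_,
    dim = ncol(X), seed = seed),
    class = "ana_ensemble")
}

member_probs <- function(member, Xs, class_names) UseMethod("member_probs")

#' @export
member_probs.ana_member_svm <- function(member, Xs, class_names) {
  p <- attr(predict(member$fit, Xs, probability = TRUE), "probabilities")
  p[, class_names, drop = FALSE]
}

#' @export
member_probs.ana_member_knn <- function(member, Xs, class_names) {
  # inverse-distance-weighted vote among the k nearest training points;
  # an exact match (zero distance) takes the whole vote
  tr <- member$X; k <- member$k
  d2 <- outer(rowSums(Xs^2), rep(1, nrow(tr))) +
        outer(rep(1, nrow(Xs)), rowSums(tr^2)) - 2 * Xs %*% t(tr)
  d2[d2 < 0] <- 0
  P <- matrix(0, nrow(Xs), length(class_names),
              dimnames = list(NULL, class_names))
  for (i in seq_len(nrow(Xs))) {
    nn <- order(d2[i, ])[seq_len(min(k, ncol(d2)))]
    dist <- sqrt(d2[i, nn])
    w <- if (any(dist < 1e-12)) as.numeric(dist < 1e-12) else 1 / dist
    for (j in seq_along(nn))
      P[i, as.character(member$y[nn[j]])] <-
        P[i, as.character(member$y[nn[j]])] + w[j]
    P[i, ] <- P[i, ] / sum(P[i, ])
  }
  P
}

#' @export
member_probs.ana_member_rf <- function(member, Xs, class_names) {
  predict(member$fit, Xs, type = "prob")[, class_names, drop = FALSE]
}

standardize <- function(ens, X) {
  X <- as.matrix(X)
  if (ncol(X) != ens$dim)
    stop("feature dimension ", ncol(X), " does not match training dimension ",
         ens$dim)
  sweep(sweep(X, 2, ens$centre), 2, ens$scale, "/")
}

#' Soft-voting prediction
#'
#' Sums the three members' class-probability vectors per sample and
#' predicts the argmax — the soft-voting rule of the ensemble classifier
#' (ECLF). Ties go to the earlier class in `class_names`.
#'
#' @param ens an `ana_ensemble` from [train_members()].
#' @param X feature matrix with the training dimension.
#' @return list with `labels` (character vector) and `probs` (matrix of
#'   summed probabilities; each row sums to 3, one unit per member).
#' @export
soft_vote <- function(ens, X) {
  Xs <- standardize(ens, X)
  P <- Reduce(`+`, lapply(ens$members, member_probs, Xs = Xs,
                          class_names = ens$class_names))
  idx <- max.col(P, ties.method = "first")
  list(labels = ens$class_names[idx], probs = P)
}

ana_predict <- function(model, X) {
  if (inherits(model, "ana_ensemble")) return(soft_vote(model, X)$labels)
  stop("unsupported model class: ", paste(class(model), collapse = ","))
}

#' Evaluate a classifier on a test set
#'
#' Computes the confusion matrix (rows = truth), accuracy and per-class
#' precision/recall/F1 under the standard one-vs-rest count formulas, with
#' the `F1 = 0` guard when precision + recall is 0.
#'
#' @param model an `ana_ensemble`, or `NULL` when `predicted` is supplied.
#' @param X test feature matrix (ignored when `predicted` given).
#' @param y true labels.
#' @param predicted optional precomputed predicted labels.
#' @return object of class `ana_eval`: `confusion`, `accuracy`, `per_class`
#'   (data.frame with precision, recall, f1 per class), `n`.
#' @export
evaluate_model <- function(model, X, y, predicted = NULL) {
  y <- as.character(y)
  if (!length(y)) stop("test set is empty")
  if (is.null(predicted)) {
    if (!all(unique(y) %in% model$class_names))
      stop("test set contains classes unseen in training: ",
           paste(setdiff(unique(y), model$class_names), collapse = ", "))
    predicted <- ana_predict(model, X)
  }
  classes <- if (!is.null(model)) model$class_names else sort(unique(c(y, predicted)))
  conf <- table(factor(y, levels = classes), factor(predicted, levels = classes))
  conf <- unclass(conf)
  n <- sum(conf)
  acc <- sum(diag(conf)) / n
  per <- lapply(seq_along(classes), function(i) {
    tp <- conf[i, i]
    prec <- if (sum(conf[, i]) > 0) tp / sum(conf[, i]) else 0
    rec <- if (sum(conf[i, ]) > 0) tp / sum(conf[i, ]) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(class = classes[i], precision = prec, recall = rec, f1 = f1)
  })
  structure(list(confusion = conf, accuracy = acc,
                 per_class = do.call(rbind, per), n = n),
            class = "ana_eval")
}

#' @export
print.ana_eval <- function(x, ...) {
  cat("Evaluation on", x$n, "samples — accuracy",
      sprintf("%.4f", x$accuracy), "\n\nConfusion (rows = truth):\n")
  print(x$confusion)
  cat("\n")
  print(x$per_class, row.names = FALSE, digits = 4)
  invisible(x)
}
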