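make_blobs <- function(n_per, d = 5, sep = 4, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(rnorm(n_per * d), n_per, d),
             matrix(rnorm(n_per * d, mean = sep), n_per, d))
  list(X = X, y = rep(c("a", "b"), each = n_per))
}

test_that("train/test split is image-level, stratified and reproducible", {
  items <- data.frame(image = rep(sprintf("img%02d", 1:10), each = 3),
                      label = rep(c("x", "y"), each = 15))
  sp <- split_train_test(items, ratio = 0.8, seed = 4)
  expect_length(sp$train_images, 8)
  expect_length(sp$test_images, 2)
  # no image straddles the split
  expect_length(intersect(unique(sp$train$image), unique(sp$test$image)), 0)

  sp2 <- split_train_test(items, ratio = 0.8, seed = 4)
  expect_identical(sp, sp2)

  big <- data.frame(image = sprintf("i%03d", 1:100),
                    label = rep(c("x", "y"), 50))
  spb <- split_train_test(big, ratio = 0.8, seed = 7)
  expect_identical(unname(table(big$label[match(spb$train_images, big$image)])),
                   table(c(rep("x", 40), rep("y", 40))) |> unname())
  expect_length(spb$test_images, 20)

  solo <- data.frame(image = c("i1", "i1", "i2"), label = c("x", "x", "y"))
  expect_error(split_train_test(solo), "single source image")
})

test_that("the three members fit separable data and train deterministically", {
  bl <- make_blobs(100, seed = 11)
  ens <- train_members(bl$X, bl$y, ntree = 200, seed = 3)
  Xs <- anakit:::standardize(ens, bl$X)
  for (m in ens$members) {
    p <- anakit:::member_probs(m, Xs, ens$class_names)
    acc <- mean(ens$class_names[max.col(p)] == bl$y)
    expect_gte(acc, 0.99)
  }

  ens2 <- train_members(bl$X, bl$y, ntree = 200, seed = 3)
  held <- make_blobs(30, seed = 12)$X
  expect_identical(
    anakit:::member_probs(ens$members$rf, anakit:::standardize(ens, held),
                          ens$class_names),
    anakit:::member_probs(ens2$members$rf, anakit:::standardize(ens2, held),
                          ens2$class_names))

  expect_error(train_members(bl$X[1:50, ], rep("a", 50)), "single class")
})

test_that("soft voting sums member probabilities and takes the argmax", {
  # worked ternary example: (0.6,0.4) + (0.3,0.7) + (0.55,0.45) -> class 2
  p <- rbind(c(0.6, 0.4)) + rbind(c(0.3, 0.7)) + rbind(c(0.55, 0.45))
  expect_identical(which.max(p), 2L)

  bl <- make_blobs(50, seed = 21)
  ens <- train_members(bl$X, bl$y, ntree = 100, seed = 5)
  sv <- soft_vote(ens, bl$X)
  # row sums equal 3: one unit of probability per member
  expect_equal(unname(rowSums(sv$probs)), rep(3, nrow(bl$X)))
  # vote equals an independent recomputation from the member probabilities
  Xs <- anakit:::standardize(ens, bl$X)
  psum <- Reduce(`+`, lapply(ens$members, anakit:::member_probs,
                             Xs = Xs, class_names = ens$class_names))
  expect_identical(sv$labels, ens$class_names[max.col(psum, ties.method = "first")])

  expect_error(soft_vote(ens, bl$X[, 1:3]), "dimension")
})

test_that("soft voting arithmetic matches the argmax-of-sums oracle", {
  # synthetic members emitting fixed random probability rows
  set.seed(42)
  n <- 100; k <- 3
  mk_probs <- function() {
    p <- matrix(runif(n * k), n, k)
    p / rowSums(p)
  }
  probs <- list(mk_probs(), mk_probs(), mk_probs())
  for (i in 1:3) {
    cls <- paste0("fake", i)
    assign(paste0("P_", cls), probs[[i]], envir = globalenv())
    registerS3method("member_probs", cls,
                     eval(bquote(function(member, Xs, class_names)
                       get(.(paste0("P_", cls)), envir = globalenv()))),
                     envir = asNamespace("anakit"))
  }
  ens <- structure(list(
    members = list(structure(list(), class = "fake1"),
                   structure(list(), class = "fake2"),
                   structure(list(), class = "fake3")),
    class_names = c("c1", "c2", "c3"),
    centre = rep(0, 4), scale = rep(1, 4), dim = 4L),
    class = "ana_ensemble")
  sv <- soft_vote(ens, matrix(0, n, 4))
  total <- probs[[1]] + probs[[2]] + probs[[3]]
  oracle_labels <- apply(total, 1, function(row)
    c("c1", "c2", "c3")[which.max(row)])
  expect_identical(sv$labels, unname(oracle_labels))
  expect_equal(unname(sv$probs), unname(total))
  rm(list = paste0("P_fake", 1:3), envir = globalenv())
})

test_that("evaluation reports standard one-vs-rest metrics", {
  pred <- c(rep("a", 8), rep("b", 2), rep("a", 1), rep("b", 9))
  truth <- c(rep("a", 10), rep("b", 10))
  ev <- evaluate_model(NULL, NULL, truth, predicted = pred)
  expect_identical(unname(ev$confusion), rbind(c(8L, 2L), c(1L, 9L)))
  expect_equal(ev$accuracy, 17 / 20)
  p <- 8 / 9; r <- 0.8
  expect_equal(ev$per_class$precision[1], p)
  expect_equal(ev$per_class$recall[1], r)
  expect_equal(ev$per_class$f1[1], 2 * p * r / (p + r))

  # perfect predictions
  ev <- evaluate_model(NULL, NULL, truth, predicted = truth)
  expect_equal(ev$accuracy, 1)
  expect_true(all(ev$per_class$f1 == 1))

  # a never-predicted class gets precision 0 via the guard
  ev <- evaluate_model(NULL, NULL, c("a", "b"), predicted = c("a", "a"))
  expect_equal(ev$per_class$precision[2], 0)
  expect_equal(ev$per_class$f1[2], 0)
})

test_that("evaluation identities hold for random confusions", {
  set.seed(8)
  for (i in 1:10) {
    k <- sample(2:4, 1); n <- 60L
    classes <- letters[1:k]
    truth <- sample(classes, n, TRUE)
    pred <- sample(classes, n, TRUE)
    ev <- evaluate_model(NULL, NULL, truth, predicted = pred)
    expect_equal(ev$accuracy, sum(diag(ev$confusion)) / n)
    expect_identical(sum(ev$confusion), n)
    # micro-averaged recall (support-weighted) equals accuracy
    support <- rowSums(ev$confusion)
    micro <- sum(ev$per_class$recall * support) / n
    expect_equal(micro, ev$accuracy)
  }
})

test_that("soft voting does not fall below the best member by more than 0.02", {
  set.seed(31)
  n_per <- 100; d <- 5
  X <- rbind(matrix(rnorm(n_per * d), n_per, d),
             matrix(rnorm(n_per * d, mean = 1.2), n_per, d))
  y <- rep(c("a", "b"), each = n_per)
  test <- rbind(matrix(rnorm(60 * d), 60, d),
                matrix(rnorm(60 * d, mean = 1.2), 60, d))
  ytest <- rep(c("a", "b"), each = 60)
  ens <- train_members(X, y, ntree = 300, seed = 13)
  Xs <- anakit:::standardize(ens, test)
  member_acc <- vapply(ens$members, function(m) {
    p <- anakit:::member_probs(m, Xs, ens$class_names)
    mean(ens$class_names[max.col(p, ties.method = "first")] == ytest)
  }, numeric(1))
  ens_acc <- mean(soft_vote(ens, test)$labels == ytest)
  expect_gte(ens_acc, max(member_acc) - 0.02)
})
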