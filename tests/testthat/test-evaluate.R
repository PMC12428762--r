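test_that("confusion matrices count pairs exactly", {
  cm <- confusion(c(1, 1, 2, 2), c(1, 2, 2, 2))
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 2L), 2,
                                   dimnames = list(actual = c("1", "2"),
                                                   predicted = c("1", "2"))),
               ignore_attr = FALSE)
  expect_equal(sum(cm), 4L)
  perfect <- confusion(1:3, 1:3)
  expect_true(all(perfect[upper.tri(perfect)] == 0 &
                  perfect[lower.tri(perfect)] == 0))
  expect_error(confusion(1:3, 1:2), "equal length")
})

test_that("metrics match hand arithmetic on a 2-class table", {
  cm <- structure(matrix(c(40L, 20L, 10L, 30L), 2,
                         dimnames = list(c("x", "y"), c("x", "y"))),
                  class = c("confusion_matrix", "matrix"))
  m <- metrics(cm)
  expect_equal(m$accuracy, 0.70)
  expect_equal(m$pe, 0.50)
  expect_equal(m$kappa, 0.40)
  expect_equal(m$precision[["x"]], 40 / 60)
  expect_equal(m$recall[["x"]], 40 / 50)
  # identity predictions
  id <- metrics(confusion(rep(1:4, 5), rep(1:4, 5)))
  expect_equal(id$accuracy, 1)
  expect_equal(id$macro_f1, 1)
  expect_equal(id$kappa, 1)
})

test_that("metrics agree with a per-sample counting oracle", {
  set.seed(6)
  for (trial in 1:200) {
    n <- sample(5:40, 1)
    labs <- sample(1:4, 2)
    actual <- sample(labs, n, TRUE)
    predicted <- sample(labs, n, TRUE)
    m <- metrics(confusion(actual, predicted))
    expect_equal(m$accuracy, mean(actual == predicted), tolerance = 1e-12)
    for (k in sort(unique(c(actual, predicted)))) {
      kk <- as.character(k)
      npred <- sum(predicted == k)
      nact <- sum(actual == k)
      hits <- sum(actual == k & predicted == k)
      if (npred > 0) expect_equal(m$precision[[kk]], hits / npred,
                                  tolerance = 1e-12)
      if (nact > 0) expect_equal(m$recall[[kk]], hits / nact,
                                 tolerance = 1e-12)
    }
    pe <- sum(sapply(sort(unique(c(actual, predicted))), function(k) {
      mean(actual == k) * mean(predicted == k)
    }))
    expect_equal(m$pe, pe, tolerance = 1e-12)
    expect_equal(m$kappa, (m$accuracy - pe) / (1 - pe), tolerance = 1e-12)
  }
})

test_that("recall decomposes accuracy and kappa never exceeds it", {
  set.seed(8)
  for (trial in 1:20) {
    actual <- sample(1:5, 60, TRUE)
    predicted <- sample(1:5, 60, TRUE)
    m <- metrics(confusion(actual, predicted))
    freq <- rowSums(m$confusion) / m$n
    rec <- ifelse(is.na(m$recall), 0, m$recall)
    expect_equal(sum(rec * freq), m$accuracy, tolerance = 1e-12)
    expect_lte(m$kappa, m$accuracy + 1e-12)
    expect_gte(m$kappa, -1)
  }
})

test_that("uniform random guessing over 13 categories scores near 1/13", {
  set.seed(10)
  cats <- seq(1, 4, 0.25)
  actual <- sample(cats, 26000, TRUE)
  predicted <- sample(cats, 26000, TRUE)
  m <- metrics(confusion(actual, predicted))
  expect_lt(abs(m$accuracy - 1 / 13), 0.005)
})

test_that("noise sensitivity at fraction zero is exactly the clean error", {
  ds <- generate_dataset(small_config(seed = 91L))
  part <- partition_consistency(ds)$consistent
  sp <- split_dataset(part, seed = 4L)
  x <- as.matrix(as.data.frame(sp$train)[, c("L", "a", "b")])
  y <- factor(aveobs(sp$train))
  xt <- as.matrix(as.data.frame(sp$test)[, c("L", "a", "b")])
  yt <- factor(aveobs(sp$test))
  clf <- fit_comparator(x, y, algorithm = "lda", folds = 0L, seed = 1L)
  clean_err <- mean(as.character(predict(clf, xt)) != as.character(yt))
  expect_identical(noise_sensitivity(clf, xt, yt, fraction = 0, reps = 3L,
                                     seed = 2L), clean_err)
  # determinism
  n1 <- noise_sensitivity(clf, xt, yt, fraction = 0.1, reps = 5L, seed = 7L)
  n2 <- noise_sensitivity(clf, xt, yt, fraction = 0.1, reps = 5L, seed = 7L)
  expect_identical(n1, n2)
})

test_that("stronger noise cannot make predictions cleaner on average", {
  lo <- hi <- numeric(10)
  ds <- generate_dataset(small_config(seed = 121L))
  part <- partition_consistency(ds)$consistent
  sp <- split_dataset(part, seed = 4L)
  x <- as.matrix(as.data.frame(sp$train)[, c("L", "a", "b")])
  y <- factor(aveobs(sp$train))
  xt <- as.matrix(as.data.frame(sp$test)[, c("L", "a", "b")])
  yt <- factor(aveobs(sp$test))
  clf <- fit_comparator(x, y, algorithm = "lda", folds = 0L, seed = 1L)
  for (s in 1:10) {
    lo[s] <- noise_sensitivity(clf, xt, yt, fraction = 0.1, reps = 5L, seed = s)
    hi[s] <- noise_sensitivity(clf, xt, yt, fraction = 0.5, reps = 5L, seed = s)
  }
  expect_gte(mean(hi), mean(lo))
})

test_that("throughput returns positive finite rates in both modes", {
  toy <- make_separable_toy(n_per = 15L)
  clf <- fit_comparator(toy$x, toy$y, algorithm = "lda", folds = 0L, seed = 1L)
  tp_pred <- throughput(clf, toy$x, mode = "predict")
  expect_true(is.finite(tp_pred) && tp_pred > 0)
  tp_train <- throughput(function(x, y) fit_lda(x, y), toy$x, toy$y,
                         mode = "train")
  expect_true(is.finite(tp_train) && tp_train > 0)
  expect_error(throughput(clf, toy$x[0, , drop = FALSE]), "empty")
})
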