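test_that("train/test split is disjoint, exhaustive and deterministic", {
  ds <- make_eggs(n = 100L, seed = 2L)
  sp <- split_dataset(ds, fraction = 0.7, seed = 5L, stratified = FALSE)
  expect_equal(nrow(sp$train), 70L)
  expect_equal(nrow(sp$test), 30L)
  expect_length(intersect(sp$train$egg_id, sp$test$egg_id), 0L)
  expect_setequal(c(sp$train$egg_id, sp$test$egg_id), ds$egg_id)
  sp2 <- split_dataset(ds, fraction = 0.7, seed = 5L, stratified = FALSE)
  expect_identical(sp$train$egg_id, sp2$train$egg_id)
  expect_error(split_dataset(ds, fraction = 1.2), "in \\(0, 1\\)")
})

test_that("stratified split keeps every class near the target fraction", {
  ds <- generate_dataset(small_config(seed = 44L))
  part <- partition_consistency(ds)$consistent
  sp <- split_dataset(part, fraction = 0.7, seed = 9L)
  ave_tr <- table(aveobs(sp$train))
  ave_all <- table(aveobs(part))
  for (lv in names(ave_all)) {
    expect_lte(abs(ave_tr[[lv]] - 0.7 * ave_all[[lv]]), 1)
  }
  # a singleton class cannot be split
  df <- as.data.frame(make_eggs(n = 12L, obs_noise = FALSE))
  df[1, paste0("obs", 1:4)] <- 4L
  df[-1, paste0("obs", 1:4)] <- 2L
  expect_error(split_dataset(egg_dataset(df), seed = 1L), "single egg")
})

test_that("LDA separates well-separated classes perfectly", {
  toy <- make_separable_toy()
  fit <- fit_lda(toy$x, toy$y)
  expect_equal(mean(predict(fit, toy$x) == toy$y), 1.0)
  expect_equal(sum(fit$proportion_of_trace), 1, tolerance = 1e-9)
  expect_equal(ncol(fit$scalings), 2L)  # min(3 features, 3 classes - 1)
})

test_that("LDA scalings sphere the pooled within-class covariance", {
  ds <- generate_dataset(small_config(seed = 55L))
  x <- as.matrix(as.data.frame(ds)[, c("L", "a", "b")])
  y <- factor(round(aveobs(ds)))
  fit <- fit_lda(x, y)
  Wt <- t(fit$scalings) %*% fit$pooled_cov %*% fit$scalings
  expect_equal(Wt, diag(ncol(fit$scalings)), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_true(all(diff(fit$proportion_of_trace) <= 1e-9))
})

test_that("LDA matches a brute-force generalised-eigen oracle", {
  # hand-checkable 6-point, 3-class fixture
  x6 <- rbind(c(0, 0, 0), c(2, 1, 0), c(10, 1, 0), c(12, 1, 1),
              c(5, 8, 4), c(5, 9, 5))
  colnames(x6) <- c("L", "a", "b")
  y6 <- factor(c(1, 1, 2, 2, 3, 3))
  fit <- fit_lda(x6, y6)
  orc <- lda_oracle(x6, y6)
  expect_equal(abs(fit$scalings), abs(orc$scalings), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(fit$proportion_of_trace, orc$prop, tolerance = 1e-8)
  # random 5-class instances
  for (seed in 1:5) {
    set.seed(seed)
    x <- matrix(rnorm(60 * 3), 60, 3,
                dimnames = list(NULL, c("L", "a", "b")))
    y <- factor(sample(1:5, 60, TRUE))
    x <- x + as.integer(y)        # give the classes some separation
    fit <- fit_lda(x, y)
    orc <- lda_oracle(x, y)
    expect_equal(abs(fit$scalings), abs(orc$scalings), tolerance = 1e-6,
                 ignore_attr = TRUE)
    expect_equal(fit$eigenvalues, orc$eigenvalues, tolerance = 1e-6)
  }
})

test_that("LDA agrees with the reference implementation", {
  ds <- generate_dataset(small_config(seed = 66L))
  part <- partition_consistency(ds)$consistent
  x <- as.matrix(as.data.frame(part)[, c("L", "a", "b")])
  y <- factor(aveobs(part))
  fit <- fit_lda(x, y)
  ref <- MASS::lda(x, grouping = y)
  expect_equal(abs(unclass(fit$scalings)), abs(unclass(ref$scaling)),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(fit$proportion_of_trace, ref$svd^2 / sum(ref$svd^2),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(as.character(predict(fit, x)),
               as.character(predict(ref, x)$class))
})

test_that("LDA prediction respects class means and affine invariance", {
  toy <- make_separable_toy(n_per = 30L, seed = 12L)
  fit <- fit_lda(toy$x, toy$y, prior = rep(1 / 3, 3))
  means <- fit$means
  expect_equal(as.character(predict(fit, means)), levels(toy$y))
  # invertible affine transform of the features leaves predictions unchanged
  set.seed(3)
  A <- matrix(rnorm(9), 3, 3) + diag(3) * 2
  shift <- c(5, -2, 7)
  tx <- toy$x %*% A + matrix(shift, nrow(toy$x), 3, byrow = TRUE)
  newx <- matrix(rnorm(60, sd = 8), 20, 3) +
    toy$x[sample(nrow(toy$x), 20), ]
  tnewx <- newx %*% A + matrix(shift, nrow(newx), 3, byrow = TRUE)
  fit_t <- fit_lda(tx, toy$y, prior = rep(1 / 3, 3))
  expect_equal(as.character(predict(fit, newx)),
               as.character(predict(fit_t, tnewx)))
  expect_true(all(predict(fit, newx) %in% levels(toy$y)))
})

test_that("degenerate LDA inputs are rejected with guidance", {
  x <- matrix(rnorm(20 * 3), 20, 3)
  expect_error(fit_lda(x, rep(1, 20)), "at least 2 classes")
  expect_error(fit_lda(x, c(1, rep(2, 19))), "fewer than 2")
  xs <- cbind(x[, 1], x[, 1], x[, 2])   # collinear features
  expect_error(fit_lda(xs, rep(1:2, 10)), "singular")
  fit <- fit_lda(x[, 1:2], rep(1:2, 10))
  expect_error(predict(fit, x), "feature columns")
})

test_that("every comparator algorithm learns a separable toy", {
  toy <- make_separable_toy(n_per = 20L, seed = 10L)
  test <- make_separable_toy(n_per = 10L, seed = 20L)
  for (alg in c("lda", "rf", "svm", "nnet")) {
    clf <- fit_comparator(toy$x, toy$y, algorithm = alg, folds = 5L, seed = 2L)
    pred <- predict(clf, test$x)
    expect_length(pred, nrow(test$x))
    expect_false(anyNA(pred))
    expect_equal(mean(as.character(pred) == as.character(test$y)), 1.0)
    expect_gte(clf$cv_accuracy, 0.9)
  }
  expect_error(fit_comparator(toy$x, toy$y, algorithm = "knn"), "arg")
})

test_that("comparator training is deterministic given the seed", {
  ds <- generate_dataset(small_config(seed = 31L))
  x <- as.matrix(as.data.frame(ds)[, c("L", "a", "b")])
  y <- factor(round(aveobs(ds)))
  for (alg in c("rf", "nnet")) {
    c1 <- fit_comparator(x, y, algorithm = alg, folds = 0L, seed = 9L)
    c2 <- fit_comparator(x, y, algorithm = alg, folds = 0L, seed = 9L)
    expect_identical(as.character(predict(c1, x)),
                     as.character(predict(c2, x)))
  }
})

test_that("scenario subsets partition the data", {
  ds <- generate_dataset(small_config(seed = 70L))
  all <- scenario_subset(ds, "all")
  cons <- scenario_subset(ds, "consistent")
  incons <- scenario_subset(ds, "inconsistent")
  expect_equal(nrow(cons) + nrow(incons), nrow(all))
  expect_length(intersect(cons$egg_id, incons$egg_id), 0L)
})
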