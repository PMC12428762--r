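#' Stratified train/test split
#'
#' Splits a dataset into training and testing subsets, by default
#' stratified on the mean-visual-score category so that sparse categories
#' are represented on both sides.  Deterministic given `seed`.
#'
#' @param ds an `egg_dataset`.
#' @param fraction training fraction in (0, 1); default 0.70.
#' @param seed integer seed.
#' @param stratified stratify on the AveObs category (default `TRUE`).
#' @return List with elements `train` and `test` (`egg_dataset`s).
#' @export
split_dataset <- function(ds, fraction = 0.7, seed = 1L, stratified = TRUE) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  n <- nrow(ds)
  ave <- aveobs(ds)
  with_seed(seed, {
    if (stratified) {
      cls <- factor(ave)
      sizes <- table(cls)
      if (any(sizes < 2L)) {
        stop("stratified split impossible: class ",
             names(sizes)[which(sizes < 2L)[1L]], " has a single egg")
      }
      idx_train <- unlist(lapply(levels(cls), function(lv) {
        rows <- which(cls == lv)
        k <- round(fraction * length(rows))
        k <- min(max(k, 1L), length(rows) - 1L)   # both sides non-empty
        sample(rows, k)
      }), use.names = FALSE)
    } else {
      idx_train <- sample.int(n, round(fraction * n))
    }
    idx_train <- sort(idx_train)
    sub <- function(rows) egg_dataset(as.data.frame(ds)[rows, , drop = FALSE],
                                      state = dataset_state(ds))
    list(train = sub(idx_train), test = sub(setdiff(seq_len(n), idx_train)))
  })
}

#' Multi-class linear discriminant analysis
#'
#' Fits LDA by solving the generalised eigenproblem of the between-class
#' scatter against the pooled within-class covariance.  The scalings
#' sphere the within-class covariance (each discriminant has unit pooled
#' within-class variance), and each column is oriented so its
#' largest-magnitude coefficient is positive.  The proportion of trace is
#' the share of between-class variance carried by each discriminant.
#'
#' @param x numeric matrix of features (rows = samples).
#' @param y class labels (coerced to factor); every class needs >= 2
#'   samples.
#' @param prior class prior probabilities; defaults to training
#'   proportions.
#' @return An `egg_lda` model with `means`, `pooled_cov`, `scalings`,
#'   `eigenvalues`, `proportion_of_trace`, `prior` and `levels`.
#' @export
fit_lda <- function(x, y, prior = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  y <- droplevels(factor(y))
  K <- nlevels(y)
  p <- ncol(x)
  if (K < 2L) stop("need at least 2 classes")
  counts <- table(y)
  if (any(counts < 2L)) {
    stop("class ", names(counts)[which(counts < 2L)[1L]],
         " has fewer than 2 samples")
  }
  if (is.null(prior)) prior <- as.vector(counts) / length(y)
  if (abs(sum(prior) - 1) > 1e-8) stop("priors must sum to 1")

  means <- t(vapply(levels(y), function(lv) colMeans(x[y == lv, , drop = FALSE]),
                    numeric(p)))
  W <- matrix(0, p, p)
  for (lv in levels(y)) {
    xc <- scale(x[y == lv, , drop = FALSE], center = TRUE, scale = FALSE)
    W <- W + crossprod(xc)
  }
  W <- W / (length(y) - K)
  grand <- colSums(means * as.vector(counts)) / length(y)
  Mc <- sweep(means, 2L, grand)
  B <- crossprod(Mc * sqrt(as.vector(counts)))  # weighted between-class scatter

  Uc <- tryCatch(chol(W), error = function(e) {
    stop("pooled within-class covariance is singular; ",
         "jitter the features or merge classes")
  })
  Uinv <- backsolve(Uc, diag(p))
  Mw <- t(Uinv) %*% B %*% Uinv
  es <- eigen((Mw + t(Mw)) / 2, symmetric = TRUE)
  d <- min(p, K - 1L)
  vals <- pmax(es$values[seq_len(d)], 0)
  scalings <- Uinv %*% es$vectors[, seq_len(d), drop = FALSE]
  for (j in seq_len(d)) {
    i <- which.max(abs(scalings[, j]))
    if (scalings[i, j] < 0) scalings[, j] <- -scalings[, j]
  }
  dimnames(scalings) <- list(colnames(x), paste0("LD", seq_len(d)))

  structure(list(levels = levels(y), prior = stats::setNames(prior, levels(y)),
                 counts = counts, means = means, pooled_cov = W,
                 scalings = scalings, eigenvalues = vals,
                 proportion_of_trace = vals / sum(vals),
                 features = colnames(x)),
            class = "egg_lda")
}

#' @export
print.egg_lda <- function(x, digits = 3, ...) {
  cat(sprintf("<egg_lda> %d classes, %d features\n",
              length(x$levels), length(x$features)))
  cat("discriminant coefficients:\n")
  print(round(x$scalings, digits))
  cat("proportion of trace:",
      paste(sprintf("%.4f", x$proportion_of_trace), collapse = " "), "\n")
  invisible(x)
}

#' Predict classes with a fitted LDA model
#'
#' Gaussian equal-covariance Bayes rule with the training priors;
#' deterministic.
#'
#' @param object an `egg_lda` model.
#' @param newdata feature matrix with the training feature count.
#' @param ... unused.
#' @return Factor of predicted class labels (a subset of the training
#'   labels).
#' @export
predict.egg_lda <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  if (ncol(x) != length(object$features)) {
    stop("newdata must have ", length(object$features), " feature columns")
  }
  Wi <- solve(object$pooled_cov)
  A <- object$means %*% Wi                     # K x p
  const <- -0.5 * rowSums(A * object$means) + log(object$prior)
  scores <- x %*% t(A) + matrix(const, nrow(x), length(object$levels),
                                byrow = TRUE)
  factor(object$levels[max.col(scores, ties.method = "first")],
         levels = object$levels)
}

#' Train a classifier for visual colour scores
#'
#' Wraps the four algorithms compared by the pipeline behind one surface:
#' in-package LDA, random forest (500 trees, `floor(sqrt(p))` variables
#' per split), SVM with a radial basis kernel and automatic feature
#' scaling, and a single-hidden-layer neural network with 10 logistic
#' (sigmoid) units, whose inputs are standardised to zero mean and unit
#' variance before training.  k-fold cross-validated accuracy on the
#' training data is recorded (folds shrink to the smallest class size if a
#' class is rarer than the fold count).  Deterministic given `seed`.
#'
#' @param x training feature matrix (rows = samples).
#' @param y training class labels.
#' @param algorithm `"lda"`, `"rf"`, `"svm"` or `"nnet"`.
#' @param folds cross-validation folds (default 10); set to 0 to skip CV.
#' @param seed integer seed feeding fold assignment and the stochastic
#'   learners.
#' @return An `egg_classifier`; call [predict()] on it with a feature
#'   matrix.  Carries `cv_accuracy` when CV was run.
#' @export
fit_comparator <- function(x, y, algorithm = c("lda", "rf", "svm", "nnet"),
                           folds = 10L, seed = 1L) {
  algorithm <- match.arg(algorithm)
  x <- as.matrix(x)
  y <- droplevels(factor(y))
  if (folds > 0) {
    folds <- min(folds, min(table(y)))
    if (folds < 2L) folds <- 0L
  }
  fit_one <- function(xt, yt) {
    yt <- droplevels(yt)
    switch(algorithm,
      lda = fit_lda(xt, yt),
      rf = randomForest::randomForest(
        x = xt, y = yt, ntree = 500L,
        mtry = max(1L, floor(sqrt(ncol(xt))))),
      svm = e1071::svm(x = xt, y = yt, kernel = "radial", scale = TRUE),
      nnet = {
        ctr <- colMeans(xt)
        scl <- apply(xt, 2L, stats::sd)
        scl[scl == 0] <- 1
        xs <- scale(xt, center = ctr, scale = scl)
        fit <- nnet::nnet(xs, nnet::class.ind(yt), size = 10L, softmax = TRUE,
                          maxit = 500L, trace = FALSE)
        list(fit = fit, center = ctr, scale = scl, levels = levels(yt))
      })
  }
  predict_one <- function(model, newx) {
    switch(algorithm,
      lda = predict(model, newx),
      rf = predict(model, newx),
      svm = predict(model, newx),
      nnet = {
        xs <- scale(as.matrix(newx), center = model$center, scale = model$scale)
        pr <- predict(model$fit, xs)
        factor(model$levels[max.col(pr, ties.method = "first")],
               levels = model$levels)
      })
  }
  cv_acc <- NA_real_
  with_seed(seed, {
    if (folds >= 2L) {
      fold_id <- integer(length(y))
      for (lv in levels(y)) {            # stratified fold assignment
        rows <- which(y == lv)
        fold_id[rows] <- sample(rep_len(seq_len(folds), length(rows)))
      }
      hits <- 0L
      for (f in seq_len(folds)) {
        tr <- fold_id != f
        m <- fit_one(x[tr, , drop = FALSE], y[tr])
        pr <- predict_one(m, x[!tr, , drop = FALSE])
        hits <- hits + sum(as.character(pr) == as.character(y[!tr]))
      }
      cv_acc <- hits / length(y)
    }
    model <- fit_one(x, y)
  })
  structure(list(algorithm = algorithm, model = model,
                 predict_fun = predict_one, levels = levels(y),
                 cv_accuracy = cv_acc, folds = folds),
            class = "egg_classifier")
}

#' @export
predict.egg_classifier <- function(object, newdata, ...) {
  object$predict_fun(object$model, as.matrix(newdata))
}

#' @export
print.egg_classifier <- function(x, ...) {
  cat(sprintf("<egg_classifier> %s, %d classes%s\n", x$algorithm,
              length(x$levels),
              if (is.na(x$cv_accuracy)) "" else
                sprintf(", %d-fold CV accuracy %.3f", x$folds, x$cv_accuracy)))
  invisible(x)
}

#' Restrict a dataset to an analysis scenario
#'
#' The three scenarios mirror the analysis design: `"all"` eggs (13
#' possible AveObs categories), `"consistent"` (unanimous observer codes;
#' 4 categories) and `"inconsistent"` (the remainder).
#'
#' @param ds an `egg_dataset`.
#' @param scenario `"all"`, `"consistent"` or `"inconsistent"`.
#' @return The subset as an `egg_dataset`.
#' @export
scenario_subset <- function(ds, scenario = c("all", "consistent", "inconsistent")) {
  scenario <- match.arg(scenario)
  if (scenario == "all") return(ds)
  part <- partition_consistency(ds)
  part[[scenario]]
}
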