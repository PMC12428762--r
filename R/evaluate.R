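#' Confusion matrix
#'
#' Square count matrix indexed by (actual, predicted) over the sorted
#' union of the observed labels.
#'
#' @param actual,predicted label vectors of equal length.
#' @return Integer matrix of class `confusion_matrix` (rows = actual,
#'   columns = predicted).
#' @export
confusion <- function(actual, predicted) {
  if (length(actual) != length(predicted)) {
    stop("actual and predicted must have equal length")
  }
  if (length(actual) == 0L) stop("no samples to tabulate")
  labs <- sort(unique(c(as.character(actual), as.character(predicted))))
  cm <- table(actual = factor(as.character(actual), levels = labs),
              predicted = factor(as.character(predicted), levels = labs))
  structure(unclass(cm), class = c("confusion_matrix", "matrix"))
}

#' Classification metrics from a confusion matrix
#'
#' Computes overall accuracy, per-class precision (correct / total
#' predicted as the class), recall (correct / total actually in the
#' class), F1 (harmonic mean), their macro averages, the chance agreement
#' `Pe` (sum over classes of the product of actual and predicted
#' marginals, divided by the squared total) and Cohen's kappa,
#' `(accuracy - Pe) / (1 - Pe)`.  Classes never predicted have undefined
#' precision/F1 and are excluded from the corresponding macro averages.
#'
#' @param cm a `confusion_matrix`, or the actual labels (with `predicted`
#'   supplied).
#' @param predicted optional predicted labels when `cm` is a label vector.
#' @return A `metrics_report` list.
#' @examples
#' m <- metrics(confusion(c(1, 1, 2, 2), c(1, 2, 2, 2)))
#' m$accuracy
#' @export
metrics <- function(cm, predicted = NULL) {
  if (!inherits(cm, "confusion_matrix")) {
    if (is.null(predicted)) stop("supply a confusion matrix or two label vectors")
    cm <- confusion(cm, predicted)
  }
  total <- sum(cm)
  if (total == 0L) stop("empty confusion matrix")
  diagv <- diag(cm)
  actual_marg <- rowSums(cm)
  pred_marg <- colSums(cm)
  accuracy <- sum(diagv) / total
  precision <- ifelse(pred_marg > 0, diagv / pred_marg, NA_real_)
  recall <- ifelse(actual_marg > 0, diagv / actual_marg, NA_real_)
  f1 <- ifelse(!is.na(precision) & !is.na(recall) & (precision + recall) > 0,
               2 * precision * recall / (precision + recall),
               ifelse(!is.na(precision) & !is.na(recall), 0, NA_real_))
  pe <- sum(actual_marg * pred_marg) / total^2
  kappa <- if (pe < 1) (accuracy - pe) / (1 - pe) else NA_real_
  structure(list(n = total, accuracy = accuracy, pe = pe, kappa = kappa,
                 precision = precision, recall = recall, f1 = f1,
                 macro_precision = mean(precision, na.rm = TRUE),
                 macro_recall = mean(recall, na.rm = TRUE),
                 macro_f1 = mean(f1, na.rm = TRUE),
                 confusion = cm),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 3, ...) {
  cat(sprintf("<metrics_report> n = %d\n", x$n))
  cat(sprintf("accuracy %.3f | macro P %.3f R %.3f F1 %.3f | kappa %.3f (Pe %.3f)\n",
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1,
              x$kappa, x$pe))
  invisible(x)
}

#' Noise sensitivity of a classifier
#'
#' Mean prediction error rate when independent Gaussian noise is added to
#' every feature of the test inputs simultaneously, at a stated fraction
#' of each feature's (test-set) standard deviation, averaged over
#' repetitions.  The model is fixed; only the inputs are perturbed.  A
#' zero-variance feature receives no noise.  Deterministic given `seed`.
#'
#' @param model anything with a [predict()] method returning labels (an
#'   `egg_classifier`, `egg_lda`, ...).
#' @param x test feature matrix.
#' @param y true test labels.
#' @param fraction noise SD as a fraction of each feature SD (default
#'   0.10).
#' @param reps repetitions (default 30).
#' @param seed integer seed.
#' @return Mean error rate (`1 - accuracy`) over repetitions.
#' @export
noise_sensitivity <- function(model, x, y, fraction = 0.1, reps = 30L,
                              seed = 1L) {
  if (fraction < 0) stop("fraction must be non-negative")
  if (reps < 1L) stop("need at least one repetition")
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("empty test set")
  y <- as.character(y)
  sds <- apply(x, 2L, stats::sd)
  sds[is.na(sds) | sds == 0] <- 0
  with_seed(seed, {
    errs <- vapply(seq_len(reps), function(r) {
      noise <- matrix(stats::rnorm(length(x)), nrow(x), ncol(x))
      noise <- sweep(noise, 2L, fraction * sds, `*`)
      xn <- x + noise
      colnames(xn) <- colnames(x)
      mean(as.character(predict(model, xn)) != y)
    }, numeric(1))
    mean(errs)
  })
}

#' Throughput of a classifier
#'
#' Samples processed per second, measured by wall clock, for either
#' training (refits the supplied fit function) or prediction.  Reported
#' for comparison only; the value is hardware dependent.
#'
#' @param model an `egg_classifier` (for `mode = "predict"`), or a
#'   function `function(x, y)` returning a fitted model (for
#'   `mode = "train"`).
#' @param x feature matrix.
#' @param y labels (training mode only).
#' @param mode `"predict"` or `"train"`.
#' @param min_time minimum measured wall time in seconds; the operation is
#'   repeated until this is reached so fast models are timed reliably.
#' @return Samples per second (positive finite number).
#' @export
throughput <- function(model, x, y = NULL, mode = c("predict", "train"),
                       min_time = 0.05) {
  mode <- match.arg(mode)
  x <- as.matrix(x)
  if (nrow(x) == 0L) stop("empty data")
  op <- if (mode == "predict") {
    function() predict(model, x)
  } else {
    if (is.null(y)) stop("training mode needs labels")
    if (!is.function(model)) stop("training mode needs a fit function(x, y)")
    function() model(x, y)
  }
  reps <- 0L
  elapsed <- 0
  t0 <- proc.time()[["elapsed"]]
  repeat {
    op()
    reps <- reps + 1L
    elapsed <- proc.time()[["elapsed"]] - t0
    if (elapsed >= min_time || reps >= 1000L) break
  }
  reps * nrow(x) / max(elapsed, .Machine$double.eps)
}
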