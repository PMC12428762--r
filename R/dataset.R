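EGG_COLUMNS <- c("batch", "egg_id", "L", "a", "b",
                 "obs1", "obs2", "obs3", "obs4")

#' Construct a validated egg-colour dataset
#'
#' An egg dataset is a data frame with one row per egg holding the batch
#' label, a unique egg identifier, the CIELab colour reading (`L`, `a`, `b`)
#' and the four observers' ordinal colour scores (`obs1`..`obs4`, each in
#' 1 = Light, 2 = Blue, 3 = Green, 4 = Olive).  The mean visual score
#' (`AveObs`) and the canonical four-observer code are derived on demand via
#' [aveobs()] and [obs_code()].
#'
#' @param df data frame with columns `batch`, `egg_id`, `L`, `a`, `b`,
#'   `obs1`..`obs4`.
#' @param state either `"raw"` (as measured) or `"corrected"`
#'   (batch-corrected).
#' @return An object of class `egg_dataset` (a data frame).
#' @examples
#' df <- data.frame(batch = "B1", egg_id = c("e1", "e2"),
#'                  L = c(82, 80), a = c(-7, -6), b = c(10, 12),
#'                  obs1 = c(2, 3), obs2 = c(2, 3), obs3 = c(2, 3), obs4 = c(2, 3))
#' ds <- egg_dataset(df)
#' aveobs(ds)
#' @export
egg_dataset <- function(df, state = c("raw", "corrected")) {
  state <- match.arg(state)
  stopifnot(is.data.frame(df))
  missing_cols <- setdiff(EGG_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df)[, c(EGG_COLUMNS,
                              setdiff(names(df), EGG_COLUMNS))]
  df$batch <- as.character(df$batch)
  df$egg_id <- as.character(df$egg_id)
  if (nrow(df) == 0L) stop("dataset has no rows")
  for (col in c("L", "a", "b", "obs1", "obs2", "obs3", "obs4")) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      bad <- suppressWarnings(which(is.na(as.numeric(as.character(v)))))
      stop("non-numeric value in column '", col, "' at row ",
           if (length(bad)) bad[1L] else 1L)
    }
    if (anyNA(v)) stop("missing value in column '", col, "' at row ",
                       which(is.na(v))[1L])
  }
  if (anyDuplicated(df$egg_id)) {
    stop("duplicate egg_id: ", df$egg_id[anyDuplicated(df$egg_id)])
  }
  bad <- which(df$L < 0 | df$L > 100)
  if (length(bad)) stop("L outside [0, 100] at row ", bad[1L])
  for (col in c("a", "b")) {
    bad <- which(abs(df[[col]]) > 120)
    if (length(bad)) stop(col, " outside [-120, 120] at row ", bad[1L])
  }
  for (col in paste0("obs", 1:4)) {
    v <- df[[col]]
    bad <- which(!(v %in% 1:4))
    if (length(bad)) {
      stop("column '", col, "' has value outside {1, 2, 3, 4} at row ", bad[1L])
    }
  }
  structure(df, class = c("egg_dataset", "data.frame"), state = state)
}

#' @export
print.egg_dataset <- function(x, ...) {
  cat(sprintf("<egg_dataset> %d eggs, %d batch(es), state: %s\n",
              nrow(x), length(unique(x$batch)), dataset_state(x)))
  print.data.frame(utils::head(as.data.frame(x), 6L), ...)
  if (nrow(x) > 6L) cat("... and", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

#' Dataset state flag
#'
#' @param ds an `egg_dataset`.
#' @return `"raw"` or `"corrected"`.
#' @export
dataset_state <- function(ds) {
  s <- attr(ds, "state")
  if (is.null(s)) "raw" else s
}

obs_matrix <- function(ds) {
  as.matrix(as.data.frame(ds)[, paste0("obs", 1:4)])
}

color_matrix <- function(ds) {
  m <- as.matrix(as.data.frame(ds)[, c("L", "a", "b")])
  storage.mode(m) <- "double"
  m
}

#' Mean visual colour score of one or more eggs
#'
#' `compute_aveobs()` averages a quadruple of ordinal observer scores; the
#' result always lies on the 13-point grid 1.00, 1.25, ..., 4.00.
#' `aveobs()` is the dataset-level shortcut.
#'
#' @param obs integer vector of length 4, or a matrix with 4 columns (one
#'   row per egg); all entries in `{1, 2, 3, 4}`.
#' @return Numeric vector of mean scores.
#' @examples
#' compute_aveobs(c(1, 1, 1, 2)) # 1.25
#' @export
compute_aveobs <- function(obs) {
  if (is.matrix(obs) || is.data.frame(obs)) {
    obs <- as.matrix(obs)
    if (ncol(obs) != 4L) stop("observer matrix must have 4 columns")
  } else {
    if (length(obs) != 4L) stop("obs must hold exactly 4 scores")
    obs <- matrix(obs, nrow = 1L)
  }
  if (!all(obs %in% 1:4)) stop("observer scores must be in {1, 2, 3, 4}")
  rowMeans(obs)
}

#' @rdname compute_aveobs
#' @param ds an `egg_dataset`.
#' @export
aveobs <- function(ds) compute_aveobs(obs_matrix(ds))

#' Canonical four-observer code
#'
#' The code is the multiset of the four scores written as digits in
#' ascending order, e.g. `(2, 1, 2, 3)` becomes `"1223"`.  Unanimous codes
#' (`"1111"`, `"2222"`, `"3333"`, `"4444"`) identify consistent samples.
#'
#' @inheritParams compute_aveobs
#' @return Character vector of 4-digit codes.
#' @export
obs_code <- function(obs) {
  if (is.matrix(obs) || is.data.frame(obs)) {
    obs <- as.matrix(obs)
  } else {
    obs <- matrix(obs, nrow = 1L)
  }
  if (ncol(obs) != 4L) stop("observer matrix must have 4 columns")
  if (!all(obs %in% 1:4)) stop("observer scores must be in {1, 2, 3, 4}")
  apply(obs, 1L, function(z) paste(sort(z), collapse = ""))
}

#' Read an egg-colour table from CSV
#'
#' Expects a comma-separated UTF-8 file with header columns
#' `batch,egg_id,L,a,b,obs1,obs2,obs3,obs4`; extra columns are kept.
#'
#' @param path file path.
#' @param state state flag passed to [egg_dataset()].
#' @return An `egg_dataset`, row order preserved.
#' @export
read_dataset <- function(path, state = c("raw", "corrected")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  egg_dataset(df, state = match.arg(state))
}

#' Write an egg-colour table to CSV
#'
#' Appends derived `aveobs` and `code` columns to the standard columns.
#'
#' @param ds an `egg_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  out <- as.data.frame(ds)
  out$aveobs <- aveobs(ds)
  out$code <- obs_code(obs_matrix(ds))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Split a dataset into consistent and inconsistent samples
#'
#' Consistent samples are those on which all four observers agreed (codes
#' 1111, 2222, 3333 or 4444); all remaining eggs are inconsistent.  The
#' returned count table cross-tabulates mean score and observer code.
#'
#' @param ds an `egg_dataset`.
#' @return A list with elements `consistent` and `inconsistent` (both
#'   `egg_dataset`s, either possibly empty) and `counts`, a data frame of
#'   per-(AveObs, code) sample counts with a `consistent` flag.
#' @export
partition_consistency <- function(ds) {
  codes <- obs_code(obs_matrix(ds))
  ave <- aveobs(ds)
  is_cons <- codes %in% c("1111", "2222", "3333", "4444")
  counts <- as.data.frame(table(aveobs = ave, code = codes),
                          stringsAsFactors = FALSE)
  counts <- counts[counts$Freq > 0L, ]
  counts$aveobs <- as.numeric(counts$aveobs)
  counts$consistent <- counts$code %in% c("1111", "2222", "3333", "4444")
  counts <- counts[order(counts$aveobs, counts$code), ]
  names(counts)[names(counts) == "Freq"] <- "n"
  rownames(counts) <- NULL
  keep_class <- function(sub) {
    if (nrow(sub) == 0L) return(structure(sub, class = class(ds),
                                          state = dataset_state(ds)))
    egg_dataset(as.data.frame(sub), state = dataset_state(ds))
  }
  list(consistent = keep_class(ds[is_cons, , drop = FALSE]),
       inconsistent = keep_class(ds[!is_cons, , drop = FALSE]),
       counts = counts)
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper around [stats::cor()] shared by the summary,
#' index-scan and index-comparison code paths.
#'
#' @param x,y numeric vectors of equal length (at least 3), neither
#'   constant.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for constant input")
  }
  stats::cor(x, y)
}

#' Descriptive statistics for the colour channels
#'
#' Computes per-channel mean, sample standard deviation (n - 1 denominator)
#' and coefficient of variation (`100 * SD / |mean|`, so a negative-mean
#' channel still reports a positive CV), the pairwise Pearson correlation
#' matrix of (L, a, b), and the correlation of each channel with the mean
#' visual score.  Correlations involving a zero-variance channel are
#' reported as `NA`.
#'
#' @param ds an `egg_dataset` with at least 3 rows.
#' @return A `color_summary` list with components `n`, `mean`, `sd`, `cv`,
#'   `cor` (3 x 3) and `cor_aveobs` (length 3).
#' @export
summarize_colors <- function(ds) {
  X <- color_matrix(ds)
  if (nrow(X) < 3L) stop("need at least 3 eggs to summarise")
  ave <- aveobs(ds)
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  cv <- ifelse(mu == 0, NA_real_, 100 * sdv / abs(mu))
  cmat <- matrix(NA_real_, 3L, 3L, dimnames = list(colnames(X), colnames(X)))
  diag(cmat) <- 1
  cav <- stats::setNames(rep(NA_real_, 3L), colnames(X))
  ave_const <- stats::sd(ave) == 0
  for (i in 1:3) {
    if (sdv[i] == 0) next
    for (j in 1:3) {
      if (i != j && sdv[j] > 0) cmat[i, j] <- stats::cor(X[, i], X[, j])
    }
    if (!ave_const) cav[i] <- stats::cor(X[, i], ave)
  }
  structure(list(n = nrow(X), mean = mu, sd = sdv, cv = cv,
                 cor = cmat, cor_aveobs = cav),
            class = "color_summary")
}

#' @export
print.color_summary <- function(x, digits = 3, ...) {
  cat(sprintf("<color_summary> n = %d\n", x$n))
  tab <- rbind(mean = x$mean, sd = x$sd, `cv%` = x$cv)
  print(round(tab, digits))
  cat("correlations:\n")
  print(round(x$cor, digits))
  cat("correlation with AveObs:\n")
  print(round(x$cor_aveobs, digits))
  invisible(x)
}

#' Reference distribution of visual scores
#'
#' Counts of eggs by mean visual score and four-observer code in the
#' reference population of 2274 blue-green eggs used to calibrate the
#' synthetic generator: 860 consistent and 1414 inconsistent samples across
#' the 13 possible mean-score values.
#'
#' @return Data frame with columns `aveobs`, `codes` (comma-separated codes
#'   observed at that score), `n_consistent`, `n_inconsistent`, `n_all`.
#' @export
reference_visual_counts <- function() {
  data.frame(
    aveobs = seq(1, 4, by = 0.25),
    codes = c("1111", "1112", "1113,1122", "1114,1123,1222",
              "1124,1133,1223,2222", "1134,1224,1233,2223",
              "1144,1234,1333,2233", "1334,2234,2333",
              "1344,2334,3333", "1444,2344,3334", "2444,3344",
              "3444", "4444"),
    n_consistent = c(63, 0, 0, 0, 199, 0, 0, 0, 484, 0, 0, 0, 114),
    n_inconsistent = c(0, 29, 69, 135, 80, 260, 287, 337, 9, 95, 59, 54, 0),
    n_all = c(63, 29, 69, 135, 279, 260, 287, 337, 493, 95, 59, 54, 114),
    stringsAsFactors = FALSE
  )
}
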