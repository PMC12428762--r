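#' Fit an empirical-Bayes location/scale batch-correction model
#'
#' Parametric ComBat-style correction of the three colour channels, with
#' the mean visual score retained as a covariate so biological colour
#' variation is not removed along with the batch effects.  The channels are
#' the feature dimension (a 3 x n matrix), so the empirical-Bayes priors
#' borrow strength across only three features; with a single feature the
#' model falls back to the plain location/scale estimates (the priors would
#' be degenerate).
#'
#' Fitting follows the standard parametric algorithm: (1) estimate a grand
#' model per channel (batch means plus covariate slope) by least squares
#' and standardise each channel by the covariate-adjusted grand mean and
#' pooled variance; (2) estimate per-batch location (`gamma`) and variance
#' (`delta`) on the standardised scale; (3) shrink them via normal /
#' inverse-gamma priors with method-of-moments hyperparameters, iterating
#' the posterior updates to convergence.  The corrected value of egg j in
#' batch i is `(x_ij - alpha_i) / gamma_i` around the covariate-adjusted
#' grand model, returned on the original measurement scale.
#'
#' @param ds an `egg_dataset` with at least 2 batches, each of size >= 2.
#' @param covariate numeric covariate preserved during correction; defaults
#'   to the mean visual score [aveobs()].
#' @param eb use empirical-Bayes shrinkage (`TRUE`) or the raw per-batch
#'   estimates (`FALSE`).
#' @param tol convergence tolerance of the EB iteration.
#' @param maxit maximum EB iterations; non-convergence is an error.
#' @return A `combat_model` with per-batch location/scale parameters
#'   (`alpha`, `gamma`, on the measurement scale), their standardised-scale
#'   counterparts (`gamma_star`, `delta_star`), the unshrunk estimates and
#'   prior hyperparameters, and the grand model.
#' @export
fit_combat <- function(ds, covariate = aveobs(ds), eb = TRUE,
                       tol = 1e-6, maxit = 500L) {
  X <- t(color_matrix(ds))            # features (3) x samples (n)
  batch <- factor(ds$batch)
  n <- ncol(X)
  G <- nrow(X)
  if (nlevels(batch) < 2L) stop("nothing to correct: only one batch")
  if (any(table(batch) < 2L)) stop("every batch must contain at least 2 eggs")
  if (length(covariate) != n) stop("covariate length must match dataset size")

  batch_design <- stats::model.matrix(~ -1 + batch)
  design <- cbind(batch_design, covariate = covariate)
  nb <- nlevels(batch)
  n_batches <- as.vector(table(batch))

  B_hat <- solve(crossprod(design), crossprod(design, t(X)))
  grand_mean <- drop(crossprod(n_batches / n, B_hat[seq_len(nb), , drop = FALSE]))
  resid <- X - t(design %*% B_hat)
  var_pooled <- rowSums(resid^2) / n

  cov_part <- design
  cov_part[, seq_len(nb)] <- 0
  stand_mean <- outer(grand_mean, rep(1, n)) + t(cov_part %*% B_hat)
  s_data <- (X - stand_mean) / sqrt(var_pooled)

  gamma_hat <- t(solve(crossprod(batch_design),
                       crossprod(batch_design, t(s_data))))   # G x nb
  delta_hat <- matrix(NA_real_, G, nb)
  for (i in seq_len(nb)) {
    delta_hat[, i] <- apply(s_data[, batch == levels(batch)[i], drop = FALSE],
                            1L, stats::var)
  }

  if (eb && G > 1L) {
    gamma_bar <- colMeans(gamma_hat)
    t2 <- apply(gamma_hat, 2L, stats::var)
    a_prior <- apply(delta_hat, 2L, function(d) {
      m <- mean(d); s2 <- stats::var(d); (2 * s2 + m^2) / s2
    })
    b_prior <- apply(delta_hat, 2L, function(d) {
      m <- mean(d); s2 <- stats::var(d); (m * s2 + m^3) / s2
    })
    gamma_star <- gamma_hat
    delta_star <- delta_hat
    for (i in seq_len(nb)) {
      sd_i <- s_data[, batch == levels(batch)[i], drop = FALSE]
      n_i <- ncol(sd_i)
      g_old <- gamma_hat[, i]
      d_old <- delta_hat[, i]
      change <- Inf
      it <- 0L
      while (change > tol) {
        it <- it + 1L
        if (it > maxit) stop("EB iteration failed to converge for batch ",
                             levels(batch)[i])
        g_new <- (t2[i] * n_i * gamma_hat[, i] + d_old * gamma_bar[i]) /
          (t2[i] * n_i + d_old)
        sum2 <- rowSums((sd_i - g_new)^2)
        d_new <- (0.5 * sum2 + b_prior[i]) / (n_i / 2 + a_prior[i] - 1)
        change <- max(abs(g_new - g_old) / abs(g_old),
                      abs(d_new - d_old) / abs(d_old))
        g_old <- g_new
        d_old <- d_new
      }
      gamma_star[, i] <- g_old
      delta_star[, i] <- d_old
    }
  } else {
    gamma_bar <- t2 <- a_prior <- b_prior <- NULL
    gamma_star <- gamma_hat
    delta_star <- delta_hat
  }

  dimnames(gamma_star) <- dimnames(delta_star) <- dimnames(gamma_hat) <-
    dimnames(delta_hat) <- list(rownames(X), levels(batch))

  structure(list(
    batches = levels(batch),
    channels = rownames(X),
    grand_mean = grand_mean,
    covariate_coef = drop(B_hat[nb + 1L, ]),
    var_pooled = var_pooled,
    gamma_hat = gamma_hat, delta_hat = delta_hat,
    gamma_star = gamma_star, delta_star = delta_star,
    gamma_bar = gamma_bar, t2 = t2,
    a_prior = a_prior, b_prior = b_prior,
    alpha = sqrt(var_pooled) * gamma_star,   # batch location, original scale
    gamma = sqrt(delta_star),                # batch scale
    eb = eb && G > 1L
  ), class = "combat_model")
}

#' @export
print.combat_model <- function(x, digits = 3, ...) {
  cat(sprintf("<combat_model> %d batches, %d channels, EB shrinkage: %s\n",
              length(x$batches), length(x$channels), x$eb))
  cat("batch location shifts (measurement scale):\n")
  print(round(x$alpha, digits))
  cat("batch scale factors:\n")
  print(round(x$gamma, digits))
  invisible(x)
}

#' Apply a fitted batch-correction model
#'
#' Transforms the colour channels of `ds` by the fitted location/scale
#' adjustment; observer scores are untouched.  The batch labels in `ds`
#' must all have been seen during fitting.
#'
#' @param model a `combat_model` from [fit_combat()].
#' @param ds an `egg_dataset`.
#' @param covariate covariate values for `ds` (defaults to its mean visual
#'   score); must match the covariate used at fit time in meaning.
#' @return The corrected `egg_dataset` (state flag `"corrected"`).
#' @export
apply_combat <- function(model, ds, covariate = aveobs(ds)) {
  X <- t(color_matrix(ds))
  batch <- as.character(ds$batch)
  unseen <- setdiff(unique(batch), model$batches)
  if (length(unseen)) stop("unseen batch label(s): ",
                           paste(unseen, collapse = ", "))
  n <- ncol(X)
  stand_mean <- outer(model$grand_mean, rep(1, n)) +
    outer(model$covariate_coef, rep(1, n)) *
      matrix(covariate, nrow = nrow(X), ncol = n, byrow = TRUE)
  bi <- match(batch, model$batches)
  z <- (X - stand_mean) / sqrt(model$var_pooled)
  z <- (z - model$gamma_star[, bi, drop = FALSE]) /
    sqrt(model$delta_star[, bi, drop = FALSE])
  corrected <- z * sqrt(model$var_pooled) + stand_mean
  out <- as.data.frame(ds)
  out$L <- corrected["L", ]
  out$a <- corrected["a", ]
  out$b <- corrected["b", ]
  egg_dataset(out, state = "corrected")
}

#' Coefficient of variation of batch means
#'
#' For each colour channel, the CV (percent) of the per-batch mean values:
#' `100 * SD(batch means) / |mean(batch means)|` with the sample SD.  The
#' standard diagnostic for residual batch-to-batch variability.
#'
#' @param ds an `egg_dataset` with at least 2 batches.
#' @return Named numeric vector of per-channel CVs (`NA` where the mean of
#'   batch means is zero).
#' @export
batch_cv <- function(ds) {
  X <- color_matrix(ds)
  batch <- factor(ds$batch)
  if (nlevels(batch) < 2L) stop("need at least 2 batches")
  bm <- apply(X, 2L, function(v) tapply(v, batch, mean))
  m <- colMeans(bm)
  s <- apply(bm, 2L, stats::sd)
  ifelse(m == 0, NA_real_, 100 * s / abs(m))
}

#' Relative reduction of a CV after correction
#'
#' @param before,after CV values (percent) before and after correction;
#'   `before` must be positive.
#' @return `100 * (before - after) / before`.
#' @examples
#' reduction_rate(1.55, 0.35) # 77.4
#' @export
reduction_rate <- function(before, after) {
  if (any(before <= 0)) stop("'before' CV must be positive")
  100 * (before - after) / before
}
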