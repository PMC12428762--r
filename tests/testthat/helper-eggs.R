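# Builders for small in-memory fixtures used across the test files.

# Valid random dataset with `nb` batches of `per` eggs each.
make_eggs <- function(n = 30L, nb = 2L, seed = 42L, obs_noise = TRUE) {
  set.seed(seed)
  cls <- sample(1:4, n, replace = TRUE)
  obs <- sapply(1:4, function(o) {
    if (obs_noise) pmin(pmax(cls + sample(c(-1L, 0L, 1L), n, TRUE,
                                          prob = c(0.1, 0.8, 0.1)), 1L), 4L)
    else cls
  })
  egg_dataset(data.frame(
    batch = rep(paste0("B", seq_len(nb)), length.out = n),
    egg_id = sprintf("e%04d", seq_len(n)),
    L = 70 + cls * 3 + rnorm(n, sd = 2),
    a = -6 + rnorm(n, sd = 1.5),
    b = 4 + cls * 2 + rnorm(n, sd = 2),
    obs1 = obs[, 1], obs2 = obs[, 2], obs3 = obs[, 3], obs4 = obs[, 4]))
}

# Dataset in which AveObs is an exact affine function of L - 2 b, so the
# k-scan over the L - k b family has a known perfect optimum at k = 2.
make_linear_scan_eggs <- function() {
  quads <- list(c(1,1,1,1), c(1,1,1,2), c(1,1,2,2), c(2,2,2,2), c(2,2,2,3),
                c(2,2,3,3), c(3,3,3,3), c(3,3,3,4), c(3,3,4,4), c(4,4,4,4))
  quads <- rep(quads, 3)
  ave <- vapply(quads, mean, numeric(1))
  set.seed(7)
  b <- runif(length(quads), 2, 16)
  # L - 2 b = 60 - 10 * AveObs  exactly
  L <- 60 - 10 * ave + 2 * b
  obs <- do.call(rbind, quads)
  egg_dataset(data.frame(
    batch = "B1", egg_id = sprintf("lin%03d", seq_along(quads)),
    L = L, a = rnorm(length(quads), -6, 1), b = b,
    obs1 = obs[, 1], obs2 = obs[, 2], obs3 = obs[, 3], obs4 = obs[, 4]))
}

# Three well-separated Gaussian classes in 3 dimensions.
make_separable_toy <- function(n_per = 25L, seed = 11L) {
  set.seed(seed)
  mu <- list(c(0, 0, 0), c(30, 0, 0), c(0, 30, 30))
  x <- do.call(rbind, lapply(mu, function(m) {
    sweep(matrix(rnorm(n_per * 3), n_per, 3), 2L, m, `+`)
  }))
  colnames(x) <- c("L", "a", "b")
  list(x = x, y = factor(rep(1:3, each = n_per)))
}

# Independent brute-force LDA oracle: explicitly form solve(W) %*% B and
# take its dense (non-symmetric) eigendecomposition.
lda_oracle <- function(x, y) {
  y <- droplevels(factor(y))
  p <- ncol(x); K <- nlevels(y); n <- nrow(x)
  means <- t(sapply(levels(y), function(lv) colMeans(x[y == lv, , drop = FALSE])))
  counts <- as.vector(table(y))
  W <- matrix(0, p, p)
  for (lv in levels(y)) {
    xc <- scale(x[y == lv, , drop = FALSE], center = TRUE, scale = FALSE)
    W <- W + crossprod(xc)
  }
  W <- W / (n - K)
  grand <- colSums(means * counts) / n
  Mc <- sweep(means, 2L, grand)
  B <- t(Mc) %*% (Mc * counts)
  ee <- eigen(solve(W) %*% B)
  ord <- order(-Re(ee$values))
  d <- min(p, K - 1L)
  vec <- Re(ee$vectors)[, ord[seq_len(d)], drop = FALSE]
  val <- pmax(Re(ee$values)[ord[seq_len(d)]], 0)
  for (j in seq_len(d)) {
    vec[, j] <- vec[, j] / sqrt(drop(t(vec[, j]) %*% W %*% vec[, j]))
    i <- which.max(abs(vec[, j]))
    if (vec[i, j] < 0) vec[, j] <- -vec[, j]
  }
  list(scalings = vec, eigenvalues = val, prop = val / sum(val))
}

# Small fast generator configuration (seven batches, ~620 eggs).
small_config <- function(seed = 5L, ...) {
  cfg <- default_config(seed = seed, ...)
  cfg$batch_sizes <- c(132L, 126L, 109L, 88L, 54L, 66L, 48L)
  cfg
}
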