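INDEX_FAMILIES <- c("CHROMA", "SCI", "L_MINUS_KB", "L_MINUS_KC")

#' CIELab chroma
#'
#' Colour saturation, the Euclidean norm of the chromaticity pair:
#' `sqrt(a^2 + b^2)`.
#'
#' @param a,b chromaticity coordinates (vectorised).
#' @return Non-negative chroma values.
#' @examples
#' chroma(3, 4) # 5
#' @export
chroma <- function(a, b) sqrt(a^2 + b^2)

#' Shell colour index (SCI)
#'
#' The industry index `L - a - b`, originally developed for selection on
#' brown eggshells.
#'
#' @param L,a,b CIELab coordinates (vectorised).
#' @export
sci <- function(L, a, b) L - a - b

#' Define a shell-colour index
#'
#' @param family one of `"CHROMA"`, `"SCI"`, `"L_MINUS_KB"` (index
#'   `L - k * b`) or `"L_MINUS_KC"` (index `L - k * C*`).
#' @param k coefficient for the two parametric families; ignored otherwise.
#' @return An `index_def` object.
#' @export
index_def <- function(family, k = NA_real_) {
  family <- match.arg(family, INDEX_FAMILIES)
  if (family %in% c("L_MINUS_KB", "L_MINUS_KC")) {
    if (!is.finite(k)) stop("family ", family, " requires a finite k")
  }
  structure(list(family = family, k = k), class = "index_def")
}

#' Evaluate a shell-colour index
#'
#' @param def an `index_def`, or a family name (with `k` supplied).
#' @param L,a,b CIELab coordinates (vectorised).
#' @param k coefficient, used when `def` is given as a family name.
#' @return Numeric index values.
#' @examples
#' index_value("L_MINUS_KC", 81.82, -6.74, 9.76, k = 4)
#' @export
index_value <- function(def, L, a, b, k = NA_real_) {
  if (is.character(def)) def <- index_def(def, k)
  if (!inherits(def, "index_def")) stop("unknown index definition")
  switch(def$family,
         CHROMA = chroma(a, b),
         SCI = sci(L, a, b),
         L_MINUS_KB = L - def$k * b,
         L_MINUS_KC = L - def$k * chroma(a, b),
         stop("unknown index family: ", def$family))
}

#' Grid scan for the optimal index coefficient
#'
#' Evaluates the Pearson correlation between the index and the mean visual
#' score over a uniform grid of k and returns the k with the strongest
#' (most negative) correlation; ties break toward the smaller k (the
#' simpler formula).  Grid points at which the index is constant across
#' the dataset are recorded with an `NA` correlation and skipped.
#'
#' @param ds an `egg_dataset` (normally batch-corrected).
#' @param family `"L_MINUS_KB"` or `"L_MINUS_KC"`.
#' @param k_min,k_max,step scan grid (defaults 0 to 10 by 0.1).
#' @return A `scan_result` with the `(k, r)` grid, `best_k` and `best_r`.
#' @export
k_scan <- function(ds, family = c("L_MINUS_KB", "L_MINUS_KC"),
                   k_min = 0, k_max = 10, step = 0.1) {
  family <- match.arg(family)
  if (!(k_min < k_max)) stop("k_min must be below k_max")
  if (step <= 0) stop("step must be positive")
  X <- color_matrix(ds)
  ave <- aveobs(ds)
  if (stats::sd(ave) == 0) stop("mean visual score is constant; scan undefined")
  base <- if (family == "L_MINUS_KB") X[, "b"] else chroma(X[, "a"], X[, "b"])
  ks <- seq(k_min, k_max, by = step)
  r <- vapply(ks, function(k) {
    v <- X[, "L"] - k * base
    if (stats::sd(v) == 0) NA_real_ else stats::cor(v, ave)
  }, numeric(1))
  if (all(is.na(r))) stop("index degenerate over the whole grid")
  best <- which(r == min(r, na.rm = TRUE))[1L]   # ties -> smallest k
  structure(list(family = family, k = ks, r = r,
                 best_k = ks[best], best_r = r[best]),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result> %s: best k = %.1f (r = %.3f) over k in [%.1f, %.1f]\n",
              x$family, x$best_k, x$best_r, min(x$k), max(x$k)))
  invisible(x)
}

#' Compare the strength of two correlations (Fisher Z)
#'
#' Tests whether two correlation magnitudes differ, using the Fisher
#' variance-stabilising transform: `z = (atanh(|r2|) - atanh(|r1|)) /
#' sqrt(2 / (n - 3))` with a two-sided normal p-value.  Magnitudes are
#' compared, so the sign of either correlation is irrelevant (an index and
#' its negative rank eggs identically).
#'
#' @param r1,r2 correlation coefficients with `|r| < 1`.
#' @param n number of paired samples behind both correlations (> 3).
#' @return A `correlation_comparison` with `r1`, `r2`, `n`, `z`, `p`.
#' @examples
#' fisher_compare(-0.782, -0.810, 2274)$p # about 0.010
#' @export
fisher_compare <- function(r1, r2, n) {
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be below 1")
  if (n <= 3) stop("n must exceed 3")
  z <- unname((atanh(abs(r2)) - atanh(abs(r1))) / sqrt(2 / (n - 3)))
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(r1 = unname(r1), r2 = unname(r2), n = n, z = z, p = p),
            class = "correlation_comparison")
}

#' @export
print.correlation_comparison <- function(x, ...) {
  cat(sprintf("<correlation_comparison> |r| %.3f vs %.3f (n = %d): z = %.3f, p = %.4g\n",
              abs(x$r1), abs(x$r2), x$n, x$z, x$p))
  invisible(x)
}

#' Dependent-correlation comparison (Steiger variant)
#'
#' Stricter alternative to [fisher_compare()] for two correlations sharing
#' the visual-score variable, accounting for the correlation `r12` between
#' the two indices themselves (Steiger 1980, using Fisher-transformed
#' statistics).  Provided as an optional variant; the independent-samples
#' comparison is the package default.
#'
#' @param r1,r2 correlations of each index with the shared variable.
#' @param r12 correlation between the two indices.
#' @param n sample size (> 3).
#' @return A `correlation_comparison`.
#' @export
fisher_compare_dependent <- function(r1, r2, r12, n) {
  if (abs(r1) >= 1 || abs(r2) >= 1 || abs(r12) >= 1) stop("|r| must be below 1")
  if (n <= 3) stop("n must exceed 3")
  a1 <- abs(r1); a2 <- abs(r2); a12 <- abs(r12)
  rbar2 <- ((a1 + a2) / 2)^2
  # covariance term between the two dependent correlations
  psi <- a12 * (1 - 2 * rbar2) - 0.5 * rbar2 * (1 - 2 * rbar2 - a12^2)
  s <- psi / (1 - rbar2)^2
  z <- (atanh(a2) - atanh(a1)) * sqrt((n - 3) / (2 - 2 * s))
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(r1 = r1, r2 = r2, n = n, z = z, p = p),
            class = "correlation_comparison")
}

#' Correlation matrix of shell-colour indices with the visual score
#'
#' Computes, for a set of indices, the correlation of each with the mean
#' visual score, and the pairwise Fisher comparisons of their magnitudes.
#'
#' @param ds an `egg_dataset` (normally batch-corrected).
#' @param defs named list of `index_def`s; the default covers SCI, chroma
#'   and the two optimised simplified indices `L - 2b` and `L - 4C*`.
#' @return A list with `r` (named correlations), `p` (matrix of pairwise
#'   two-sided p-values, upper triangle) and `n`.
#' @export
index_comparison <- function(ds, defs = list(
                               SCI = index_def("SCI"),
                               `C*` = index_def("CHROMA"),
                               `L-2b` = index_def("L_MINUS_KB", 2),
                               `L-4C` = index_def("L_MINUS_KC", 4))) {
  X <- color_matrix(ds)
  ave <- aveobs(ds)
  vals <- vapply(defs, function(d) index_value(d, X[, "L"], X[, "a"], X[, "b"]),
                 numeric(nrow(X)))
  r <- vapply(seq_along(defs), function(i) pearson_corr(vals[, i], ave),
              numeric(1))
  names(r) <- names(defs)
  m <- length(defs)
  p <- matrix(NA_real_, m, m, dimnames = list(names(defs), names(defs)))
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      p[i, j] <- fisher_compare(r[i], r[j], nrow(X))$p
    }
  }
  list(r = r, p = p, n = nrow(X))
}

#' Grade an egg from its colour reading
#'
#' Threshold grading on the optimised index `v = L - 4 * C*` with `a` as
#' the auxiliary axis: LIGHT when `v > 40` and `a > -5`; BLUE when `v > 40`
#' and `a < -6`; GREEN when `v < 30` and `a < -6`; OLIVE when `v < 30` and
#' `a > -5`; all remaining eggs (the boundary band `30 <= v <= 40` or
#' `-6 <= a <= -5`) are INDETERMINATE.  Total over the (L, a, b) space.
#'
#' @param L,a,b CIELab coordinates (vectorised, recycled to a common
#'   length).
#' @return Factor with levels LIGHT, BLUE, GREEN, OLIVE, INDETERMINATE.
#' @examples
#' grade_egg(85, -3, 6)   # LIGHT
#' grade_egg(78, -8, 14)  # GREEN
#' @export
grade_egg <- function(L, a, b) {
  n <- max(length(L), length(a), length(b))
  L <- rep_len(L, n); a <- rep_len(a, n); b <- rep_len(b, n)
  v <- L - 4 * chroma(a, b)
  g <- rep("INDETERMINATE", n)
  g[v > 40 & a > -5] <- "LIGHT"
  g[v > 40 & a < -6] <- "BLUE"
  g[v < 30 & a < -6] <- "GREEN"
  g[v < 30 & a > -5] <- "OLIVE"
  factor(g, levels = c("LIGHT", "BLUE", "GREEN", "OLIVE", "INDETERMINATE"))
}
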