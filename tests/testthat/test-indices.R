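test_that("chroma and SCI follow their closed forms", {
  expect_equal(chroma(3, 4), 5)
  expect_equal(chroma(0, 0), 0)
  expect_equal(chroma(-6.74, 9.76), sqrt(6.74^2 + 9.76^2))
  expect_equal(round(chroma(-6.74, 9.76), 3), 11.861)
  expect_equal(sci(81.82, -6.74, 9.76), 78.80)
  expect_equal(sci(0, 0, 0), 0)
  expect_equal(sci(50, 10, 10), 30)
})

test_that("index dispatch covers every family", {
  expect_equal(round(index_value("L_MINUS_KC", 81.82, -6.74, 9.76, k = 4), 2),
               round(81.82 - 4 * chroma(-6.74, 9.76), 2))
  expect_lt(abs(index_value("L_MINUS_KC", 81.82, -6.74, 9.76, k = 4) - 34.38),
            0.01)
  expect_equal(index_value("L_MINUS_KB", 77.3, 2, 10, k = 0), 77.3)
  expect_equal(index_value("L_MINUS_KB", 80, 0, 10, k = 2), 60)
  expect_equal(index_value("CHROMA", 1, 3, 4), 5)
  expect_equal(index_value("SCI", 50, 10, 10), 30)
  expect_error(index_value("NOPE", 1, 1, 1), "arg")
  expect_error(index_def("L_MINUS_KB"), "finite k")
})

test_that("the scan finds an exact linear optimum", {
  ds <- make_linear_scan_eggs()
  res <- k_scan(ds, "L_MINUS_KB", 0, 5, 0.1)
  expect_equal(res$best_k, 2.0)
  expect_equal(res$best_r, -1.0, tolerance = 1e-10)
})

test_that("the scan returns the exact grid minimum", {
  ds <- generate_dataset(small_config(seed = 17L))
  for (fam in c("L_MINUS_KB", "L_MINUS_KC")) {
    res <- k_scan(ds, fam, 0, 6, 0.2)
    X <- as.matrix(as.data.frame(ds)[, c("L", "a", "b")])
    ave <- aveobs(ds)
    base <- if (fam == "L_MINUS_KB") X[, "b"] else sqrt(X[, "a"]^2 + X[, "b"]^2)
    oracle <- sapply(seq(0, 6, 0.2), function(k) cor(X[, "L"] - k * base, ave))
    expect_equal(res$r, oracle, tolerance = 1e-12)
    expect_equal(res$best_r, min(oracle))
    expect_equal(res$best_k, seq(0, 6, 0.2)[which.min(oracle)])
  }
})

test_that("Fisher comparison reproduces the printed index contrasts", {
  # pairwise p-values among the four index correlations at n = 2274
  r <- c(-0.782, 0.797, -0.803, -0.810)
  printed <- matrix(NA_real_, 4, 4)
  printed[1, 2] <- 0.179; printed[1, 3] <- 0.057; printed[1, 4] <- 0.010
  printed[2, 3] <- 0.574; printed[2, 4] <- 0.216; printed[3, 4] <- 0.500
  for (i in 1:3) for (j in (i + 1):4) {
    expect_lt(abs(fisher_compare(r[i], r[j], 2274)$p - printed[i, j]), 0.001)
  }
})

test_that("Fisher comparison is symmetric, sign-blind and monotone", {
  cmp <- fisher_compare(0.4, 0.4, 100)
  expect_equal(cmp$z, 0)
  expect_equal(cmp$p, 1)
  expect_equal(fisher_compare(0.3, 0.6, 50)$p, fisher_compare(0.6, 0.3, 50)$p)
  expect_equal(fisher_compare(-0.3, 0.6, 50)$p, fisher_compare(0.3, -0.6, 50)$p)
  ps <- sapply(seq(0.45, 0.85, 0.1), function(r2) fisher_compare(0.4, r2, 80)$p)
  expect_true(all(diff(ps) < 0))
  expect_error(fisher_compare(1, 0.5, 10), "below 1")
  expect_error(fisher_compare(0.2, 0.5, 3), "exceed 3")
})

test_that("the dependent-correlation variant is stricter for correlated indices", {
  ind <- fisher_compare(0.70, 0.78, 300)
  dep <- fisher_compare_dependent(0.70, 0.78, r12 = 0.9, n = 300)
  expect_lt(dep$p, ind$p)   # shared variance makes the contrast sharper
  expect_equal(fisher_compare_dependent(0.5, 0.5, 0.7, 100)$p, 1)
})

test_that("index comparison table carries correlations and p-values", {
  ds <- generate_dataset(small_config(seed = 23L))
  cmp <- index_comparison(ds)
  expect_named(cmp$r, c("SCI", "C*", "L-2b", "L-4C"))
  expect_true(all(abs(cmp$r) <= 1))
  expect_true(all(cmp$p[upper.tri(cmp$p)] >= 0 & cmp$p[upper.tri(cmp$p)] <= 1))
  expect_true(all(is.na(cmp$p[lower.tri(cmp$p, diag = TRUE)])))
})

test_that("grading is total and matches the threshold rules", {
  expect_equal(as.character(grade_egg(85, -3, 6)), "LIGHT")
  expect_equal(as.character(grade_egg(78, -8, 14)), "GREEN")
  expect_equal(as.character(grade_egg(75, -8, 2)), "BLUE")   # v = 42.0, a < -6
  expect_equal(as.character(grade_egg(80, -3, 15)), "OLIVE") # v = 18.8, a > -5
  g <- grade_egg(c(85, 78), c(-3, -8), c(6, 14))
  expect_equal(as.character(g), c("LIGHT", "GREEN"))
  # boundary band: v in [30, 40] or a in [-6, -5]
  expect_equal(as.character(grade_egg(35 + 4 * chroma(-3, 0), -3, 0)),
               "INDETERMINATE")
  set.seed(4)
  L <- runif(500, 40, 100); a <- runif(500, -15, 5); b <- runif(500, -5, 25)
  g <- grade_egg(L, a, b)
  expect_equal(length(g), 500L)
  expect_false(anyNA(g))
  expect_true(all(levels(g) == c("LIGHT", "BLUE", "GREEN", "OLIVE",
                                 "INDETERMINATE")))
})
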