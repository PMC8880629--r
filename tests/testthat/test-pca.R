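test_that("collinear data yields a zero second eigenvalue", {
  x <- seq(0, 1, length.out = 10)
  X <- cbind(x, 2 * x + 3)
  m <- fit_pca(X)
  expect_equal(m$eigenvalues[2], 0, tolerance = 1e-12)
  expect_error(fit_pca(X[1, , drop = FALSE]),
               class = "dissolvenet_error_too_few_rows")
})

test_that("isotropic data has near-unit eigenvalues (Monte Carlo)", {
  X <- withr::with_seed(99, matrix(rnorm(10000 * 4), ncol = 4))
  m <- fit_pca(X)
  expect_true(all(abs(m$eigenvalues - 1) < 0.1))
})

test_that("full-rank transform is a lossless rotation", {
  X <- withr::with_seed(5, matrix(runif(40), 10, 4))
  m <- fit_pca(X)
  scores <- pca_transform(m, X, k = 4)
  back <- scores %*% t(m$components) + rep(m$mean, each = nrow(X))
  expect_lt(max(abs(back - X)), 1e-8)
  # orthonormality
  expect_lt(max(abs(crossprod(m$components) - diag(4))), 1e-8)
  # eigenvalue sum equals total variance of the centered data
  expect_equal(sum(m$eigenvalues), sum(apply(X, 2, var)), tolerance = 1e-8)
})

test_that("eigendecomposition agrees with prcomp", {
  X <- withr::with_seed(6, matrix(rnorm(200), 50, 4))
  m <- fit_pca(X)
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  expect_equal(m$eigenvalues, unname(pr$sdev^2), tolerance = 1e-10)
  # axes agree up to sign
  expect_equal(abs(pca_transform(m, X, 4)), abs(unname(pr$x)),
               tolerance = 1e-8)
})

# Independent brute-force oracle: scan all interior indices for the largest
# discrete second difference.
elbow_oracle <- function(ev) {
  best <- 1L; best_d2 <- 0
  for (i in 2:(length(ev) - 1)) {
    d2 <- ev[i - 1] - 2 * ev[i] + ev[i + 1]
    if (d2 > best_d2 + 1e-15) { best <- i; best_d2 <- d2 }
  }
  best
}

test_that("elbow selection maximizes curvature, deterministically", {
  ev <- c(10, 6, 3, 1, 0.9, 0.85, 0.8)
  expect_identical(select_elbow(ev), elbow_oracle(ev))
  expect_identical(select_elbow(ev), 4L)

  # slow geometric decay joining a flat tail: the joint wins
  ev2 <- c(0.9^(0:3), rep(0.9^3, 3))
  expect_identical(select_elbow(ev2), elbow_oracle(ev2))
  expect_identical(select_elbow(ev2), 4L)

  expect_identical(select_elbow(rep(2, 6)), 1L)   # no structure
  expect_error(select_elbow(c(3, 1)),
               class = "dissolvenet_error_too_few_values")
  # scale equivariance
  for (c_ in c(1e-6, 1, 3e4))
    expect_identical(select_elbow(c_ * ev), 4L)
})

test_that("cumulative variance is a non-decreasing fraction ending at 1", {
  expect_equal(cumulative_variance(c(3, 1)), c(0.75, 1))
  expect_equal(cumulative_variance(rep(1, 4)), c(0.25, 0.5, 0.75, 1))
  withr::with_seed(8, {
    for (i in 1:20) {
      ev <- sort(rexp(sample(3:12, 1)), decreasing = TRUE)
      cv <- cumulative_variance(ev)
      expect_true(all(diff(cv) >= -1e-15))
      expect_equal(cv[length(cv)], 1, tolerance = 1e-12)
    }
  })
  expect_error(cumulative_variance(c(0, 0)),
               class = "dissolvenet_error_zero_variance")
})

test_that("PCA scores are pairwise decorrelated", {
  X <- withr::with_seed(10, matrix(runif(600), 100, 6) %*%
                          matrix(runif(36, -1, 1), 6, 6))
  m <- fit_pca(X)
  S <- pca_transform(m, X, 6)
  C <- correlation_matrix(S)
  expect_lt(max(abs(C[upper.tri(C)])), 1e-8)
})

test_that("correlation matrix conventions: unit diagonal, +-1, constants", {
  x <- rnorm(20)
  C <- correlation_matrix(cbind(x, x, -x))
  expect_equal(diag(C), rep(1, 3), ignore_attr = TRUE)
  expect_equal(C[1, 2], 1)
  expect_equal(C[1, 3], -1)
  expect_warning(C2 <- correlation_matrix(cbind(x, rep(2, 20))),
                 class = "dissolvenet_warning_constant_column")
  expect_equal(C2[1, 2], 0)
  expect_equal(diag(C2), rep(1, 2), ignore_attr = TRUE)
})

test_that("projection is leakage-free and validates widths", {
  Xtr <- withr::with_seed(2, matrix(rnorm(60), 15, 4))
  m <- fit_pca(Xtr)
  Xte <- matrix(rnorm(8), 2, 4)
  sc <- pca_transform(m, Xte, 2)
  manual <- (Xte - rep(m$mean, each = 2)) %*% m$components[, 1:2]
  expect_equal(sc, manual)
  expect_error(pca_transform(m, Xte[, 1:3], 2),
               class = "dissolvenet_error_width_mismatch")
  expect_error(pca_transform(m, Xte, 9), class = "dissolvenet_error_bad_k")
})
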