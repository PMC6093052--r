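test_that("PCA explains variance correctly and fixes signs", {
  # rank-1 data: one direction carries all variance
  set.seed(1)
  t1 <- rnorm(12)
  x <- outer(t1, c(1, 2, -1)) + 5
  p1 <- pca(x, 1)
  expect_equal(p1$explained_fraction, 1)
  expect_lt(max(abs(colMeans(p1$scores))), 1e-10)
  # sign convention: dominant loading positive
  expect_gt(p1$loadings[which.max(abs(p1$loadings[, 1])), 1], 0)
  expect_error(pca(x, 5), "k must be")
})

test_that("PCA explained fractions match the covariance eigenvalues", {
  set.seed(2)
  x <- cbind(rnorm(50, sd = 3), rnorm(50, sd = 1))
  x[, 2] <- x[, 2] + 0.5 * x[, 1]
  ev <- eigen(stats::cov(x), symmetric = TRUE)$values
  p <- pca(x, 2)
  expect_equal(p$explained_fraction, ev / sum(ev), tolerance = 1e-10)
  # full-rank reconstruction reproduces the centered data
  rec <- p$scores %*% t(p$loadings)
  expect_equal(rec, sweep(x, 2, colMeans(x)), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("Mahalanobis distances match closed forms", {
  # pre-whitened scores: MD equals Euclidean distance from the mean
  set.seed(3)
  z <- matrix(rnorm(200), 50)
  zw <- scale(z %*% solve(chol(stats::cov(z))), scale = FALSE)
  d <- mahalanobis_distances(zw)
  expect_equal(d, sqrt(rowSums(zw^2)), tolerance = 1e-8,
               ignore_attr = TRUE)
  # a sample at the mean has distance ~0 (include the mean point itself)
  x <- rbind(zw, 0)
  expect_lt(mahalanobis_distances(x)[51], 0.05)
})

test_that("2-D Mahalanobis matches a hand-inverted covariance", {
  x <- cbind(c(1, 2, 3, 4, 6), c(1.2, 1.9, 3.4, 3.9, 6.1))
  S <- stats::cov(x)
  det_ <- S[1, 1] * S[2, 2] - S[1, 2]^2
  Sinv <- matrix(c(S[2, 2], -S[1, 2], -S[2, 1], S[1, 1]), 2) / det_
  mu <- colMeans(x)
  d_oracle <- apply(x, 1, function(r) {
    v <- r - mu
    sqrt(drop(t(v) %*% Sinv %*% v))
  })
  expect_equal(mahalanobis_distances(x), d_oracle, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("Mahalanobis distance is affine invariant", {
  set.seed(4)
  z <- matrix(rnorm(40 * 3), 40)
  d0 <- mahalanobis_distances(z)
  for (i in 1:5) {
    A <- matrix(rnorm(9), 3)
    while (abs(det(A)) < 0.1) A <- matrix(rnorm(9), 3)
    b <- rnorm(3)
    zt <- sweep(z %*% A, 2, b, `+`)
    expect_equal(mahalanobis_distances(zt), d0, tolerance = 1e-8)
  }
})

test_that("leverage matches the explicit hat matrix", {
  # intercept-only design: every leverage is 1/n
  expect_equal(hat_leverage(matrix(1, 8, 1)), rep(1 / 8, 8))
  set.seed(5)
  X <- matrix(rnorm(30), 10, 3)
  h <- hat_leverage(X)
  H <- X %*% solve(crossprod(X)) %*% t(X)
  expect_equal(h, diag(H), tolerance = 1e-10)
  expect_equal(sum(h), 3, tolerance = 1e-10)
  expect_true(all(h >= 0 & h <= 1))
  # idempotence and symmetry of the projector
  expect_lt(max(abs(H %*% H - H)), 1e-8)
  expect_lt(max(abs(H - t(H))), 1e-12)
  expect_error(hat_leverage(cbind(X, X[, 1])), "rank")
})

test_that("a grossly displaced sample is the one flagged", {
  set.seed(6)
  x <- matrix(rnorm(30 * 12), 30)
  p <- pca(x, 2)
  dir <- p$loadings[, 1]
  x[7, ] <- x[7, ] + 10 * stats::sd(p$scores[, 1]) * dir
  rep <- flag_outliers(x, k = 2)
  expect_true(rep$flag[7])
  expect_equal(which.max(rep$md), 7)
  expect_lte(sum(rep$flag), 2)
})

test_that("outlier screening on identical spectra fails loudly", {
  x <- matrix(1, 10, 6)
  expect_error(flag_outliers(x, k = 2))
})

test_that("removing a flagged gross outlier lowers the maximum distance", {
  ds <- generate_dataset(small_config(seed = 8, n = 35, p = 100))
  sp <- inject_outliers(ds$spectra, 5, severity = 4, shift = 0.2)
  rep <- flag_outliers(sp)
  expect_true(rep$flag[5])
  max_before <- max(rep$md)
  keep <- sp$absorbance[-5, ]
  rep2 <- flag_outliers(keep)
  expect_lt(max(rep2$md), max_before)
})
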