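test_that("rmse matches hand arithmetic", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 4)), sqrt(1 / 3))
  expect_equal(rmse(2, 5), 3)
  expect_error(rmse(numeric(0), numeric(0)), "non-empty")
  expect_error(rmse(1:3, 1:4), "equal length")
})

test_that("correlation follows 1 - SSE/SST with its square root", {
  expect_equal(correlation_r(1:4, 1:4), list(r = 1, r2 = 1))
  expect_equal(correlation_r(c(1, 2, 3), rep(2, 3))$r2, 0)
  y <- c(1, 2, 3, 4)
  yh <- c(1.1, 1.9, 3.2, 3.8)
  sse <- sum((yh - y)^2)
  sst <- sum((y - mean(y))^2)
  got <- correlation_r(y, yh)
  expect_equal(got$r2, 1 - sse / sst)
  expect_equal(got$r, sqrt(1 - sse / sst))
  # worse-than-null predictions: r2 < 0, r floored at 0
  bad <- correlation_r(c(1, 2, 3), c(9, -4, 12))
  expect_lt(bad$r2, 0)
  expect_equal(bad$r, 0)
  expect_error(correlation_r(c(2, 2, 2), 1:3), "constant")
})

test_that("Kennard-Stone selects extremes first and honors the ratio", {
  x <- matrix(0:4, ncol = 1)
  sp <- kennard_stone_split(x, 0.4)
  expect_equal(sp$calibration, c(1, 5))
  expect_equal(sp$prediction, c(2, 3, 4))
  set.seed(1)
  sp10 <- kennard_stone_split(matrix(rnorm(20), 10), 0.8)
  expect_equal(length(sp10$calibration), 8)
  expect_equal(length(sp10$prediction), 2)
  expect_equal(sort(c(sp10$calibration, sp10$prediction)), 1:10)
  expect_error(kennard_stone_split(x, 1.2), "between 0 and 1")
  expect_error(kennard_stone_split(x, 0.1), "empty")
})

test_that("Kennard-Stone equals the naive max-min oracle up to n = 12", {
  set.seed(2)
  for (trial in 1:6) {
    n <- sample(6:12, 1)
    x <- matrix(rnorm(n * 2), n)
    n_cal <- max(2, round(0.5 * n))
    sp <- kennard_stone_split(x, 0.5)
    expect_equal(sp$calibration, ks_naive(x, n_cal))
  }
})

test_that("PLS reaches the exact-fit and least-squares limits", {
  set.seed(3)
  X <- matrix(rnorm(12 * 4), 12)
  beta <- c(2, -1, 0.5, 1.5)
  y_exact <- drop(X %*% beta)
  m <- fit_pls(X, y_exact, 4)
  expect_lt(max(abs(predict_pls(m, X) - y_exact)), 1e-8)
  # with noise, full-rank PLS equals ordinary least squares
  y <- y_exact + rnorm(12)
  m2 <- fit_pls(X, y, 4)
  ols <- stats::lm(y ~ X)
  expect_equal(predict_pls(m2, X), unname(stats::fitted(ols)),
               tolerance = 1e-8)
  expect_error(fit_pls(X, y, 12), "n_factors")
  expect_error(fit_pls(X, rep(1, 12), 2), "zero variance")
})

test_that("the first factor matches a hand-run NIPALS step", {
  X <- matrix(c(1, 2, 3, 4,
                2, 1, 0.5, 3,
                0, 1, 2, 1), 4)
  y <- c(1, 3, 2, 5)
  Ec <- scale(X, scale = FALSE)
  fc <- y - mean(y)
  w1 <- drop(crossprod(Ec, fc))
  w1 <- w1 / sqrt(sum(w1^2))
  t1 <- drop(Ec %*% w1)
  p1 <- drop(crossprod(Ec, t1)) / sum(t1^2)
  q1 <- sum(fc * t1) / sum(t1^2)
  m <- fit_pls(X, y, 1)
  expect_equal(drop(m$x_weights), w1, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(drop(m$scores), t1, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(drop(m$x_loadings), p1, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(m$y_loadings, q1, tolerance = 1e-10)
  # successive scores are orthogonal
  m3 <- fit_pls(matrix(rnorm(40), 10), rnorm(10), 3)
  G <- crossprod(m3$scores)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
})

test_that("prediction is the collapsed centered linear form", {
  set.seed(4)
  X <- matrix(rnorm(30), 10, 3)
  y <- rnorm(10)
  m <- fit_pls(X, y, 2)
  expect_equal(predict_pls(m, matrix(m$x_center, 1)), m$y_center)
  Xn <- matrix(rnorm(9), 3)
  expect_equal(predict_pls(m, Xn),
               drop(sweep(Xn, 2, m$x_center) %*% m$coefficients) +
                 m$y_center,
               tolerance = 1e-12)
  expect_error(predict_pls(m, matrix(1, 2, 5)), "columns")
})

test_that("fold assignment is balanced and seeded", {
  a <- nirflav:::cv_folds(20, 10, seed = 5)
  expect_equal(unname(tabulate(a, 10)), rep(2, 10))
  expect_identical(a, nirflav:::cv_folds(20, 10, seed = 5))
  a2 <- nirflav:::cv_folds(23, 10, seed = 5)
  expect_equal(sort(unname(tabulate(a2, 10))), c(rep(2, 7), rep(3, 3)))
})

test_that("the RMSECV curve equals an independent fold-by-fold loop", {
  set.seed(6)
  X <- matrix(rnorm(30 * 8), 30)
  y <- drop(X[, 1:3] %*% c(1, 2, -1)) + rnorm(30, sd = 0.3)
  cv <- cross_validate(X, y, max_factors = 5, folds = 10, seed = 77)
  # oracle: refit from scratch per fold and factor count
  press <- numeric(5)
  for (a in 1:5) {
    for (fold in 1:10) {
      te <- which(cv$fold_assignment == fold)
      tr <- which(cv$fold_assignment != fold)
      fit <- fit_pls(X[tr, ], y[tr], a)
      press[a] <- press[a] + sum((predict_pls(fit, X[te, , drop = FALSE]) -
                                    y[te])^2)
    }
  }
  expect_equal(unname(cv$rmsecv), sqrt(press / 30), tolerance = 1e-10)
  expect_equal(cv$optimal_factors, unname(which.min(cv$rmsecv)))
  expect_warning(cross_validate(X, y, max_factors = 50, folds = 10,
                                seed = 1),
                 "reduced")
})

test_that("training error never increases with more factors", {
  for (seed in 1:3) {
    set.seed(seed)
    X <- matrix(rnorm(25 * 10), 25)
    y <- rnorm(25)
    errs <- sapply(1:6, function(a) {
      rmse(y, predict_pls(fit_pls(X, y, a), X), "calibration")
    })
    expect_true(all(diff(errs) <= 1e-12))
  }
})
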