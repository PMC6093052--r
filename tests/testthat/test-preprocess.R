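test_that("reflectance conversion is log10(1/R) with domain checks", {
  expect_equal(absorbance_from_reflectance(matrix(1)), matrix(0))
  expect_equal(absorbance_from_reflectance(matrix(0.1)), matrix(1))
  expect_error(absorbance_from_reflectance(matrix(0)), "> 0")
  expect_error(absorbance_from_reflectance(matrix(c(0.5, -0.1), 1)), "> 0")
  expect_error(absorbance_from_reflectance(matrix(1.5)), "<= 1")
})

test_that("SNV standardizes rows and rejects constant spectra", {
  expect_equal(snv(matrix(c(2, 4, 6), 1)), matrix(c(-1, 0, 1), 1))
  expect_error(snv(matrix(5, 1, 3)), "constant")
  m <- matrix(rnorm(10 * 50), 10)
  s <- snv(m)
  expect_lt(max(abs(rowMeans(s))), 1e-12)
  expect_lt(max(abs(apply(s, 1, stats::sd) - 1)), 1e-12)
})

test_that("MSC removes exact affine scatter and reports coefficients", {
  ref <- c(1, 2, 3)
  out <- msc(rbind(2 + 3 * ref, ref), reference = ref)
  expect_equal(out$spectra[1, ], ref, ignore_attr = TRUE)
  expect_equal(out$offset[1], 2)
  expect_equal(out$slope[1], 3)
  # a row equal to the reference is untouched
  expect_equal(out$spectra[2, ], ref, ignore_attr = TRUE)
  expect_equal(out$offset[2], 0)
  expect_equal(out$slope[2], 1)
})

test_that("MSC-corrected rows regress onto the reference as identity", {
  set.seed(7)
  x <- matrix(rnorm(8 * 30), 8)
  out <- msc(x)
  ref <- out$reference
  # oracle: normal-equations least squares of each corrected row on ref
  X <- cbind(1, ref)
  for (i in 1:8) {
    ab <- solve(crossprod(X), crossprod(X, out$spectra[i, ]))
    expect_equal(ab[1], 0, tolerance = 1e-10, ignore_attr = TRUE)
    expect_equal(ab[2], 1, tolerance = 1e-10, ignore_attr = TRUE)
  }
  # idempotence with the reference held fixed
  again <- msc(out$spectra, reference = ref)
  expect_equal(again$spectra, out$spectra, tolerance = 1e-10)
})

test_that("moving-window smoothing averages with truncated edges", {
  expect_equal(moving_window_smooth(matrix(7, 1, 9), 3), matrix(7, 1, 9))
  expect_equal(moving_window_smooth(matrix(1:5, 1), 3),
               matrix(c(1.5, 2, 3, 4, 4.5), 1))
  expect_error(moving_window_smooth(matrix(1:5, 1), 1), "odd")
  expect_error(moving_window_smooth(matrix(1:5, 1), 4), "odd")
  expect_error(moving_window_smooth(matrix(1:5, 1), 7), "odd")
})

test_that("Savitzky-Golay filters are exact on polynomials", {
  # derivative of a line, with physical spacing
  x <- matrix(2 + 3 * (0:20), 1)
  expect_equal(savgol(x, 5, 2, deriv = 1, spacing = 2),
               matrix(1.5, 1, 21), tolerance = 1e-10)
  # exact second derivative of a quadratic
  q <- matrix((0:20)^2, 1)
  expect_equal(savgol(q, 7, 2, deriv = 2), matrix(2, 1, 21),
               tolerance = 1e-9)
  # deriv 0 with interpolating order reproduces the input
  set.seed(1)
  r <- matrix(rnorm(40), 2)
  expect_equal(savgol(r, 5, 4, deriv = 0), r, tolerance = 1e-8)
  expect_error(savgol(r, 5, 5, 0), "polyorder")
  expect_error(savgol(r, 4, 2, 0), "odd")
  expect_error(savgol(r, 5, 2, 3), "deriv")
})

test_that("interior SG weights solve the local least-squares system", {
  # oracle: fit a quadratic over offsets -2..2 and differentiate at 0
  V <- outer(-2:2, 0:2, `^`)
  proj <- solve(crossprod(V), t(V))
  w_oracle <- proj[2, ]  # first-derivative row (coefficient of offset^1)
  expect_equal(w_oracle, c(-2, -1, 0, 1, 2) / 10)
  # the filter must apply those weights in its interior
  set.seed(2)
  r <- matrix(rnorm(30), 1)
  out <- savgol(r, 5, 2, deriv = 1)
  manual <- sapply(3:28, function(j) sum(w_oracle * r[1, (j - 2):(j + 2)]))
  expect_equal(out[1, 3:28], manual, tolerance = 1e-10)
})

test_that("chains compose in order, preserve metadata, and validate", {
  ds <- generate_dataset(small_config(seed = 4, n = 8, p = 60))
  s <- ds$spectra
  expect_identical(apply_chain(s, preprocess_chain()), s)
  ch1 <- preprocess_chain(list(method = "snv"))
  expect_equal(apply_chain(s, ch1)$absorbance, snv(s$absorbance))
  ch <- preprocess_chain(list(method = "savgol", window = 11,
                              polyorder = 2, deriv = 1),
                         list(method = "snv"))
  manual <- snv(savgol(s$absorbance, 11, 2, 1,
                       spacing = diff(s$wavenumbers)[1]))
  out <- apply_chain(s, ch)
  expect_equal(out$absorbance, manual)
  expect_identical(out$sample_ids, s$sample_ids)
  expect_identical(out$wavenumbers, s$wavenumbers)
  expect_error(preprocess_chain(list(method = "nope")), "method")
  expect_error(preprocess_chain(list(method = "savgol", window = 4)), "odd")
  # non-uniform grids are rejected for savgol steps
  bad <- spectra_set(matrix(rnorm(20), 2), c(4000, 4100, 4150, 4500,
                                             5000, 6000, 6100, 7000,
                                             7500, 8000))
  expect_error(apply_chain(bad, preprocess_chain(
    list(method = "savgol", window = 3, polyorder = 1, deriv = 1))),
    "uniform")
})

test_that("fitted chains freeze the MSC reference from the training set", {
  set.seed(11)
  train <- matrix(rnorm(6 * 25, mean = 1), 6)
  test <- matrix(rnorm(4 * 25, mean = 5), 4)
  ch <- preprocess_chain(list(method = "msc"))
  fc <- fit_chain(ch, train)
  expect_equal(fc[[1]]$reference, colMeans(train))
  # applying the fitted chain to new data must use the frozen reference
  got <- apply_chain(test, fc)
  expect_equal(got, msc(test, reference = colMeans(train))$spectra)
  # whereas the unfitted chain self-references
  self <- apply_chain(test, ch)
  expect_equal(self, msc(test)$spectra)
})

test_that("preprocessing operations are permutation-equivariant", {
  set.seed(5)
  x <- matrix(rnorm(9 * 40), 9)
  perm <- sample(9)
  ops <- list(snv = function(m) snv(m),
              msc = function(m) msc(m, reference = colMeans(x))$spectra,
              mw = function(m) moving_window_smooth(m, 5),
              sg = function(m) savgol(m, 7, 2, 1))
  for (op in ops) {
    expect_equal(op(x[perm, ]), op(x)[perm, ], ignore_attr = TRUE)
  }
})
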