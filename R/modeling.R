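# Calibration modelling: Kennard-Stone sample partitioning, NIPALS partial
# least squares regression (single response, mean-centering only), k-fold
# cross-validated factor selection, and the standard error/correlation
# metrics (RMSECV / RMSEC / RMSEP, r and r^2).

#' Root mean square error
#'
#' `sqrt(mean((predicted - measured)^2))`. The same form serves for
#' cross-validation (RMSECV), calibration (RMSEC) and prediction (RMSEP)
#' errors; `flavor` is recorded only for labelling.
#'
#' @param measured,predicted equal-length numeric vectors
#' @param flavor one of `"cv"`, `"calibration"`, `"prediction"`
#' @return non-negative scalar in the units of `measured`
#' @export
rmse <- function(measured, predicted,
                 flavor = c("cv", "calibration", "prediction")) {
  flavor <- match.arg(flavor)
  if (length(measured) == 0 || length(measured) != length(predicted)) {
    stop("measured and predicted must be non-empty and of equal length",
         call. = FALSE)
  }
  sqrt(mean((predicted - measured)^2))
}

#' Correlation between measurement and prediction
#'
#' Computes `r2 = 1 - SSE/SST` (SSE about the predictions, SST about the
#' mean of the measured values) and `r = sqrt(max(r2, 0))`. Both are
#' returned: some reporting conventions quote 1 - SSE/SST itself as "R",
#' others its square root.
#'
#' @param measured,predicted equal-length numeric vectors, `length >= 2`;
#'   `measured` must not be constant
#' @return list with elements `r` and `r2`
#' @export
correlation_r <- function(measured, predicted) {
  if (length(measured) < 2 || length(measured) != length(predicted)) {
    stop("need equal-length vectors with >= 2 values", call. = FALSE)
  }
  sst <- sum((measured - mean(measured))^2)
  if (sst < .Machine$double.eps * 100) {
    stop("measured values are constant; correlation undefined", call. = FALSE)
  }
  r2 <- 1 - sum((predicted - measured)^2) / sst
  list(r = sqrt(max(r2, 0)), r2 = r2)
}

#' Kennard-Stone calibration/prediction split
#'
#' Greedy max-min Euclidean selection: start from the two most mutually
#' distant samples, then repeatedly add the sample whose minimum distance to
#' the already-selected set is largest, until `round(ratio * n)` samples are
#' chosen. The selected samples form the calibration set; ties are broken by
#' lowest index, so the split is deterministic.
#'
#' @param spectra `n x p` matrix or [spectra_set()], `n >= 3`
#' @param ratio fraction of samples assigned to calibration, in `(0, 1)`
#' @return list of class `split_result` with sorted `calibration` and
#'   `prediction` index vectors, the selection `order`, and `ratio`
#' @export
kennard_stone_split <- function(spectra, ratio = 0.8) {
  x <- .as_matrix(spectra)
  n <- nrow(x)
  if (n < 3) stop("Kennard-Stone needs at least 3 samples", call. = FALSE)
  if (!is.finite(ratio) || ratio <= 0 || ratio >= 1) {
    stop("ratio must be strictly between 0 and 1", call. = FALSE)
  }
  n_cal <- round(ratio * n)
  if (n_cal < 2 || n_cal >= n) {
    stop("ratio ", ratio, " leaves an empty calibration or prediction set",
         call. = FALSE)
  }
  dm <- as.matrix(stats::dist(x))
  # seed pair: maximum pairwise distance, ties -> lowest (i, j)
  up <- which(upper.tri(dm), arr.ind = TRUE)
  up <- up[order(up[, 1], up[, 2]), , drop = FALSE]
  best <- unname(up[which.max(dm[up]), ])
  sel <- c(best[1], best[2])
  mind <- pmin(dm[, sel[1]], dm[, sel[2]])
  while (length(sel) < n_cal) {
    mind[sel] <- -Inf
    nxt <- unname(which.max(mind))
    sel <- c(sel, nxt)
    mind <- pmin(mind, dm[, nxt])
  }
  sel <- as.integer(sel)
  structure(list(calibration = sort(sel),
                 prediction = setdiff(seq_len(n), sel),
                 order = unname(sel),
                 ratio = ratio),
            class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat(sprintf("<split_result> %d calibration / %d prediction (ratio %.2f)\n",
              length(x$calibration), length(x$prediction), x$ratio))
  invisible(x)
}

#' Fit a PLS1 regression by NIPALS
#'
#' Mean-centers `X` and `y` (no variance scaling) and extracts `n_factors`
#' latent factors by the NIPALS algorithm with deflation of `X` after each
#' factor. For a single response the inner loop converges in one pass; the
#' iteration is retained for robustness (score change < 1e-12 or 500
#' iterations). The factorization is collapsed into a single regression
#' vector so that prediction is
#' `yhat = (X - x_center) %*% coefficients + y_center`.
#'
#' @param X `n x p` predictor matrix
#' @param y length-n response
#' @param n_factors number of latent factors `A <= min(n - 1, p)`
#' @return object of class `pls_model` with `x_weights`, `x_loadings`,
#'   `y_loadings`, `scores`, `coefficients`, `x_center`, `y_center`,
#'   `n_factors`
#' @export
fit_pls <- function(X, y, n_factors) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("X and y must be finite", call. = FALSE)
  }
  A <- n_factors
  if (A < 1 || A != round(A) || A > min(n - 1, p)) {
    stop("n_factors must be an integer in 1..", min(n - 1, p), call. = FALSE)
  }
  y_center <- mean(y)
  if (stats::sd(y) < .Machine$double.eps * 100) {
    stop("response has zero variance", call. = FALSE)
  }
  core <- nipals_pls1(X, y, A)
  if (core$achieved < A) {
    stop("factor ", core$achieved + 1,
         " exceeds the effective rank of X (or the response is already ",
         "fitted exactly)", call. = FALSE)
  }
  coef <- pls_coefficients(core$W, core$P, core$q, A)
  structure(list(n_factors = A, x_weights = core$W, x_loadings = core$P,
                 y_loadings = core$q, scores = core$Tm, coefficients = coef,
                 x_center = core$x_center, y_center = y_center,
                 chain = NULL),
            class = "pls_model")
}

# NIPALS PLS1 core: extracts up to A factors with deflation, stopping early
# (achieved < A) when the residual response or the weight vector collapses
# numerically.
nipals_pls1 <- function(X, y, A) {
  n <- nrow(X)
  p <- ncol(X)
  x_center <- colMeans(X)
  E <- sweep(X, 2, x_center)
  f <- y - mean(y)
  f0 <- sqrt(sum(f^2))
  W <- matrix(0, p, A)
  P <- matrix(0, p, A)
  Tm <- matrix(0, n, A)
  q <- numeric(A)
  achieved <- 0L
  for (a in seq_len(A)) {
    if (sqrt(sum(f^2)) < 1e-10 * max(f0, 1e-300)) break
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * max(1, sqrt(sum(f^2)))) break
    w <- w / nw
    tt <- as.numeric(E %*% w)
    for (it in seq_len(500L)) {
      # PLS1 inner iteration; with a single response the weight vector is
      # stationary after the first pass, so this exits immediately
      w_new <- crossprod(E, f)
      w_new <- w_new / sqrt(sum(w_new^2))
      t_new <- as.numeric(E %*% w_new)
      if (sqrt(sum((t_new - tt)^2)) < 1e-12 * max(1, sqrt(sum(t_new^2)))) {
        w <- w_new
        tt <- t_new
        break
      }
      w <- w_new
      tt <- t_new
    }
    tt2 <- sum(tt^2)
    if (tt2 < 1e-24) break
    pvec <- crossprod(E, tt) / tt2
    qa <- sum(f * tt) / tt2
    E <- E - tcrossprod(tt, pvec)
    f <- f - qa * tt
    W[, a] <- w
    P[, a] <- pvec
    Tm[, a] <- tt
    q[a] <- qa
    achieved <- a
  }
  list(W = W, P = P, Tm = Tm, q = q, x_center = x_center,
       achieved = achieved)
}

# Collapse a NIPALS factorization into a regression vector:
# B = W (P'W)^-1 q, using the first `a` factors.
pls_coefficients <- function(W, P, q, a) {
  Wa <- W[, seq_len(a), drop = FALSE]
  Pa <- P[, seq_len(a), drop = FALSE]
  as.numeric(Wa %*% solve(crossprod(Pa, Wa), q[seq_len(a)]))
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d latent factors, %d wavelengths%s\n",
              x$n_factors, length(x$coefficients),
              if (is.null(x$chain)) "" else
                paste0(", chain: ", chain_label(x$chain))))
  invisible(x)
}

#' Predict from a fitted PLS model
#'
#' @param model a [fit_pls()] model
#' @param X_new `m x p` matrix on the same (already preprocessed) variable
#'   space as the training data
#' @return length-m numeric vector of predictions
#' @export
predict_pls <- function(model, X_new) {
  stopifnot(inherits(model, "pls_model"))
  X_new <- as.matrix(X_new)
  if (ncol(X_new) != length(model$x_center)) {
    stop("X_new has ", ncol(X_new), " columns; model expects ",
         length(model$x_center), call. = FALSE)
  }
  as.numeric(sweep(X_new, 2, model$x_center) %*% model$coefficients +
               model$y_center)
}

# Seeded fold assignment: random permutation then contiguous blocks whose
# sizes differ by at most one.
cv_folds <- function(n, folds, seed) {
  if (folds < 2 || folds > n) {
    stop("folds must satisfy 2 <= folds <= n", call. = FALSE)
  }
  perm <- with_local_seed(seed, sample.int(n))
  sizes <- rep(n %/% folds, folds)
  extra <- n %% folds
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  assignment <- integer(n)
  assignment[perm] <- rep(seq_len(folds), times = sizes)
  assignment
}

#' Cross-validated RMSECV curve and factor selection
#'
#' Assigns samples to `folds` folds by a seeded random permutation (fold
#' sizes differ by at most one). For each candidate factor count
#' `A in 1..max_factors`, every sample is predicted by the model fitted
#' without its fold, and `RMSECV(A) = sqrt(mean((yhat - y)^2))` over all n
#' samples. The optimal factor count is the argmin; ties go to the smallest
#' A. If `max_factors` is infeasible for the smallest training fold it is
#' reduced with a warning.
#'
#' @param X `n x p` predictor matrix (already preprocessed)
#' @param y length-n response
#' @param max_factors largest factor count to score
#' @param folds number of folds (default 10)
#' @param seed integer seed for the fold permutation
#' @return object of class `cv_curve` with `rmsecv` (named by factor
#'   count), `optimal_factors`, `fold_assignment`, `seed`
#' @export
cross_validate <- function(X, y, max_factors, folds = 10, seed = 1L) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  assignment <- cv_folds(n, folds, seed)
  min_train <- n - max(tabulate(assignment, folds))
  a_cap <- min(min_train - 1, ncol(X))
  if (max_factors > a_cap) {
    warning("max_factors reduced from ", max_factors, " to ", a_cap,
            " (limited by fold size / predictors)", call. = FALSE)
    max_factors <- a_cap
  }
  if (max_factors < 1) stop("no feasible factor count", call. = FALSE)
  press <- numeric(max_factors)
  for (fold in seq_len(folds)) {
    test <- which(assignment == fold)
    train <- which(assignment != fold)
    ytr <- y[train]
    core <- nipals_pls1(X[train, , drop = FALSE], ytr, max_factors)
    Xc <- sweep(X[test, , drop = FALSE], 2, core$x_center)
    for (a in seq_len(max_factors)) {
      # an exact fit before max_factors keeps the curve flat beyond it
      a_eff <- min(a, max(core$achieved, 1L))
      b <- pls_coefficients(core$W, core$P, core$q, a_eff)
      pred <- as.numeric(Xc %*% b) + mean(ytr)
      press[a] <- press[a] + sum((pred - y[test])^2)
    }
  }
  rmsecv <- sqrt(press / n)
  names(rmsecv) <- seq_len(max_factors)
  structure(list(rmsecv = rmsecv,
                 optimal_factors = unname(which.min(rmsecv)),
                 fold_assignment = assignment,
                 seed = seed),
            class = "cv_curve")
}

#' @export
print.cv_curve <- function(x, ...) {
  cat(sprintf("<cv_curve> %d candidate factor counts; optimum A = %d (RMSECV %.4g)\n",
              length(x$rmsecv), x$optimal_factors,
              x$rmsecv[x$optimal_factors]))
  invisible(x)
}
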