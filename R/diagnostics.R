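# Outlier diagnostics: PCA score exploration, Mahalanobis distance on the
# score subspace, hat-matrix leverage, and combined flagging.

#' Principal component analysis of spectra
#'
#' Column-mean-centered PCA (no variance scaling). Component signs are fixed
#' so the largest-magnitude loading of each component is positive, making
#' results reproducible across BLAS/LAPACK builds.
#'
#' @param spectra `n x p` matrix or [spectra_set()]
#' @param k number of components, `k <= min(n - 1, p)`
#' @return list of class `pca_result` with `scores` (`n x k`), `loadings`
#'   (`p x k`), `explained_fraction` (per component, relative to the total
#'   variance) and `center`
#' @export
pca <- function(spectra, k) {
  x <- .as_matrix(spectra)
  n <- nrow(x)
  if (n < 2) stop("PCA needs at least 2 samples", call. = FALSE)
  kmax <- min(n - 1, ncol(x))
  if (k < 1 || k != round(k) || k > kmax) {
    stop("k must be an integer in 1..", kmax, call. = FALSE)
  }
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  total_var <- sum(pr$sdev^2)
  scores <- pr$x[, seq_len(k), drop = FALSE]
  loadings <- pr$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    if (loadings[which.max(abs(loadings[, j])), j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(list(scores = scores, loadings = loadings,
                 explained_fraction = pr$sdev[seq_len(k)]^2 / total_var,
                 center = pr$center),
            class = "pca_result")
}

#' Mahalanobis distances of score rows
#'
#' `d_i = sqrt((x_i - xbar)' S^-1 (x_i - xbar))` with `S` the sample
#' covariance (n-1 denominator) of the rows.
#'
#' @param scores `n x k` numeric matrix, `n > k`
#' @return numeric vector of n distances
#' @export
mahalanobis_distances <- function(scores) {
  x <- as.matrix(scores)
  n <- nrow(x)
  k <- ncol(x)
  if (n <= k) stop("need more samples than score dimensions", call. = FALSE)
  S <- stats::cov(x)
  d2 <- tryCatch(stats::mahalanobis(x, colMeans(x), S),
                 error = function(e) {
                   stop("score covariance is singular; reduce the number ",
                        "of components", call. = FALSE)
                 })
  if (any(!is.finite(d2))) {
    stop("score covariance is singular; reduce the number of components",
         call. = FALSE)
  }
  sqrt(pmax(d2, 0))
}

#' Hat-matrix leverage
#'
#' Diagonal of `H = X (X'X)^-1 X'` for a full-column-rank design.
#'
#' @param design `n x m` numeric matrix, `n > m`, full column rank
#' @return numeric vector of n leverages in `[0, 1]` summing to `m`
#' @export
hat_leverage <- function(design) {
  x <- as.matrix(design)
  if (nrow(x) <= ncol(x)) {
    stop("need more samples than design columns", call. = FALSE)
  }
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    stop("design matrix is rank deficient (rank ", qrx$rank, " < ",
         ncol(x), ")", call. = FALSE)
  }
  stats::hat(x, intercept = FALSE)
}

#' Flag anomalous spectra
#'
#' Screens samples in a PCA score subspace with two complementary measures:
#' Mahalanobis distance from the centroid, and hat-matrix leverage of the
#' design `[1 | scores]`. A sample is flagged when it exceeds either
#' threshold; the combined flag is the union.
#'
#' Default rules: the squared distance is compared with the `chi^2(k)`
#' quantile `md_quantile` (0.975), and leverage with
#' `leverage_multiplier * m / n` (multiplier 3, `m = k + 1` design columns).
#'
#' @param spectra a [spectra_set()] or matrix
#' @param k PCA components to screen in; default: smallest k explaining
#'   >= 99% of variance, capped at 10
#' @param md_quantile chi-squared quantile for the distance rule, or use
#'   `md_threshold` to give the distance cutoff directly
#' @param leverage_multiplier multiplier for the mean-leverage rule, or use
#'   `leverage_threshold` directly
#' @param md_threshold,leverage_threshold optional explicit cutoffs
#'   overriding the rules
#' @return an `outlier_report`: data frame with per-sample `id`, `md`,
#'   `leverage`, `md_flag`, `leverage_flag`, `flag`; thresholds and `k`
#'   recorded as attributes
#' @export
flag_outliers <- function(spectra, k = NULL, md_quantile = 0.975,
                          leverage_multiplier = 3, md_threshold = NULL,
                          leverage_threshold = NULL) {
  x <- .as_matrix(spectra)
  n <- nrow(x)
  ids <- if (inherits(spectra, "spectra_set")) spectra$sample_ids
         else .row_label(x, seq_len(n))
  if (is.null(k)) {
    kmax <- min(n - 1, ncol(x), 10)
    full <- pca(x, min(n - 1, ncol(x)))
    cum <- cumsum(full$explained_fraction)
    k <- which(cum >= 0.99)[1]
    if (is.na(k)) k <- kmax
    k <- min(k, kmax)
  }
  pc <- pca(x, k)
  md <- mahalanobis_distances(pc$scores)
  design <- cbind(1, pc$scores)
  lev <- hat_leverage(design)
  if (is.null(md_threshold)) {
    md_threshold <- sqrt(stats::qchisq(md_quantile, df = k))
  }
  if (is.null(leverage_threshold)) {
    leverage_threshold <- leverage_multiplier * ncol(design) / n
  }
  rep <- data.frame(id = ids, md = md, leverage = lev,
                    md_flag = md > md_threshold,
                    leverage_flag = lev > leverage_threshold,
                    stringsAsFactors = FALSE)
  rep$flag <- rep$md_flag | rep$leverage_flag
  structure(rep,
            class = c("outlier_report", "data.frame"),
            k = k, md_threshold = md_threshold,
            leverage_threshold = leverage_threshold)
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf(
    "<outlier_report> %d samples screened in %d PCs; MD cutoff %.3f, leverage cutoff %.4f\n",
    nrow(x), attr(x, "k"), attr(x, "md_threshold"),
    attr(x, "leverage_threshold")))
  flagged <- x$id[x$flag]
  if (length(flagged)) {
    cat("flagged:", paste(flagged, collapse = ", "), "\n")
  } else {
    cat("no samples flagged\n")
  }
  invisible(x)
}
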