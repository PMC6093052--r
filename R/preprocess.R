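# Spectral preprocessing: log(1/R) conversion, SNV, MSC, moving-window
# smoothing, Savitzky-Golay smoothing/derivatives, and ordered chains of
# these. All row-wise statistics use the n-1 denominator.

.as_matrix <- function(x) {
  if (inherits(x, "spectra_set")) x$absorbance else as.matrix(x)
}

.row_label <- function(x, i) {
  rn <- rownames(x)
  if (is.null(rn)) as.character(i) else rn[i]
}

#' Convert diffuse reflectance to pseudo-absorbance
#'
#' Elementwise `log10(1/R)`, the log(1/R) mode NIR instruments report.
#'
#' @param reflectance numeric matrix (or vector) of reflectance values in
#'   `(0, 1]`
#' @return matrix of the same shape with absorbance values
#' @export
absorbance_from_reflectance <- function(reflectance) {
  r <- as.matrix(reflectance)
  if (!all(is.finite(r)) || any(r <= 0)) {
    stop("reflectance values must be finite and > 0", call. = FALSE)
  }
  if (any(r > 1)) {
    stop("reflectance values must be <= 1", call. = FALSE)
  }
  -log10(r)
}

#' Standard normal variate transform
#'
#' Centers and scales each spectrum (row) to mean 0 and standard deviation 1
#' (n-1 denominator), removing per-sample additive offsets and multiplicative
#' scatter.
#'
#' @param spectra `n x p` numeric matrix, `p >= 2`
#' @return transformed matrix of the same shape
#' @export
snv <- function(spectra) {
  x <- .as_matrix(spectra)
  if (ncol(x) < 2) stop("SNV needs at least 2 points per spectrum",
                        call. = FALSE)
  mu <- rowMeans(x)
  sdev <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1))
  bad <- which(sdev < .Machine$double.eps * 100)
  if (length(bad)) {
    stop("constant (zero-variance) spectrum, sample ",
         paste(vapply(bad, function(i) .row_label(x, i), ""), collapse = ", "),
         call. = FALSE)
  }
  (x - mu) / sdev
}

#' Multiplicative scatter correction
#'
#' Each spectrum `x` is regressed on a reference spectrum by ordinary least
#' squares, `x ~ a + b * ref`, and corrected to `(x - a) / b`. The reference
#' defaults to the column-mean spectrum of the set being corrected; to
#' correct a prediction set against a calibration set, pass the calibration
#' reference explicitly (see [fit_chain()]).
#'
#' @param spectra `n x p` numeric matrix
#' @param reference optional length-`p` reference spectrum; must not be
#'   constant
#' @return a list with `spectra` (corrected matrix), `offset` and `slope`
#'   (per-sample correction coefficients `a`, `b`) and `reference`
#' @export
msc <- function(spectra, reference = NULL) {
  x <- .as_matrix(spectra)
  if (is.null(reference)) {
    if (nrow(x) < 2) {
      stop("MSC needs >= 2 spectra when no reference is given", call. = FALSE)
    }
    reference <- colMeans(x)
  }
  reference <- as.numeric(reference)
  if (length(reference) != ncol(x)) {
    stop("reference length does not match spectra", call. = FALSE)
  }
  rc <- reference - mean(reference)
  ss <- sum(rc^2)
  if (ss < .Machine$double.eps * 100) {
    stop("MSC reference spectrum is constant", call. = FALSE)
  }
  mu_row <- unname(rowMeans(x))
  b <- as.numeric((x - mu_row) %*% rc) / ss
  a <- mu_row - b * mean(reference)
  bad <- which(abs(b) < 1e-10)
  if (length(bad)) {
    stop("MSC slope numerically zero, sample ",
         paste(vapply(bad, function(i) .row_label(x, i), ""), collapse = ", "),
         call. = FALSE)
  }
  list(spectra = (x - a) / b, offset = a, slope = b, reference = reference)
}

#' Moving-window mean smoothing
#'
#' Each point is replaced by the mean of a centered window of `window`
#' points; at the edges the window is truncated so the output keeps the full
#' spectrum length.
#'
#' @param spectra `n x p` numeric matrix
#' @param window odd integer window length, `3 <= window <= p`
#' @return smoothed matrix of the same shape
#' @export
moving_window_smooth <- function(spectra, window) {
  x <- .as_matrix(spectra)
  p <- ncol(x)
  if (length(window) != 1 || window != round(window) || window < 3 ||
      window %% 2 == 0 || window > p) {
    stop("window must be an odd integer with 3 <= window <= ", p,
         call. = FALSE)
  }
  h <- (window - 1) / 2
  cs <- cbind(0, t(apply(x, 1, cumsum)))
  out <- x
  for (j in seq_len(p)) {
    lo <- max(1L, j - h)
    hi <- min(p, j + h)
    out[, j] <- (cs[, hi + 1] - cs[, lo]) / (hi - lo + 1)
  }
  out
}

#' Savitzky-Golay filtering and derivatives
#'
#' Local least-squares polynomial filtering. Edge points are produced by
#' evaluating the boundary polynomial fits, so the output length equals the
#' input length. Derivatives are returned in per-cm^-1 units: the per-index
#' derivative is divided by `spacing^deriv`, with signed spacing so that a
#' descending wavenumber grid yields the correctly signed d/dnu.
#'
#' @param spectra `n x p` numeric matrix on a uniform grid
#' @param window odd integer filter length
#' @param polyorder polynomial degree, `< window`
#' @param deriv derivative order 0, 1 or 2 (`<= polyorder`)
#' @param spacing grid step in cm^-1 per point (may be negative for
#'   descending grids); default 1 gives per-index derivatives
#' @return filtered matrix of the same shape
#' @export
savgol <- function(spectra, window, polyorder, deriv = 0, spacing = 1) {
  x <- .as_matrix(spectra)
  p <- ncol(x)
  if (length(window) != 1 || window != round(window) || window < 3 ||
      window %% 2 == 0 || window > p) {
    stop("window must be an odd integer with 3 <= window <= ", p,
         call. = FALSE)
  }
  if (polyorder != round(polyorder) || polyorder < 0 || polyorder >= window) {
    stop("polyorder must be a non-negative integer < window", call. = FALSE)
  }
  if (!deriv %in% c(0, 1, 2) || deriv > polyorder) {
    stop("deriv must be 0, 1 or 2 and <= polyorder", call. = FALSE)
  }
  if (!is.finite(spacing) || spacing == 0) {
    stop("spacing must be a nonzero finite grid step", call. = FALSE)
  }
  # signal::sgolay builds the filter matrix incl. boundary polynomial rows
  # and applies the m! factor, i.e. true per-index derivatives.
  fm <- signal::sgolay(p = polyorder, n = window, m = deriv)
  out <- t(apply(x, 1, function(r) signal::sgolayfilt(r, fm)))
  dimnames(out) <- dimnames(x)
  out / spacing^deriv
}

.chain_methods <- c("snv", "msc", "moving_window", "savgol")

#' Define an ordered preprocessing chain
#'
#' @param ... steps, each a list with element `method` (one of `"snv"`,
#'   `"msc"`, `"moving_window"`, `"savgol"`) plus that step's parameters
#'   (`window`, `polyorder`, `deriv`, optional `reference` for msc). An
#'   empty chain is the identity.
#' @return an object of class `preprocess_chain`
#' @examples
#' preprocess_chain(list(method = "savgol", window = 11, polyorder = 2,
#'                       deriv = 1),
#'                  list(method = "snv"))
#' @export
preprocess_chain <- function(...) {
  steps <- list(...)
  if (length(steps) == 1 && is.null(steps[[1]]$method) &&
      is.list(steps[[1]]) && (length(steps[[1]]) == 0 ||
                              is.list(steps[[1]][[1]]))) {
    steps <- steps[[1]]  # accept a single list of steps
  }
  for (i in seq_along(steps)) {
    st <- steps[[i]]
    if (!is.list(st) || is.null(st$method) ||
        !st$method %in% .chain_methods) {
      stop("step ", i, ": method must be one of ",
           paste(.chain_methods, collapse = ", "), call. = FALSE)
    }
    if (st$method %in% c("moving_window", "savgol")) {
      w <- st$window
      if (is.null(w) || w %% 2 == 0 || w < 3) {
        stop("step ", i, " (", st$method,
             "): window must be odd and >= 3", call. = FALSE)
      }
    }
    if (st$method == "savgol") {
      po <- if (is.null(st$polyorder)) 2 else st$polyorder
      dv <- if (is.null(st$deriv)) 0 else st$deriv
      if (po >= st$window) {
        stop("step ", i, ": polyorder must be < window", call. = FALSE)
      }
      if (!dv %in% 0:2) {
        stop("step ", i, ": deriv must be 0, 1 or 2", call. = FALSE)
      }
      steps[[i]]$polyorder <- po
      steps[[i]]$deriv <- dv
    }
  }
  structure(steps, class = "preprocess_chain")
}

#' @export
print.preprocess_chain <- function(x, ...) {
  cat("<preprocess_chain>", chain_label(x), "\n")
  invisible(x)
}

#' Human-readable label for a chain
#' @param chain a [preprocess_chain()]
#' @return a single string such as `"savgol(11,2,1) > snv"`
#' @export
chain_label <- function(chain) {
  if (length(chain) == 0) return("raw")
  paste(vapply(chain, function(st) {
    switch(st$method,
           snv = "snv",
           msc = "msc",
           moving_window = sprintf("mw(%d)", st$window),
           savgol = sprintf("savgol(%d,%d,%d)", st$window, st$polyorder,
                            st$deriv))
  }, character(1)), collapse = " > ")
}

.grid_spacing <- function(wavenumbers) {
  d <- diff(wavenumbers)
  if (max(abs(d - d[1])) > 1e-6 * abs(d[1])) {
    stop("wavenumber grid is not uniform (required for savgol)",
         call. = FALSE)
  }
  d[1]
}

.apply_step <- function(x, st, wavenumbers) {
  switch(st$method,
         snv = snv(x),
         msc = msc(x, reference = st$reference)$spectra,
         moving_window = moving_window_smooth(x, st$window),
         savgol = savgol(x, st$window, st$polyorder, st$deriv,
                         spacing = if (is.null(wavenumbers)) 1
                                   else .grid_spacing(wavenumbers)))
}

#' Fit a preprocessing chain on a calibration set
#'
#' Freezes any data-dependent state so the identical transform can later be
#' applied to new spectra: an `msc` step without an explicit `reference`
#' gains the column-mean reference of the calibration data as seen at that
#' point of the chain. This prevents prediction-set spectra from influencing
#' the correction applied to calibration spectra.
#'
#' @param chain a [preprocess_chain()]
#' @param spectra calibration [spectra_set()] or matrix
#' @param wavenumbers grid (taken from `spectra` when it is a spectra set)
#' @return the chain with references frozen, class
#'   `c("fitted_chain", "preprocess_chain")`
#' @export
fit_chain <- function(chain, spectra, wavenumbers = NULL) {
  stopifnot(inherits(chain, "preprocess_chain"))
  if (inherits(spectra, "spectra_set")) {
    wavenumbers <- spectra$wavenumbers
  }
  x <- .as_matrix(spectra)
  steps <- unclass(chain)
  for (i in seq_along(steps)) {
    st <- steps[[i]]
    if (st$method == "msc" && is.null(st$reference)) {
      steps[[i]]$reference <- colMeans(x)
    }
    x <- tryCatch(.apply_step(x, steps[[i]], wavenumbers),
                  error = function(e) {
                    stop("chain step ", i, " (", st$method, "): ",
                         conditionMessage(e), call. = FALSE)
                  })
  }
  structure(steps, class = c("fitted_chain", "preprocess_chain"))
}

#' Apply a preprocessing chain
#'
#' Steps are applied in order; sample ids and the wavenumber grid are
#' preserved. The empty chain is the identity. An unfitted `msc` step uses
#' the mean spectrum of the set being transformed; a [fit_chain()]-frozen
#' chain reuses its calibration reference.
#'
#' @param spectra a [spectra_set()] or numeric matrix
#' @param chain a [preprocess_chain()] or fitted chain
#' @return object of the same kind as `spectra`, transformed
#' @export
apply_chain <- function(spectra, chain) {
  stopifnot(inherits(chain, "preprocess_chain"))
  is_set <- inherits(spectra, "spectra_set")
  wavenumbers <- if (is_set) spectra$wavenumbers else NULL
  x <- .as_matrix(spectra)
  for (i in seq_along(chain)) {
    st <- chain[[i]]
    x <- tryCatch(.apply_step(x, st, wavenumbers),
                  error = function(e) {
                    stop("chain step ", i, " (", st$method, "): ",
                         conditionMessage(e), call. = FALSE)
                  })
  }
  if (is_set) {
    spectra_set(x, spectra$wavenumbers, spectra$sample_ids)
  } else {
    x
  }
}
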