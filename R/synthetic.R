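# Synthetic NIR dataset generator. Spectra are built by linear constituent
# mixing (Gaussian absorption bands) plus a per-sample polynomial baseline,
# multiplicative/additive scatter, and white noise -- the statistical
# structure a scatter-corrected PLS calibration assumes -- so the whole
# pipeline can be exercised when no measured spectra are available.

#' Describe a spectrally active constituent
#'
#' A constituent contributes `concentration * sum_k h_k *
#' exp(-((nu - c_k) / w_k)^2 / 2)` to each spectrum.
#'
#' @param name constituent label
#' @param bands numeric matrix with columns `center` (cm^-1), `width`
#'   (cm^-1, Gaussian sigma, > 0) and `height` (absorbance units per
#'   concentration unit, >= 0)
#' @param conc_range length-2 non-negative concentration range the
#'   generator draws from (uniformly)
#' @return object of class `constituent_band_model`
#' @export
constituent_band_model <- function(name, bands, conc_range) {
  bands <- as.matrix(bands)
  colnames(bands) <- c("center", "width", "height")
  if (any(bands[, "width"] <= 0) || any(bands[, "height"] < 0)) {
    stop("band widths must be > 0 and heights >= 0", call. = FALSE)
  }
  conc_range <- as.numeric(conc_range)
  if (length(conc_range) != 2 || any(conc_range < 0) ||
      conc_range[2] < conc_range[1]) {
    stop("conc_range must be a non-negative increasing pair", call. = FALSE)
  }
  structure(list(name = name, bands = bands, conc_range = conc_range),
            class = "constituent_band_model")
}

# Unit-concentration spectrum of one constituent on a grid.
constituent_spectrum <- function(constituent, grid) {
  b <- constituent$bands
  s <- numeric(length(grid))
  for (k in seq_len(nrow(b))) {
    s <- s + b[k, "height"] *
      exp(-0.5 * ((grid - b[k, "center"]) / b[k, "width"])^2)
  }
  s
}

#' Default constituent set
#'
#' Three NIR-plausible constituents: a flavonoid fraction (band near 5352
#' cm^-1, the carbonyl second overtone region, plus weaker combination
#' bands), moisture (intense O-H bands near 6900 and 5180 cm^-1), and a
#' non-flavonoid phenolic fraction that co-determines antioxidant activity.
#' The flavonoid concentration range is the span observed in the packaged
#' 113-sample reference table.
#'
#' @return named list of [constituent_band_model()] objects
#' @export
default_constituents <- function() {
  list(
    flavonoids = constituent_band_model(
      "flavonoids",
      rbind(c(5352, 180, 0.004),
            c(4420, 150, 0.0025),
            c(6010, 220, 0.0015)),
      conc_range = c(1.47, 49.20)),
    water = constituent_band_model(
      "water",
      rbind(c(6900, 260, 0.018),
            c(5180, 200, 0.020)),
      conc_range = c(40, 60)),
    phenolics = constituent_band_model(
      "phenolics",
      rbind(c(4700, 160, 0.008),
            c(5600, 240, 0.005),
            c(6350, 300, 0.003)),
      conc_range = c(0, 10))
  )
}

#' Default antioxidant-activity link
#'
#' TAA is modelled as `slope * TFC + intercept + co_coef * (phenolics -
#' mid-range) + N(0, noise_sd)`, truncated at 0. Slope and intercept are the
#' least-squares fit of TAA on TFC over the packaged reference table;
#' `noise_sd` is the mean reported TAA assay standard deviation
#' (repeatability); `co_coef` is sized so the phenolic co-constituent
#' carries the remaining observed scatter about the TFC line.
#'
#' @param phenolics_range concentration range of the co-constituent (used to
#'   size its coefficient)
#' @return list with `slope`, `intercept`, `noise_sd`, `co_constituent`,
#'   `co_coef`
#' @export
default_taa_link <- function(phenolics_range = c(0, 10)) {
  ref <- load_table1_fixture()
  fit <- stats::lm(taa ~ tfc, data = ref)
  resid_sd <- summary(fit)$sigma
  noise_sd <- mean(ref$taa_sd)
  comp_sd <- sqrt(max(resid_sd^2 - noise_sd^2, 0))
  phen_sd <- diff(phenolics_range) / sqrt(12)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       noise_sd = noise_sd,
       co_constituent = "phenolics",
       co_coef = if (phen_sd > 0) comp_sd / phen_sd else 0)
}

#' Configuration for the synthetic dataset generator
#'
#' Defaults emulate the calibration study's conditions: 113 samples on a
#' 4150-point grid over 4000-8000 cm^-1, flavonoid content spanning
#' 1.47-49.20 mg/g, antioxidant activity coupled to it as in
#' [default_taa_link()], moderate multiplicative/additive scatter, a
#' quadratic baseline, and instrument-level white noise.
#'
#' @param n_samples number of samples (>= 2)
#' @param grid wavenumber grid (strictly monotonic, cm^-1)
#' @param constituents named list of [constituent_band_model()]; the first
#'   one named by `tfc_constituent` supplies the TFC reference values
#' @param tfc_constituent name of the constituent reported as TFC
#' @param baseline_order polynomial degree of the per-sample baseline
#' @param baseline_offset mean baseline level (absorbance units)
#' @param baseline_coef_sd sd of the random baseline coefficients
#' @param scatter_slope_sd sd of the per-sample multiplicative scatter
#'   factor about 1
#' @param scatter_offset_sd sd of the per-sample additive offset
#' @param noise_sd sd of the additive white noise (absorbance units)
#' @param taa_link list as returned by [default_taa_link()]
#' @param seed RNG seed (mandatory for reproducibility)
#' @return object of class `synthetic_config`
#' @export
synthetic_config <- function(n_samples = 113,
                             grid = seq(4000, 8000, length.out = 4150),
                             constituents = default_constituents(),
                             tfc_constituent = "flavonoids",
                             baseline_order = 2,
                             baseline_offset = 0.3,
                             baseline_coef_sd = 0.02,
                             scatter_slope_sd = 0.05,
                             scatter_offset_sd = 0.02,
                             noise_sd = 5e-4,
                             taa_link = default_taa_link(),
                             seed = 20180801) {
  if (n_samples < 2) stop("n_samples must be >= 2", call. = FALSE)
  grid <- as.numeric(grid)
  if (length(grid) < 2 || !(all(diff(grid) > 0) || all(diff(grid) < 0))) {
    stop("grid must be strictly monotonic with >= 2 points", call. = FALSE)
  }
  if (!tfc_constituent %in% names(constituents)) {
    stop("tfc_constituent '", tfc_constituent,
         "' is not among the constituents", call. = FALSE)
  }
  sds <- c(baseline_coef_sd, scatter_slope_sd, scatter_offset_sd, noise_sd,
           taa_link$noise_sd)
  if (any(sds < 0)) stop("all sd parameters must be >= 0", call. = FALSE)
  if (baseline_order < 0 || baseline_order != round(baseline_order)) {
    stop("baseline_order must be a non-negative integer", call. = FALSE)
  }
  structure(list(n_samples = as.integer(n_samples), grid = grid,
                 constituents = constituents,
                 tfc_constituent = tfc_constituent,
                 baseline_order = baseline_order,
                 baseline_offset = baseline_offset,
                 baseline_coef_sd = baseline_coef_sd,
                 scatter_slope_sd = scatter_slope_sd,
                 scatter_offset_sd = scatter_offset_sd,
                 noise_sd = noise_sd, taa_link = taa_link,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic spectra + reference dataset
#'
#' Row i of the absorbance matrix is
#' `b_i * (sum_k c_ik s_k(nu) + baseline_i(nu)) + a_i + eps_i(nu)`, with
#' concentrations drawn uniformly from each constituent's range, `b_i ~ 1 +
#' N(0, scatter_slope_sd)`, `a_i ~ N(0, scatter_offset_sd)` and white noise
#' `eps`. TFC is the designated constituent's concentration; TAA follows the
#' configured link, truncated at 0. The same configuration (including seed)
#' always produces the identical dataset.
#'
#' @param config a [synthetic_config()]
#' @return list with `spectra` (a [spectra_set()]), `reference` (a
#'   [reference_table()]) and `concentrations` (true `n x K` matrix)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_samples
  grid <- config$grid
  p <- length(grid)
  K <- length(config$constituents)
  S <- t(vapply(config$constituents, constituent_spectrum, numeric(p),
                grid = grid))
  with_local_seed(config$seed, {
    conc <- vapply(config$constituents, function(cm) {
      stats::runif(n, cm$conc_range[1], cm$conc_range[2])
    }, numeric(n))
    conc <- matrix(conc, nrow = n, ncol = K,
                   dimnames = list(NULL, names(config$constituents)))
    mix <- conc %*% S
    tnu <- (grid - min(grid)) / (max(grid) - min(grid))
    base_coef <- matrix(stats::rnorm(n * (config$baseline_order + 1),
                                     sd = config$baseline_coef_sd),
                        nrow = n)
    base_coef[, 1] <- base_coef[, 1] + config$baseline_offset
    baseline <- base_coef %*% t(outer(tnu, 0:config$baseline_order, `^`))
    b <- pmax(1 + stats::rnorm(n, sd = config$scatter_slope_sd), 0.05)
    a <- stats::rnorm(n, sd = config$scatter_offset_sd)
    eps <- matrix(stats::rnorm(n * p, sd = config$noise_sd), nrow = n)
    absorb <- b * (mix + baseline) + a + eps
    tfc <- conc[, config$tfc_constituent]
    link <- config$taa_link
    taa <- link$slope * tfc + link$intercept
    if (!is.null(link$co_constituent) && isTRUE(link$co_coef != 0)) {
      co <- config$constituents[[link$co_constituent]]
      if (is.null(co)) {
        stop("taa_link co_constituent '", link$co_constituent,
             "' is not among the constituents", call. = FALSE)
      }
      taa <- taa + link$co_coef *
        (conc[, link$co_constituent] - mean(co$conc_range))
    }
    taa <- pmax(taa + stats::rnorm(n, sd = link$noise_sd), 0)
    ids <- sprintf("S%03d", seq_len(n))
    list(spectra = spectra_set(absorb, grid, sample_ids = ids),
         reference = reference_table(ids, tfc, taa),
         concentrations = conc)
  })
}

#' Scatter-corrupted study conditions
#'
#' A [synthetic_config()] for the scatter-stress scenario: each spectrum
#' undergoes a strong per-sample affine transform (multiplicative factor sd
#' 0.25, additive offset sd 0.15) with no other per-sample baseline
#' variation, i.e. exactly the corruption the standard normal variate
#' transform is designed to remove. Used to compare preprocessing
#' candidates under severe scatter.
#'
#' @param seed RNG seed
#' @param ... further arguments passed to [synthetic_config()]
#' @return a `synthetic_config`
#' @export
scatter_corrupted_config <- function(seed = 20180801, ...) {
  synthetic_config(baseline_coef_sd = 0, scatter_slope_sd = 0.25,
                   scatter_offset_sd = 0.15, seed = seed, ...)
}

#' Inject gross scatter outliers
#'
#' Perturbs the listed spectra by a multiplicative factor plus a baseline
#' shift, emulating grossly anomalous diffuse-reflectance measurements;
#' other spectra are untouched. With `severity = 1` and `shift = 0` the
#' input is returned unchanged.
#'
#' @param spectra a [spectra_set()]
#' @param indices sample positions to perturb (may be empty)
#' @param severity multiplicative factor, > 0
#' @param shift additive baseline shift (absorbance units)
#' @return the perturbed [spectra_set()]
#' @export
inject_outliers <- function(spectra, indices, severity = 3, shift = 0.05) {
  stopifnot(inherits(spectra, "spectra_set"))
  if (!is.finite(severity) || severity <= 0) {
    stop("severity must be > 0", call. = FALSE)
  }
  indices <- as.integer(indices)
  if (length(indices) == 0) return(spectra)
  if (any(indices < 1 | indices > n_samples(spectra))) {
    stop("outlier index out of range 1..", n_samples(spectra), call. = FALSE)
  }
  x <- spectra$absorbance
  x[indices, ] <- severity * x[indices, , drop = FALSE] + shift
  spectra_set(x, spectra$wavenumbers, spectra$sample_ids)
}
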