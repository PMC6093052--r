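# Reference-assay arithmetic: the rutin-calibrated colorimetric TFC assay
# (absorbance -> concentration -> mg rutin equivalents per g dry weight via
# the extraction volumetrics) and DPPH scavenging with Trolox-equivalent
# conversion.

#' Linear assay calibration
#'
#' @param slope absorbance per concentration unit (nonzero)
#' @param intercept absorbance at zero concentration
#' @param correlation_r Pearson r of the fit, `|r| <= 1`
#' @param concentration_unit label carried through the arithmetic
#' @return object of class `assay_calibration`
#' @export
assay_calibration <- function(slope, intercept, correlation_r = NA_real_,
                              concentration_unit = "conc") {
  if (!is.finite(slope) || slope == 0) {
    stop("calibration slope must be nonzero", call. = FALSE)
  }
  if (is.finite(correlation_r) && abs(correlation_r) > 1) {
    stop("|correlation_r| must be <= 1", call. = FALSE)
  }
  structure(list(slope = slope, intercept = intercept,
                 correlation_r = correlation_r,
                 concentration_unit = concentration_unit),
            class = "assay_calibration")
}

#' The rutin standard line of the TFC assay
#'
#' The colorimetric flavonoid assay's published rutin calibration,
#' `A = 8.0045 C + 0.0914` with r = 0.9959. The concentration unit of the
#' printed line is carried symbolically.
#'
#' @return an [assay_calibration()]
#' @export
rutin_calibration <- function() {
  assay_calibration(slope = 8.0045, intercept = 0.0914,
                    correlation_r = 0.9959,
                    concentration_unit = "mg/mL rutin eq")
}

#' Extraction / dilution scheme of the wet assays
#'
#' Defaults follow the reference procedure: 0.90-1.00 g sample (0.95 g
#' nominal) extracted and made up to 25 mL, a 1.5 mL aliquot reacted and
#' made up to 25 mL.
#'
#' @param sample_mass g dry sample extracted
#' @param extract_volume mL of final extract
#' @param aliquot_volume mL of extract taken into the reaction
#' @param reaction_volume mL of final reaction mixture
#' @return object of class `extraction_scheme`
#' @export
extraction_scheme <- function(sample_mass = 0.95, extract_volume = 25,
                              aliquot_volume = 1.5, reaction_volume = 25) {
  v <- c(sample_mass, extract_volume, aliquot_volume, reaction_volume)
  if (any(!is.finite(v)) || any(v <= 0)) {
    stop("all extraction scheme quantities must be positive", call. = FALSE)
  }
  if (aliquot_volume > extract_volume) {
    stop("aliquot volume cannot exceed extract volume", call. = FALSE)
  }
  structure(list(sample_mass = sample_mass, extract_volume = extract_volume,
                 aliquot_volume = aliquot_volume,
                 reaction_volume = reaction_volume),
            class = "extraction_scheme")
}

#' Fit a linear assay calibration by least squares
#'
#' @param concentrations standard concentrations (>= 2 distinct values)
#' @param absorbances matching absorbance readings
#' @param concentration_unit unit label for the fitted line
#' @return an [assay_calibration()] with the OLS slope/intercept and
#'   Pearson r
#' @export
fit_linear_calibration <- function(concentrations, absorbances,
                                   concentration_unit = "conc") {
  x <- as.numeric(concentrations)
  y <- as.numeric(absorbances)
  if (length(x) < 2 || length(x) != length(y)) {
    stop("need equal-length vectors with >= 2 points", call. = FALSE)
  }
  if (stats::sd(x) < .Machine$double.eps * 100) {
    stop("standard concentrations are constant; cannot fit a line",
         call. = FALSE)
  }
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  r <- stats::cor(x, y)
  assay_calibration(slope, intercept, correlation_r = r,
                    concentration_unit = concentration_unit)
}

# Volumetric scaling common to both assays: reaction-mixture concentration
# -> per g dry weight.
scheme_factor <- function(scheme) {
  stopifnot(inherits(scheme, "extraction_scheme"))
  scheme$reaction_volume * (scheme$extract_volume / scheme$aliquot_volume) /
    scheme$sample_mass
}

#' Total flavonoid content from assay absorbance
#'
#' Inverts the calibration line to the reaction-mixture concentration
#' `C = (A - intercept) / slope`, then scales through the extraction
#' volumetrics: `TFC = C * reaction_volume * (extract_volume /
#' aliquot_volume) / sample_mass`. Absorbances below the intercept give a
#' 0-truncated concentration with a warning.
#'
#' @param absorbance assay absorbance reading(s)
#' @param calibration an [assay_calibration()]; default [rutin_calibration()]
#' @param scheme an [extraction_scheme()]
#' @return TFC in `concentration_unit * mL / g` of dry weight (mg rutin
#'   eq / g DW for a mg/mL standard line)
#' @export
tfc_from_absorbance <- function(absorbance,
                                calibration = rutin_calibration(),
                                scheme = extraction_scheme()) {
  stopifnot(inherits(calibration, "assay_calibration"))
  conc <- (absorbance - calibration$intercept) / calibration$slope
  if (any(conc < 0)) {
    warning("absorbance below the calibration intercept; ",
            "concentration truncated at 0", call. = FALSE)
    conc <- pmax(conc, 0)
  }
  conc * scheme_factor(scheme)
}

#' DPPH radical scavenging fraction
#'
#' `(a_blank - a_sample) / a_blank`: the fractional decrease in DPPH
#' absorbance caused by the sample.
#'
#' @param a_blank blank (no antioxidant) absorbance, > 0
#' @param a_sample sample absorbance, >= 0
#' @param clip clip the result into `[0, 1]`?
#' @return scavenging fraction (`<= 1`; can be negative unless clipped)
#' @export
dpph_scavenging <- function(a_blank, a_sample, clip = FALSE) {
  if (any(!is.finite(a_blank)) || any(a_blank <= 0)) {
    stop("blank absorbance must be finite and > 0", call. = FALSE)
  }
  if (any(a_sample < 0)) {
    stop("sample absorbance must be >= 0", call. = FALSE)
  }
  s <- (a_blank - a_sample) / a_blank
  if (clip) s <- pmin(pmax(s, 0), 1)
  s
}

#' Trolox-equivalent antioxidant capacity
#'
#' Inverts a scavenging-vs-Trolox-concentration calibration line, then
#' applies the extraction scheme's volumetric scaling to per-g-dry-weight
#' units.
#'
#' @param scavenging DPPH scavenging fraction(s)
#' @param trolox_curve an [assay_calibration()] relating scavenging to
#'   Trolox concentration (slope per mM)
#' @param scheme an [extraction_scheme()], or `NULL` to return the reaction
#'   concentration unscaled
#' @return mM Trolox equivalents (per g DW when a scheme is given)
#' @export
trolox_equivalent <- function(scavenging, trolox_curve,
                              scheme = extraction_scheme()) {
  stopifnot(inherits(trolox_curve, "assay_calibration"))
  conc <- (scavenging - trolox_curve$intercept) / trolox_curve$slope
  if (is.null(scheme)) conc else conc * scheme_factor(scheme)
}
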