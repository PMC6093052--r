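# End-to-end calibration workflow: id alignment, one-shot outlier removal,
# Kennard-Stone partitioning, preprocessing-candidate comparison by minimum
# RMSECV, cross-validated factor selection, final fit, and evaluation on the
# untouched prediction set.

#' Default preprocessing candidates
#'
#' The raw spectra plus the four preprocessing families the pipeline
#' compares: SNV, MSC, moving-window smoothing, and Savitzky-Golay first and
#' second derivatives (window 11, polynomial order 2).
#'
#' @return named list of [preprocess_chain()] objects
#' @export
default_chain_candidates <- function() {
  list(
    raw = preprocess_chain(),
    snv = preprocess_chain(list(method = "snv")),
    msc = preprocess_chain(list(method = "msc")),
    mw = preprocess_chain(list(method = "moving_window", window = 11)),
    sg1 = preprocess_chain(list(method = "savgol", window = 11,
                                polyorder = 2, deriv = 1)),
    sg2 = preprocess_chain(list(method = "savgol", window = 11,
                                polyorder = 2, deriv = 2))
  )
}

#' Run the full calibration workflow for one response
#'
#' Stages, in order: (1) align spectra with reference values by sample id;
#' (2) screen and remove outliers once ([flag_outliers()]); (3) split the
#' remaining samples into calibration and prediction sets by Kennard-Stone;
#' (4) score every candidate preprocessing chain by its minimum 10-fold
#' RMSECV on the calibration set and keep the best (ties: shorter chain,
#' then listed order); (5) select the factor count at the winning chain's
#' RMSECV minimum and refit on the whole calibration set; (6) evaluate
#' RMSEC/RMSEP and r/r^2 on both sets. Prediction-set samples never
#' influence preprocessing references, cross-validation, factor choice or
#' centering.
#'
#' @param spectra a [spectra_set()]
#' @param reference a [reference_table()] covering the spectra ids
#' @param target response column, `"tfc"` or `"taa"`
#' @param chains named list of candidate [preprocess_chain()]s
#' @param ratio Kennard-Stone calibration fraction
#' @param folds cross-validation folds
#' @param max_factors largest factor count scored; default
#'   `min(20, n_cal - ceil(n_cal/folds) - 1, p)`
#' @param cv_seed seed for the fold permutation
#' @param remove_outliers screen and drop outliers first?
#' @param k PCA components for outlier screening (`NULL` = automatic)
#' @param split optional precomputed `split_result` (indices into the
#'   post-outlier-removal sample order); when given, Kennard-Stone is
#'   skipped. This also supports leakage audits with a frozen split.
#' @param verbose emit one message per stage?
#' @return object of class `nir_calibration`: list with `target`, `model`,
#'   `cv`, `evaluation`, `outliers`, `split`, `chain` (fitted winning
#'   chain), `chain_rmsecv` (per-candidate minimum RMSECV),
#'   `calibration_ids`, `prediction_ids`, `removed_ids`
#' @export
run_calibration_workflow <- function(spectra, reference,
                                     target = c("tfc", "taa"),
                                     chains = default_chain_candidates(),
                                     ratio = 0.8, folds = 10,
                                     max_factors = NULL,
                                     cv_seed = 20180801,
                                     remove_outliers = TRUE, k = NULL,
                                     split = NULL, verbose = FALSE) {
  target <- match.arg(target)
  stopifnot(inherits(spectra, "spectra_set"),
            inherits(reference, "reference_table"))
  say <- function(...) if (verbose) message("[", target, "] ", ...)

  idx <- match(spectra$sample_ids, reference$id)
  if (anyNA(idx)) {
    stop("spectra ids missing from the reference table: ",
         paste(spectra$sample_ids[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  y_all <- reference[[target]][idx]
  say("aligned ", n_samples(spectra), " spectra x ",
      length(spectra$wavenumbers), " points with reference values")

  if (remove_outliers) {
    outliers <- flag_outliers(spectra, k = k)
    keep <- !outliers$flag
    removed_ids <- outliers$id[outliers$flag]
    say("outlier screening flagged ", sum(outliers$flag), " of ",
        nrow(outliers), " samples")
  } else {
    outliers <- NULL
    keep <- rep(TRUE, n_samples(spectra))
    removed_ids <- character(0)
  }
  x_kept <- spectra$absorbance[keep, , drop = FALSE]
  ids_kept <- spectra$sample_ids[keep]
  y_kept <- y_all[keep]

  if (is.null(split)) {
    split <- kennard_stone_split(x_kept, ratio)
  } else {
    stopifnot(inherits(split, "split_result"))
    if (length(split$calibration) + length(split$prediction) !=
        nrow(x_kept)) {
      stop("provided split does not cover the retained samples",
           call. = FALSE)
    }
  }
  cal <- split$calibration
  prd <- split$prediction
  say("split: ", length(cal), " calibration / ", length(prd), " prediction")

  x_cal <- x_kept[cal, , drop = FALSE]
  y_cal <- y_kept[cal]
  n_cal <- length(cal)
  if (is.null(max_factors)) {
    max_factors <- min(20, n_cal - ceiling(n_cal / folds) - 1, ncol(x_cal))
  }

  fitted_chains <- vector("list", length(chains))
  cvs <- vector("list", length(chains))
  scores <- rep(NA_real_, length(chains))
  for (ci in seq_along(chains)) {
    fc <- fit_chain(chains[[ci]], x_cal, wavenumbers = spectra$wavenumbers)
    xc <- apply_chain(x_cal, fc)
    cvs[[ci]] <- cross_validate(xc, y_cal, max_factors = max_factors,
                                folds = folds, seed = cv_seed)
    scores[ci] <- min(cvs[[ci]]$rmsecv)
    fitted_chains[[ci]] <- fc
    say("chain ", chain_label(chains[[ci]]), ": min RMSECV ",
        signif(scores[ci], 4), " at A = ", cvs[[ci]]$optimal_factors)
  }
  names(scores) <- if (is.null(names(chains)))
    vapply(chains, chain_label, character(1)) else names(chains)
  ord <- order(scores, lengths(chains), seq_along(chains))
  win <- ord[1]
  say("winning chain: ", chain_label(chains[[win]]))

  chain_fit <- fitted_chains[[win]]
  cv <- cvs[[win]]
  x_cal_t <- apply_chain(x_cal, chain_fit)
  model <- fit_pls(x_cal_t, y_cal, cv$optimal_factors)
  model$chain <- chain_fit

  yhat_cal <- predict_pls(model, x_cal_t)
  cor_cal <- correlation_r(y_cal, yhat_cal)
  x_prd_t <- apply_chain(x_kept[prd, , drop = FALSE], chain_fit)
  yhat_prd <- predict_pls(model, x_prd_t)
  cor_prd <- correlation_r(y_kept[prd], yhat_prd)

  evaluation <- structure(list(
    rmsec = rmse(y_cal, yhat_cal, "calibration"),
    rmsep = rmse(y_kept[prd], yhat_prd, "prediction"),
    rmsecv_min = min(cv$rmsecv),
    r_calibration = cor_cal$r, r2_calibration = cor_cal$r2,
    r_prediction = cor_prd$r, r2_prediction = cor_prd$r2,
    n_calibration = n_cal, n_prediction = length(prd),
    y_mean_calibration = mean(y_cal),
    y_mean_prediction = mean(y_kept[prd]),
    optimal_factors = cv$optimal_factors), class = "model_evaluation")
  say(sprintf("RMSEC %.4g, RMSEP %.4g, r2(cal) %.4f, r2(pred) %.4f",
              evaluation$rmsec, evaluation$rmsep,
              evaluation$r2_calibration, evaluation$r2_prediction))

  structure(list(target = target, model = model, cv = cv,
                 evaluation = evaluation, outliers = outliers,
                 split = split, chain = chain_fit,
                 chain_rmsecv = scores,
                 calibration_ids = ids_kept[cal],
                 prediction_ids = ids_kept[prd],
                 removed_ids = removed_ids),
            class = "nir_calibration")
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat(sprintf(
    paste0("<model_evaluation> A = %d\n",
           "  calibration (n = %d): RMSEC %.4g, r = %.4f, r2 = %.4f\n",
           "  prediction  (n = %d): RMSEP %.4g, r = %.4f, r2 = %.4f\n"),
    x$optimal_factors, x$n_calibration, x$rmsec, x$r_calibration,
    x$r2_calibration, x$n_prediction, x$rmsep, x$r_prediction,
    x$r2_prediction))
  invisible(x)
}

#' @export
print.nir_calibration <- function(x, ...) {
  cat("<nir_calibration> target:", x$target, "| chain:",
      chain_label(x$chain), "\n")
  if (length(x$removed_ids)) {
    cat("outliers removed:", paste(x$removed_ids, collapse = ", "), "\n")
  }
  print(x$evaluation)
  invisible(x)
}
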