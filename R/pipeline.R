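# Pipeline orchestration over a single configuration: data acquisition
# (synthetic simulation or CSV paths), per-target calibration workflow, and
# a deterministic machine-readable run report. One global seed fans out to
# fixed per-stage seeds so identical config + seed reproduces every number.

#' Default pipeline configuration
#'
#' @param seed global seed; per-stage seeds are derived from it
#' @return nested configuration list (see [run_pipeline()])
#' @export
default_pipeline_config <- function(seed = 20180801) {
  list(
    seed = as.integer(seed),
    synthetic = list(n_samples = 113, n_points = 4150,
                     wn_min = 4000, wn_max = 8000),
    preprocess = list(
      list(),
      list(list(method = "snv")),
      list(list(method = "msc")),
      list(list(method = "moving_window", window = 11)),
      list(list(method = "savgol", window = 11, polyorder = 2, deriv = 1)),
      list(list(method = "savgol", window = 11, polyorder = 2, deriv = 2))
    ),
    diagnostics = list(md_quantile = 0.975, leverage_multiplier = 3),
    split = list(ratio = 0.8),
    cv = list(folds = 10),
    targets = c("tfc", "taa"),
    paths = list()
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the sections of [default_pipeline_config()];
#'   missing sections fall back to the defaults
#' @return validated configuration list
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  user <- yaml::read_yaml(path)
  config <- default_pipeline_config()
  for (nm in names(user)) {
    # named sections merge key-by-key; list-valued sections (preprocess,
    # targets, paths) replace the default wholesale
    if (nm %in% c("synthetic", "cv", "split", "diagnostics") &&
        is.list(config[[nm]])) {
      config[[nm]] <- utils::modifyList(config[[nm]], user[[nm]])
    } else {
      config[[nm]] <- user[[nm]]
    }
  }
  validate_pipeline_config(config)
  config
}

#' Validate a pipeline configuration
#'
#' Fails fast, before any computation, on out-of-range settings.
#'
#' @param config configuration list
#' @return the config, invisibly
#' @export
validate_pipeline_config <- function(config) {
  ratio <- config$split$ratio
  if (is.null(ratio) || !is.finite(ratio) || ratio <= 0 || ratio >= 1) {
    stop("split ratio must be strictly between 0 and 1", call. = FALSE)
  }
  folds <- config$cv$folds
  if (is.null(folds) || folds < 2) {
    stop("cv folds must be >= 2", call. = FALSE)
  }
  if (!all(config$targets %in% c("tfc", "taa"))) {
    stop("targets must be a subset of tfc, taa", call. = FALSE)
  }
  for (p in unlist(config$paths)) {
    if (!file.exists(p)) stop("configured file does not exist: ", p,
                              call. = FALSE)
  }
  for (ch in config$preprocess) do.call(preprocess_chain, ch)
  invisible(config)
}

config_chains <- function(config) {
  chains <- lapply(config$preprocess, function(ch) {
    do.call(preprocess_chain, ch)
  })
  names(chains) <- vapply(chains, chain_label, character(1))
  chains
}

config_synthetic <- function(config, seed) {
  sc <- config$synthetic
  grid <- seq(sc$wn_min %||% 4000, sc$wn_max %||% 8000,
              length.out = sc$n_points %||% 4150)
  synthetic_config(n_samples = sc$n_samples %||% 113, grid = grid,
                   seed = derive_seed(seed, "synthetic"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Acquire the pipeline's input data: configured CSV paths if given,
# otherwise a seeded synthetic dataset.
pipeline_data <- function(config, seed) {
  if (!is.null(config$paths$spectra_csv)) {
    if (is.null(config$paths$reference_csv)) {
      stop("paths$reference_csv is required when spectra_csv is given",
           call. = FALSE)
    }
    list(spectra = read_spectra_csv(config$paths$spectra_csv),
         reference = load_reference_table(config$paths$reference_csv),
         synthetic = FALSE)
  } else {
    ds <- generate_dataset(config_synthetic(config, seed))
    list(spectra = ds$spectra, reference = ds$reference, synthetic = TRUE)
  }
}

#' Run the full pipeline and write a reproducible report
#'
#' Executes the calibration workflow for every configured target and writes
#' `report.json` (machine-readable run report), `evaluation.csv`,
#' `rmsecv_<target>.csv`, `outliers_<target>.csv` and `model_<target>.json`
#' into `out_dir`. Identical config + seed yields byte-identical
#' machine-readable outputs. Any stage failure aborts with the stage name
#' before anything is written.
#'
#' @param config configuration list ([default_pipeline_config()] /
#'   [read_pipeline_config()])
#' @param out_dir output directory (created if missing); `NULL` skips
#'   writing
#' @param seed optional override of `config$seed`
#' @param verbose log one line per stage?
#' @return the run report list, invisibly when writing
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir = NULL,
                         seed = NULL, verbose = FALSE) {
  validate_pipeline_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  seed <- config$seed %||% 20180801
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  dat <- stage("data", pipeline_data(config, seed))
  chains <- stage("config", config_chains(config))
  results <- list()
  for (target in config$targets) {
    results[[target]] <- stage(paste0("calibrate-", target),
      run_calibration_workflow(
        dat$spectra, dat$reference, target = target, chains = chains,
        ratio = config$split$ratio, folds = config$cv$folds,
        max_factors = config$cv$max_factors,
        cv_seed = derive_seed(seed, "folds"),
        verbose = verbose))
  }

  first <- results[[1]]
  report <- list(
    software = paste0("nirflav ",
                      as.character(utils::packageVersion("nirflav"))),
    seed = seed,
    n_samples = n_samples(dat$spectra),
    n_points = length(dat$spectra$wavenumbers),
    synthetic_data = dat$synthetic,
    outlier_ids = first$removed_ids,
    split = list(n_calibration = length(first$split$calibration),
                 n_prediction = length(first$split$prediction),
                 ratio = config$split$ratio),
    targets = lapply(results, function(res) {
      ev <- res$evaluation
      list(chain = chain_label(res$chain),
           optimal_factors = ev$optimal_factors,
           chain_rmsecv = as.list(res$chain_rmsecv),
           rmsec = ev$rmsec, rmsecv = ev$rmsecv_min, rmsep = ev$rmsep,
           r2_calibration = ev$r2_calibration,
           r2_prediction = ev$r2_prediction,
           r_calibration = ev$r_calibration,
           r_prediction = ev$r_prediction,
           n_calibration = ev$n_calibration,
           n_prediction = ev$n_prediction)
    }),
    config = config[c("seed", "split", "cv", "targets")]
  )

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    stage("report", {
      jsonlite::write_json(report, file.path(out_dir, "report.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      ev_df <- do.call(rbind, lapply(names(results), function(t) {
        ev <- results[[t]]$evaluation
        data.frame(target = t, chain = chain_label(results[[t]]$chain),
                   factors = ev$optimal_factors, rmsec = ev$rmsec,
                   rmsecv = ev$rmsecv_min, rmsep = ev$rmsep,
                   r2_calibration = ev$r2_calibration,
                   r2_prediction = ev$r2_prediction)
      }))
      utils::write.csv(ev_df, file.path(out_dir, "evaluation.csv"),
                       row.names = FALSE)
      for (t in names(results)) {
        res <- results[[t]]
        utils::write.csv(
          data.frame(factors = seq_along(res$cv$rmsecv),
                     rmsecv = unname(res$cv$rmsecv)),
          file.path(out_dir, paste0("rmsecv_", t, ".csv")),
          row.names = FALSE)
        if (!is.null(res$outliers)) {
          utils::write.csv(as.data.frame(res$outliers),
                           file.path(out_dir, paste0("outliers_", t, ".csv")),
                           row.names = FALSE)
        }
        write_pls_model(res$model, file.path(out_dir,
                                             paste0("model_", t, ".json")))
      }
    })
    return(invisible(c(report, list(results = results))))
  }
  c(report, list(results = results))
}

ARCHIVE_FORMAT <- "nirflav-pls-1"

#' Write a PLS model archive
#'
#' Plain-text JSON holding every model field (weights, loadings, regression
#' vector, centering terms, preprocessing chain) at full double precision;
#' [read_pls_model()] restores it bit-exactly.
#'
#' @param model a [fit_pls()] model
#' @param path destination file
#' @return `path`, invisibly
#' @export
write_pls_model <- function(model, path) {
  stopifnot(inherits(model, "pls_model"))
  chain <- if (is.null(model$chain)) list() else
    lapply(unclass(model$chain), function(st) st)
  payload <- list(
    format = ARCHIVE_FORMAT,
    n_factors = model$n_factors,
    x_weights = model$x_weights,
    x_loadings = model$x_loadings,
    y_loadings = model$y_loadings,
    coefficients = model$coefficients,
    x_center = model$x_center,
    y_center = model$y_center,
    chain = chain)
  # digits = I(17): significant-digit mode, enough for exact double
  # round-trips (decimal-digit and shortest-representation modes are not)
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' Read a PLS model archive
#'
#' @param path file written by [write_pls_model()]
#' @return a `pls_model`
#' @export
read_pls_model <- function(path) {
  if (!file.exists(path)) stop("model archive not found: ", path,
                               call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(raw$format, ARCHIVE_FORMAT)) {
    stop("unsupported model archive format: ", raw$format, call. = FALSE)
  }
  chain <- if (length(raw$chain) == 0) NULL else {
    structure(raw$chain, class = c("fitted_chain", "preprocess_chain"))
  }
  structure(list(n_factors = raw$n_factors,
                 x_weights = as.matrix(raw$x_weights),
                 x_loadings = as.matrix(raw$x_loadings),
                 y_loadings = as.numeric(raw$y_loadings),
                 scores = NULL,
                 coefficients = as.numeric(raw$coefficients),
                 x_center = as.numeric(raw$x_center),
                 y_center = raw$y_center,
                 chain = chain),
            class = "pls_model")
}
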