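#' Construct a spectra set
#'
#' A spectra set couples an `n x p` matrix of log(1/R) pseudo-absorbance
#' values with the shared wavenumber grid (cm^-1) its columns live on and a
#' unique identifier per sample (row). The grid must be strictly monotonic;
#' both ascending and descending instrument export conventions are accepted,
#' and [grid_descending()] reports which one a set uses.
#'
#' @param absorbance numeric matrix, one row per sample, one column per
#'   wavenumber; all values must be finite. A 0-row matrix is allowed (empty
#'   set).
#' @param wavenumbers numeric vector of length `ncol(absorbance)`; strictly
#'   monotonic, finite, positive, length >= 2.
#' @param sample_ids character vector of unique sample labels, one per row.
#'   Defaults to the matrix rownames.
#' @return An object of class `spectra_set`: a list with elements
#'   `sample_ids`, `wavenumbers` and `absorbance`.
#' @examples
#' s <- spectra_set(matrix(runif(6), 2, 3,
#'                         dimnames = list(c("a", "b"), NULL)),
#'                  c(4000, 6000, 8000))
#' n_samples(s)
#' @export
spectra_set <- function(absorbance, wavenumbers,
                        sample_ids = rownames(absorbance)) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  wavenumbers <- as.numeric(wavenumbers)
  if (length(wavenumbers) < 2) {
    stop("wavenumber grid must have at least 2 points", call. = FALSE)
  }
  if (!all(is.finite(wavenumbers)) || any(wavenumbers <= 0)) {
    stop("wavenumbers must all be finite and positive", call. = FALSE)
  }
  d <- diff(wavenumbers)
  if (!(all(d > 0) || all(d < 0))) {
    stop("wavenumber grid must be strictly monotonic", call. = FALSE)
  }
  if (ncol(absorbance) != length(wavenumbers)) {
    stop("absorbance has ", ncol(absorbance), " columns but the grid has ",
         length(wavenumbers), " points", call. = FALSE)
  }
  if (is.null(sample_ids)) sample_ids <- as.character(seq_len(nrow(absorbance)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != nrow(absorbance)) {
    stop("need one sample id per spectrum", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(absorbance) > 0 && !all(is.finite(absorbance))) {
    stop("absorbance values must all be finite", call. = FALSE)
  }
  dimnames(absorbance) <- list(sample_ids, NULL)
  structure(list(sample_ids = sample_ids,
                 wavenumbers = wavenumbers,
                 absorbance = absorbance),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  rng <- range(x$wavenumbers)
  cat(sprintf(
    "<spectra_set> %d samples x %d points, %g-%g cm^-1 (%s)\n",
    n_samples(x), length(x$wavenumbers), rng[1], rng[2],
    if (grid_descending(x)) "descending" else "ascending"))
  invisible(x)
}

#' Number of samples in a spectra set
#' @param x a `spectra_set`
#' @return integer count of spectra
#' @export
n_samples <- function(x) {
  stopifnot(inherits(x, "spectra_set"))
  nrow(x$absorbance)
}

#' Is the wavenumber grid stored in descending order?
#' @param x a `spectra_set`
#' @return `TRUE` if the grid runs high-to-low wavenumber
#' @export
grid_descending <- function(x) {
  stopifnot(inherits(x, "spectra_set"))
  x$wavenumbers[1] > x$wavenumbers[2]
}

#' Read a spectra CSV file
#'
#' Expected dialect: comma separator, `.` decimal mark, UTF-8, mandatory
#' header row `id,<w1>,<w2>,...` with the wavenumber grid, then one row
#' `<sample_id>,<a1>,...` per spectrum. Descending wavenumber headers are
#' accepted and preserved.
#'
#' @param path path to a CSV file
#' @return a [spectra_set()]
#' @seealso [write_spectra_csv()] for the inverse (exact round trip)
#' @export
read_spectra_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  if (ncol(raw) < 3) {
    stop("spectra CSV needs an id column plus >= 2 wavenumber columns",
         call. = FALSE)
  }
  wn <- suppressWarnings(as.numeric(names(raw)[-1]))
  if (anyNA(wn)) {
    stop("header contains non-numeric wavenumbers: ",
         paste(names(raw)[-1][is.na(wn)], collapse = ", "), call. = FALSE)
  }
  d <- diff(wn)
  if (!(all(d > 0) || all(d < 0))) {
    stop("header wavenumbers are not strictly monotonic", call. = FALSE)
  }
  ids <- raw[[1]]
  body <- as.matrix(raw[, -1, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(body), dim = dim(body)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "non-numeric or blank absorbance at data row %d ('%s'), column %d (%s cm^-1)",
      bad[1], ids[bad[1]], bad[2], names(raw)[-1][bad[2]]), call. = FALSE)
  }
  spectra_set(vals, wn, sample_ids = ids)
}

#' Write a spectra set to CSV
#'
#' Values are written with 17 significant digits so that
#' `read_spectra_csv(write_spectra_csv(x, f))` reproduces `x` bit-exactly.
#'
#' @param spectra a [spectra_set()]
#' @param path destination file
#' @return `path`, invisibly
#' @export
write_spectra_csv <- function(spectra, path) {
  stopifnot(inherits(spectra, "spectra_set"))
  con <- tryCatch(file(path, open = "wt", encoding = "UTF-8"),
                  error = function(e) {
                    stop("cannot open '", path, "' for writing: ",
                         conditionMessage(e), call. = FALSE)
                  })
  on.exit(close(con))
  fmt <- function(v) sprintf("%.17g", v)
  writeLines(paste(c("id", fmt(spectra$wavenumbers)), collapse = ","), con)
  if (n_samples(spectra) > 0) {
    rows <- vapply(seq_len(n_samples(spectra)), function(i) {
      paste(c(spectra$sample_ids[i], fmt(spectra$absorbance[i, ])),
            collapse = ",")
    }, character(1))
    writeLines(rows, con)
  }
  invisible(path)
}

#' Construct a reference table
#'
#' Holds the wet-chemistry reference values the calibration regresses on:
#' total flavonoid content (TFC, mg rutin equivalents per g dry weight) and
#' total antioxidant activity (TAA, mM Trolox equivalents per g dry weight),
#' optionally with per-sample assay standard deviations.
#'
#' @param id character vector of unique sample ids
#' @param tfc,taa non-negative numeric vectors, same length as `id`
#' @param tfc_sd,taa_sd optional non-negative dispersion vectors
#' @param label optional original printed label per record
#' @return a `data.frame` with class `reference_table`
#' @export
reference_table <- function(id, tfc, taa, tfc_sd = NULL, taa_sd = NULL,
                            label = NULL) {
  id <- as.character(id)
  tfc <- as.numeric(tfc)
  taa <- as.numeric(taa)
  if (length(tfc) != length(id) || length(taa) != length(id)) {
    stop("id, tfc and taa must have the same length", call. = FALSE)
  }
  if (anyDuplicated(id)) {
    stop("duplicate sample ids in reference table", call. = FALSE)
  }
  if (anyNA(tfc) || anyNA(taa) || any(tfc < 0) || any(taa < 0)) {
    stop("tfc and taa must be non-negative and non-missing", call. = FALSE)
  }
  out <- data.frame(id = id, tfc = tfc, taa = taa, stringsAsFactors = FALSE)
  for (nm in c("tfc_sd", "taa_sd")) {
    v <- get(nm)
    if (!is.null(v)) {
      v <- as.numeric(v)
      if (length(v) != length(id) || anyNA(v) || any(v < 0)) {
        stop(nm, " must be non-negative with one value per record",
             call. = FALSE)
      }
      out[[nm]] <- v
    }
  }
  if (!is.null(label)) out$label <- as.character(label)
  class(out) <- c("reference_table", "data.frame")
  out
}

#' Load a reference-value CSV
#'
#' @param path CSV file with columns `id`, `tfc`, `taa` and optionally
#'   `tfc_sd`, `taa_sd`
#' @return a [reference_table()] in file order
#' @export
load_reference_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("id", "tfc", "taa")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("reference CSV is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  reference_table(raw$id, raw$tfc, raw$taa,
                  tfc_sd = raw[["tfc_sd"]], taa_sd = raw[["taa_sd"]],
                  label = raw[["label"]])
}

#' Write a reference table to CSV
#'
#' @param reference a [reference_table()]
#' @param path destination file
#' @return `path`, invisibly
#' @export
write_reference_csv <- function(reference, path) {
  stopifnot(inherits(reference, "reference_table"))
  df <- as.data.frame(reference)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' The packaged 113-sample reference table
#'
#' Returns the printed reference measurements for the 113 Ginkgo biloba leaf
#' batches the calibration study is built on: TFC (mg rutin eq / g DW) and
#' TAA (mM Trolox eq / g DW), each with its reported standard deviation.
#' Records are keyed by POSITION 1..113 in printed order; the table as
#' printed carries a duplicated label "16" (position 18), so the original
#' label is kept in the `label` column while `id` is the position.
#'
#' @return a [reference_table()] with 113 records and columns `id`, `tfc`,
#'   `tfc_sd`, `taa`, `taa_sd`, `label`
#' @examples
#' ref <- load_table1_fixture()
#' range(ref$tfc)  # 1.47 .. 49.20
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "ginkgo_table1.csv", package = "nirflav",
                      mustWork = TRUE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  reference_table(raw$position, raw$tfc, raw$taa,
                  tfc_sd = raw$tfc_sd, taa_sd = raw$taa_sd,
                  label = raw$label)
}
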