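# Shared fixtures, built in code.

# A reduced-scale synthetic configuration for fast tests.
small_config <- function(seed = 1, n = 40, p = 120, ...) {
  synthetic_config(n_samples = n, grid = seq(4000, 8000, length.out = p),
                   seed = seed, ...)
}

# Noise-free, scatter-free configuration with `k` independently varying
# constituents and no baseline: spectra are an exact linear mixture.
noiseless_config <- function(seed = 1, n = 30, p = 80, k = 2) {
  bands <- list(
    rbind(c(4500, 150, 0.01), c(6800, 200, 0.006)),
    rbind(c(5400, 180, 0.012), c(7400, 250, 0.005)),
    rbind(c(6100, 160, 0.009), c(4800, 300, 0.004)))
  constituents <- lapply(seq_len(k), function(i) {
    constituent_band_model(paste0("c", i), bands[[i]], c(1, 50))
  })
  names(constituents) <- paste0("c", seq_len(k))
  synthetic_config(
    n_samples = n, grid = seq(4000, 8000, length.out = p),
    constituents = constituents, tfc_constituent = "c1",
    baseline_order = 0, baseline_offset = 0, baseline_coef_sd = 0,
    scatter_slope_sd = 0, scatter_offset_sd = 0, noise_sd = 0,
    taa_link = list(slope = 0.08, intercept = 0.6, noise_sd = 0),
    seed = seed)
}

# Write a spectra CSV from raw text lines (for parser edge cases).
write_csv_lines <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

# Independent naive Kennard-Stone: explicit loops, no shared code with the
# implementation beyond base R.
ks_naive <- function(x, n_cal) {
  n <- nrow(x)
  d <- function(i, j) sqrt(sum((x[i, ] - x[j, ])^2))
  best <- c(1, 2); bestd <- -1
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (d(i, j) > bestd) { bestd <- d(i, j); best <- c(i, j) }
  }
  sel <- best
  while (length(sel) < n_cal) {
    cand <- setdiff(seq_len(n), sel)
    mind <- sapply(cand, function(i) min(sapply(sel, function(j) d(i, j))))
    sel <- c(sel, cand[which.max(mind)])
  }
  sort(sel)
}
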