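test_that("spectra CSV parsing handles both grid directions and errors", {
  f <- write_csv_lines(c("id,4000,6000,8000", "a,0.1,0.2,0.3",
                         "b,0.4,0.5,0.6"))
  s <- read_spectra_csv(f)
  expect_equal(n_samples(s), 2)
  expect_equal(s$wavenumbers, c(4000, 6000, 8000))
  expect_equal(s$absorbance[2, ], c(0.4, 0.5, 0.6), ignore_attr = TRUE)
  expect_false(grid_descending(s))

  fd <- write_csv_lines(c("id,8000,6000,4000", "a,0.1,0.2,0.3"))
  sd_ <- read_spectra_csv(fd)
  expect_true(grid_descending(sd_))
  expect_equal(sd_$wavenumbers, c(8000, 6000, 4000))

  fblank <- write_csv_lines(c("id,4000,6000,8000", "a,0.1,,0.3"))
  expect_error(read_spectra_csv(fblank), "row 1.*column 2")
  fbad <- write_csv_lines(c("id,4000,6000,8000", "a,0.1,x,0.3"))
  expect_error(read_spectra_csv(fbad), "non-numeric")
  fmono <- write_csv_lines(c("id,4000,8000,6000", "a,0.1,0.2,0.3"))
  expect_error(read_spectra_csv(fmono), "monotonic")
  fdup <- write_csv_lines(c("id,4000,6000,8000", "a,1,2,3", "a,4,5,6"))
  expect_error(read_spectra_csv(fdup), "duplicate")
})

test_that("spectra CSV write/read round-trips bit-exactly", {
  set.seed(3)
  s <- spectra_set(matrix(rnorm(5 * 7), 5), seq(4001.3, 7999.7,
                                                length.out = 7),
                   sample_ids = paste0("s", 1:5))
  f <- tempfile(fileext = ".csv")
  write_spectra_csv(s, f)
  back <- read_spectra_csv(f)
  expect_identical(back$absorbance, s$absorbance)
  expect_identical(back$wavenumbers, s$wavenumbers)
  expect_identical(back$sample_ids, s$sample_ids)

  empty <- spectra_set(matrix(numeric(0), 0, 3), c(4000, 5000, 6000),
                       sample_ids = character(0))
  f2 <- tempfile(fileext = ".csv")
  write_spectra_csv(empty, f2)
  expect_equal(n_samples(read_spectra_csv(f2)), 0)
})

test_that("a simulated full-size set survives the CSV round trip", {
  ds <- generate_dataset(small_config(seed = 9, n = 25, p = 300))
  f <- tempfile(fileext = ".csv")
  write_spectra_csv(ds$spectra, f)
  back <- read_spectra_csv(f)
  expect_identical(back$absorbance, ds$spectra$absorbance)
  expect_identical(back$wavenumbers, ds$spectra$wavenumbers)

  fr <- tempfile(fileext = ".csv")
  write_reference_csv(ds$reference, fr)
  refback <- load_reference_table(fr)
  expect_identical(refback$tfc, ds$reference$tfc)
  expect_identical(refback$taa, ds$reference$taa)
})

test_that("reference table loading validates its schema", {
  f <- write_csv_lines(c("id,tfc,taa", "a,1.2,0.5", "b,3,1", "c,0,0"))
  ref <- load_reference_table(f)
  expect_s3_class(ref, "reference_table")
  expect_equal(nrow(ref), 3)

  fneg <- write_csv_lines(c("id,tfc,taa", "a,-1,0.5"))
  expect_error(load_reference_table(fneg), "non-negative")
  fmiss <- write_csv_lines(c("id,tfc", "a,1"))
  expect_error(load_reference_table(fmiss), "missing column")
})

test_that("the packaged reference table matches its printed source", {
  ref <- load_table1_fixture()
  expect_equal(nrow(ref), 113)
  expect_equal(ref$tfc[1], 2.10)
  expect_equal(ref$taa[1], 0.47)
  expect_equal(ref$tfc[110], 1.47)
  expect_equal(ref$taa[110], 0.24)
  expect_true(all(ref$tfc >= 1.47 & ref$tfc <= 49.20))
  expect_true(all(ref$taa >= 0.24 & ref$taa <= 4.65))
  # the printed table repeats label "16"; positions stay unique
  expect_equal(sum(ref$label == "16"), 2)
  expect_equal(ref$label[18], "16")
  expect_equal(ref$tfc[18], 48.82)
  expect_false(anyDuplicated(ref$id) > 0)
})
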