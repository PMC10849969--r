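make_fixture_spectra <- function(seed = 3, n = 3) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    k <- sample(6:12, 1)
    ms_spectrum(
      spectrum_id = paste0("fix", i),
      precursor_mz = round(runif(1, 200, 800), 6),
      precursor_intensity = round(runif(1, 1e3, 1e6), 3),
      charge = sample(c(1L, -1L), 1),
      mz = round(sort(runif(k, 50, 800)), 6),
      intensity = round(runif(k, 1, 1e4), 4),
      scan_number = i, source_file = "fix.mzML")
  })
}

test_that("MGF write/read round-trips all generator-produced fields", {
  sp <- make_fixture_spectra()
  path <- tempfile(fileext = ".mgf")
  write_mgf(sp, path)
  back <- read_mgf(path)
  expect_length(back, 3L)
  for (i in seq_along(sp)) {
    expect_identical(back[[i]]$spectrum_id, sp[[i]]$spectrum_id)
    expect_equal(back[[i]]$precursor_mz, sp[[i]]$precursor_mz,
                 tolerance = 1e-9)
    expect_equal(back[[i]]$precursor_intensity, sp[[i]]$precursor_intensity,
                 tolerance = 1e-6)
    expect_identical(back[[i]]$charge, sp[[i]]$charge)
    expect_identical(back[[i]]$scan_number, sp[[i]]$scan_number)
    expect_identical(back[[i]]$source_file, sp[[i]]$source_file)
    expect_equal(back[[i]]$mz, sp[[i]]$mz, tolerance = 1e-9)
    expect_equal(back[[i]]$intensity, sp[[i]]$intensity, tolerance = 1e-6)
  }
})

test_that("malformed MGF blocks error with a line position", {
  path <- tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=x", "100.0 1.0", "END IONS"), path)
  expect_error(read_mgf(path), "PEPMASS")
  writeLines(c("BEGIN IONS", "TITLE=x", "PEPMASS=100.0", "100.0 1.0"), path)
  expect_error(read_mgf(path), "without END IONS")
  writeLines(c("END IONS"), path)
  expect_error(read_mgf(path), "without BEGIN")
})

test_that("unsorted MGF peaks are re-sorted and flagged", {
  path <- tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=x", "PEPMASS=300.0",
               "200.0 2.0", "100.0 1.0", "150.0 3.0", "END IONS"), path)
  s <- read_mgf(path)[[1]]
  expect_true(s$resorted)
  expect_identical(s$mz, sort(c(200.0, 100.0, 150.0)))
  expect_identical(s$intensity, c(1.0, 3.0, 2.0))
})

test_that("minimal mzML round-trips, zlib twin equals uncompressed", {
  sp <- make_fixture_spectra(seed = 4)
  ms1 <- ms_spectrum("survey", NA, mz = sort(runif(5, 100, 900)),
                     intensity = runif(5), ms_level = 1L, scan_number = 99L)
  all_sp <- c(sp, list(ms1))
  f_none <- tempfile(fileext = ".mzML")
  f_zlib <- tempfile(fileext = ".mzML")
  write_mzml_minimal(all_sp, f_none, compression = "none")
  write_mzml_minimal(all_sp, f_zlib, compression = "zlib")
  a <- read_mzml_minimal(f_none)
  b <- read_mzml_minimal(f_zlib)
  expect_length(a, 4L)
  for (i in seq_along(a)) {
    expect_equal(a[[i]]$mz, b[[i]]$mz, tolerance = 0)
    expect_equal(a[[i]]$intensity, b[[i]]$intensity, tolerance = 0)
    expect_equal(a[[i]]$mz, all_sp[[i]]$mz, tolerance = 1e-12)
  }
  ms2 <- Filter(function(s) s$ms_level == 2L, a)
  expect_length(ms2, 3L)
  expect_equal(ms2[[1]]$precursor_mz, sp[[1]]$precursor_mz,
               tolerance = 1e-9)
  expect_identical(a[[4]]$ms_level, 1L)
  expect_true(is.na(a[[4]]$precursor_mz))
})

test_that("an MS1-only mzML gives an empty MS2 list, not an error", {
  ms1 <- ms_spectrum("survey", NA, mz = c(100, 200), intensity = c(1, 2),
                     ms_level = 1L, scan_number = 1L)
  f <- tempfile(fileext = ".mzML")
  write_mzml_minimal(list(ms1), f)
  got <- read_mzml_minimal(f)
  expect_length(Filter(function(s) s$ms_level == 2L, got), 0L)
  expect_length(Filter(function(s) s$ms_level == 1L, got), 1L)
})

test_that("unsupported mzML encodings raise an explicit dialect error", {
  sp <- make_fixture_spectra(seed = 5, n = 1)
  f <- tempfile(fileext = ".mzML")
  write_mzml_minimal(sp, f)
  txt <- readLines(f)
  # swap the 64-bit float accession for 32-bit integer
  bad <- gsub("MS:1000523", "MS:1000519", txt, fixed = TRUE)
  writeLines(bad, f)
  expect_error(read_mzml_minimal(f), "unsupported mzML dialect")
  # swap zlib/none for an unknown compression accession
  write_mzml_minimal(sp, f, compression = "zlib")
  txt <- readLines(f)
  bad <- gsub("MS:1000574", "MS:1002312", txt, fixed = TRUE)
  writeLines(bad, f)
  expect_error(read_mzml_minimal(f), "unsupported mzML dialect")
})

test_that("the mzML writer is readable by an independent parser", {
  skip_if_not_installed("mzR")
  sp <- make_fixture_spectra(seed = 6, n = 2)
  f <- tempfile(fileext = ".mzML")
  write_mzml_minimal(sp, f, compression = "zlib")
  ms <- mzR::openMSfile(f)
  on.exit(mzR::close(ms))
  pk <- mzR::peaks(ms, 1)
  hd <- mzR::header(ms)
  expect_equal(pk[, 1], sp[[1]]$mz, tolerance = 1e-12)
  expect_equal(pk[, 2], sp[[1]]$intensity, tolerance = 1e-12)
  expect_equal(hd$precursorMZ[1], sp[[1]]$precursor_mz, tolerance = 1e-6)
})

test_that("normalization modes hit their targets and are idempotent", {
  s <- ms_spectrum("n", 300, mz = c(100, 200), intensity = c(4, 1))
  expect_equal(normalize_spectrum(s, "base_peak")$intensity, c(1, 0.25))
  s2 <- ms_spectrum("n", 300, mz = c(100, 200), intensity = c(3, 4))
  expect_equal(normalize_spectrum(s2, "l2")$intensity, c(0.6, 0.8))
  s3 <- ms_spectrum("n", 300, mz = c(100, 200), intensity = c(4, 4))
  expect_equal(normalize_spectrum(s3, "sqrt_l2")$intensity,
               c(0.7071, 0.7071), tolerance = 1e-4)
  set.seed(8)
  for (mode in c("base_peak", "l2", "sqrt_l2")) {
    r <- random_spectrum(n = 7)
    once <- normalize_spectrum(r, mode)
    twice <- normalize_spectrum(once, mode)
    expect_equal(twice$intensity, once$intensity, tolerance = 1e-12,
                 info = mode)
  }
  z <- ms_spectrum("z", 300, mz = c(100), intensity = c(0))
  expect_error(normalize_spectrum(z), "all-zero")
})
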