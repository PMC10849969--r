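test_that("theoretical spectra contain the expected fragment ladder", {
  ca <- list(name = "CA", block_class = "bile_acid", formula = "C24H40O5")
  gly <- list(name = "Gly", block_class = "amino_acid",
              formula = "C2H5NO2")
  rec <- condense(ca, gly, "bile_amidate")
  rec$hydroxyls <- 3
  sp <- theoretical_spectrum(rec)
  want <- c(466.3163, 448.3058, 430.2952, 412.2846, 76.0393)
  for (w in want) {
    expect_true(any(abs(sp$mz - w) < 5e-4), info = sprintf("%.4f", w))
  }
  expect_gte(n_peaks(sp), 6L)
  # determinism
  sp2 <- theoretical_spectrum(rec)
  expect_identical(sp$mz, sp2$mz)
  expect_identical(sp$intensity, sp2$intensity)
})

test_that("templates reject empty rule sets and non-positive fragments", {
  tmpl <- fragmentation_template("amide")
  tmpl$rules <- tmpl$rules[0, ]
  rec <- list(compound_id = "x", rule = "amide", monoisotopic_mass = 300,
              left_mass = 250, right_mass = 68)
  expect_error(theoretical_spectrum(rec, tmpl), "no rules")
  # a tiny left block drives acylium-CO below zero
  rec2 <- list(compound_id = "y", rule = "amide", monoisotopic_mass = 80,
               left_mass = 44, right_mass = 54)
  expect_error(theoretical_spectrum(rec2), "non-positive")
})

test_that("zero noise is the identity and seeds reproduce", {
  set.seed(1)
  s <- random_spectrum(n = 8)
  zero <- list(mz_jitter_sd = 0, intensity_cv = 0, peak_dropout_prob = 0)
  expect_identical(perturb_spectrum(s, zero)$mz, s$mz)
  expect_identical(perturb_spectrum(s, zero)$intensity, s$intensity)

  noisy <- list(mz_jitter_sd = 0.005, intensity_cv = 0.3,
                peak_dropout_prob = 0.2)
  set.seed(42); a <- perturb_spectrum(s, noisy)
  set.seed(42); b <- perturb_spectrum(s, noisy)
  expect_identical(a$mz, b$mz)
  expect_identical(a$intensity, b$intensity)
})

test_that("m/z jitter has the half-normal mean |error|", {
  set.seed(123)
  sd <- 0.005
  n <- 10000
  s <- ms_spectrum("big", 1500, mz = seq(100, 1099.9, length.out = n),
                   intensity = rep(1, n))
  noise <- list(mz_jitter_sd = sd, intensity_cv = 0, peak_dropout_prob = 0)
  p <- perturb_spectrum(s, noise)
  # jitter then re-sort: displacement vs original grid, spacing >> sd
  err <- abs(p$mz - s$mz)
  want <- sd * sqrt(2 / pi)
  se <- sd * sqrt(1 - 2 / pi) / sqrt(n)
  expect_lt(abs(mean(err) - want), 3 * se)
})

test_that("dropout never leaves fewer than the peak floor", {
  set.seed(31)
  s <- random_spectrum(n = 8)
  noise <- list(mz_jitter_sd = 0, intensity_cv = 0, peak_dropout_prob = 0.95)
  for (i in 1:20) {
    expect_gte(n_peaks(perturb_spectrum(s, noise, min_peaks = 6L)), 6L)
  }
})

test_that("simulator output is reproducible and ledger-complete", {
  lib <- small_bile_library(4)
  occ <- matrix(0.4, 4, 2, dimnames = list(lib$compound_id,
                                           c("CD", "nonIBD")))
  cfg <- sim_config(seed = 19, n_files_per_group = 6, occurrence = occ)
  sim1 <- simulate_repository(lib, cfg)
  sim2 <- simulate_repository(lib, cfg)
  expect_identical(
    lapply(sim1$corpus, function(s) s$mz),
    lapply(sim2$corpus, function(s) s$mz))
  # ledger conservation: every MS2 spectrum is planted or decoy
  expect_equal(length(sim1$corpus),
               nrow(sim1$ground_truth$planted) +
                 nrow(sim1$ground_truth$decoys))
  expect_setequal(
    vapply(sim1$corpus, function(s) s$spectrum_id, character(1)),
    c(sim1$ground_truth$planted$spectrum_id,
      sim1$ground_truth$decoys$spectrum_id))
  expect_identical(sim1$ground_truth$seed, 19L)
  # metadata carries group labels and file counts
  expect_equal(nrow(sim1$metadata), 12L)
  expect_equal(sum(sim1$metadata$phenotype == "CD"), 6L)
})

test_that("zero occurrence and zero decoys give an empty corpus", {
  lib <- small_bile_library(3)
  occ <- matrix(0, 3, 2, dimnames = list(lib$compound_id,
                                         c("CD", "nonIBD")))
  cfg <- sim_config(seed = 23, n_files_per_group = 4, occurrence = occ,
                    n_decoys = 0)
  sim <- simulate_repository(lib, cfg)
  expect_length(sim$corpus, 0L)
  expect_equal(nrow(sim$metadata), 8L)
})

test_that("per-file spectra do not depend on how many files precede them", {
  lib <- small_bile_library(3)
  occ <- matrix(0.8, 3, 2, dimnames = list(lib$compound_id,
                                           c("CD", "nonIBD")))
  cfg_a <- sim_config(seed = 29, n_files_per_group = 3, occurrence = occ)
  cfg_b <- sim_config(seed = 29, n_files_per_group = 1, occurrence = occ)
  sim_a <- simulate_repository(lib, cfg_a)
  sim_b <- simulate_repository(lib, cfg_b)
  first_file <- sim_a$metadata$source_file[1]
  a1 <- Filter(function(s) s$source_file == first_file, sim_a$corpus)
  b1 <- Filter(function(s) s$source_file == first_file, sim_b$corpus)
  expect_identical(lapply(a1, function(s) s$mz),
                   lapply(b1, function(s) s$mz))
})

test_that("MGF corpus export round-trips through the reader", {
  lib <- small_bile_library(3)
  occ <- matrix(0.9, 3, 2, dimnames = list(lib$compound_id,
                                           c("CD", "nonIBD")))
  cfg <- sim_config(seed = 37, n_files_per_group = 2, occurrence = occ)
  out <- file.path(tempdir(), "sim_corpus")
  unlink(out, recursive = TRUE)
  sim <- simulate_repository(lib, cfg, out_dir = out)
  mgfs <- list.files(out, pattern = "\\.mgf$", full.names = TRUE)
  expect_gt(length(mgfs), 0L)
  back <- unlist(lapply(mgfs, read_mgf), recursive = FALSE)
  expect_equal(length(back), length(sim$corpus))
  expect_true(file.exists(file.path(out, "metadata.tsv")))
  meta <- read_sample_metadata(file.path(out, "metadata.tsv"))
  expect_setequal(meta$source_file, sim$metadata$source_file)
})

test_that("abundance tables honor presence, shift and the null", {
  meta <- as_sample_metadata(data.frame(
    source_file = paste0("s", 1:100),
    phenotype = rep(c("CD", "nonIBD"), each = 50),
    stringsAsFactors = FALSE))
  presence <- matrix(TRUE, 3, 100,
                     dimnames = list(c("c1", "c2", "c3"),
                                     meta$source_file))
  presence["c3", ] <- FALSE
  set.seed(51)
  ab <- simulate_abundance_table(presence, meta, enriched = "c1",
                                 shift_group = "CD", shift = 2)
  expect_true(all(ab["c3", ] == 0))
  expect_true(all(ab[c("c1", "c2"), ] > 0))
  grp <- stats::setNames(meta$phenotype, meta$source_file)
  res <- pairwise_wilcoxon_bh(ab, grp, pairs = list(c("CD", "nonIBD")))
  expect_lt(res$p_value[res$compound_id == "c1"], 1e-6)
  expect_gt(res$p_value[res$compound_id == "c2"], 0.001)
})

test_that("decoys pass the precursor filter but rarely match", {
  lib <- small_bile_library(4)
  occ <- matrix(0.5, 4, 2, dimnames = list(lib$compound_id,
                                           c("CD", "nonIBD")))
  false_rates <- vapply(1:10, function(seed) {
    cfg <- sim_config(seed = seed, n_files_per_group = 5, occurrence = occ,
                      n_decoys = 4)
    sim <- simulate_repository(lib, cfg)
    res <- repository_search(library_reference_spectra(lib), sim$corpus,
                             match_criteria("qtof"))
    decoy_ids <- sim$ground_truth$decoys$spectrum_id
    n_decoy_matches <- sum(res$corpus_spectrum_id %in% decoy_ids)
    n_decoy_matches / max(length(decoy_ids), 1)
  }, numeric(1))
  expect_lt(mean(false_rates), 0.01)
})
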