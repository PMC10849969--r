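test_that("peak pairing handles identity, disjoint and conflict cases", {
  s6 <- ms_spectrum("q", 400, mz = c(100, 150, 200, 250, 300, 350),
                    intensity = c(5, 10, 20, 10, 5, 1))
  expect_equal(nrow(pair_peaks(s6, s6, 0.02)), 6L)

  t_disj <- ms_spectrum("t", 400, mz = c(110, 160, 210),
                        intensity = c(1, 1, 1))
  expect_equal(nrow(pair_peaks(s6, t_disj, 0.02)), 0L)

  # two query peaks compete for one target peak: greedy must equal the
  # exhaustive maximum-weight assignment on this instance
  q <- ms_spectrum("q", 400, mz = c(100.000, 100.010),
                   intensity = c(10, 50))
  t <- ms_spectrum("t", 400, mz = c(100.005), intensity = c(7))
  p <- pair_peaks(q, t, 0.02)
  expect_equal(nrow(p), 1L)
  expect_equal(p$query_idx, 2L)  # higher intensity product wins
  expect_equal(greedy_pair_weight(q, t, 0.02),
               oracle_assignment_weight(q, t, 0.02))
})

test_that("greedy pairing equals the exhaustive assignment on random instances", {
  set.seed(101)
  for (i in 1:120) {
    q <- random_spectrum("q")
    t <- random_spectrum("t")
    expect_equal(greedy_pair_weight(q, t, 0.02),
                 oracle_assignment_weight(q, t, 0.02), tolerance = 1e-9)
  }
})

test_that("cosine score matches hand-computed values", {
  s <- ms_spectrum("s", 400, mz = c(100, 150, 200, 250, 300, 350),
                   intensity = c(5, 10, 20, 10, 5, 1))
  self <- cosine_score(s, s, 0.02)
  expect_equal(self$cosine, 1.0, tolerance = 1e-12)
  expect_equal(self$n_matched_ions, 6L)

  q <- ms_spectrum("q", 400, mz = c(100.0, 200.0), intensity = c(1, 1))
  t <- ms_spectrum("t", 400, mz = c(100.0, 300.0), intensity = c(1, 1))
  got <- cosine_score(q, t, 0.02)
  expect_equal(got$cosine, 0.5, tolerance = 1e-12)
  expect_equal(got$n_matched_ions, 1L)

  t1000 <- ms_spectrum("t2", 400, mz = t$mz, intensity = t$intensity * 1000)
  expect_equal(cosine_score(q, t1000, 0.02)$cosine, 0.5, tolerance = 1e-12)
  expect_error(cosine_score(q, ms_spectrum("e", 400), 0.02), "non-empty")
})

test_that("cosine is symmetric and bounded on random pairs", {
  set.seed(202)
  for (i in 1:60) {
    a <- random_spectrum("a")
    b <- random_spectrum("b")
    ab <- cosine_score(a, b, 0.02)
    ba <- cosine_score(b, a, 0.02)
    expect_equal(ab$cosine, ba$cosine, tolerance = 1e-9)
    expect_identical(ab$n_matched_ions, ba$n_matched_ions)
    expect_gte(ab$cosine, 0); expect_lte(ab$cosine, 1)
  }
})

test_that("repository search counts matches and unique files", {
  q <- ms_spectrum("query", 466.3163,
                   mz = c(76.04, 391.28, 412.28, 430.30, 448.31, 466.32),
                   intensity = c(7, 3, 4, 6, 8, 10))
  copies <- lapply(1:5, function(i) {
    s <- q
    s$spectrum_id <- paste0("copy", i)
    s$source_file <- paste0("file", ((i - 1) %% 3) + 1)
    s
  })
  res <- repository_search(q, copies, match_criteria("qtof"))
  expect_equal(nrow(res), 5L)
  expect_equal(length(unique(res$source_file)), 3L)
  expect_equal(attr(res, "file_counts")[["query"]], 3L)
  # empty corpus is an empty result, not an error
  res0 <- repository_search(q, list(), match_criteria("qtof"))
  expect_equal(nrow(res0), 0L)
})

test_that("a 5-peak identical spectrum fails only the 6-ion rule", {
  q5 <- ms_spectrum("q5", 500.25, mz = c(110, 160, 210, 260, 310),
                    intensity = c(2, 4, 8, 4, 2))
  t5 <- q5; t5$spectrum_id <- "t5"; t5$source_file <- "f"
  sc <- cosine_score(q5, t5, 0.02)
  expect_equal(sc$cosine, 1.0, tolerance = 1e-12)
  expect_equal(sc$n_matched_ions, 5L)
  res <- repository_search(q5, list(t5), match_criteria("qtof"))
  expect_equal(nrow(res), 0L)
  res_relaxed <- repository_search(q5, list(t5),
                                   match_criteria("qtof",
                                                  min_matched_ions = 5L))
  expect_equal(nrow(res_relaxed), 1L)
})

test_that("every emitted match satisfies the criteria invariants", {
  lib <- small_bile_library(6)
  occ <- matrix(0.6, 6, 2, dimnames = list(lib$compound_id,
                                           c("CD", "nonIBD")))
  cfg <- sim_config(seed = 31, n_files_per_group = 8, occurrence = occ)
  sim <- simulate_repository(lib, cfg)
  crit <- match_criteria("qtof")
  res <- repository_search(library_reference_spectra(lib), sim$corpus, crit)
  expect_gt(nrow(res), 0L)
  expect_true(all(res$cosine >= crit$min_cosine))
  expect_true(all(res$n_matched_ions >= crit$min_matched_ions))
  expect_true(all(abs(res$precursor_delta) <= crit$precursor_tol))
})

test_that("feature matching applies the drift window and factorial toggles", {
  crit <- feature_match_criteria(ppm_tol = 10, rt_tol = 0.1,
                                 ims_resolving_power = 40, min_idotp = 0.8)
  ref <- list(mz = 466.31632, rt = 5.0, drift_time = 30,
              formula = "C26H43NO6")
  # drift half-window = 30 / (2*40) = 0.375 ms; inclusive boundary
  base <- list(mz = 466.31632, rt = 5.0, drift_time = 30.0, intensity = 1)
  expect_true(feature_library_match(base, ref, crit)$match)
  for (dt in c(30.30, 30.37, 30.375)) {
    f <- base; f$drift_time <- dt
    expect_true(feature_library_match(f, ref, crit)$match)
  }
  f <- base; f$drift_time <- 30.3751
  expect_false(feature_library_match(f, ref, crit)$match)

  # near-threshold pass on all four sub-tests
  env <- isotope_envelope("C26H43NO6", 3)
  obs_env <- env$abundance * c(1, 1.05, 0.9)  # idotp just under 1
  ok <- list(mz = 466.31632 * (1 + 9.9e-6), rt = 5.09, drift_time = 30.3,
             observed_envelope = obs_env, intensity = 1)
  res <- feature_library_match(ok, ref, crit)
  expect_true(res$match)
  expect_gt(res$diagnostics$value[res$diagnostics$test == "idotp"], 0.8)

  # flipping any single criterion past threshold flips the decision
  toggles <- list(
    function(f) { f$mz <- 466.31632 * (1 + 11e-6); f },
    function(f) { f$rt <- 5.11; f },
    function(f) { f$drift_time <- 30.38; f },
    function(f) { f$observed_envelope <- c(0.1, 1, 1); f }
  )
  for (tg in toggles) {
    expect_false(feature_library_match(tg(ok), ref, crit)$match)
  }
})

test_that("missing drift time is skipped and flagged, not failed", {
  ref <- list(mz = 466.31632, rt = 5.0, drift_time = 30)
  f <- list(mz = 466.31632, rt = 5.0, intensity = 1)
  res <- feature_library_match(f, ref)
  expect_true(res$match)
  drow <- res$diagnostics[res$diagnostics$test == "drift", ]
  expect_true(drow$skipped)
  expect_true(drow$passed)
})
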