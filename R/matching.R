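#' Repository-style match criteria
#'
#' The stringency used for repository searches: precursor tolerance 0.01
#' m/z for Orbitrap data and 0.02 m/z for Q-ToF data, a minimum of 6
#' matched fragment ions, and a cosine score of at least 0.7.
#'
#' @param instrument `"orbitrap"` or `"qtof"` (sets the default precursor
#'   tolerance), ignored when `precursor_tol` is given.
#' @param precursor_tol Precursor tolerance in m/z units (Da).
#' @param fragment_tol Fragment pairing tolerance in Da; defaults to the
#'   precursor tolerance (the instrument-class value).
#' @param min_matched_ions Minimum matched fragment ions (default 6).
#' @param min_cosine Minimum cosine score (default 0.7).
#' @return A `match_criteria` list.
#' @export
match_criteria <- function(instrument = c("qtof", "orbitrap"),
                           precursor_tol = NULL, fragment_tol = NULL,
                           min_matched_ions = 6L, min_cosine = 0.7) {
  instrument <- match.arg(instrument)
  if (is.null(precursor_tol)) {
    precursor_tol <- if (instrument == "orbitrap") 0.01 else 0.02
  }
  if (is.null(fragment_tol)) fragment_tol <- precursor_tol
  stopifnot(precursor_tol > 0, fragment_tol > 0, min_matched_ions >= 1,
            min_cosine >= 0, min_cosine <= 1)
  structure(list(instrument = instrument, precursor_tol = precursor_tol,
                 fragment_tol = fragment_tol,
                 min_matched_ions = as.integer(min_matched_ions),
                 min_cosine = min_cosine),
            class = "match_criteria")
}

#' Tolerance-based one-to-one peak pairing
#'
#' Pairs peaks of two centroided spectra with `|delta mz| <= fragment_tol`,
#' greedily by descending intensity product so that each peak is used at
#' most once.  Ties on intensity product are broken by lower query m/z,
#' then by smaller absolute m/z difference, making the result
#' deterministic.  Greedy pairing approximates (and on non-adversarial
#' instances equals) the maximum-weight one-to-one assignment at
#' repository-scale cost.
#'
#' @param query,target [ms_spectrum()] objects.
#' @param fragment_tol Pairing tolerance in Da.
#' @return Data.frame with columns `query_idx`, `target_idx` (peak
#'   indices), zero rows when nothing pairs.
#' @export
pair_peaks <- function(query, target, fragment_tol) {
  stopifnot(fragment_tol > 0)
  nq <- n_peaks(query); nt <- n_peaks(target)
  empty <- data.frame(query_idx = integer(0), target_idx = integer(0))
  if (nq == 0L || nt == 0L) return(empty)
  # candidate pairs within tolerance (both peak lists sorted ascending)
  qi <- ti <- integer(0)
  lo <- 1L
  for (i in seq_len(nq)) {
    while (lo <= nt && target$mz[lo] < query$mz[i] - fragment_tol) {
      lo <- lo + 1L
    }
    j <- lo
    while (j <= nt && target$mz[j] <= query$mz[i] + fragment_tol) {
      qi <- c(qi, i); ti <- c(ti, j)
      j <- j + 1L
    }
  }
  if (length(qi) == 0L) return(empty)
  w <- query$intensity[qi] * target$intensity[ti]
  dmz <- abs(query$mz[qi] - target$mz[ti])
  o <- order(-w, query$mz[qi], dmz)
  used_q <- logical(nq); used_t <- logical(nt)
  keep <- integer(0)
  for (k in o) {
    if (!used_q[qi[k]] && !used_t[ti[k]]) {
      used_q[qi[k]] <- TRUE; used_t[ti[k]] <- TRUE
      keep <- c(keep, k)
    }
  }
  keep <- keep[order(qi[keep])]
  data.frame(query_idx = qi[keep], target_idx = ti[keep])
}

#' Cosine similarity between two MS/MS spectra
#'
#' Intensities are square-root scaled and each spectrum's transformed
#' intensity vector is L2-normalized over all its peaks; the score is the
#' dot product over tolerance-paired peaks.  The score is symmetric,
#' scale-invariant, lies in \[0, 1\], and equals 1 exactly when the
#' spectra are identical up to a global intensity scale.
#'
#' @param query,target [ms_spectrum()] objects with at least one peak each.
#' @param fragment_tol Pairing tolerance in Da.
#' @param scaling `"sqrt"` (default) or `"raw"` intensity scaling.
#' @return List with `cosine` and `n_matched_ions`.
#' @export
cosine_score <- function(query, target, fragment_tol, scaling = c("sqrt", "raw")) {
  scaling <- match.arg(scaling)
  if (n_peaks(query) == 0L || n_peaks(target) == 0L) {
    stop("cosine_score requires non-empty spectra")
  }
  pairs <- pair_peaks(query, target, fragment_tol)
  if (nrow(pairs) == 0L) return(list(cosine = 0, n_matched_ions = 0L))
  tq <- if (scaling == "sqrt") sqrt(query$intensity) else query$intensity
  tt <- if (scaling == "sqrt") sqrt(target$intensity) else target$intensity
  nq <- sqrt(sum(tq^2)); nt <- sqrt(sum(tt^2))
  if (nq == 0 || nt == 0) stop("all-zero intensity vector")
  cosine <- sum(tq[pairs$query_idx] * tt[pairs$target_idx]) / (nq * nt)
  list(cosine = min(cosine, 1), n_matched_ions = nrow(pairs))
}

#' Search query spectra against a spectral corpus
#'
#' Desk-scale re-implementation of repository-wide MS/MS search: for each
#' query, candidate corpus spectra are those whose precursor m/z lies
#' within `precursor_tol`; candidates are scored with [cosine_score()] and
#' a match is emitted when it reaches `min_cosine` with at least
#' `min_matched_ions` paired fragments.
#'
#' @param queries List of MS2 [ms_spectrum()] objects (or a single one).
#' @param corpus List of MS2 [ms_spectrum()] objects carrying
#'   `source_file` provenance.
#' @param criteria A [match_criteria()] object.
#' @return A `spectral_matches` data.frame with columns `query_id`,
#'   `corpus_spectrum_id`, `source_file`, `cosine`, `n_matched_ions`,
#'   `precursor_delta`; the per-query distinct-source-file count is
#'   attached as attribute `file_counts` (named integer, one entry per
#'   query id).
#' @export
repository_search <- function(queries, corpus, criteria = match_criteria()) {
  if (inherits(queries, "ms_spectrum")) queries <- list(queries)
  qids <- vapply(queries, function(s) s$spectrum_id, character(1))
  empty <- data.frame(query_id = character(0),
                      corpus_spectrum_id = character(0),
                      source_file = character(0), cosine = numeric(0),
                      n_matched_ions = integer(0),
                      precursor_delta = numeric(0))
  if (length(corpus) == 0L) {
    attr(empty, "file_counts") <- stats::setNames(integer(length(qids)), qids)
    class(empty) <- c("spectral_matches", "data.frame")
    return(empty)
  }
  cpmz <- vapply(corpus, function(s) s$precursor_mz, numeric(1))
  o <- order(cpmz)
  cpmz_sorted <- cpmz[o]
  rows <- vector("list", length(queries))
  for (iq in seq_along(queries)) {
    q <- queries[[iq]]
    if (q$ms_level != 2L || is.na(q$precursor_mz)) {
      stop("query ", sQuote(q$spectrum_id), " is not an MS2 spectrum ",
           "with a precursor m/z")
    }
    lo <- findInterval(q$precursor_mz - criteria$precursor_tol, cpmz_sorted) + 1L
    hi <- findInterval(q$precursor_mz + criteria$precursor_tol, cpmz_sorted)
    if (hi < lo) next
    hits <- list()
    for (j in o[lo:hi]) {
      t <- corpus[[j]]
      if (n_peaks(t) == 0L || n_peaks(q) == 0L) next
      sc <- cosine_score(q, t, criteria$fragment_tol)
      if (sc$cosine >= criteria$min_cosine &&
          sc$n_matched_ions >= criteria$min_matched_ions) {
        hits[[length(hits) + 1L]] <- data.frame(
          query_id = q$spectrum_id,
          corpus_spectrum_id = t$spectrum_id,
          source_file = t$source_file,
          cosine = sc$cosine,
          n_matched_ions = sc$n_matched_ions,
          precursor_delta = t$precursor_mz - q$precursor_mz,
          stringsAsFactors = FALSE)
      }
    }
    if (length(hits)) rows[[iq]] <- do.call(rbind, hits)
  }
  out <- do.call(rbind, c(list(empty), rows[!vapply(rows, is.null, logical(1))]))
  rownames(out) <- NULL
  fc <- vapply(qids, function(id) {
    length(unique(out$source_file[out$query_id == id]))
  }, integer(1))
  attr(out, "file_counts") <- fc
  class(out) <- c("spectral_matches", "data.frame")
  out
}

#' Feature-vs-library match criteria for LC-IMS data
#'
#' Skyline-style multi-attribute acceptance: mass accuracy within 10 ppm,
#' isotope dot product above 0.8, retention time within 0.1 min, and
#' drift time within the window implied by an IMS resolving power of 40.
#'
#' @param ppm_tol Mass tolerance in ppm.
#' @param rt_tol Retention-time tolerance in minutes.
#' @param ims_resolving_power Dimensionless IMS resolving power Rp; the
#'   drift acceptance half-window is `reference_drift / (2 * Rp)` (FWHM
#'   interpretation: full window = drift/Rp).
#' @param min_idotp Minimum isotope dot product; the test is strict
#'   (`idotp > min_idotp`).
#' @return A `feature_match_criteria` list.
#' @export
feature_match_criteria <- function(ppm_tol = 10, rt_tol = 0.1,
                                   ims_resolving_power = 40,
                                   min_idotp = 0.8) {
  stopifnot(ppm_tol > 0, rt_tol > 0, ims_resolving_power > 0,
            min_idotp > 0, min_idotp <= 1)
  structure(list(ppm_tol = ppm_tol, rt_tol = rt_tol,
                 ims_resolving_power = ims_resolving_power,
                 min_idotp = min_idotp),
            class = "feature_match_criteria")
}

#' Match an observed LC-IMS feature against a library record
#'
#' All available sub-tests must pass: ppm error, retention time, drift
#' time, and isotope dot product.  A missing drift time or missing
#' observed envelope causes that sub-test to be skipped and flagged in the
#' diagnostics, not failed.
#'
#' @param feature List/row with `mz`, `rt` (min), optional `drift_time`
#'   (ms), optional `observed_envelope` (an [isotope_envelope()] or
#'   abundance vector), `intensity`.
#' @param reference List/row with theoretical `mz` (adduct-specific),
#'   `rt`, optional `drift_time`, optional `formula` (Hill string, used to
#'   predict the theoretical envelope when an observed envelope is given).
#' @param criteria A [feature_match_criteria()] object.
#' @return List with `match` (logical) and `diagnostics` (per-sub-test
#'   data.frame with columns `test`, `passed`, `skipped`, `value`,
#'   `threshold`).
#' @export
feature_library_match <- function(feature, reference,
                                  criteria = feature_match_criteria()) {
  diag <- list()
  ppm <- ppm_error(feature$mz, reference$mz)
  diag$ppm <- c(passed = abs(ppm) <= criteria$ppm_tol, skipped = FALSE,
                value = abs(ppm), threshold = criteria$ppm_tol)
  drt <- abs(feature$rt - reference$rt)
  diag$rt <- c(passed = drt <= criteria$rt_tol, skipped = FALSE,
               value = drt, threshold = criteria$rt_tol)

  ref_drift <- reference$drift_time
  if (!is.null(ref_drift) && !is.na(ref_drift)) {
    if (is.null(feature$drift_time) || is.na(feature$drift_time)) {
      diag$drift <- c(passed = TRUE, skipped = TRUE, value = NA_real_,
                      threshold = NA_real_)
    } else {
      half <- ref_drift / (2 * criteria$ims_resolving_power)
      dd <- abs(feature$drift_time - ref_drift)
      diag$drift <- c(passed = dd <= half, skipped = FALSE, value = dd,
                      threshold = half)
    }
  }

  env <- feature$observed_envelope
  if (!is.null(env)) {
    theo <- if (!is.null(reference$theoretical_envelope)) {
      reference$theoretical_envelope
    } else if (!is.null(reference$formula)) {
      isotope_envelope(reference$formula,
                       n_peaks = length(envelope_abundance(env)))
    } else {
      stop("observed envelope supplied but reference has neither a ",
           "theoretical envelope nor a formula")
    }
    idotp <- isotope_dot_product(theo, env)
    diag$idotp <- c(passed = idotp > criteria$min_idotp, skipped = FALSE,
                    value = idotp, threshold = criteria$min_idotp)
  }

  dd <- do.call(rbind, lapply(diag, function(x) {
    data.frame(passed = as.logical(x[["passed"]]),
               skipped = as.logical(x[["skipped"]]),
               value = as.numeric(x[["value"]]),
               threshold = as.numeric(x[["threshold"]]))
  }))
  dd <- cbind(test = names(diag), dd)
  rownames(dd) <- NULL
  list(match = all(dd$passed), diagnostics = dd)
}
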