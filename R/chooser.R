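#' Select a reference MS/MS spectrum for a target compound
#'
#' Emulates the reference-scan selection procedure used when building
#' spectral libraries from acquisition runs of synthetic mixtures: among
#' candidate MS2 spectra whose precursor m/z lies within a ppm window of
#' the target's adduct m/z, return the one with the most abundant
#' precursor ion.  Ties on precursor intensity are broken by smaller
#' absolute ppm error, then by smaller scan number, so the result does not
#' depend on candidate order.
#'
#' If a passing candidate lacks a recorded precursor intensity the summed
#' fragment intensity is used as a ranking proxy for all candidates, and
#' the degraded ranking mode is reported via a warning.
#'
#' @param candidates List of MS2 [ms_spectrum()] objects.
#' @param target_mass Neutral monoisotopic mass of the target compound (Da).
#' @param ppm_window Mass tolerance window in ppm (default 10).
#' @param adduct Adduct name (default `"[M+H]+"`).
#' @return The selected `ms_spectrum`, or `NULL` if no candidate passes.
#' @export
choose_reference_spectrum <- function(candidates, target_mass,
                                      ppm_window = 10, adduct = "[M+H]+") {
  if (ppm_window <= 0) stop("ppm_window must be positive")
  target_mz <- adduct_mz(target_mass, adduct)
  if (length(candidates) == 0L) return(NULL)
  is_ms2 <- vapply(candidates, function(s) s$ms_level == 2L, logical(1))
  pmz <- vapply(candidates, function(s) s$precursor_mz, numeric(1))
  pass <- is_ms2 & !is.na(pmz) & abs(ppm_error(pmz, target_mz)) <= ppm_window
  if (!any(pass)) return(NULL)
  passing <- candidates[pass]
  rank_int <- vapply(passing, function(s) s$precursor_intensity, numeric(1))
  if (anyNA(rank_int)) {
    warning("precursor intensity missing on ", sum(is.na(rank_int)),
            " passing candidate(s); ranking by summed fragment intensity")
    rank_int <- vapply(passing, function(s) sum(s$intensity), numeric(1))
  }
  abs_ppm <- abs(ppm_error(vapply(passing, function(s) s$precursor_mz,
                                  numeric(1)), target_mz))
  scan <- vapply(passing, function(s) {
    if (is.na(s$scan_number)) .Machine$integer.max else s$scan_number
  }, numeric(1))
  o <- order(-rank_int, abs_ppm, scan)
  passing[[o[[1L]]]]
}

#' Select reference spectra for every record of a compound library
#'
#' Applies [choose_reference_spectrum()] per library record.
#'
#' @param library A `compound_library` data.frame.
#' @param candidates List of MS2 spectra (an acquisition run).
#' @param ppm_window ppm tolerance (default 10).
#' @param adduct Adduct name.
#' @return Named list (by `compound_id`) of selected spectra; records with
#'   no passing candidate are absent from the list.
#' @export
choose_library_references <- function(library, candidates, ppm_window = 10,
                                      adduct = "[M+H]+") {
  out <- list()
  for (i in seq_len(nrow(library))) {
    hit <- choose_reference_spectrum(candidates,
                                     library$monoisotopic_mass[[i]],
                                     ppm_window = ppm_window, adduct = adduct)
    if (!is.null(hit)) out[[library$compound_id[[i]]]] <- hit
  }
  out
}
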