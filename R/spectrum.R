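#' Construct an MS spectrum object
#'
#' Centroided peak lists only.  Peaks are stored as parallel numeric
#' vectors and are sorted strictly ascending in m/z on construction; if the
#' input order had to be changed, the `resorted` flag records it (MGF files
#' with unsorted peaks are accepted but flagged).
#'
#' @param spectrum_id Identifier (MGF TITLE).
#' @param precursor_mz Precursor m/z (required for MS2).
#' @param mz,intensity Numeric peak vectors (equal length; mz > 0,
#'   intensity >= 0).
#' @param precursor_intensity Optional precursor ion intensity.
#' @param charge Optional signed integer charge.
#' @param ms_level 1 or 2.
#' @param source_file Originating file id (join key for metadata).
#' @param scan_number Integer scan number.
#' @param instrument_tag One of `"orbitrap"`, `"qtof"`, `"other"`.
#' @return An object of class `ms_spectrum`.
#' @export
ms_spectrum <- function(spectrum_id, precursor_mz = NA_real_,
                        mz = numeric(0), intensity = numeric(0),
                        precursor_intensity = NA_real_, charge = NA_integer_,
                        ms_level = 2L, source_file = NA_character_,
                        scan_number = NA_integer_,
                        instrument_tag = c("other", "orbitrap", "qtof")) {
  instrument_tag <- match.arg(instrument_tag)
  if (length(mz) != length(intensity)) {
    stop("mz and intensity must have equal length")
  }
  if (any(mz <= 0)) stop("peak m/z must be positive")
  if (any(intensity < 0)) stop("peak intensity must be non-negative")
  if (!ms_level %in% c(1L, 2L)) stop("ms_level must be 1 or 2")
  resorted <- is.unsorted(mz, strictly = TRUE)
  if (resorted) {
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]
    if (anyDuplicated(mz)) {
      # merge exactly coincident centroids
      agg <- rowsum(intensity, group = mz)
      mz <- as.numeric(rownames(agg)); intensity <- as.numeric(agg)
    }
  }
  structure(list(
    spectrum_id = as.character(spectrum_id),
    precursor_mz = as.numeric(precursor_mz),
    precursor_intensity = as.numeric(precursor_intensity),
    charge = as.integer(charge),
    mz = as.numeric(mz),
    intensity = as.numeric(intensity),
    ms_level = as.integer(ms_level),
    source_file = as.character(source_file),
    scan_number = as.integer(scan_number),
    instrument_tag = instrument_tag,
    resorted = resorted
  ), class = "ms_spectrum")
}

#' @export
print.ms_spectrum <- function(x, ...) {
  cat(sprintf("<ms_spectrum> %s  MS%d  precursor %.4f  %d peaks\n",
              x$spectrum_id, x$ms_level,
              if (is.na(x$precursor_mz)) NA else x$precursor_mz,
              length(x$mz)))
  invisible(x)
}

#' Number of peaks in a spectrum
#' @param s An `ms_spectrum`.
#' @export
n_peaks <- function(s) length(s$mz)

#' Normalize spectrum intensities
#'
#' Three modes: `base_peak` scales the maximum intensity to 1; `l2` scales
#' the intensity vector to unit Euclidean norm; `sqrt_l2` replaces
#' intensities by their square roots, then L2-normalizes (the scaling used
#' by the cosine score).  The applied mode is recorded on the spectrum and
#' re-applying the same mode is a no-op, so every mode is idempotent
#' (`sqrt_l2` would otherwise re-compress intensities on each
#' application).
#'
#' @param s An `ms_spectrum` with at least one peak.
#' @param mode Normalization mode.
#' @return The spectrum with transformed intensities; field
#'   `normalization` records the mode.
#' @export
normalize_spectrum <- function(s, mode = c("base_peak", "l2", "sqrt_l2")) {
  mode <- match.arg(mode)
  if (n_peaks(s) == 0L) stop("cannot normalize a spectrum with no peaks")
  if (all(s$intensity == 0)) stop("all-zero intensities")
  if (identical(s$normalization, mode)) return(s)
  s$normalization <- mode
  s$intensity <- switch(mode,
    base_peak = s$intensity / max(s$intensity),
    l2 = s$intensity / sqrt(sum(s$intensity^2)),
    sqrt_l2 = {
      r <- sqrt(s$intensity)
      r / sqrt(sum(r^2))
    })
  s
}
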