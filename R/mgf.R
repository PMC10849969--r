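#' Read an MGF file
#'
#' Standard BEGIN IONS / END IONS dialect.  TITLE carries the spectrum id;
#' PEPMASS carries precursor m/z and, optionally, precursor intensity;
#' CHARGE, SCANS, SOURCE_FILE and INSTRUMENT are honoured when present.
#' Peaks that arrive unsorted are re-sorted and the spectrum's `resorted`
#' flag is set.
#'
#' @param path MGF file path.
#' @param source_file Fallback source-file id for spectra lacking a
#'   SOURCE_FILE header (defaults to the file's base name).
#' @return List of [ms_spectrum()] objects.
#' @export
read_mgf <- function(path, source_file = basename(path)) {
  if (!file.exists(path)) stop("MGF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- trimws(lines[[i]])
    if (line == "BEGIN IONS") {
      block_start <- i
      hdr <- list()
      mzv <- numeric(0); intv <- numeric(0)
      i <- i + 1L
      closed <- FALSE
      while (i <= n) {
        l <- trimws(lines[[i]])
        if (l == "END IONS") { closed <- TRUE; break }
        if (l == "BEGIN IONS") {
          stop("malformed MGF: nested BEGIN IONS at line ", i)
        }
        if (nzchar(l)) {
          if (grepl("=", l, fixed = TRUE)) {
            key <- toupper(sub("=.*$", "", l))
            hdr[[key]] <- sub("^[^=]*=", "", l)
          } else {
            parts <- strsplit(l, "[ \t]+")[[1]]
            if (length(parts) < 2L || anyNA(suppressWarnings(
                  as.numeric(parts[1:2])))) {
              stop("malformed MGF peak line at line ", i, ": ", sQuote(l))
            }
            mzv <- c(mzv, as.numeric(parts[[1]]))
            intv <- c(intv, as.numeric(parts[[2]]))
          }
        }
        i <- i + 1L
      }
      if (!closed) {
        stop("malformed MGF: BEGIN IONS at line ", block_start,
             " without END IONS")
      }
      if (is.null(hdr$PEPMASS)) {
        stop("malformed MGF: block at line ", block_start, " lacks PEPMASS")
      }
      pm <- strsplit(trimws(hdr$PEPMASS), "[ \t]+")[[1]]
      charge <- NA_integer_
      if (!is.null(hdr$CHARGE)) {
        ch <- hdr$CHARGE
        sign <- if (grepl("-", ch, fixed = TRUE)) -1L else 1L
        charge <- sign * as.integer(gsub("[^0-9]", "", ch))
      }
      spectra[[length(spectra) + 1L]] <- ms_spectrum(
        spectrum_id = if (!is.null(hdr$TITLE)) hdr$TITLE else
          paste0("scan=", length(spectra) + 1L),
        precursor_mz = as.numeric(pm[[1]]),
        precursor_intensity = if (length(pm) > 1L) as.numeric(pm[[2]])
          else NA_real_,
        charge = charge,
        mz = mzv, intensity = intv,
        ms_level = 2L,
        source_file = if (!is.null(hdr$SOURCE_FILE)) hdr$SOURCE_FILE
          else source_file,
        scan_number = if (!is.null(hdr$SCANS)) as.integer(hdr$SCANS)
          else NA_integer_,
        instrument_tag = if (!is.null(hdr$INSTRUMENT) &&
                             tolower(hdr$INSTRUMENT) %in%
                               c("orbitrap", "qtof"))
          tolower(hdr$INSTRUMENT) else "other"
      )
    } else if (nzchar(line) && line == "END IONS") {
      stop("malformed MGF: END IONS without BEGIN IONS at line ", i)
    }
    i <- i + 1L
  }
  spectra
}

#' Write spectra to an MGF file
#'
#' Lossless round-trip partner of [read_mgf()] for spectrum id, precursor
#' m/z (and intensity), charge, scan number, source file, instrument tag
#' and peaks.
#'
#' @param spectra Non-empty list of [ms_spectrum()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  if (length(spectra) == 0L) stop("no spectra to write")
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", s$spectrum_id), con)
    pep <- format_mz(s$precursor_mz)
    if (!is.na(s$precursor_intensity)) {
      pep <- paste(pep, format_intensity(s$precursor_intensity))
    }
    writeLines(paste0("PEPMASS=", pep), con)
    if (!is.na(s$charge)) {
      writeLines(paste0("CHARGE=", abs(s$charge),
                        if (s$charge < 0) "-" else "+"), con)
    }
    if (!is.na(s$scan_number)) {
      writeLines(paste0("SCANS=", s$scan_number), con)
    }
    if (!is.na(s$source_file)) {
      writeLines(paste0("SOURCE_FILE=", s$source_file), con)
    }
    if (s$instrument_tag != "other") {
      writeLines(paste0("INSTRUMENT=", s$instrument_tag), con)
    }
    if (n_peaks(s) > 0L) {
      writeLines(paste(format_mz(s$mz), format_intensity(s$intensity)), con)
    }
    writeLines("END IONS", con)
    writeLines("", con)
  }
  invisible(path)
}

format_mz <- function(x) formatC(x, format = "f", digits = 6)
format_intensity <- function(x) formatC(x, format = "g", digits = 10)
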