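#' Read a minimal-dialect mzML file
#'
#' A deliberately minimal mzML reader covering the subset this toolkit
#' emits and consumes: uncompressed XML, little-endian 64- or 32-bit float
#' binary arrays, zlib or no compression.  MS1 and MS2 spectra are
#' returned with scan numbers, and precursor m/z / intensity / charge when
#' present.  Any other array encoding raises an explicit
#' unsupported-dialect error rather than being skipped silently.
#' Vendor-grade parsing is delegated to ecosystem libraries (e.g. mzR).
#'
#' @param path mzML file path.
#' @param source_file Source-file id recorded on each spectrum (defaults to
#'   the file's base name).
#' @return List of [ms_spectrum()] objects (MS1 and MS2).
#' @export
read_mzml_minimal <- function(path, source_file = basename(path)) {
  if (!file.exists(path)) stop("mzML file not found: ", path)
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  nodes <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
  lapply(nodes, function(node) {
    id <- xml2::xml_attr(node, "id")
    scan <- suppressWarnings(as.integer(sub(".*scan=([0-9]+).*", "\\1", id)))
    ms_level <- as.integer(cv_value(node, "MS:1000511"))
    if (is.na(ms_level)) {
      stop("spectrum ", sQuote(id), " lacks an ms level cvParam")
    }
    ion <- xml2::xml_find_first(
      node, ".//precursorList/precursor/selectedIonList/selectedIon")
    pmz <- pint <- NA_real_; charge <- NA_integer_
    if (!inherits(ion, "xml_missing")) {
      pmz <- as.numeric(cv_value(ion, "MS:1000744"))
      pint <- as.numeric(cv_value(ion, "MS:1000042"))
      charge <- as.integer(cv_value(ion, "MS:1000041"))
    }
    arrays <- xml2::xml_find_all(node, ".//binaryDataArrayList/binaryDataArray")
    mzv <- intv <- numeric(0)
    for (arr in arrays) {
      vals <- decode_binary_array(arr, id)
      if (!is.na(cv_value(arr, "MS:1000514", attr = "name"))) {
        mzv <- vals
      } else if (!is.na(cv_value(arr, "MS:1000515", attr = "name"))) {
        intv <- vals
      }
    }
    ms_spectrum(
      spectrum_id = id, precursor_mz = pmz, precursor_intensity = pint,
      charge = charge, mz = mzv, intensity = intv, ms_level = ms_level,
      source_file = source_file, scan_number = scan
    )
  })
}

# Value of a cvParam by accession (NA if absent).
cv_value <- function(node, accession, attr = "value") {
  p <- xml2::xml_find_first(
    node, sprintf(".//cvParam[@accession='%s']", accession))
  if (inherits(p, "xml_missing")) return(NA_character_)
  v <- xml2::xml_attr(p, attr)
  if (is.na(v)) "" else v
}

decode_binary_array <- function(arr, spectrum_id) {
  has64 <- !is.na(cv_value(arr, "MS:1000523", attr = "name"))
  has32 <- !is.na(cv_value(arr, "MS:1000521", attr = "name"))
  zlib <- !is.na(cv_value(arr, "MS:1000574", attr = "name"))
  none <- !is.na(cv_value(arr, "MS:1000576", attr = "name"))
  if (!has64 && !has32) {
    stop("unsupported mzML dialect in spectrum ", sQuote(spectrum_id),
         ": binary array precision is neither 64- nor 32-bit float")
  }
  if (!zlib && !none) {
    stop("unsupported mzML dialect in spectrum ", sQuote(spectrum_id),
         ": binary array compression is neither zlib nor none")
  }
  b64 <- trimws(xml2::xml_text(xml2::xml_find_first(arr, ".//binary")))
  if (!nzchar(b64)) return(numeric(0))
  raw <- jsonlite::base64_dec(b64)
  if (zlib) raw <- memDecompress(raw, type = "gzip")
  size <- if (has64) 8L else 4L
  readBin(raw, what = "double", n = length(raw) %/% size, size = size,
          endian = "little")
}

#' Write a minimal mzML file (fixture writer)
#'
#' Emits the same minimal dialect [read_mzml_minimal()] consumes: 64-bit
#' little-endian float arrays, zlib or no compression.  Intended for
#' fixtures and round-trip testing, not as a general-purpose mzML writer.
#'
#' @param spectra List of [ms_spectrum()] objects.
#' @param path Output path.
#' @param compression `"none"` or `"zlib"`.
#' @return `path`, invisibly.
#' @export
write_mzml_minimal <- function(spectra, path, compression = c("none", "zlib")) {
  compression <- match.arg(compression)
  enc <- function(x) {
    raw <- writeBin(as.numeric(x), raw(), size = 8L, endian = "little")
    if (compression == "zlib") raw <- memCompress(raw, type = "gzip")
    gsub("[\r\n]", "", jsonlite::base64_enc(raw))
  }
  comp_cv <- if (compression == "zlib") {
    '<cvParam cvRef="MS" accession="MS:1000574" name="zlib compression"/>'
  } else {
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression"/>'
  }
  lines <- c(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    sprintf('<run id="%s">', xml_escape(basename(path))),
    sprintf('<spectrumList count="%d">', length(spectra))
  )
  for (i in seq_along(spectra)) {
    s <- spectra[[i]]
    scan <- if (is.na(s$scan_number)) i else s$scan_number
    lines <- c(lines, sprintf(
      '<spectrum index="%d" id="scan=%d" defaultArrayLength="%d">',
      i - 1L, scan, n_peaks(s)),
      sprintf('<cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>',
              s$ms_level))
    if (s$ms_level == 2L && !is.na(s$precursor_mz)) {
      ion <- sprintf(
        '<cvParam cvRef="MS" accession="MS:1000744" name="selected ion m/z" value="%s"/>',
        format_mz(s$precursor_mz))
      if (!is.na(s$precursor_intensity)) {
        ion <- c(ion, sprintf(
          '<cvParam cvRef="MS" accession="MS:1000042" name="peak intensity" value="%s"/>',
          format_intensity(s$precursor_intensity)))
      }
      if (!is.na(s$charge)) {
        ion <- c(ion, sprintf(
          '<cvParam cvRef="MS" accession="MS:1000041" name="charge state" value="%d"/>',
          s$charge))
      }
      lines <- c(lines,
        '<precursorList count="1"><precursor>',
        '<selectedIonList count="1"><selectedIon>', ion,
        '</selectedIon></selectedIonList>',
        '</precursor></precursorList>')
    }
    mz_b64 <- enc(s$mz)
    int_b64 <- enc(s$intensity)
    lines <- c(lines,
      '<binaryDataArrayList count="2">',
      sprintf('<binaryDataArray encodedLength="%d">', nchar(mz_b64)),
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
      comp_cv,
      '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array"/>',
      paste0('<binary>', mz_b64, '</binary>'),
      '</binaryDataArray>',
      sprintf('<binaryDataArray encodedLength="%d">', nchar(int_b64)),
      '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float"/>',
      comp_cv,
      '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array"/>',
      paste0('<binary>', int_b64, '</binary>'),
      '</binaryDataArray>',
      '</binaryDataArrayList>',
      '</spectrum>')
  }
  lines <- c(lines, '</spectrumList>', '</run>', '</mzML>')
  writeLines(lines, path)
  invisible(path)
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}
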