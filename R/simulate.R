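#' Simulator configuration
#'
#' Defines the conditions of a synthetic repository: group labels, files
#' per group, per-compound per-group occurrence probabilities, instrument
#' noise, and decoys.  Defaults model a two-group (CD vs nonIBD)
#' case-control design of 100 files per group with moderate
#' high-resolution instrument noise.
#'
#' @param seed Master RNG seed (integer); recorded in all outputs.
#' @param groups Character vector of group labels.
#' @param n_files_per_group Files simulated per group.
#' @param occurrence Numeric matrix of occurrence probabilities, compounds
#'   x groups (rownames = compound ids, colnames = groups).
#' @param mz_jitter_sd Gaussian m/z jitter SD in Da.
#' @param intensity_cv Coefficient of variation of multiplicative
#'   log-normal intensity noise.
#' @param peak_dropout_prob Bernoulli per-peak dropout probability
#'   (planted spectra never drop below `min_peaks` surviving peaks).
#' @param min_peaks Minimum surviving peaks per planted spectrum
#'   (default 6, the matched-ion criterion).
#' @param n_decoys Decoy spectra added per file.
#' @param instrument_tag Instrument class tag recorded on spectra.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed, groups = c("CD", "nonIBD"),
                       n_files_per_group = 100L, occurrence,
                       mz_jitter_sd = 0.005, intensity_cv = 0.2,
                       peak_dropout_prob = 0.1, min_peaks = 6L,
                       n_decoys = 2L,
                       instrument_tag = c("qtof", "orbitrap", "other")) {
  instrument_tag <- match.arg(instrument_tag)
  occurrence <- as.matrix(occurrence)
  if (is.null(colnames(occurrence))) colnames(occurrence) <- groups
  stopifnot(all(colnames(occurrence) == groups),
            all(occurrence >= 0), all(occurrence <= 1),
            mz_jitter_sd >= 0, intensity_cv >= 0,
            peak_dropout_prob >= 0, peak_dropout_prob <= 1,
            n_files_per_group >= 1, n_decoys >= 0)
  structure(list(
    seed = as.integer(seed), groups = groups,
    n_files_per_group = as.integer(n_files_per_group),
    occurrence = occurrence,
    noise = list(mz_jitter_sd = mz_jitter_sd, intensity_cv = intensity_cv,
                 peak_dropout_prob = peak_dropout_prob),
    min_peaks = as.integer(min_peaks),
    n_decoys = as.integer(n_decoys),
    instrument_tag = instrument_tag
  ), class = "sim_config")
}

#' Apply instrument noise to a spectrum
#'
#' Gaussian m/z jitter, multiplicative log-normal intensity noise
#' (parameterized by CV, mean 1), and Bernoulli peak dropout that never
#' leaves fewer than `min_peaks` peaks (the highest-intensity peaks are
#' retained when dropout would go below the floor).  Uses the current RNG
#' state; seed externally for reproducibility.  Zero noise is the
#' identity.
#'
#' @param s An [ms_spectrum()].
#' @param noise List with `mz_jitter_sd`, `intensity_cv`,
#'   `peak_dropout_prob`.
#' @param min_peaks Dropout floor (default 6).
#' @return The perturbed spectrum.
#' @export
perturb_spectrum <- function(s, noise, min_peaks = 6L) {
  stopifnot(noise$mz_jitter_sd >= 0, noise$intensity_cv >= 0,
            noise$peak_dropout_prob >= 0, noise$peak_dropout_prob <= 1)
  n <- n_peaks(s)
  if (n == 0L) return(s)
  keep <- rep(TRUE, n)
  if (noise$peak_dropout_prob > 0) {
    keep <- stats::runif(n) >= noise$peak_dropout_prob
    floor_n <- min(min_peaks, n)
    if (sum(keep) < floor_n) {
      keep[order(s$intensity, decreasing = TRUE)[seq_len(floor_n)]] <- TRUE
    }
  }
  mz <- s$mz[keep]
  intensity <- s$intensity[keep]
  if (noise$mz_jitter_sd > 0) {
    mz <- mz + stats::rnorm(length(mz), 0, noise$mz_jitter_sd)
  }
  if (noise$intensity_cv > 0) {
    sdlog <- sqrt(log(1 + noise$intensity_cv^2))
    intensity <- intensity *
      stats::rlnorm(length(intensity), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  out <- s
  out$mz <- mz; out$intensity <- intensity
  o <- order(out$mz)
  out$mz <- out$mz[o]; out$intensity <- out$intensity[o]
  out
}

# Stable per-file RNG stream seed derived from the master seed, so
# per-file outputs do not depend on simulation order.
file_stream_seed <- function(master_seed, file_index) {
  as.integer((as.double(master_seed) * 48271 + file_index * 16807) %%
               2147483647)
}

#' Simulate a spectral repository with planted ground truth
#'
#' For each file and library compound, a perturbed copy of the compound's
#' theoretical reference spectrum is planted with the file's group
#' occurrence probability; each file additionally receives decoy spectra
#' (planted precursor retained -- so decoys always pass the precursor
#' filter -- with fragment m/z redrawn uniformly at random).  Sample
#' metadata carries the group label as phenotype, and the ground-truth
#' ledger accounts for every MS2 spectrum exactly once (planted or
#' decoy).
#'
#' @param library A `compound_library` whose compound ids match the
#'   rownames of `config$occurrence`.
#' @param config A [sim_config()].
#' @param adduct Adduct for reference spectra.
#' @param out_dir Optional directory: when given, one MGF per file is
#'   written there and a `metadata.tsv` alongside.
#' @return List with `corpus` (list of [ms_spectrum()]), `metadata`
#'   (`sample_metadata`), and `ground_truth` (list with `planted`
#'   data.frame `source_file`/`compound_id`/`spectrum_id`, `decoys`
#'   data.frame, `occurrence` matrix, `seed`).
#' @export
simulate_repository <- function(library, config, adduct = "[M+H]+",
                                out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"), nrow(library) >= 1)
  occ <- config$occurrence
  if (is.null(rownames(occ))) {
    stopifnot(nrow(occ) == nrow(library))
    rownames(occ) <- library$compound_id
  }
  missing <- setdiff(rownames(occ), library$compound_id)
  if (length(missing)) {
    stop("occurrence rows not in library: ", paste(missing, collapse = ", "))
  }
  refs <- library_reference_spectra(library, adduct = adduct)

  corpus <- list()
  meta_rows <- list()
  planted <- list()
  decoys <- list()
  file_index <- 0L
  for (g in config$groups) {
    for (f in seq_len(config$n_files_per_group)) {
      file_index <- file_index + 1L
      src <- sprintf("sim_%s_%03d.mzML", g, f)
      set.seed(file_stream_seed(config$seed, file_index))
      scan <- 0L
      file_spectra <- list()
      for (cid in rownames(occ)) {
        if (stats::runif(1) < occ[cid, g]) {
          scan <- scan + 1L
          sp <- perturb_spectrum(refs[[cid]], config$noise,
                                 min_peaks = config$min_peaks)
          sp$spectrum_id <- sprintf("%s:scan=%d", src, scan)
          sp$source_file <- src
          sp$scan_number <- scan
          sp$instrument_tag <- config$instrument_tag
          sp$precursor_intensity <- sum(sp$intensity)
          file_spectra[[length(file_spectra) + 1L]] <- sp
          planted[[length(planted) + 1L]] <- data.frame(
            source_file = src, compound_id = cid,
            spectrum_id = sp$spectrum_id, stringsAsFactors = FALSE)
        }
      }
      if (config$n_decoys > 0L) {
        for (d in seq_len(config$n_decoys)) {
          scan <- scan + 1L
          tmpl_id <- sample(rownames(occ), 1L)
          ref <- refs[[tmpl_id]]
          dec <- ref
          lo <- 50
          hi <- max(ref$precursor_mz - 1, lo + 1)
          dec_mz <- sort(stats::runif(n_peaks(ref), lo, hi))
          dec$mz <- dec_mz
          dec$spectrum_id <- sprintf("%s:decoy=%d", src, d)
          dec$source_file <- src
          dec$scan_number <- scan
          dec$instrument_tag <- config$instrument_tag
          dec$precursor_intensity <- sum(dec$intensity)
          file_spectra[[length(file_spectra) + 1L]] <- dec
          decoys[[length(decoys) + 1L]] <- data.frame(
            source_file = src, spectrum_id = dec$spectrum_id,
            template_compound = tmpl_id, stringsAsFactors = FALSE)
        }
      }
      corpus <- c(corpus, file_spectra)
      meta_rows[[file_index]] <- data.frame(
        source_file = src, organism = "Homo sapiens",
        sample_type = "feces", phenotype = g, dataset_id = "SIM000001",
        stringsAsFactors = FALSE)
      if (!is.null(out_dir) && length(file_spectra)) {
        if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
        write_mgf(file_spectra,
                  file.path(out_dir, sub("\\.mzML$", ".mgf", src)))
      }
    }
  }
  metadata <- as_sample_metadata(do.call(rbind, meta_rows))
  gt <- list(
    planted = if (length(planted)) do.call(rbind, planted) else
      data.frame(source_file = character(0), compound_id = character(0),
                 spectrum_id = character(0)),
    decoys = if (length(decoys)) do.call(rbind, decoys) else
      data.frame(source_file = character(0), spectrum_id = character(0),
                 template_compound = character(0)),
    occurrence = occ,
    seed = config$seed
  )
  if (!is.null(out_dir)) {
    utils::write.table(metadata, file.path(out_dir, "metadata.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(corpus = corpus, metadata = metadata, ground_truth = gt)
}

#' Ground-truth occurrence matrix of a simulation
#'
#' Boolean compounds x samples matrix of planted occurrences, the
#' reference against which detected presence matrices are evaluated.
#'
#' @param ground_truth The `ground_truth` element returned by
#'   [simulate_repository()].
#' @param metadata The matching `sample_metadata`.
#' @param compounds Row universe (default: occurrence matrix rownames).
#' @return Logical matrix (compounds x samples).
#' @export
ground_truth_matrix <- function(ground_truth, metadata, compounds = NULL) {
  if (is.null(compounds)) compounds <- rownames(ground_truth$occurrence)
  mat <- matrix(FALSE, length(compounds), nrow(metadata),
                dimnames = list(compounds, metadata$source_file))
  p <- ground_truth$planted
  if (nrow(p)) {
    mat[cbind(match(p$compound_id, compounds),
              match(p$source_file, metadata$source_file))] <- TRUE
  }
  mat
}

#' Simulate a compound-by-sample abundance table
#'
#' Log-normal abundances where a compound is present, exact zeros where
#' it is absent, with an optional group-specific location shift (in log
#' units) for enriched compounds.  Uses the current RNG state; seed
#' externally for reproducibility.
#'
#' @param presence Logical compounds x samples matrix (a ground-truth
#'   matrix, a detected `presence_matrix`, or all-`TRUE` for a fully
#'   observed design).
#' @param metadata `sample_metadata` covering the columns (used to apply
#'   the group shift).
#' @param enriched Compound ids receiving the location shift.
#' @param shift_group Group label whose samples receive the shift.
#' @param shift Location shift in natural-log units (default 0 = null).
#' @param meanlog,sdlog Baseline log-normal parameters.
#' @return Numeric matrix, compounds x samples.
#' @export
simulate_abundance_table <- function(presence, metadata,
                                     enriched = character(0),
                                     shift_group = NULL, shift = 0,
                                     meanlog = log(1e5), sdlog = 1) {
  m <- unclass(presence)
  attr(m, "orphan_matches") <- NULL
  storage.mode(m) <- "logical"
  groups <- metadata$phenotype[match(colnames(m), metadata$source_file)]
  out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) {
    mu <- rep(meanlog, ncol(m))
    if (rownames(m)[i] %in% enriched && !is.null(shift_group)) {
      mu[groups == shift_group] <- meanlog + shift
    }
    present <- m[i, ]
    if (any(present)) {
      out[i, present] <- stats::rlnorm(sum(present),
                                       meanlog = mu[present], sdlog = sdlog)
    }
  }
  out
}
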