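#' Built-in fragmentation templates
#'
#' Rule-based model of the key fragment ions of each compound class:
#' sequential neutral water losses from the precursor (three for
#' trihydroxylated and two for dihydroxylated bile-acid cores, one for
#' acyl amides/esters), the protonated right-hand fragment (amine, amino
#' acid or hydroxy acid) released on amide/ester bond cleavage, and the
#' acylium ion (left block minus hydroxide), with secondary water/CO
#' losses from the acylium for the acyl classes.  Relative intensities
#' are arbitrary modeling defaults (the acceptance surface of the toolkit
#' never depends on matching real spectra peak-for-peak); every template
#' yields at least 6 fragments so simulated spectra can satisfy the
#' minimum-matched-ions criterion.
#'
#' @param compound_class One of `"amide"`, `"ester"`, `"bile_amidate_di"`,
#'   `"bile_amidate_tri"`.
#' @return A `fragmentation_template`: list with `compound_class` and
#'   `rules` (data.frame with columns `name`, `base`, `n_water_loss`,
#'   `intensity`).  `base` is one of `"precursor"`, `"right_protonated"`,
#'   `"acylium"`.
#' @export
fragmentation_template <- function(compound_class = c(
    "amide", "ester", "bile_amidate_di", "bile_amidate_tri")) {
  compound_class <- match.arg(compound_class)
  rules <- switch(compound_class,
    amide = , ester = data.frame(
      name = c("precursor", "precursor-H2O", "right+H", "acylium",
               "acylium-H2O", "acylium-CO"),
      base = c("precursor", "precursor", "right_protonated", "acylium",
               "acylium", "acylium_co"),
      n_water_loss = c(0L, 1L, 0L, 0L, 1L, 0L),
      intensity = c(1.0, 0.35, 0.8, 0.6, 0.25, 0.15)),
    bile_amidate_di = data.frame(
      name = c("precursor", "precursor-H2O", "precursor-2H2O", "right+H",
               "acylium", "acylium-H2O"),
      base = c("precursor", "precursor", "precursor", "right_protonated",
               "acylium", "acylium"),
      n_water_loss = c(0L, 1L, 2L, 0L, 0L, 1L),
      intensity = c(1.0, 0.8, 0.6, 0.7, 0.3, 0.2)),
    bile_amidate_tri = data.frame(
      name = c("precursor", "precursor-H2O", "precursor-2H2O",
               "precursor-3H2O", "right+H", "acylium"),
      base = c("precursor", "precursor", "precursor", "precursor",
               "right_protonated", "acylium"),
      n_water_loss = c(0L, 1L, 2L, 3L, 0L, 0L),
      intensity = c(1.0, 0.8, 0.6, 0.4, 0.7, 0.3))
  )
  structure(list(compound_class = compound_class, rules = rules),
            class = "fragmentation_template")
}

#' Fragmentation template appropriate for a library record
#'
#' Maps the record's condensation rule (and, for bile amidates, the
#' hydroxyl count of the bile-acid core) to one of the built-in templates.
#'
#' @param record A row of a `compound_library` (list-like with `rule` and
#'   optionally `hydroxyls`).
#' @return A `fragmentation_template`.
#' @export
template_for_record <- function(record) {
  cls <- switch(as.character(record$rule),
    amide = "amide",
    ester = "ester",
    bile_amidate = {
      h <- record$hydroxyls
      if (is.null(h) || is.na(h)) h <- 3
      if (h >= 3) "bile_amidate_tri" else "bile_amidate_di"
    },
    stop("no fragmentation template for rule ", sQuote(record$rule)))
  fragmentation_template(cls)
}

.H2O_MASS <- 18.0105646863   # 2 H + O, monoisotopic
.OH_MASS <- 17.0027396541    # H + O
.CO_MASS <- 27.9949146196    # C + O

#' Deterministic theoretical MS/MS spectrum for a library record
#'
#' Applies a fragmentation template to a compound record: each rule's m/z
#' is computed from the record's adduct m/z and its building-block masses
#' (protonated right-hand fragment = right-block mass + proton; acylium =
#' left-block mass - hydroxide), minus the rule's water losses.  The same
#' record and template always produce the identical spectrum.
#'
#' @param record A row of a `compound_library` (list-like; needs
#'   `compound_id`, `monoisotopic_mass`, `left_mass`, `right_mass`).
#' @param template A `fragmentation_template`; defaults to
#'   [template_for_record()].
#' @param adduct Adduct name (default `"[M+H]+"`).
#' @return An MS2 [ms_spectrum()] whose `spectrum_id` is the record's
#'   `compound_id` and whose precursor is the adduct ion.
#' @export
theoretical_spectrum <- function(record, template = NULL,
                                 adduct = "[M+H]+") {
  if (is.null(template)) template <- template_for_record(record)
  rules <- template$rules
  if (nrow(rules) == 0L) stop("fragmentation template has no rules")
  precursor <- adduct_mz(record$monoisotopic_mass, adduct)
  base_mz <- vapply(seq_len(nrow(rules)), function(i) {
    switch(rules$base[[i]],
      precursor = precursor,
      right_protonated = record$right_mass + PROTON_MASS,
      acylium = record$left_mass - .OH_MASS,
      acylium_co = record$left_mass - .OH_MASS - .CO_MASS,
      stop("unknown fragment base: ", rules$base[[i]]))
  }, numeric(1))
  mz <- base_mz - rules$n_water_loss * .H2O_MASS
  bad <- mz <= 0
  if (any(bad)) {
    stop("fragment rule(s) yield non-positive m/z: ",
         paste(rules$name[bad], collapse = ", "))
  }
  ms_spectrum(
    spectrum_id = record$compound_id,
    precursor_mz = precursor,
    precursor_intensity = NA_real_,
    charge = get_adduct(adduct)$charge,
    mz = mz, intensity = rules$intensity,
    ms_level = 2L
  )
}

#' Reference spectra for every record of a library
#'
#' @param library A `compound_library`.
#' @param adduct Adduct name.
#' @return Named list of [ms_spectrum()] (by `compound_id`).
#' @export
library_reference_spectra <- function(library, adduct = "[M+H]+") {
  out <- vector("list", nrow(library))
  for (i in seq_len(nrow(library))) {
    rec <- as.list(library[i, ])
    out[[i]] <- theoretical_spectrum(rec, adduct = adduct)
  }
  names(out) <- library$compound_id
  out
}
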