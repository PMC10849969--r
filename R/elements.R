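#' Bundled element data
#'
#' Static table of monoisotopic masses and isotope compositions for the
#' elements supported by the formula calculus (C, H, N, O, P, S, Na, Cl).
#' Masses are the 2021 IUPAC/AME atomic masses in Da; abundances are the
#' IUPAC representative isotopic compositions.  `shift` is the nominal-mass
#' offset of each isotope from the most abundant ("A") isotope, which is the
#' aggregation unit used by [isotope_envelope()].
#'
#' @format A list keyed by element symbol; each entry is a data.frame with
#'   columns `mass` (Da), `abundance` (fraction) and `shift` (integer),
#'   ordered by increasing mass, with the most abundant isotope first in
#'   abundance rank but not necessarily first in mass.
#' @keywords internal
.element_isotopes <- list(
  H = data.frame(
    mass      = c(1.00782503223, 2.01410177812),
    abundance = c(0.999885, 0.000115),
    shift     = c(0L, 1L)
  ),
  C = data.frame(
    mass      = c(12.0, 13.00335483507),
    abundance = c(0.9893, 0.0107),
    shift     = c(0L, 1L)
  ),
  N = data.frame(
    mass      = c(14.00307400443, 15.00010889888),
    abundance = c(0.99636, 0.00364),
    shift     = c(0L, 1L)
  ),
  O = data.frame(
    mass      = c(15.99491461957, 16.99913175650, 17.99915961286),
    abundance = c(0.99757, 0.00038, 0.00205),
    shift     = c(0L, 1L, 2L)
  ),
  P = data.frame(
    mass      = 30.97376199842,
    abundance = 1.0,
    shift     = 0L
  ),
  S = data.frame(
    mass      = c(31.9720711744, 32.9714589098, 33.967867004, 35.96708071),
    abundance = c(0.9499, 0.0075, 0.0425, 0.0001),
    shift     = c(0L, 1L, 2L, 4L)
  ),
  Na = data.frame(
    mass      = 22.9897692820,
    abundance = 1.0,
    shift     = 0L
  ),
  Cl = data.frame(
    mass      = c(34.968852682, 36.965902602),
    abundance = c(0.7576, 0.2424),
    shift     = c(0L, 2L)
  )
)

# Monoisotopic (most abundant isotope) mass per element, Da.
.element_monoisotopic <- vapply(
  .element_isotopes,
  function(tab) tab$mass[which.max(tab$abundance)],
  numeric(1)
)

#' Mass of a proton in Da
#'
#' Used for protonated/deprotonated adduct shifts.  Using the proton mass
#' (not the hydrogen atom mass) accounts for the electron gained or lost on
#' ionization, a difference high-resolution instruments resolve.
#' @export
PROTON_MASS <- 1.007276466879

#' Supported element symbols
#'
#' @return Character vector of element symbols known to the mass calculus.
#' @export
supported_elements <- function() names(.element_isotopes)
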