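#' Built-in adduct definitions
#'
#' Single-molecule (1M) adducts only; multimer aggregation is out of scope.
#' Mass shifts use the proton mass for protonation/deprotonation so that
#' the electron mass is accounted for.
#'
#' @return A data.frame with columns `name`, `mass_shift` (Da) and `charge`.
#' @export
adduct_table <- function() {
  data.frame(
    name = c("[M+H]+", "[M-H]-", "[M+Na]+", "[M+2H]2+"),
    mass_shift = c(
      PROTON_MASS,
      -PROTON_MASS,
      .element_monoisotopic[["Na"]] - 5.48579909e-4,  # Na+ = Na atom - e-
      2 * PROTON_MASS
    ),
    charge = c(1L, -1L, 1L, 2L),
    stringsAsFactors = FALSE
  )
}

#' Look up an adduct definition by name
#'
#' Accepts ASCII hyphen or Unicode minus in the name.
#' @param name Adduct name, e.g. `"[M+H]+"`.
#' @return One-row data.frame with `name`, `mass_shift`, `charge`.
#' @export
get_adduct <- function(name) {
  name <- gsub("−", "-", name)
  tab <- adduct_table()
  i <- match(name, tab$name)
  if (is.na(i)) stop("unknown adduct: ", sQuote(name))
  tab[i, , drop = FALSE]
}

#' Adduct m/z from a neutral monoisotopic mass
#'
#' `m/z = (mass + mass_shift) / |charge|` for single-M adducts.
#'
#' @param mass Neutral monoisotopic mass in Da; must be positive.
#' @param adduct Adduct name (see [adduct_table()]) or a one-row data.frame
#'   with `mass_shift` and `charge`.
#' @return m/z value.
#' @examples
#' adduct_mz(465.30904, "[M+H]+")  # 466.31632
#' @export
adduct_mz <- function(mass, adduct) {
  if (is.character(adduct)) adduct <- get_adduct(adduct)
  if (adduct$charge == 0L) stop("adduct charge must be non-zero")
  if (any(mass <= 0)) stop("mass must be positive")
  (mass + adduct$mass_shift) / abs(adduct$charge)
}

#' Signed ppm mass error
#'
#' `(observed - theoretical) / theoretical * 1e6`.
#'
#' @param observed,theoretical m/z values; `theoretical` must be positive.
#' @return Signed error in parts per million.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive")
  (observed - theoretical) / theoretical * 1e6
}

#' Test an observed m/z against a ppm window
#'
#' Inclusive test: `|ppm| <= window`.
#' @param observed,theoretical m/z values.
#' @param window Window half-width in ppm.
#' @return Logical.
#' @export
within_ppm <- function(observed, theoretical, window) {
  abs(ppm_error(observed, theoretical)) <= window
}
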