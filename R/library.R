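#' Condense two building blocks into a virtual compound record
#'
#' Product formula is `left + right - loss` (loss is H2O for all built-in
#' rules).  Regiochemistry is ignored: one (left, right, rule) triple
#' yields one record even when regioisomeric products are chemically
#' possible, because their MS/MS spectra are nearly indistinguishable.
#'
#' @param left,right One-row data.frames (or lists) with `name`,
#'   `block_class`, `formula`.
#' @param rule A `condensation_rule` or rule name.
#' @param adducts Character vector of adduct names for which to compute
#'   product m/z values (default `"[M+H]+"`).
#' @return A `compound_record`: list with `compound_id`, `rule`,
#'   `left_block`, `right_block`, `formula` (`mol_formula`),
#'   `monoisotopic_mass` and `adduct_mzs` (named numeric).
#' @examples
#' ca  <- list(name = "CA",  block_class = "bile_acid",  formula = "C24H40O5")
#' gly <- list(name = "Gly", block_class = "amino_acid", formula = "C2H5NO2")
#' condense(ca, gly, "bile_amidate")
#' @export
condense <- function(left, right, rule, adducts = "[M+H]+") {
  if (is.character(rule)) rule <- condensation_rule(rule)
  if (left$block_class != rule$left_class) {
    stop("left block ", sQuote(left$name), " has class ", left$block_class,
         "; rule ", rule$name, " requires ", rule$left_class)
  }
  if (right$block_class != rule$right_class) {
    stop("right block ", sQuote(right$name), " has class ", right$block_class,
         "; rule ", rule$name, " requires ", rule$right_class)
  }
  lf <- parse_formula(left$formula)
  rf <- parse_formula(right$formula)
  product <- formula_subtract(formula_add(lf, rf), rule$loss)
  mass <- monoisotopic_mass(product)
  mzs <- vapply(adducts, function(a) adduct_mz(mass, a), numeric(1))
  names(mzs) <- adducts
  structure(list(
    compound_id = paste(rule$name, left$name, right$name, sep = "|"),
    rule = rule$name,
    left_block = left$name,
    right_block = right$name,
    formula = product,
    monoisotopic_mass = mass,
    left_mass = monoisotopic_mass(lf),
    right_mass = monoisotopic_mass(rf),
    adduct_mzs = mzs
  ), class = "compound_record")
}

#' @export
print.compound_record <- function(x, ...) {
  cat("<compound_record> ", x$compound_id, "  ",
      format_formula(x$formula), "  M = ",
      formatC(x$monoisotopic_mass, digits = 5, format = "f"), " Da\n", sep = "")
  invisible(x)
}

#' Enumerate a virtual combinatorial library
#'
#' Forms every ordered (left, right) pair under a condensation rule.  The
#' record count is `nrow(left_blocks) * nrow(right_blocks)`; formula
#' collisions between distinct pairs (e.g. Ile vs Leu conjugates) are kept
#' as distinct records keyed by the block pair.
#'
#' @param left_blocks,right_blocks `building_blocks` tables (see
#'   [read_building_blocks()]).
#' @param rule A `condensation_rule` or rule name.
#' @param adducts Character vector of adduct names.
#' @return A `compound_library` data.frame with columns `compound_id`,
#'   `rule`, `left_block`, `right_block`, `formula` (Hill string),
#'   `monoisotopic_mass`, and one `mz_<adduct>` column per adduct.  If the
#'   right-block table has a `mass_group` column, it is propagated as
#'   `mass_degenerate_group` to link mass-identical records.
#' @examples
#' bile <- read_building_blocks(bundled_blocks("bile_acids"))
#' aa   <- read_building_blocks(bundled_blocks("amino_acids"))
#' lib  <- enumerate_library(bile, aa, "bile_amidate")
#' nrow(lib)  # 8 x 22 = 176
#' @export
enumerate_library <- function(left_blocks, right_blocks, rule,
                              adducts = "[M+H]+") {
  if (is.character(rule)) rule <- condensation_rule(rule)
  if (nrow(left_blocks) == 0L || nrow(right_blocks) == 0L) {
    stop("building-block tables must be non-empty")
  }
  pairs <- expand.grid(li = seq_len(nrow(left_blocks)),
                       ri = seq_len(nrow(right_blocks)),
                       KEEP.OUT.ATTRS = FALSE)
  # enumerate in left-major order
  pairs <- pairs[order(pairs$li, pairs$ri), ]
  records <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    l <- as.list(left_blocks[pairs$li[k], ])
    r <- as.list(right_blocks[pairs$ri[k], ])
    rec <- tryCatch(condense(l, r, rule, adducts), error = function(e) {
      stop("condensation failed for pair (", l$name, ", ", r$name, "): ",
           conditionMessage(e), call. = FALSE)
    })
    records[[k]] <- rec
  }
  out <- data.frame(
    compound_id = vapply(records, `[[`, character(1), "compound_id"),
    rule = rule$name,
    left_block = vapply(records, `[[`, character(1), "left_block"),
    right_block = vapply(records, `[[`, character(1), "right_block"),
    formula = vapply(records, function(x) format_formula(x$formula),
                     character(1)),
    monoisotopic_mass = vapply(records, `[[`, numeric(1), "monoisotopic_mass"),
    left_mass = vapply(records, `[[`, numeric(1), "left_mass"),
    right_mass = vapply(records, `[[`, numeric(1), "right_mass"),
    stringsAsFactors = FALSE
  )
  for (a in adducts) {
    out[[paste0("mz_", a)]] <- vapply(records, function(x) x$adduct_mzs[[a]],
                                      numeric(1))
  }
  if (!is.null(right_blocks$mass_group)) {
    grp <- right_blocks$mass_group[pairs$ri]
    out$mass_degenerate_group <- ifelse(
      nzchar(grp), paste(out$left_block, grp, sep = "|"), "")
  }
  if (!is.null(left_blocks$hydroxyls)) {
    out$hydroxyls <- left_blocks$hydroxyls[pairs$li]
  }
  rownames(out) <- NULL
  class(out) <- c("compound_library", "data.frame")
  out
}

#' Write / read a compound library as TSV
#'
#' @param lib A `compound_library` data.frame.
#' @param path Output TSV path.
#' @return `path`, invisibly (write); a `compound_library` (read).
#' @export
write_library <- function(lib, path) {
  utils::write.table(lib, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  lib <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  class(lib) <- c("compound_library", "data.frame")
  lib
}
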