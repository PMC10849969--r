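#' Parse a molecular formula in Hill notation
#'
#' Converts a formula string such as `"C24H40O5"` into a named integer
#' vector of element counts (class `mol_formula`).  An omitted count means
#' 1.  Multi-letter symbols (Na, Cl) are recognised greedily: an uppercase
#' letter followed by optional lowercase letters forms the symbol.
#'
#' @param text Formula string, e.g. `"C26H43NO6"`.  The empty-ish formula is
#'   not allowed; use `mol_formula()` for an explicit empty formula.
#' @return A `mol_formula`: named integer vector of counts in Hill order.
#' @examples
#' parse_formula("C24H40O5")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("formula must be a single character string")
  }
  text <- trimws(text)
  if (!nzchar(text)) stop("empty formula string")
  m <- gregexpr("([A-Z][a-z]*)([0-9]*)", text)[[1]]
  toks <- regmatches(text, gregexpr("([A-Z][a-z]*)([0-9]*)", text))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    stop("cannot parse formula: ", sQuote(text))
  }
  sym <- sub("[0-9]*$", "", toks)
  cnt <- sub("^[A-Za-z]+", "", toks)
  cnt <- ifelse(nzchar(cnt), as.integer(cnt), 1L)
  unknown <- setdiff(sym, supported_elements())
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  counts <- tapply(cnt, sym, sum)
  mol_formula(stats::setNames(as.integer(counts), names(counts)))
}

#' Construct a molecular formula from element counts
#'
#' @param counts Named integer vector (element symbol -> count).  Zero
#'   counts are dropped; negative counts are an error.  An empty vector
#'   yields the empty formula (mass 0).
#' @return A `mol_formula` in canonical Hill order.
#' @export
mol_formula <- function(counts = integer(0)) {
  if (length(counts) == 0L) {
    out <- integer(0)
    class(out) <- "mol_formula"
    return(out)
  }
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("counts must be named by element symbol")
  }
  unknown <- setdiff(names(counts), supported_elements())
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  counts <- counts[counts != 0]
  if (any(counts < 0)) {
    stop("negative element count for: ",
         paste(names(counts)[counts < 0], collapse = ", "))
  }
  out <- as.integer(counts)
  names(out) <- names(counts)
  out <- out[hill_order(names(out))]
  class(out) <- "mol_formula"
  out
}

# Hill order: C first, then H, then other elements alphabetically; if no
# carbon, all elements alphabetically.
hill_order <- function(symbols) {
  if ("C" %in% symbols) {
    rest <- sort(setdiff(symbols, c("C", "H")))
    match(c(intersect(c("C", "H"), symbols), rest), symbols)
  } else {
    order(symbols)
  }
}

#' Serialize a formula to Hill notation
#'
#' @param f A `mol_formula`.
#' @return Character scalar, e.g. `"C26H43NO6"`; `""` for the empty formula.
#' @export
format_formula <- function(f) {
  stopifnot(inherits(f, "mol_formula"))
  if (length(f) == 0L) return("")
  paste0(names(f), ifelse(unclass(f) == 1L, "", unclass(f)), collapse = "")
}

#' @export
print.mol_formula <- function(x, ...) {
  cat("<mol_formula> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

#' Add two molecular formulas count-wise
#' @param a,b `mol_formula` objects.
#' @return A `mol_formula`.
#' @export
formula_add <- function(a, b) {
  stopifnot(inherits(a, "mol_formula"), inherits(b, "mol_formula"))
  syms <- union(names(a), names(b))
  counts <- vapply(syms, function(s) {
    sum(c(unclass(a)[s], unclass(b)[s]), na.rm = TRUE)
  }, numeric(1))
  mol_formula(stats::setNames(as.integer(counts), syms))
}

#' Subtract one molecular formula from another
#'
#' Errors if any element count would go negative (the loss is not
#' subtractable), naming the offending element.
#' @param a,b `mol_formula` objects; computes `a - b`.
#' @return A `mol_formula`.
#' @export
formula_subtract <- function(a, b) {
  stopifnot(inherits(a, "mol_formula"), inherits(b, "mol_formula"))
  syms <- union(names(a), names(b))
  counts <- vapply(syms, function(s) {
    av <- unclass(a)[s]; bv <- unclass(b)[s]
    sum(av, na.rm = TRUE) - sum(bv, na.rm = TRUE)
  }, numeric(1))
  if (any(counts < 0)) {
    stop("loss not subtractable; negative count for: ",
         paste(syms[counts < 0], collapse = ", "))
  }
  mol_formula(stats::setNames(as.integer(counts), syms))
}

#' Monoisotopic mass of a molecular formula
#'
#' Sum over elements of count times the mass of the element's most abundant
#' isotope.  The empty formula has mass 0.
#'
#' @param f A `mol_formula`, or a formula string (parsed on the fly).
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass(parse_formula("C24H40O5"))  # cholic acid, 408.28757
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  stopifnot(inherits(f, "mol_formula"))
  if (length(f) == 0L) return(0)
  sum(.element_monoisotopic[names(f)] * unclass(f))
}
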