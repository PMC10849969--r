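#' Built-in condensation rules
#'
#' Three schemes, all losing water on bond formation: `amide` couples a
#' fatty acyl to an amine (N-acyl amides), `ester` couples a fatty acyl to
#' a hydroxy acid (acyl esters), and `bile_amidate` couples a bile acid's
#' C24 carboxyl to an amino acid (conjugated bile acids).
#'
#' @param name One of `"amide"`, `"ester"`, `"bile_amidate"`.
#' @return A `condensation_rule`: list with `name`, `left_class`,
#'   `right_class` and `loss` (a `mol_formula`, H2O by default).
#' @export
condensation_rule <- function(name) {
  rules <- list(
    amide = list(left_class = "fatty_acyl", right_class = "amine"),
    ester = list(left_class = "fatty_acyl", right_class = "hydroxy_acid"),
    bile_amidate = list(left_class = "bile_acid", right_class = "amino_acid")
  )
  if (!name %in% names(rules)) {
    stop("unknown condensation rule: ", sQuote(name))
  }
  out <- c(list(name = name), rules[[name]], list(loss = parse_formula("H2O")))
  class(out) <- "condensation_rule"
  out
}

.block_classes <- c("fatty_acyl", "amine", "hydroxy_acid", "bile_acid",
                    "amino_acid")

#' Read a building-block table
#'
#' Building blocks are the reactants of the combinatorial condensation
#' schemes.  The table must have columns `name`, `block_class` and
#' `formula` (Hill notation); extra columns (e.g. `hydroxyls` for bile-acid
#' cores, `mass_group` linking mass-degenerate blocks such as Ile/Leu) are
#' kept.
#'
#' @param path TSV or CSV file path (delimiter inferred from extension;
#'   `.tsv`/`.txt` tab, otherwise comma).
#' @return A `building_blocks` data.frame with a `monoisotopic_mass` column
#'   appended.
#' @export
read_building_blocks <- function(path) {
  if (!file.exists(path)) stop("building-block table not found: ", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  as_building_blocks(tab)
}

#' Validate and annotate a building-block data.frame
#'
#' @param tab data.frame with columns `name`, `block_class`, `formula`.
#' @return A `building_blocks` data.frame with `monoisotopic_mass` added.
#' @export
as_building_blocks <- function(tab) {
  need <- c("name", "block_class", "formula")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("building-block table lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(tab$name)) {
    stop("duplicate building-block names: ",
         paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "))
  }
  bad <- setdiff(unique(tab$block_class), .block_classes)
  if (length(bad)) {
    stop("unknown block_class: ", paste(bad, collapse = ", "))
  }
  tab$monoisotopic_mass <- vapply(tab$formula,
                                  function(x) monoisotopic_mass(parse_formula(x)),
                                  numeric(1), USE.NAMES = FALSE)
  class(tab) <- c("building_blocks", "data.frame")
  tab
}

#' Paths to the bundled building-block fixture tables
#'
#' Plausible synthetic fixture tables for the three condensation schemes,
#' with the scheme sizes of the combinatorial design (46 fatty acyls, 32
#' amines, 17 hydroxy acids, 8 di/trihydroxylated bile acids, 22 amino
#' acids).  Block identities are representative fixtures, not a transcript
#' of any experimental reagent list; formulas are exact.
#'
#' @param which One of `"fatty_acyls"`, `"amines"`, `"hydroxy_acids"`,
#'   `"bile_acids"`, `"amino_acids"`.
#' @return File path inside the installed package.
#' @export
bundled_blocks <- function(which = c("fatty_acyls", "amines", "hydroxy_acids",
                                     "bile_acids", "amino_acids")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, ".tsv"), package = "revmet")
  if (!nzchar(path)) stop("bundled table not found: ", which)
  path
}
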