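#' Read a sample-metadata table
#'
#' Accepts repository-style metadata headers (e.g. `filename`,
#' `SampleType`, `UBERONBodyPartName`, `DiseaseCommon`, `NCBITaxonomy`) and
#' maps them onto the canonical columns `source_file`, `sample_type`,
#' `body_site`, `phenotype`, `organism`; already-canonical headers pass
#' through.  Extra columns are kept.  Empty cells in controlled-vocabulary
#' columns are replaced with the explicit token `"missing"`.
#'
#' @param path TSV/CSV path (delimiter from extension).
#' @return A `sample_metadata` data.frame keyed by unique `source_file`.
#' @export
read_sample_metadata <- function(path) {
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  as_sample_metadata(tab)
}

#' @rdname read_sample_metadata
#' @param tab A data.frame of per-sample descriptors.
#' @export
as_sample_metadata <- function(tab) {
  aliases <- c(filename = "source_file", SampleType = "sample_type",
               UBERONBodyPartName = "body_site", DiseaseCommon = "phenotype",
               NCBITaxonomy = "organism")
  for (a in names(aliases)) {
    if (a %in% names(tab) && !aliases[[a]] %in% names(tab)) {
      names(tab)[names(tab) == a] <- aliases[[a]]
    }
  }
  if (!"source_file" %in% names(tab)) {
    stop("metadata must have a source_file (or filename) column")
  }
  if (anyDuplicated(tab$source_file)) {
    stop("duplicate source_file in metadata: ",
         paste(unique(tab$source_file[duplicated(tab$source_file)]),
               collapse = ", "))
  }
  vocab_cols <- intersect(c("organism", "sample_type", "body_site",
                            "phenotype", "dataset_id"), names(tab))
  for (cc in vocab_cols) {
    empty <- is.na(tab[[cc]]) | !nzchar(trimws(tab[[cc]]))
    tab[[cc]][empty] <- "missing"
  }
  if ("phenotype" %in% names(tab)) {
    tab$phenotype <- normalize_phenotype(tab$phenotype)
  }
  class(tab) <- c("sample_metadata", "data.frame")
  tab
}

#' Normalize phenotype vocabulary
#'
#' Bundled synonym map for common health-phenotype labels (e.g.
#' `"healthy"` and `"no disease"` both map to `"no disease"`); unmapped
#' labels pass through verbatim.
#'
#' @param x Character vector of phenotype labels.
#' @return Normalized character vector.
#' @export
normalize_phenotype <- function(x) {
  syn <- c("healthy" = "no disease", "no_disease" = "no disease",
           "none" = "no disease", "control" = "no disease",
           "crohn's disease" = "CD", "crohns disease" = "CD",
           "crohn disease" = "CD",
           "ulcerative colitis" = "UC",
           "inflammatory bowel disease" = "IBD",
           "non-ibd" = "nonIBD", "non ibd" = "nonIBD", "non_ibd" = "nonIBD")
  key <- tolower(trimws(x))
  mapped <- syn[key]
  ifelse(is.na(mapped), x, unname(mapped))
}

#' Build a compound-by-sample presence/absence matrix
#'
#' Cell (compound, sample) is `TRUE` iff at least one criteria-passing
#' spectral match of that compound was found in that sample's file.
#' Presence is defined from criteria-passing matches only; there is no
#' softer presence rule.  Matches whose `source_file` is absent from the
#' metadata are collected into an orphan report (attribute
#' `orphan_matches`), never dropped silently.
#'
#' @param matches A `spectral_matches` data.frame ([repository_search()]);
#'   `query_id` identifies the compound.
#' @param metadata A `sample_metadata` table.
#' @param compounds Optional character vector fixing the row universe
#'   (defaults to the compounds seen in `matches`).
#' @return A logical matrix (compounds x samples) of class
#'   `presence_matrix`, with attribute `orphan_matches`.
#' @export
build_presence_matrix <- function(matches, metadata, compounds = NULL) {
  samples <- metadata$source_file
  if (is.null(compounds)) compounds <- sort(unique(matches$query_id))
  mat <- matrix(FALSE, nrow = length(compounds), ncol = length(samples),
                dimnames = list(compounds, samples))
  orphan <- matches[!(matches$source_file %in% samples), , drop = FALSE]
  ok <- matches[matches$source_file %in% samples, , drop = FALSE]
  ok <- ok[ok$query_id %in% compounds, , drop = FALSE]
  if (nrow(ok)) {
    mat[cbind(match(ok$query_id, compounds),
              match(ok$source_file, samples))] <- TRUE
  }
  attr(mat, "orphan_matches") <- orphan
  class(mat) <- c("presence_matrix", class(mat))
  mat
}

#' Per-phenotype detection proportions
#'
#' For each compound and phenotype group: the number of samples in the
#' group, the number in which the compound was detected, and the detected
#' proportion.  Groups with zero samples are excluded with a warning.
#'
#' @param matrix A `presence_matrix`.
#' @param metadata A `sample_metadata` table covering the matrix columns.
#' @param group_by Metadata column defining the groups (default
#'   `"phenotype"`).
#' @return Data.frame with columns `compound_id`, `group`, `n_samples`,
#'   `n_detected`, `proportion`.
#' @export
phenotype_proportions <- function(matrix, metadata, group_by = "phenotype") {
  if (!group_by %in% names(metadata)) {
    stop("metadata lacks grouping column ", sQuote(group_by))
  }
  groups <- metadata[[group_by]][match(colnames(matrix),
                                       metadata$source_file)]
  if (anyNA(groups)) {
    stop("presence-matrix samples missing from metadata: ",
         paste(colnames(matrix)[is.na(groups)], collapse = ", "))
  }
  labels <- unique(groups)
  empty <- setdiff(unique(metadata[[group_by]]), labels)
  if (length(empty)) {
    warning("excluding group(s) with 0 samples in matrix: ",
            paste(empty, collapse = ", "))
  }
  out <- expand.grid(compound_id = rownames(matrix), group = labels,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$n_samples <- NA_integer_; out$n_detected <- NA_integer_
  for (g in labels) {
    cols <- which(groups == g)
    sel <- out$group == g
    out$n_samples[sel] <- length(cols)
    out$n_detected[sel] <- as.integer(
      rowSums(matrix[, cols, drop = FALSE]))[match(out$compound_id[sel],
                                                   rownames(matrix))]
  }
  out$proportion <- out$n_detected / out$n_samples
  out
}

#' Log-scale spectral-match count table
#'
#' Counts spectral matches per (compound, category) cell, where the
#' category is a metadata attribute of the matched sample (e.g. sample
#' type).  Cells with zero matches are absent from the output rather than
#' carrying `-Inf`.
#'
#' @param matches A `spectral_matches` data.frame.
#' @param metadata A `sample_metadata` table.
#' @param category Metadata column to aggregate over (default
#'   `"sample_type"`).
#' @return Data.frame with `compound_id`, `category`, `n_matches`,
#'   `log10_matches`.
#' @export
log_match_counts <- function(matches, metadata, category = "sample_type") {
  if (!category %in% names(metadata)) {
    stop("metadata lacks category column ", sQuote(category))
  }
  cat_of <- metadata[[category]][match(matches$source_file,
                                       metadata$source_file)]
  keep <- !is.na(cat_of)
  agg <- stats::aggregate(
    list(n_matches = rep(1L, sum(keep))),
    by = list(compound_id = matches$query_id[keep], category = cat_of[keep]),
    FUN = sum)
  agg$log10_matches <- log10(agg$n_matches)
  agg[order(agg$compound_id, agg$category), , drop = FALSE]
}
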