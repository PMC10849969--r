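#' Pairwise Wilcoxon rank-sum tests with Benjamini-Hochberg adjustment
#'
#' For each requested pair of group labels, every compound's abundances
#' are compared between the two groups with a two-sided Wilcoxon rank-sum
#' test; p-values are adjusted with the Benjamini-Hochberg step-up
#' procedure *within each group-pair family* (each pair is its own
#' multiple-testing family, matching pairwise reporting of e.g. CD vs
#' non-IBD separately from UC vs non-IBD).
#'
#' The exact null distribution is used for group sizes up to 25 (when the
#' data have no ties); larger groups or tied data use the normal
#' approximation with tie correction.  Constant/all-tied data yield p = 1
#' with the `tied` flag set.
#'
#' @param abundance Numeric matrix or data.frame, compounds x samples.
#' @param groups Named character vector or factor mapping sample (column)
#'   names to group labels, or a vector aligned with the columns.
#' @param pairs List of 2-vectors of group labels, or a character vector
#'   like `"CD:nonIBD"`; default: all label pairs.
#' @param exact_max Largest per-group size for which the exact test is
#'   attempted (default 25).
#' @return Data.frame with columns `compound_id`, `group_a`, `group_b`,
#'   `statistic` (rank-sum W), `p_value`, `q_value`, `direction` (sign of
#'   median difference, a - b), `n_a`, `n_b`, `tied`.
#' @export
pairwise_wilcoxon_bh <- function(abundance, groups, pairs = NULL,
                                 exact_max = 25L) {
  abundance <- as.matrix(abundance)
  if (!is.null(names(groups))) {
    groups <- groups[colnames(abundance)]
    if (anyNA(groups)) stop("groups missing for some abundance columns")
  } else if (length(groups) != ncol(abundance)) {
    stop("groups must be named by sample or aligned with columns")
  }
  groups <- as.character(groups)
  labels <- unique(groups)
  if (is.null(pairs)) {
    pairs <- utils::combn(labels, 2, simplify = FALSE)
  } else if (is.character(pairs)) {
    pairs <- strsplit(pairs, ":", fixed = TRUE)
  }
  out <- list()
  for (pr in pairs) {
    if (length(pr) != 2L) stop("each pair must have exactly 2 labels")
    ia <- which(groups == pr[[1]]); ib <- which(groups == pr[[2]])
    if (length(ia) < 2L || length(ib) < 2L) {
      stop("need >= 2 samples per group for pair ",
           paste(pr, collapse = " vs "))
    }
    res <- lapply(seq_len(nrow(abundance)), function(i) {
      x <- abundance[i, ia]; y <- abundance[i, ib]
      wt <- wilcoxon_two_sided(x, y, exact_max = exact_max)
      data.frame(
        compound_id = rownames(abundance)[i] %||% as.character(i),
        group_a = pr[[1]], group_b = pr[[2]],
        statistic = wt$statistic, p_value = wt$p_value,
        direction = sign(stats::median(x) - stats::median(y)),
        n_a = length(ia), n_b = length(ib), tied = wt$tied,
        stringsAsFactors = FALSE)
    })
    fam <- do.call(rbind, res)
    fam$q_value <- stats::p.adjust(fam$p_value, method = "BH")
    out[[paste(pr, collapse = ":")]] <- fam
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[, c("compound_id", "group_a", "group_b", "statistic", "p_value",
          "q_value", "direction", "n_a", "n_b", "tied")]
}

# Two-sided Wilcoxon rank-sum wrapper: exact for small untied samples,
# normal approximation with continuity and tie correction otherwise;
# degenerate all-tied data -> p = 1.
wilcoxon_two_sided <- function(x, y, exact_max = 25L) {
  if (length(unique(c(x, y))) == 1L) {
    return(list(statistic = length(x) * length(y) / 2, p_value = 1,
                tied = TRUE))
  }
  has_ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- !has_ties && length(x) <= exact_max && length(y) <= exact_max
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = "two.sided", exact = use_exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = min(wt$p.value, 1),
       tied = has_ties)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
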