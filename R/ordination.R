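#' Binary Jaccard distance matrix between samples
#'
#' `d(x, y) = 1 - |x AND y| / |x OR y|` on the boolean compound columns of
#' a presence matrix.  Samples detecting zero compounds are dropped before
#' the computation (Jaccard is undefined for two empty sets); the dropped
#' sample ids are recorded in attribute `dropped_samples`.
#'
#' @param matrix A `presence_matrix` (compounds x samples) or any logical
#'   matrix with sample columns.
#' @return A symmetric `dist`-convertible numeric matrix of distances with
#'   zero diagonal, attribute `dropped_samples`.
#' @export
jaccard_matrix <- function(matrix) {
  m <- unclass(matrix)
  attr(m, "orphan_matches") <- NULL
  storage.mode(m) <- "double"
  nonzero <- colSums(m) > 0
  dropped <- colnames(m)[!nonzero]
  m <- m[, nonzero, drop = FALSE]
  if (ncol(m) < 2L) stop("need at least 2 non-empty samples")
  inter <- crossprod(m)                      # |x AND y|
  sizes <- diag(inter)
  uni <- outer(sizes, sizes, "+") - inter    # |x OR y|
  d <- 1 - inter / uni
  diag(d) <- 0
  attr(d, "dropped_samples") <- dropped
  d
}

#' Principal coordinates analysis (classical multidimensional scaling)
#'
#' Double-centers `-0.5 * D^2`, eigendecomposes, and returns coordinates
#' scaled by the square root of the positive eigenvalues.  Negative
#' eigenvalues (non-Euclidean distances) are reported but their axes are
#' omitted.  On Euclidean-embeddable distances the configuration
#' reproduces the input distances exactly.
#'
#' @param dist Symmetric distance matrix with zero diagonal (a matrix or
#'   `dist` object).
#' @param k Number of axes to return (default: all positive-eigenvalue
#'   axes).
#' @return An `ordination_result`: list with `coordinates` (samples x
#'   axes), `eigenvalues` (all, sorted descending), and
#'   `proportion_explained` (per returned axis, relative to the sum of
#'   positive eigenvalues).
#' @export
pcoa <- function(dist, k = NULL) {
  d <- as.matrix(dist)
  if (nrow(d) != ncol(d) || !isTRUE(all.equal(d, t(d), tolerance = 1e-10))) {
    stop("distance matrix must be symmetric")
  }
  if (any(abs(diag(d)) > 1e-12)) stop("distance matrix diagonal must be zero")
  n <- nrow(d)
  j <- diag(n) - matrix(1 / n, n, n)
  b <- -0.5 * j %*% (d^2) %*% j
  b <- (b + t(b)) / 2
  eig <- eigen(b, symmetric = TRUE)
  values <- eig$values
  pos <- which(values > max(max(abs(values)) * 1e-9, 1e-12))
  if (is.null(k)) k <- length(pos)
  k <- min(k, length(pos))
  axes <- pos[seq_len(k)]
  if (k == 0L) {
    coords <- matrix(numeric(0), nrow = n, ncol = 0,
                     dimnames = list(rownames(d), NULL))
  } else {
    coords <- eig$vectors[, axes, drop = FALSE] %*%
      diag(sqrt(values[axes]), nrow = k)
    rownames(coords) <- rownames(d)
    colnames(coords) <- paste0("PCo", seq_len(k))
  }
  pos_sum <- sum(values[values > 0])
  structure(list(
    coordinates = coords,
    eigenvalues = values,
    proportion_explained = if (pos_sum > 0) values[axes] / pos_sum
      else numeric(0),
    negative_eigenvalues = values[values < 0]
  ), class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("<ordination_result> %d samples, %d axes (%s%% explained)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              paste(round(100 * x$proportion_explained, 1), collapse = ", ")))
  invisible(x)
}
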