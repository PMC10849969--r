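#' Theoretical isotope envelope of a molecular formula
#'
#' Computes the isotopologue distribution aggregated by nominal-mass shift
#' (A, A+1, A+2, ...), the unit-mass binning used by Skyline-style isotope
#' dot products.  Per-element isotope distributions are convolved exactly
#' (element powers by repeated squaring); each bin records the
#' abundance-weighted mean isotopologue mass and the summed probability.
#' Abundances are base-peak normalized (max = 1).
#'
#' @param f A `mol_formula` or formula string.
#' @param n_peaks Number of envelope entries to keep (>= 1), starting at the
#'   all-most-abundant-isotope (A) peak.
#' @return An `isotope_envelope`: data.frame with columns `mz` (Da,
#'   neutral isotopologue mass) and `abundance` (base peak = 1), ordered by
#'   increasing m/z.
#' @examples
#' isotope_envelope("C1", 2)   # A+1/A ratio = 0.0107/0.9893
#' @export
isotope_envelope <- function(f, n_peaks) {
  if (is.character(f)) f <- parse_formula(f)
  stopifnot(inherits(f, "mol_formula"))
  if (!is.numeric(n_peaks) || n_peaks < 1) stop("n_peaks must be >= 1")
  n_peaks <- as.integer(n_peaks)
  kmax <- n_peaks + 3L  # carry a small margin through the convolutions

  # empty formula: point mass at shift 0
  dist <- list(p = c(1, numeric(kmax - 1L)), m = numeric(kmax))
  for (el in names(f)) {
    tab <- .element_isotopes[[el]]
    if (is.null(tab)) stop("no isotope data for element: ", el)
    base <- list(
      p = shift_vector(tab$abundance / sum(tab$abundance), tab$shift, kmax),
      m = shift_vector(tab$mass, tab$shift, kmax)
    )
    dist <- conv_shift(dist, element_power(base, unclass(f)[[el]], kmax), kmax)
  }

  keep <- which(dist$p > 0)
  keep <- keep[keep <= n_peaks]
  env <- data.frame(mz = dist$m[keep], abundance = dist$p[keep])
  env$abundance <- env$abundance / max(env$abundance)
  class(env) <- c("isotope_envelope", "data.frame")
  env
}

# Place values at 1-based positions shift+1 in a length-kmax vector.
shift_vector <- function(values, shifts, kmax) {
  out <- numeric(kmax)
  idx <- shifts + 1L
  ok <- idx <= kmax
  out[idx[ok]] <- values[ok]
  out
}

# Convolve two shift-indexed distributions tracking per-bin mean mass.
# p: probability per shift bin; m: conditional mean mass per bin.
conv_shift <- function(a, b, kmax) {
  p <- numeric(kmax)
  msum <- numeric(kmax)
  for (i in seq_len(kmax)) {
    if (a$p[i] == 0) next
    jmax <- kmax - i + 1L
    j <- seq_len(jmax)
    w <- a$p[i] * b$p[j]
    p[i + j - 1L] <- p[i + j - 1L] + w
    msum[i + j - 1L] <- msum[i + j - 1L] + w * (a$m[i] + b$m[j])
  }
  m <- ifelse(p > 0, msum / p, 0)
  list(p = p, m = m)
}

# n-fold self-convolution by repeated squaring.
element_power <- function(base, n, kmax) {
  result <- list(p = c(1, numeric(kmax - 1L)), m = numeric(kmax))
  sq <- base
  while (n > 0) {
    if (n %% 2 == 1) result <- conv_shift(result, sq, kmax)
    n <- n %/% 2
    if (n > 0) sq <- conv_shift(sq, sq, kmax)
  }
  result
}

#' Isotope dot product between two envelopes
#'
#' Normalized dot product of abundance vectors aligned by isotopologue
#' index (A, A+1, ...) and truncated to the common length.  This is the
#' "idotp" statistic used to score an observed envelope against the one
#' predicted from a molecular formula.
#'
#' @param theoretical,observed `isotope_envelope` objects or plain numeric
#'   abundance vectors (index 1 = A peak).
#' @return Dot product in \[0, 1\].
#' @export
isotope_dot_product <- function(theoretical, observed) {
  a <- envelope_abundance(theoretical)
  b <- envelope_abundance(observed)
  if (length(a) == 0L || length(b) == 0L) stop("empty isotope envelope")
  n <- min(length(a), length(b))
  a <- a[seq_len(n)]; b <- b[seq_len(n)]
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("zero-norm abundance vector")
  sum(a * b) / (na * nb)
}

envelope_abundance <- function(x) {
  if (inherits(x, "isotope_envelope") || is.data.frame(x)) x$abundance
  else as.numeric(x)
}
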