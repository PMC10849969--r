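# Independent oracles and fixture generators used across the test suite.
# Each oracle reimplements the checked quantity by a different route than
# the package (hand-entered constants, exhaustive enumeration, closed
# forms) so that agreement is evidence, not tautology.

# --- element-mass summation oracle (hand-entered IUPAC/AME values) -------
.oracle_element_mass <- c(
  C = 12.0, H = 1.00782503223, N = 14.00307400443, O = 15.99491461957,
  S = 31.9720711744, Na = 22.9897692820, Cl = 34.968852682,
  P = 30.97376199842
)

oracle_mass <- function(formula_string) {
  toks <- regmatches(formula_string,
                     gregexpr("[A-Z][a-z]*[0-9]*", formula_string))[[1]]
  total <- 0
  for (tk in toks) {
    sym <- gsub("[0-9]", "", tk)
    n <- sub("^[A-Za-z]+", "", tk)
    n <- if (nzchar(n)) as.integer(n) else 1L
    total <- total + .oracle_element_mass[[sym]] * n
  }
  total
}

# --- brute-force isotopologue envelope oracle ----------------------------
# Enumerates per-element isotope compositions (multinomial), crosses them
# over elements, and aggregates probability mass by nominal shift.
.oracle_isotopes <- list(
  H = list(mass = c(1.00782503223, 2.01410177812),
           ab = c(0.999885, 0.000115), shift = c(0L, 1L)),
  C = list(mass = c(12.0, 13.00335483507), ab = c(0.9893, 0.0107),
           shift = c(0L, 1L)),
  N = list(mass = c(14.00307400443, 15.00010889888),
           ab = c(0.99636, 0.00364), shift = c(0L, 1L)),
  O = list(mass = c(15.99491461957, 16.99913175650, 17.99915961286),
           ab = c(0.99757, 0.00038, 0.00205), shift = c(0L, 1L, 2L)),
  S = list(mass = c(31.9720711744, 32.9714589098, 33.967867004, 35.96708071),
           ab = c(0.9499, 0.0075, 0.0425, 0.0001), shift = c(0L, 1L, 2L, 4L)),
  Cl = list(mass = c(34.968852682, 36.965902602), ab = c(0.7576, 0.2424),
            shift = c(0L, 2L))
)

# all compositions (n1..nk) with sum n
compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, 1, 1))
  out <- list()
  for (i in 0:n) {
    sub <- compositions(n - i, k - 1L)
    out[[length(out) + 1L]] <- cbind(i, sub)
  }
  do.call(rbind, out)
}

oracle_envelope <- function(formula_string, n_peaks) {
  toks <- regmatches(formula_string,
                     gregexpr("[A-Z][a-z]*[0-9]*", formula_string))[[1]]
  per_element <- list()
  for (tk in toks) {
    sym <- gsub("[0-9]", "", tk)
    n <- sub("^[A-Za-z]+", "", tk)
    n <- if (nzchar(n)) as.integer(n) else 1L
    iso <- .oracle_isotopes[[sym]]
    ab <- iso$ab / sum(iso$ab)
    comp <- compositions(n, length(ab))
    logcoef <- lgamma(n + 1) - rowSums(lgamma(comp + 1))
    prob <- exp(logcoef + comp %*% log(ab))
    per_element[[length(per_element) + 1L]] <- data.frame(
      prob = as.numeric(prob),
      mass = as.numeric(comp %*% iso$mass),
      shift = as.integer(comp %*% iso$shift))
  }
  # cross product over elements
  acc <- data.frame(prob = 1, mass = 0, shift = 0L)
  for (pe in per_element) {
    acc <- do.call(rbind, lapply(seq_len(nrow(pe)), function(i) {
      data.frame(prob = acc$prob * pe$prob[i],
                 mass = acc$mass + pe$mass[i],
                 shift = acc$shift + pe$shift[i])
    }))
    acc <- stats::aggregate(
      cbind(prob, wmass = prob * mass) ~ shift, data = acc, FUN = sum)
    acc$mass <- acc$wmass / acc$prob
    acc$wmass <- NULL
  }
  acc <- acc[order(acc$shift), ]
  acc <- acc[acc$shift < n_peaks, ]
  data.frame(mz = acc$mass, abundance = acc$prob / max(acc$prob))
}

# --- exhaustive maximum-weight one-to-one assignment oracle --------------
oracle_assignment_weight <- function(query, target, tol) {
  nq <- length(query$mz); nt <- length(target$mz)
  cand <- which(outer(query$mz, target$mz,
                      function(a, b) abs(a - b) <= tol), arr.ind = TRUE)
  best <- 0
  rec <- function(i, used_t, total) {
    if (total > best) best <<- total
    if (i > nq) return(invisible())
    rec(i + 1L, used_t, total)  # leave query peak i unpaired
    for (k in which(cand[, 1] == i)) {
      j <- cand[k, 2]
      if (!used_t[j]) {
        used_t[j] <- TRUE
        rec(i + 1L, used_t, total + query$intensity[i] * target$intensity[j])
        used_t[j] <- FALSE
      }
    }
  }
  rec(1L, logical(nt), 0)
  best
}

greedy_pair_weight <- function(query, target, tol) {
  p <- pair_peaks(query, target, tol)
  if (nrow(p) == 0L) return(0)
  sum(query$intensity[p$query_idx] * target$intensity[p$target_idx])
}

# --- random spectrum generator (uses current RNG state) ------------------
random_spectrum <- function(id = "q", n = NULL, mz_range = c(100, 500),
                            precursor = 400) {
  if (is.null(n)) n <- sample(3:8, 1)
  ms_spectrum(id, precursor_mz = precursor,
              mz = sort(runif(n, mz_range[1], mz_range[2])),
              intensity = runif(n, 1, 100),
              precursor_intensity = runif(1, 1e3, 1e5))
}

# --- small bile-amidate library reused by simulator tests ----------------
small_bile_library <- function(n = 10) {
  ba <- read_building_blocks(bundled_blocks("bile_acids"))
  aa <- read_building_blocks(bundled_blocks("amino_acids"))
  lib <- enumerate_library(ba, aa, "bile_amidate")
  lib[seq_len(n), , drop = FALSE]
}

# occurrence matrix helper: first `n_planted` compounds get (p_case,
# p_control), the rest get p_null in both groups
planted_occurrence <- function(lib, n_planted, p_case, p_control,
                               p_null = 0.3, groups = c("CD", "nonIBD")) {
  occ <- matrix(p_null, nrow(lib), 2,
                dimnames = list(lib$compound_id, groups))
  occ[seq_len(n_planted), 1] <- p_case
  occ[seq_len(n_planted), 2] <- p_control
  occ
}
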