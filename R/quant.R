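#' Internal-standard response ratio
#'
#' Analyte peak area divided by the area of its (deuterated) internal
#' standard.  A zero analyte area yields ratio 0 with the `below_signal`
#' attribute set.
#'
#' @param analyte_area Analyte peak area (>= 0).
#' @param is_area Internal-standard peak area (> 0).
#' @return Numeric ratio; attribute `below_signal` is `TRUE` when the
#'   analyte area is 0.
#' @export
normalize_to_internal_standard <- function(analyte_area, is_area) {
  if (any(is_area <= 0)) stop("internal-standard area must be positive")
  if (any(analyte_area < 0)) stop("analyte area must be non-negative")
  ratio <- analyte_area / is_area
  attr(ratio, "below_signal") <- analyte_area == 0
  ratio
}

#' Fit a linear calibration curve
#'
#' Ordinary least squares of response ratio on concentration ("linear fit
#' to determine the slope and y intercept").  An optional 1/x weighted
#' mode is available but off by default.
#'
#' @param points Data.frame with columns `concentration` (uM, strictly
#'   positive, not all identical) and `response`; at least 3 points.
#' @param analyte Analyte identifier stored on the curve.
#' @param weighting `"none"` (default) or `"1/x"`.
#' @return A `calibration_curve`: list with `analyte`, `points`, `slope`,
#'   `intercept`, `r_squared`.
#' @export
fit_calibration <- function(points, analyte = NA_character_,
                            weighting = c("none", "1/x")) {
  weighting <- match.arg(weighting)
  if (!all(c("concentration", "response") %in% names(points))) {
    stop("points must have columns concentration and response")
  }
  if (nrow(points) < 3L) stop("calibration requires at least 3 points")
  if (any(points$concentration <= 0)) {
    stop("calibration concentrations must be strictly positive")
  }
  if (length(unique(points$concentration)) < 2L) {
    stop("calibration concentrations must not all be identical")
  }
  w <- if (weighting == "1/x") 1 / points$concentration else
    rep(1, nrow(points))
  fit <- stats::lm(response ~ concentration, data = points, weights = w)
  co <- stats::coef(fit)
  ss_res <- sum(w * stats::residuals(fit)^2)
  ss_tot <- sum(w * (points$response -
                       stats::weighted.mean(points$response, w))^2)
  structure(list(
    analyte = analyte,
    points = points,
    slope = unname(co[["concentration"]]),
    intercept = unname(co[["(Intercept)"]]),
    r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  ), class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve> %s: response = %.6g * conc + %.6g (r2 = %.4f, %d pts)\n",
    x$analyte, x$slope, x$intercept, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' Back-calculate a concentration and convert to mg per kg of sample
#'
#' Inverts the calibration curve (`conc_uM = (ratio - intercept) /
#' slope`), then converts to mg of analyte per kg of original sample:
#' `mg/kg = conc_uM * 1e-6 mol/L * molecular_mass g/mol * extraction
#' volume (L) * 1e3 mg/g / (sample mass in kg)`.  A back-calculated
#' concentration below zero is reported as 0 with the `below_lod` flag;
#' values below the lowest calibration point are flagged, not censored.
#'
#' @param response_ratio Internal-standard-normalized response.
#' @param curve A `calibration_curve` with non-zero slope.
#' @param sample_mass_g Mass of the original sample in grams (> 0).
#' @param extraction_volume_mL Extraction solvent volume in mL.
#' @param molecular_mass Analyte molecular mass in Da (g/mol).
#' @param sample_id Optional sample identifier.
#' @return A `quant_result`: list with `analyte`, `sample_id`,
#'   `concentration_uM`, `concentration_mg_per_kg`, `below_lod`,
#'   `below_range`.
#' @export
quantify <- function(response_ratio, curve, sample_mass_g,
                     extraction_volume_mL, molecular_mass,
                     sample_id = NA_character_) {
  stopifnot(inherits(curve, "calibration_curve"))
  if (curve$slope == 0) stop("calibration slope is zero; cannot invert")
  if (sample_mass_g <= 0) stop("sample mass must be positive")
  if (extraction_volume_mL <= 0) stop("extraction volume must be positive")
  conc_uM <- (response_ratio - curve$intercept) / curve$slope
  below_lod <- conc_uM < 0
  if (below_lod) conc_uM <- 0
  below_range <- conc_uM < min(curve$points$concentration)
  mg_per_kg <- conc_uM * 1e-6 * molecular_mass *
    (extraction_volume_mL / 1000) * 1e3 / (sample_mass_g / 1000)
  structure(list(
    analyte = curve$analyte,
    sample_id = sample_id,
    concentration_uM = conc_uM,
    concentration_mg_per_kg = mg_per_kg,
    below_lod = below_lod,
    below_range = below_range
  ), class = "quant_result")
}
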