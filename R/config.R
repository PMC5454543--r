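#' Pipeline configuration
#'
#' All tunable knobs of the conditioning chain, the metric definitions and
#' the agreement battery, with the package defaults. Units are stated per
#' field.
#'
#' @param span_ml_mm,span_ap_mm Board sensor spans (mm).
#' @param filter_order,filter_cutoff_hz Butterworth low-pass design (order,
#'   Hz).
#' @param resample_rate_hz Uniform resampling target (Hz).
#' @param load_floor_n Minimum admissible load / |Fz| (N).
#' @param surface_offset_dz_mm Plate moment-origin to contact-surface
#'   distance (mm); the stacked-board height when a board sits on the plate.
#' @param ellipse_level Prediction-ellipse coverage level (default 0.95).
#' @param ellipse_scale `"chi2"` (large-sample chi-square(2) quantile) or
#'   `"f-small-sample"` (`2(n+1)(n-1)/(n(n-2)) * F(level; 2, n-2)`).
#' @param dispersion_denominator `"n"` (population RMS about the mean) or
#'   `"n-1"` (sample SD).
#' @param icc_mode,spearman_mode `"trial"` (subject x trial rows) or
#'   `"subject_mean"` (means over trials).
#' @param friedman_mode `"subject_mean"` or `"trial"`.
#' @param loa_multiplier Half-width multiplier of the limits of agreement
#'   (default 1.96, the 95% normal convention).
#' @return Object of class `run_config` (nested list).
#' @export
run_config <- function(span_ml_mm = 433, span_ap_mm = 238,
                       filter_order = 2, filter_cutoff_hz = 12,
                       resample_rate_hz = 1000,
                       load_floor_n = 50,
                       surface_offset_dz_mm = 53,
                       ellipse_level = 0.95,
                       ellipse_scale = c("chi2", "f-small-sample"),
                       dispersion_denominator = c("n", "n-1"),
                       icc_mode = c("trial", "subject_mean"),
                       friedman_mode = c("subject_mean", "trial"),
                       spearman_mode = c("trial", "subject_mean"),
                       loa_multiplier = 1.96) {
  ellipse_scale <- match.arg(ellipse_scale)
  dispersion_denominator <- match.arg(dispersion_denominator)
  icc_mode <- match.arg(icc_mode)
  friedman_mode <- match.arg(friedman_mode)
  spearman_mode <- match.arg(spearman_mode)
  if (resample_rate_hz <= 2 * filter_cutoff_hz) {
    sa_validation_error("resample rate must exceed twice the filter cutoff")
  }
  structure(list(
    geometry = list(span_ml_mm = span_ml_mm, span_ap_mm = span_ap_mm),
    filter = list(order = filter_order, cutoff_hz = filter_cutoff_hz),
    resample = list(rate_hz = resample_rate_hz),
    load_floor_n = load_floor_n,
    surface_offset_dz_mm = surface_offset_dz_mm,
    ellipse = list(level = ellipse_level, scale = ellipse_scale),
    dispersion = list(denominator = dispersion_denominator),
    agreement = list(icc_mode = icc_mode, friedman_mode = friedman_mode,
                     spearman_mode = spearman_mode,
                     loa_multiplier = loa_multiplier)
  ), class = "run_config")
}
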