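# The nine stabilometric parameters of a conditioned CoP trajectory.
#
# dot  : total sway path length (mm)
# area : 95% prediction ellipse area (mm^2)
# rms  : per-axis dispersion about the mean position (mm)
# adcp : per-axis amplitude, max - min (mm)
# mv   : per-axis mean velocity (mm/s)
# tmv  : total mean velocity = dot / duration (mm/s)

#' Total sway path length (DOT)
#'
#' Cumulative Euclidean path of the CoP:
#' `sum over i of sqrt(d_ap_i^2 + d_ml_i^2)`.
#'
#' @param traj A [cop_trajectory()].
#' @return Path length in mm.
#' @export
sway_path_length <- function(traj) {
  if (traj$n < 2) sa_too_short_error("need >= 2 samples")
  sum(sqrt(diff(traj$ap)^2 + diff(traj$ml)^2))
}

#' Prediction ellipse of the CoP point cloud
#'
#' Bivariate-normal prediction ellipse at `level`: centred at the sample
#' mean, shaped by the sample covariance S (denominator n-1), with squared
#' Mahalanobis radius `c`. By default `c` is the chi-square(2) quantile at
#' `level` (large-sample prediction ellipse, c = 5.9915 at 0.95); the
#' `"f-small-sample"` alternative uses
#' `c = 2(n+1)(n-1)/(n(n-2)) * F(level; 2, n-2)`.
#'
#' @param ap,ml Coordinate vectors (mm), length n >= 3.
#' @param level Coverage level.
#' @param scale `"chi2"` or `"f-small-sample"`.
#' @return List with `center` (length-2, ap/ml), `cov` (2x2, mm^2),
#'   `scale_c`, `area` (`pi * c * sqrt(det S)`, mm^2) and `n`.
#' @export
prediction_ellipse <- function(ap, ml, level = 0.95,
                               scale = c("chi2", "f-small-sample")) {
  scale <- match.arg(scale)
  n <- length(ap)
  if (n < 3 || length(ml) != n) {
    sa_too_short_error("need >= 3 paired samples for an ellipse")
  }
  S <- stats::cov(cbind(ap, ml))
  cc <- if (scale == "chi2") {
    stats::qchisq(level, df = 2)
  } else {
    2 * (n + 1) * (n - 1) / (n * (n - 2)) * stats::qf(level, 2, n - 2)
  }
  d <- det(S)
  if (!is.finite(d) || d < 0) d <- 0
  list(center = c(ap = mean(ap), ml = mean(ml)), cov = S, scale_c = cc,
       area = pi * cc * sqrt(d), n = n)
}

#' Area of the 95% prediction ellipse
#'
#' `pi * c * sqrt(lambda1 * lambda2)` with `lambda` the eigenvalues of the
#' sample covariance of (ap, ml); degenerate clouds (zero covariance) give 0.
#'
#' @param traj A [cop_trajectory()].
#' @inheritParams prediction_ellipse
#' @return Area in mm^2.
#' @export
prediction_ellipse_area <- function(traj, level = 0.95,
                                    scale = c("chi2", "f-small-sample")) {
  prediction_ellipse(traj$ap, traj$ml, level = level, scale = scale)$area
}

#' Per-axis dispersion about the mean position (RMS)
#'
#' Root-mean-square deviation from the series mean. The population form
#' (denominator n, the default) and the sample-SD form (n-1) differ
#' negligibly at posturographic sample counts but the convention is
#' explicit.
#'
#' @param series One-axis displacement series (mm), length >= 2.
#' @param denominator `"n"` or `"n-1"`.
#' @return Dispersion in mm.
#' @export
axis_dispersion <- function(series, denominator = c("n", "n-1")) {
  denominator <- match.arg(denominator)
  n <- length(series)
  if (n < 2) sa_too_short_error("need >= 2 samples")
  ss <- sum((series - mean(series))^2)
  sqrt(ss / if (denominator == "n") n else n - 1)
}

#' Per-axis amplitude (AdCP): max minus min
#'
#' @param series One-axis displacement series (mm), length >= 1.
#' @return Amplitude in mm.
#' @export
axis_amplitude <- function(series) {
  if (length(series) < 1) sa_too_short_error("empty series")
  max(series) - min(series)
}

#' Per-axis mean velocity (MV)
#'
#' Total absolute one-axis path divided by the trial duration:
#' `sum(|dx_i|) / ((n-1)/rate)`.
#'
#' @param series One-axis displacement series (mm), length >= 2.
#' @param rate Sampling rate (Hz).
#' @return Mean velocity in mm/s.
#' @export
axis_mean_velocity <- function(series, rate) {
  n <- length(series)
  if (n < 2) sa_too_short_error("need >= 2 samples")
  sum(abs(diff(series))) / ((n - 1) / rate)
}

#' Total mean velocity (TMV)
#'
#' Total sway path divided by trial duration; satisfies
#' `tmv * duration == dot` exactly.
#'
#' @param traj A [cop_trajectory()].
#' @return Mean velocity in mm/s.
#' @export
total_mean_velocity <- function(traj) {
  sway_path_length(traj) / traj$duration
}

#' All nine stabilometric parameters of one trial
#'
#' @param traj A conditioned [cop_trajectory()] (resample -> filter -> here).
#' @param ellipse_level,ellipse_scale Passed to [prediction_ellipse_area()].
#' @param dispersion_denominator Passed to [axis_dispersion()].
#' @return Object of class `sway_metrics`: named list with the nine fields
#'   of [metric_names()] plus `duration` and `n`.
#' @export
compute_sway_metrics <- function(traj, ellipse_level = 0.95,
                                 ellipse_scale = "chi2",
                                 dispersion_denominator = "n") {
  if (traj$n < 3) sa_too_short_error("need >= 3 samples for the metric set")
  dot <- sway_path_length(traj)
  structure(list(
    dot = dot,
    area = prediction_ellipse_area(traj, level = ellipse_level,
                                   scale = ellipse_scale),
    rms_ap = axis_dispersion(traj$ap, denominator = dispersion_denominator),
    rms_ml = axis_dispersion(traj$ml, denominator = dispersion_denominator),
    adcp_ap = axis_amplitude(traj$ap),
    adcp_ml = axis_amplitude(traj$ml),
    mv_ap = axis_mean_velocity(traj$ap, traj$rate),
    mv_ml = axis_mean_velocity(traj$ml, traj$rate),
    tmv = dot / traj$duration,
    duration = traj$duration,
    n = traj$n
  ), class = "sway_metrics")
}

#' @export
print.sway_metrics <- function(x, ...) {
  cat("<sway_metrics>\n")
  for (m in metric_names()) {
    unit <- switch(m, area = "mm^2", mv_ap = , mv_ml = , tmv = "mm/s", "mm")
    cat(sprintf("  %-8s %10.4f %s\n", m, x[[m]], unit))
  }
  invisible(x)
}

#' @export
as.data.frame.sway_metrics <- function(x, ...) {
  as.data.frame(x[metric_names()], ...)
}
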