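# Raw recordings -> conditioned CoP trajectories.
#
# Conventions (fixed, documented here and in the vignette): AP positive
# toward anterior (top sensor row), ML positive toward the subject's right
# (right sensor column); CoP origin at the board/plate centre; CoP in mm.

#' Quad-load-cell board geometry
#'
#' Distance between the left/right sensor columns (`span_ml_mm`) and the
#' top/bottom sensor rows (`span_ap_mm`). Defaults are commonly published
#' teardown values for the consumer board this pipeline targets.
#'
#' @param span_ml_mm,span_ap_mm Sensor spans in mm, both > 0.
#' @return Object of class `board_geometry`.
#' @export
board_geometry <- function(span_ml_mm = 433, span_ap_mm = 238) {
  if (!is.finite(span_ml_mm) || !is.finite(span_ap_mm) ||
      span_ml_mm <= 0 || span_ap_mm <= 0) {
    sa_validation_error("sensor spans must be positive")
  }
  structure(list(span_ml_mm = span_ml_mm, span_ap_mm = span_ap_mm),
            class = "board_geometry")
}

#' Uniformly sampled CoP trajectory
#'
#' @param ap,ml CoP displacement series in mm, equal length >= 2, finite.
#' @param rate Sampling rate in Hz.
#' @param start_time Acquisition-clock time of the first sample (s).
#' @return Object of class `cop_trajectory` with fields `ap`, `ml`, `rate`,
#'   `start_time`, `n` and `duration` (`(n-1)/rate` seconds).
#' @export
cop_trajectory <- function(ap, ml, rate, start_time = 0) {
  ap <- as.numeric(ap); ml <- as.numeric(ml)
  if (length(ap) != length(ml)) {
    sa_validation_error("ap and ml must have equal length")
  }
  if (length(ap) < 2) sa_too_short_error("trajectory needs >= 2 samples")
  if (!all(is.finite(ap)) || !all(is.finite(ml))) {
    sa_validation_error("trajectory values must be finite")
  }
  if (!is.finite(rate) || rate <= 0) sa_validation_error("rate must be > 0")
  n <- length(ap)
  structure(list(ap = ap, ml = ml, rate = rate, start_time = start_time,
                 n = n, duration = (n - 1) / rate),
            class = "cop_trajectory")
}

#' @export
print.cop_trajectory <- function(x, ...) {
  cat(sprintf("<cop_trajectory> %d samples @ %g Hz (%.3f s)\n  ap: [%.2f, %.2f] mm, ml: [%.2f, %.2f] mm\n",
              x$n, x$rate, x$duration, min(x$ap), max(x$ap), min(x$ml), max(x$ml)))
  invisible(x)
}

#' CoP from four corner loads (moment balance)
#'
#' Quad-cell moment balance about the board centre: with total load
#' `S = TL+TR+BL+BR`,
#' `ml = (span_ml/2) * ((TR+BR) - (TL+BL)) / S` and
#' `ap = (span_ap/2) * ((TL+TR) - (BL+BR)) / S`.
#' Scale-invariant in the total load; the CoP always lies inside the sensor
#' rectangle (weighted mean of the four sensor positions).
#'
#' @param rec Board [trial_recording()].
#' @param geom [board_geometry()].
#' @param load_floor_n Minimum admissible total load (N); any sample below it
#'   signals the subject stepped off the board and raises a low-load error
#'   with the first offending sample index.
#' @return Data frame with columns `t` (s), `ap`, `ml` (mm).
#' @export
cop_from_corner_loads <- function(rec, geom = board_geometry(),
                                  load_floor_n = 50) {
  if (!inherits(rec, "trial_recording") || rec$kind != "board") {
    sa_validation_error("rec must be a board trial_recording")
  }
  ch <- rec$channels
  total <- ch[, "TL"] + ch[, "TR"] + ch[, "BL"] + ch[, "BR"]
  low <- which(total < load_floor_n)
  if (length(low) > 0) {
    sa_low_load_error(sprintf(
      "total load %.1f N below floor %.1f N at sample %d",
      total[low[1]], load_floor_n, low[1]), index = low[1])
  }
  ml <- (geom$span_ml_mm / 2) * ((ch[, "TR"] + ch[, "BR"]) -
                                 (ch[, "TL"] + ch[, "BL"])) / total
  ap <- (geom$span_ap_mm / 2) * ((ch[, "TL"] + ch[, "TR"]) -
                                 (ch[, "BL"] + ch[, "BR"])) / total
  data.frame(t = rec$timestamps, ap = ap, ml = ml)
}

#' CoP from a force/moment wrench
#'
#' Standard force-plate CoP with transport to the contact surface a distance
#' `dz` above the plate's moment origin:
#' `ml = (-My - Fx*dz)/Fz`, `ap = (Mx - Fy*dz)/Fz` (SI units internally,
#' returned in mm). When a board is stacked on the plate, `dz` is the board
#' height (default 0 = plate top surface).
#'
#' @param rec Force-plate [trial_recording()].
#' @param surface_offset_dz_mm Moment-origin-to-surface distance in mm.
#' @param load_floor_n Minimum admissible |Fz| (N).
#' @return Data frame with columns `t` (s), `ap`, `ml` (mm).
#' @export
cop_from_wrench <- function(rec, surface_offset_dz_mm = 0, load_floor_n = 50) {
  if (!inherits(rec, "trial_recording") || rec$kind != "forceplate") {
    sa_validation_error("rec must be a forceplate trial_recording")
  }
  ch <- rec$channels
  fz <- ch[, "Fz"]
  low <- which(abs(fz) < load_floor_n)
  if (length(low) > 0) {
    sa_low_load_error(sprintf(
      "|Fz| = %.1f N below floor %.1f N at sample %d",
      abs(fz[low[1]]), load_floor_n, low[1]), index = low[1])
  }
  dz <- surface_offset_dz_mm / 1000
  ml_m <- (-ch[, "My"] - ch[, "Fx"] * dz) / fz
  ap_m <- (ch[, "Mx"] - ch[, "Fy"] * dz) / fz
  data.frame(t = rec$timestamps, ap = ap_m * 1000, ml = ml_m * 1000)
}

#' Resample timestamped CoP samples onto a uniform grid
#'
#' Linear interpolation onto a grid anchored at the first raw timestamp with
#' step `1/rate`, extending to the last raw timestamp (no extrapolation).
#' Exact on piecewise-linear input; an input already uniform at `rate` is
#' reproduced unchanged.
#'
#' @param samples Data frame with columns `t`, `ap`, `ml` (as returned by the
#'   CoP operations), timestamps strictly increasing.
#' @param rate Target rate in Hz (default 1000).
#' @return A [cop_trajectory()] at `rate`.
#' @export
resample_uniform <- function(samples, rate = 1000) {
  t <- samples$t
  if (length(t) < 2) sa_too_short_error("need >= 2 samples to resample")
  if (any(diff(t) <= 0)) {
    sa_validation_error("timestamps must be strictly increasing")
  }
  span <- t[length(t)] - t[1]
  h <- 1 / rate
  n_out <- floor(span / h + 1e-9) + 1
  if (n_out < 2) {
    sa_too_short_error(sprintf(
      "duration %.4g s shorter than one grid step (%.4g s)", span, h))
  }
  grid <- t[1] + (seq_len(n_out) - 1) * h
  if (n_out == length(t) && max(abs(grid - t)) < 1e-12) {
    # input already uniform at the target rate: identity
    return(cop_trajectory(ap = samples$ap, ml = samples$ml, rate = rate,
                          start_time = t[1]))
  }
  ap <- stats::approx(t, samples$ap, xout = grid, method = "linear",
                      rule = 1)$y
  ml <- stats::approx(t, samples$ml, xout = grid, method = "linear",
                      rule = 1)$y
  cop_trajectory(ap = ap, ml = ml, rate = rate, start_time = t[1])
}

# Single IIR pass (direct form I) with start-steady-state initial conditions:
# the filter behaves as if the signal had been constant at `x0` forever
# before the first sample. Implemented with stats::filter (C level): FIR
# convolution for the numerator, recursive pass for the denominator.
iir_pass <- function(b, a, x, x0 = x[1]) {
  nb <- length(b)
  n <- length(x)
  xx <- c(rep(x0, nb - 1), x)
  # FIR numerator as explicit shift-and-add (faster than a generic
  # convolution for the short kernels used here)
  v <- numeric(n)
  for (j in seq_len(nb)) {
    v <- v + b[j] * xx[(nb - j + 1):(nb - j + n)]
  }
  y0 <- x0 * sum(b) / sum(a)
  y <- stats::filter(v, -a[-1], method = "recursive",
                     init = rep(y0, length(a) - 1))
  as.numeric(y)
}

# Zero-phase forward-backward IIR with odd-reflection end padding.
filtfilt_zero_phase <- function(b, a, x, pad = 3 * (length(a) - 1)) {
  n <- length(x)
  if (n <= pad + 1) {
    sa_too_short_error(sprintf(
      "signal length %d too short for padding length %d", n, pad))
  }
  xp <- c(2 * x[1] - x[(pad + 1):2],
          x,
          2 * x[n] - x[(n - 1):(n - pad)])
  y <- iir_pass(b, a, xp)
  y <- rev(iir_pass(b, a, rev(y)))
  y[(pad + 1):(pad + n)]
}

#' Zero-phase Butterworth low-pass filter
#'
#' Second-order (by default) Butterworth design applied forward and backward
#' (zero phase) independently to the AP and ML series. The double pass
#' squares the single-pass magnitude `|H(f)| = (1 + (f/fc)^(2*order))^(-1/2)`,
#' so the effective -6 dB point lies below the nominal cutoff; no cutoff
#' compensation is applied. Edges are handled by odd-reflection padding of
#' length 3 x order together with steady-state initial conditions, which
#' keeps a constant signal exactly invariant (DC gain 1).
#'
#' @param traj A [cop_trajectory()].
#' @param order Filter order (default 2).
#' @param cutoff_hz Cutoff frequency in Hz (default 12); must satisfy
#'   `rate > 2 * cutoff_hz`.
#' @return Filtered [cop_trajectory()], same length and rate.
#' @export
butterworth_lowpass <- function(traj, order = 2, cutoff_hz = 12) {
  if (!inherits(traj, "cop_trajectory")) {
    sa_validation_error("traj must be a cop_trajectory")
  }
  if (traj$rate <= 2 * cutoff_hz) {
    sa_validation_error(sprintf(
      "rate (%g Hz) must exceed twice the cutoff (%g Hz)",
      traj$rate, cutoff_hz))
  }
  bf <- signal::butter(order, cutoff_hz / (traj$rate / 2), type = "low")
  ap <- filtfilt_zero_phase(bf$b, bf$a, traj$ap)
  ml <- filtfilt_zero_phase(bf$b, bf$a, traj$ml)
  cop_trajectory(ap = ap, ml = ml, rate = traj$rate,
                 start_time = traj$start_time)
}

#' Full conditioning chain for one recording
#'
#' Raw recording -> CoP samples (moment balance or wrench) -> uniform
#' resampling -> zero-phase Butterworth low-pass. Deterministic: identical
#' recordings yield bit-identical trajectories.
#'
#' @param rec A [trial_recording()] of either kind.
#' @param config A [run_config()].
#' @return Conditioned [cop_trajectory()].
#' @export
process_trial <- function(rec, config = run_config()) {
  samples <- if (rec$kind == "board") {
    cop_from_corner_loads(
      rec,
      geom = board_geometry(config$geometry$span_ml_mm,
                            config$geometry$span_ap_mm),
      load_floor_n = config$load_floor_n)
  } else {
    cop_from_wrench(rec,
                    surface_offset_dz_mm = config$surface_offset_dz_mm,
                    load_floor_n = config$load_floor_n)
  }
  traj <- resample_uniform(samples, rate = config$resample$rate_hz)
  butterworth_lowpass(traj, order = config$filter$order,
                      cutoff_hz = config$filter$cutoff_hz)
}
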