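# Domain containers for raw trials and the study design.

BOARD_CHANNELS <- c("TL", "TR", "BL", "BR")
PLATE_CHANNELS <- c("Fx", "Fy", "Fz", "Mx", "My", "Mz")

channel_names_for <- function(kind) {
  switch(kind,
    board = BOARD_CHANNELS,
    forceplate = PLATE_CHANNELS,
    sa_validation_error(sprintf("unknown recording kind '%s'", kind))
  )
}

#' Construct a raw trial recording
#'
#' One 30 s (or arbitrary-duration) quiet-stance trial from a single device:
#' either the four corner load-cell forces of a balance board (N, columns
#' TL, TR, BL, BR) or the six-component force/moment wrench of a force plate
#' (Fx, Fy, Fz in N; Mx, My, Mz in N·m).
#'
#' @param subject_id,device_id Character identifiers.
#' @param trial_index Integer >= 1, repetition number within the device.
#' @param kind `"board"` or `"forceplate"`.
#' @param timestamps Numeric vector of sample times in seconds, strictly
#'   increasing, length >= 2.
#' @param channels Numeric matrix, one row per sample; 4 columns for a board,
#'   6 for a force plate (order as above).
#' @return An object of class `trial_recording`.
#' @export
trial_recording <- function(subject_id, device_id, trial_index, kind,
                            timestamps, channels) {
  kind <- match.arg(kind, c("board", "forceplate"))
  expected <- channel_names_for(kind)
  channels <- as.matrix(channels)
  timestamps <- as.numeric(timestamps)
  n <- length(timestamps)
  if (n < 2) {
    sa_validation_error(sprintf("recording needs >= 2 samples, got %d", n))
  }
  if (nrow(channels) != n) {
    sa_validation_error(sprintf(
      "channel rows (%d) do not match number of timestamps (%d)",
      nrow(channels), n))
  }
  if (ncol(channels) != length(expected)) {
    sa_validation_error(sprintf(
      "%s recording must have %d channels, got %d",
      kind, length(expected), ncol(channels)))
  }
  if (!all(is.finite(timestamps)) || !all(is.finite(channels))) {
    sa_validation_error("timestamps and channels must be finite")
  }
  bad <- which(diff(timestamps) <= 0)
  if (length(bad) > 0) {
    sa_validation_error(
      sprintf("timestamps not strictly increasing at index %d", bad[1] + 1L),
      index = bad[1] + 1L)
  }
  colnames(channels) <- expected
  structure(
    list(subject_id = as.character(subject_id),
         device_id = as.character(device_id),
         trial_index = as.integer(trial_index),
         kind = kind,
         timestamps = timestamps,
         channels = channels),
    class = "trial_recording")
}

#' @export
print.trial_recording <- function(x, ...) {
  cat(sprintf(
    "<trial_recording> %s | subject %s, device %s, trial %d\n  %d samples over %.3f s (%s)\n",
    x$kind, x$subject_id, x$device_id, x$trial_index,
    length(x$timestamps),
    diff(range(x$timestamps)),
    paste(colnames(x$channels), collapse = ", ")))
  invisible(x)
}

recording_duration <- function(rec) {
  diff(range(rec$timestamps))
}

#' Crossover study design
#'
#' Dimensions of the repeated-measures design: every subject performs
#' `n_trials_per_device` quiet-stance trials on each of `n_devices` boards,
#' each trial recorded simultaneously by the board and the reference force
#' plate. The study emulated by default is 6 subjects x 4 devices x 3 trials
#' of 30 s.
#'
#' @param n_subjects,n_devices,n_trials_per_device Positive integers.
#' @param trial_duration Trial length in seconds.
#' @return Object of class `study_design`.
#' @export
study_design <- function(n_subjects = 6, n_devices = 4,
                         n_trials_per_device = 3, trial_duration = 30) {
  vals <- c(n_subjects, n_devices, n_trials_per_device, trial_duration)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    sa_validation_error("all study design fields must be positive")
  }
  structure(
    list(n_subjects = as.integer(n_subjects),
         n_devices = as.integer(n_devices),
         n_trials_per_device = as.integer(n_trials_per_device),
         trial_duration = as.numeric(trial_duration)),
    class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(
    "<study_design> %d subjects x %d devices x %d trials (%g s each), %d trials total\n",
    x$n_subjects, x$n_devices, x$n_trials_per_device, x$trial_duration,
    x$n_subjects * x$n_devices * x$n_trials_per_device))
  invisible(x)
}
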