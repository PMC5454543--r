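# Synthetic paired-device study generator: Ornstein-Uhlenbeck quiet-stance
# sway observed simultaneously by a (possibly miscalibrated) quad-load-cell
# board model and a force-plate wrench model.

GRAVITY <- 9.81  # m/s^2

#' Quiet-stance sway model (2-D Ornstein-Uhlenbeck)
#'
#' Each axis is a stationary OU process about the stance point with
#' relaxation time tau (s) and diffusion D (mm^2/s); the stationary SD is
#' `sqrt(D * tau / 2)`. Defaults give tau = 1 s and 3 mm stationary SD per
#' axis, a package choice emulating quiet bipedal stance amplitude, not a
#' fit to any particular cohort.
#'
#' @param relaxation_time_ap,relaxation_time_ml Relaxation times (s) > 0.
#' @param diffusion_ap,diffusion_ml Diffusion coefficients (mm^2/s) >= 0.
#' @param stance_offset Length-2 numeric `(ap, ml)` stance point (mm).
#' @return Object of class `sway_model`.
#' @export
sway_model <- function(relaxation_time_ap = 1, relaxation_time_ml = 1,
                       diffusion_ap = 18, diffusion_ml = 18,
                       stance_offset = c(ap = 0, ml = 0)) {
  if (relaxation_time_ap <= 0 || relaxation_time_ml <= 0) {
    sa_validation_error("relaxation times must be > 0")
  }
  if (diffusion_ap < 0 || diffusion_ml < 0) {
    sa_validation_error("diffusion must be >= 0")
  }
  structure(list(process = "ou",
                 relaxation_time_ap = relaxation_time_ap,
                 relaxation_time_ml = relaxation_time_ml,
                 diffusion_ap = diffusion_ap, diffusion_ml = diffusion_ml,
                 stance_offset = c(ap = unname(stance_offset[1]),
                                   ml = unname(stance_offset[2]))),
            class = "sway_model")
}

#' Measurement-device model
#'
#' Per-channel gain/offset miscalibration, additive Gaussian sensor noise,
#' optional quantization, nominal sampling rate and timestamp jitter. A
#' board has 4 channels (corner loads, N); a force plate 6 (forces N,
#' moments N·m). This emulates an uncalibrated consumer board against a
#' factory-calibrated plate.
#'
#' @param role `"board"` or `"forceplate"`.
#' @param gains Per-channel multiplicative gains (~1), length 4 or 6
#'   (scalars are recycled).
#' @param offsets Per-channel additive offsets (N or N·m).
#' @param noise_sd Per-channel additive noise SD (N or N·m).
#' @param quant_step Quantization step (N; 0 = none).
#' @param rate_hz Nominal sampling rate (Hz).
#' @param jitter_sd Timestamp jitter SD (s; 0 = none). Jitter is clamped to
#'   +/- 0.45 sample steps so timestamps stay strictly increasing.
#' @return Object of class `device_model`.
#' @export
device_model <- function(role = c("board", "forceplate"),
                         gains = 1, offsets = 0, noise_sd = 0,
                         quant_step = 0, rate_hz = NULL, jitter_sd = 0) {
  role <- match.arg(role)
  nch <- if (role == "board") 4L else 6L
  if (is.null(rate_hz)) rate_hz <- if (role == "board") 100 else 1000
  gains <- rep_len(as.numeric(gains), nch)
  offsets <- rep_len(as.numeric(offsets), nch)
  noise_sd <- rep_len(as.numeric(noise_sd), nch)
  if (any(gains <= 0)) sa_validation_error("gains must be > 0")
  if (any(noise_sd < 0)) sa_validation_error("noise SD must be >= 0")
  if (rate_hz <= 0) sa_validation_error("rate must be > 0")
  if (quant_step < 0 || jitter_sd < 0) {
    sa_validation_error("quant_step and jitter_sd must be >= 0")
  }
  structure(list(role = role, gains = gains, offsets = offsets,
                 noise_sd = noise_sd, quant_step = quant_step,
                 rate_hz = rate_hz, jitter_sd = jitter_sd),
            class = "device_model")
}

#' Subject model
#'
#' @param mass_kg Body mass (kg) > 0 (population default 81, the study
#'   cohort mean).
#' @param stance_offset_sd_mm Trial-to-trial SD of the stance point (mm).
#' @return Object of class `subject_model`.
#' @export
subject_model <- function(mass_kg = 81, stance_offset_sd_mm = 2) {
  if (!is.finite(mass_kg) || mass_kg <= 0) {
    sa_validation_error("mass must be > 0")
  }
  structure(list(mass_kg = mass_kg,
                 stance_offset_sd_mm = stance_offset_sd_mm),
            class = "subject_model")
}

#' Subject population specification
#'
#' Cohort-level distributions the generator draws each subject from: body
#' mass Normal(81, 22) kg truncated at 40 kg (the study cohort moments);
#' a subject-level stance-point offset; a per-trial stance jitter; and a
#' subject-level lognormal sway-amplitude multiplier (healthy adults differ
#' severalfold in quiet-stance amplitude).
#'
#' @param mean_mass_kg,sd_mass_kg,min_mass_kg Mass distribution (kg).
#' @param between_subject_offset_sd_mm SD of the subject-level stance point
#'   (mm, per axis).
#' @param stance_offset_sd_mm Per-trial stance jitter SD (mm, per axis).
#' @param sway_scale_sdlog SD of log sway-amplitude multiplier.
#' @return Object of class `subject_population`.
#' @export
subject_population <- function(mean_mass_kg = 81, sd_mass_kg = 22,
                               min_mass_kg = 40,
                               between_subject_offset_sd_mm = 8,
                               stance_offset_sd_mm = 2,
                               sway_scale_sdlog = 0.4) {
  structure(list(mean_mass_kg = mean_mass_kg, sd_mass_kg = sd_mass_kg,
                 min_mass_kg = min_mass_kg,
                 between_subject_offset_sd_mm = between_subject_offset_sd_mm,
                 stance_offset_sd_mm = stance_offset_sd_mm,
                 sway_scale_sdlog = sway_scale_sdlog),
            class = "subject_population")
}

#' Simulate a ground-truth CoP trajectory
#'
#' Exact discretization of the per-axis OU recursion:
#' `x[t+h] = mu + (x[t] - mu) exp(-h/tau) + xi`,
#' `xi ~ N(0, (D tau / 2)(1 - exp(-2h/tau)))`, started from the stationary
#' distribution. Deterministic given `seed`.
#'
#' @param model A [sway_model()].
#' @param duration Trial length (s).
#' @param rate Sampling rate (Hz).
#' @param seed Integer seed.
#' @param start_time Clock time of the first sample (s).
#' @return A [cop_trajectory()] with `duration * rate + 1` samples.
#' @export
simulate_true_sway <- function(model, duration = 30, rate = 1000, seed = 1,
                               start_time = 0) {
  if (duration <= 0 || rate <= 0) {
    sa_validation_error("duration and rate must be > 0")
  }
  n <- floor(duration * rate + 1e-9) + 1
  h <- 1 / rate
  one_axis <- function(tau, D, mu) {
    s2 <- D * tau / 2
    if (s2 == 0) return(rep(mu, n))
    phi <- exp(-h / tau)
    z0 <- stats::rnorm(1, 0, sqrt(s2))
    eps <- stats::rnorm(n - 1, 0, sqrt(s2 * (1 - phi^2)))
    z <- stats::filter(eps, phi, method = "recursive", init = z0)
    mu + c(z0, as.numeric(z))
  }
  with_seed(seed, {
    ap <- one_axis(model$relaxation_time_ap, model$diffusion_ap,
                   model$stance_offset["ap"])
    ml <- one_axis(model$relaxation_time_ml, model$diffusion_ml,
                   model$stance_offset["ml"])
    cop_trajectory(ap = ap, ml = ml, rate = rate, start_time = start_time)
  })
}

interp_traj <- function(traj, t_out) {
  t_in <- traj$start_time + (seq_len(traj$n) - 1) / traj$rate
  # identity grid (e.g. plate sampling at the truth rate): no interpolation
  if (length(t_out) == length(t_in) &&
      max(abs(t_out - t_in)) < 1e-12) {
    return(list(ap = traj$ap, ml = traj$ml))
  }
  list(ap = stats::approx(t_in, traj$ap, xout = t_out)$y,
       ml = stats::approx(t_in, traj$ml, xout = t_out)$y)
}

sample_times <- function(traj, rate, jitter_sd, seed_offset = 0) {
  t0 <- traj$start_time
  dur <- traj$duration
  m <- floor(dur * rate + 1e-9) + 1
  t <- t0 + (seq_len(m) - 1) / rate
  if (jitter_sd > 0) {
    j <- stats::rnorm(m, 0, jitter_sd)
    j <- pmin(pmax(j, -0.45 / rate), 0.45 / rate)
    j[1] <- max(j[1], 0)        # never before the truth start
    j[m] <- min(j[m], 0)        # never past the truth end
    t <- t + j
  }
  t
}

apply_channel_model <- function(x, device) {
  n <- nrow(x); nc <- ncol(x)
  for (j in seq_len(nc)) {
    xj <- x[, j] * device$gains[j] + device$offsets[j]
    if (device$noise_sd[j] > 0) {
      xj <- xj + stats::rnorm(n, 0, device$noise_sd[j])
    }
    x[, j] <- xj
  }
  if (device$quant_step > 0) {
    x <- round(x / device$quant_step) * device$quant_step
  }
  x
}

#' Observe a truth trajectory with a board model
#'
#' Exact inverse of the quad-cell moment balance: with normalized
#' coordinates `u = ml/span_ml`, `v = ap/span_ap` the bilinear load split
#' `TL = F(1/2-u)(1/2+v)`, `TR = F(1/2+u)(1/2+v)`, `BL = F(1/2-u)(1/2-v)`,
#' `BR = F(1/2+u)(1/2-v)` (total `F = mass * g`) reproduces the truth CoP
#' exactly; gain/offset/noise/quantization and irregular low-rate sampling
#' with timestamp jitter are then applied per the device model.
#'
#' @param truth Ground-truth [cop_trajectory()].
#' @param subject A [subject_model()].
#' @param device A board [device_model()].
#' @param geom A [board_geometry()].
#' @param seed Integer seed for noise/jitter.
#' @param subject_id,device_id,trial_index Metadata for the recording.
#' @return A board [trial_recording()].
#' @export
observe_with_board <- function(truth, subject, device,
                               geom = board_geometry(), seed = 1,
                               subject_id = "S1", device_id = "B1",
                               trial_index = 1L) {
  if (device$role != "board") sa_validation_error("device role must be 'board'")
  with_seed(seed, {
    t <- sample_times(truth, device$rate_hz, device$jitter_sd)
    cop <- interp_traj(truth, t)
    u <- cop$ml / geom$span_ml_mm
    v <- cop$ap / geom$span_ap_mm
    bad <- which(abs(u) > 0.5 | abs(v) > 0.5)
    if (length(bad) > 0) {
      sa_validation_error(sprintf(
        "truth CoP outside the sensor rectangle at sample %d: no feasible load split",
        bad[1]), index = bad[1])
    }
    F <- subject$mass_kg * GRAVITY
    loads <- cbind(TL = F * (0.5 - u) * (0.5 + v),
                   TR = F * (0.5 + u) * (0.5 + v),
                   BL = F * (0.5 - u) * (0.5 - v),
                   BR = F * (0.5 + u) * (0.5 - v))
    loads <- apply_channel_model(loads, device)
    trial_recording(subject_id, device_id, trial_index, "board",
                    timestamps = t, channels = loads)
  })
}

#' Observe a truth trajectory with a force-plate model
#'
#' The plate reports the wrench at its moment origin a distance `dz` below
#' the contact surface: `Fz = mass * g`, `Fx = Fy = 0` (plus sensor noise),
#' `Mx = ap * Fz`, `My = -ml * Fz` (CoP in m), sampled uniformly at the
#' device rate. Channel gain/offset/noise/quantization per the device model.
#'
#' @param truth Ground-truth [cop_trajectory()].
#' @param subject A [subject_model()].
#' @param device A forceplate [device_model()].
#' @param surface_offset_dz_mm Surface height above the moment origin (mm);
#'   with zero horizontal truth force it does not enter the ideal wrench,
#'   only its noisy recovery.
#' @param seed Integer seed.
#' @param subject_id,device_id,trial_index Metadata.
#' @return A forceplate [trial_recording()].
#' @export
observe_with_forceplate <- function(truth, subject, device,
                                    surface_offset_dz_mm = 53, seed = 1,
                                    subject_id = "S1", device_id = "FP",
                                    trial_index = 1L) {
  if (device$role != "forceplate") {
    sa_validation_error("device role must be 'forceplate'")
  }
  with_seed(seed, {
    t <- sample_times(truth, device$rate_hz, device$jitter_sd)
    cop <- interp_traj(truth, t)
    Fz <- subject$mass_kg * GRAVITY
    ap_m <- cop$ap / 1000; ml_m <- cop$ml / 1000
    wrench <- cbind(Fx = rep(0, length(t)), Fy = rep(0, length(t)),
                    Fz = rep(Fz, length(t)),
                    Mx = ap_m * Fz, My = -ml_m * Fz,
                    Mz = rep(0, length(t)))
    wrench <- apply_channel_model(wrench, device)
    trial_recording(subject_id, device_id, trial_index, "forceplate",
                    timestamps = t, channels = wrench)
  })
}

#' Generate a complete synthetic crossover study
#'
#' For every subject x device x trial cell, one truth sway realization is
#' observed simultaneously by the board model and the plate model (shared
#' truth, independent observation noise). Per-cell sub-seeds derive
#' deterministically from the master seed and the (subject, device, trial)
#' indices, so the corpus is a pure function of its arguments and adding a
#' subject never perturbs existing trials. The device measurement order is
#' randomized per subject (recorded in the manifest).
#'
#' @param design A [study_design()].
#' @param sway A [sway_model()]; per-subject amplitude multipliers from
#'   `population` scale its diffusion.
#' @param population A [subject_population()].
#' @param boards List of board [device_model()]s, length
#'   `design$n_devices`.
#' @param plate A forceplate [device_model()].
#' @param geom A [board_geometry()].
#' @param seed Master seed.
#' @param truth_rate_hz Ground-truth simulation rate (Hz).
#' @param surface_offset_dz_mm Plate surface offset (mm).
#' @return Object of class `synthetic_study`: `trials` (list of
#'   `list(board, plate, truth, meta)`), `manifest` (data frame), `subjects`,
#'   `design`, and the model echo.
#' @export
generate_synthetic_study <- function(design = study_design(),
                                     sway = sway_model(),
                                     population = subject_population(),
                                     boards = default_boards(design$n_devices),
                                     plate = device_model("forceplate",
                                       noise_sd = c(0.2, 0.2, 0.2, 0.05, 0.05, 0.05)),
                                     geom = board_geometry(),
                                     seed = 1,
                                     truth_rate_hz = 1000,
                                     surface_offset_dz_mm = 53) {
  if (length(boards) != design$n_devices) {
    sa_validation_error(sprintf(
      "need %d board models, got %d", design$n_devices, length(boards)))
  }
  for (i in seq_along(boards)) {
    if (!inherits(boards[[i]], "device_model") || boards[[i]]$role != "board") {
      sa_validation_error(sprintf("boards[[%d]] is not a board device_model", i))
    }
  }
  subjects <- lapply(seq_len(design$n_subjects), function(i) {
    with_seed(derive_seed(seed, 1L, i), {
      mass <- population$mean_mass_kg +
        population$sd_mass_kg * stats::qnorm(stats::runif(1,
          stats::pnorm((population$min_mass_kg - population$mean_mass_kg) /
                         population$sd_mass_kg), 1))
      # lognormal amplitude multiplier, truncated at +/- 2.5 SD on the log
      # scale so extreme draws cannot push the sway outside the sensor span
      z <- stats::rnorm(1)
      scale <- exp(population$sway_scale_sdlog * max(-2.5, min(2.5, z)))
      offset <- stats::rnorm(2, 0, population$between_subject_offset_sd_mm)
      order_dev <- sample(design$n_devices)
      list(id = sprintf("S%02d", i), mass_kg = mass, sway_scale = scale,
           stance_offset = c(ap = offset[1], ml = offset[2]),
           device_order = order_dev)
    })
  })
  trials <- list()
  manifest <- list()
  for (i in seq_len(design$n_subjects)) {
    sub <- subjects[[i]]
    smodel <- subject_model(sub$mass_kg, population$stance_offset_sd_mm)
    for (d in seq_len(design$n_devices)) {
      dev_id <- sprintf("B%d", d)
      for (tr in seq_len(design$n_trials_per_device)) {
        s_truth <- derive_seed(seed, 2L, i, d, tr)
        s_board <- derive_seed(seed, 3L, i, d, tr)
        s_plate <- derive_seed(seed, 4L, i, d, tr)
        trial_sway <- with_seed(derive_seed(seed, 5L, i, d, tr), {
          jit <- stats::rnorm(2, 0, population$stance_offset_sd_mm)
          sway_model(
            relaxation_time_ap = sway$relaxation_time_ap,
            relaxation_time_ml = sway$relaxation_time_ml,
            diffusion_ap = sway$diffusion_ap * sub$sway_scale^2,
            diffusion_ml = sway$diffusion_ml * sub$sway_scale^2,
            stance_offset = c(
              ap = unname(sway$stance_offset["ap"] + sub$stance_offset["ap"] + jit[1]),
              ml = unname(sway$stance_offset["ml"] + sub$stance_offset["ml"] + jit[2])))
        })
        truth <- simulate_true_sway(trial_sway, duration = design$trial_duration,
                                    rate = truth_rate_hz, seed = s_truth)
        brec <- observe_with_board(truth, smodel, boards[[d]], geom,
                                   seed = s_board, subject_id = sub$id,
                                   device_id = dev_id, trial_index = tr)
        prec <- observe_with_forceplate(truth, smodel, plate,
                                        surface_offset_dz_mm = surface_offset_dz_mm,
                                        seed = s_plate, subject_id = sub$id,
                                        device_id = dev_id, trial_index = tr)
        key <- sprintf("%s/%s/%d", sub$id, dev_id, tr)
        trials[[key]] <- list(board = brec, plate = prec, truth = truth,
                              meta = list(subject_id = sub$id,
                                          device_id = dev_id,
                                          trial_index = tr))
        manifest[[length(manifest) + 1]] <- data.frame(
          subject_id = sub$id, device_id = dev_id, trial_index = tr,
          mass_kg = sub$mass_kg, sway_scale = sub$sway_scale,
          measurement_order = which(sub$device_order == d),
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(trials = trials,
                 manifest = do.call(rbind, manifest),
                 subjects = subjects,
                 design = design, sway = sway, population = population,
                 boards = boards, plate = plate, geom = geom, seed = seed,
                 truth_rate_hz = truth_rate_hz,
                 surface_offset_dz_mm = surface_offset_dz_mm),
            class = "synthetic_study")
}

#' Default board models
#'
#' Illustrative uncalibrated boards: each board gets its own mild per-corner
#' gain miscalibration (SD 1%) and a tare/zero offset per load cell drawn
#' around 10 N (SD 2 N) — consumer boards without calibration typically
#' mis-read total weight by a few kilograms, and this net tare error is
#' what makes the board's CoP amplitude read a few percent low in a
#' subject-mass-dependent way. Sensor noise 0.5 N, 100 Hz nominal rate with
#' 1 ms timestamp jitter. These defaults calibrate the machinery; they are
#' not a claim about any physical board.
#'
#' @param n Number of boards.
#' @param seed Seed for the miscalibration draw.
#' @param noise_sd,quant_step,rate_hz,jitter_sd Shared device parameters.
#' @return List of `n` board [device_model()]s.
#' @export
default_boards <- function(n = 4, seed = 20, noise_sd = 0.5, quant_step = 0,
                           rate_hz = 100, jitter_sd = 0.001) {
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      device_model("board",
                   gains = exp(stats::rnorm(4, 0, 0.01)),
                   offsets = stats::rnorm(4, 10, 0.5),
                   noise_sd = noise_sd, quant_step = quant_step,
                   rate_hz = rate_hz, jitter_sd = jitter_sd)
    })
  })
}

#' Compute per-trial metrics for a synthetic study corpus (in memory)
#'
#' Runs the full conditioning chain (CoP, resample, filter) and the nine
#' parameters for every board and plate recording of a corpus, without any
#' disk round-trip.
#'
#' @param study A `synthetic_study` from [generate_synthetic_study()].
#' @param config A [run_config()].
#' @return List of two data frames, `fp` and `board`, keyed metric tables
#'   suitable for [run_interchangeability_study()].
#' @export
study_metrics <- function(study, config = run_config()) {
  nt <- length(study$trials)
  mm <- metric_names()
  vb <- matrix(NA_real_, nt, length(mm), dimnames = list(NULL, mm))
  vp <- vb
  sid <- character(nt); did <- character(nt); tix <- integer(nt)
  for (i in seq_len(nt)) {
    tr <- study$trials[[i]]
    mb <- compute_sway_metrics(process_trial(tr$board, config),
                               ellipse_level = config$ellipse$level,
                               ellipse_scale = config$ellipse$scale,
                               dispersion_denominator = config$dispersion$denominator)
    mp <- compute_sway_metrics(process_trial(tr$plate, config),
                               ellipse_level = config$ellipse$level,
                               ellipse_scale = config$ellipse$scale,
                               dispersion_denominator = config$dispersion$denominator)
    vb[i, ] <- unlist(mb[mm], use.names = FALSE)
    vp[i, ] <- unlist(mp[mm], use.names = FALSE)
    sid[i] <- tr$meta$subject_id
    did[i] <- tr$meta$device_id
    tix[i] <- tr$meta$trial_index
  }
  base <- data.frame(subject_id = sid, device_id = did, trial_index = tix,
                     stringsAsFactors = FALSE)
  list(fp = cbind(base, as.data.frame(vp)),
       board = cbind(base, as.data.frame(vb)))
}
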