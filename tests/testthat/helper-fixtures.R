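# Shared fixtures: small recordings, trajectories and study scenarios built
# in code at test time.

make_board_rec <- function(timestamps = c(0, 0.01, 0.02),
                           loads = matrix(20, length(timestamps), 4),
                           subject = "S01", device = "B1", trial = 1L) {
  trial_recording(subject, device, trial, "board", timestamps, loads)
}

make_plate_rec <- function(timestamps = seq(0, 1, by = 0.001),
                           Fz = 800, Mx = 0, My = 0, Fx = 0, Fy = 0, Mz = 0,
                           subject = "S01", device = "B1", trial = 1L) {
  n <- length(timestamps)
  ch <- cbind(Fx = rep_len(Fx, n), Fy = rep_len(Fy, n), Fz = rep_len(Fz, n),
              Mx = rep_len(Mx, n), My = rep_len(My, n), Mz = rep_len(Mz, n))
  trial_recording(subject, device, trial, "forceplate", timestamps, ch)
}

random_traj <- function(n = 300, rate = 100, scale = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cop_trajectory(ap = cumsum(rnorm(n)) * scale,
                 ml = cumsum(rnorm(n)) * scale, rate = rate)
}

# Tiny paired metric tables covering a full design, board == fp + optional
# per-row perturbation.
make_metric_tables <- function(n_sub = 2, n_dev = 2, n_tri = 2, seed = 1,
                               perturb = 0) {
  set.seed(seed)
  keys <- expand.grid(trial_index = seq_len(n_tri),
                      device_id = sprintf("B%d", seq_len(n_dev)),
                      subject_id = sprintf("S%02d", seq_len(n_sub)),
                      stringsAsFactors = FALSE)
  keys <- keys[, c("subject_id", "device_id", "trial_index")]
  vals <- matrix(abs(rnorm(nrow(keys) * 9, 10, 2)), nrow(keys), 9,
                 dimnames = list(NULL, metric_names()))
  fp <- cbind(keys, as.data.frame(vals))
  board <- fp
  if (perturb > 0) {
    for (m in metric_names()) {
      board[[m]] <- board[[m]] + rnorm(nrow(board), 0, perturb)
    }
  }
  list(fp = fp, board = board)
}

# --- frozen acceptance scenarios -------------------------------------------
# Chosen a priori from analytic variance sizing (see the methods vignette);
# identical boards with a net tare offset so the FP-board bias is
# amplitude-proportional and subject-mass dependent.

calib_boards <- function(biased_corner_gain = 1) {
  lapply(1:4, function(i) {
    g <- c(1.01, 0.99, 0.995, 1.005)
    if (biased_corner_gain != 1 && i == 2) g[2] <- g[2] * biased_corner_gain
    device_model("board", gains = g, offsets = c(16, 12, 14, 18),
                 noise_sd = 0.1, rate_hz = 250, jitter_sd = 0.001)
  })
}

calib_plate <- function() {
  device_model("forceplate", noise_sd = c(0, 0, 0, 0.02, 0.02, 0))
}

calib_sway <- function() sway_model(0.1, 0.1, 180, 180)  # sd 3 mm, tau 0.1 s

calib_population <- function() subject_population(sway_scale_sdlog = 0.7)

run_calib_replicate <- function(seed, duration = 10, biased = 1,
                                config = run_config()) {
  design <- study_design(6, 4, 3, duration)
  st <- generate_synthetic_study(
    design = design, sway = calib_sway(), population = calib_population(),
    boards = calib_boards(biased), plate = calib_plate(), seed = seed)
  met <- study_metrics(st, config)
  run_interchangeability_study(met$fp, met$board, design = design,
                               config = config)
}

ideal_board <- function(rate = 250) device_model("board", rate_hz = rate)
ideal_plate <- function() device_model("forceplate")
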