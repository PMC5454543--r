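# File-based workflow stages: simulate -> metrics -> agreement. No hidden
# state between stages; everything interchanges via delimited text files so
# partial reruns are possible and outputs are byte-reproducible given the
# scenario seed.

#' Default simulation scenario
#'
#' The emulated study conditions: 6 subjects x 4 boards x 3 trials of 30 s
#' quiet stance, OU sway, cohort mass Normal(81, 22) kg truncated at 40,
#' four mildly miscalibrated boards at 100 Hz against a clean 1000 Hz plate
#' with the board stacked 53 mm above the plate's moment origin.
#'
#' @param seed Master seed.
#' @param trial_duration Trial length (s).
#' @return Scenario list consumable by [run_simulate()].
#' @export
default_scenario <- function(seed = 1, trial_duration = 30) {
  list(design = study_design(trial_duration = trial_duration),
       sway = sway_model(),
       population = subject_population(),
       boards = default_boards(4),
       plate = device_model("forceplate",
                            noise_sd = c(0.2, 0.2, 0.2, 0.05, 0.05, 0.05)),
       geometry = board_geometry(),
       truth_rate_hz = 1000,
       surface_offset_dz_mm = 53,
       seed = seed)
}

scenario_to_list <- function(sc) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  list(design = strip(sc$design), sway = strip(sc$sway),
       population = strip(sc$population),
       boards = lapply(sc$boards, strip), plate = strip(sc$plate),
       geometry = strip(sc$geometry), truth_rate_hz = sc$truth_rate_hz,
       surface_offset_dz_mm = sc$surface_offset_dz_mm, seed = sc$seed)
}

#' Read a simulation scenario from YAML
#'
#' @param path YAML file with the fields of [default_scenario()].
#' @return Scenario list with validated model objects.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) sa_io_error(sprintf("scenario '%s' does not exist", path))
  raw <- yaml::read_yaml(path)
  need <- c("design", "sway", "population", "boards", "plate", "seed")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    sa_validation_error(sprintf("scenario missing field(s): %s",
                                paste(miss, collapse = ", ")))
  }
  boards <- lapply(seq_along(raw$boards), function(i) {
    b <- raw$boards[[i]]
    tryCatch(
      device_model("board", gains = unlist(b$gains), offsets = unlist(b$offsets),
                   noise_sd = unlist(b$noise_sd), quant_step = b$quant_step %||% 0,
                   rate_hz = b$rate_hz %||% 100, jitter_sd = b$jitter_sd %||% 0),
      swayagree_error = function(e) {
        sa_validation_error(sprintf("board %d invalid: %s", i, conditionMessage(e)))
      })
  })
  p <- raw$plate
  d <- raw$design
  so <- raw$sway$stance_offset
  if (is.null(so)) so <- list(ap = 0, ml = 0)
  if (!is.list(so)) {
    so <- if (!is.null(names(so))) as.list(so) else list(ap = so[1], ml = so[2])
  }
  list(design = study_design(d$n_subjects, d$n_devices,
                             d$n_trials_per_device, d$trial_duration),
       sway = sway_model(raw$sway$relaxation_time_ap, raw$sway$relaxation_time_ml,
                         raw$sway$diffusion_ap, raw$sway$diffusion_ml,
                         stance_offset = c(ap = so$ap %||% 0, ml = so$ml %||% 0)),
       population = do.call(subject_population,
                            raw$population[intersect(names(raw$population),
                              names(formals(subject_population)))]),
       boards = boards,
       plate = device_model("forceplate", gains = unlist(p$gains) %||% 1,
                            offsets = unlist(p$offsets) %||% 0,
                            noise_sd = unlist(p$noise_sd) %||% 0,
                            quant_step = p$quant_step %||% 0,
                            rate_hz = p$rate_hz %||% 1000,
                            jitter_sd = p$jitter_sd %||% 0),
       geometry = board_geometry(raw$geometry$span_ml_mm %||% 433,
                                 raw$geometry$span_ap_mm %||% 238),
       truth_rate_hz = raw$truth_rate_hz %||% 1000,
       surface_offset_dz_mm = raw$surface_offset_dz_mm %||% 53,
       seed = raw$seed)
}

#' Simulate a scenario and write the trial corpus to disk
#'
#' Writes one CSV per recording (`<subject>_<device>_t<trial>_<role>.csv`),
#' a `manifest.csv` and a `scenario.yaml` echo. Rerunning the same scenario
#' yields byte-identical outputs.
#'
#' @param scenario Scenario list ([default_scenario()]) or a YAML path.
#' @param out_dir Output directory (created if needed).
#' @return The manifest data frame, invisibly.
#' @export
run_simulate <- function(scenario, out_dir) {
  if (is.character(scenario)) scenario <- read_scenario(scenario)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  study <- generate_synthetic_study(
    design = scenario$design, sway = scenario$sway,
    population = scenario$population, boards = scenario$boards,
    plate = scenario$plate, geom = scenario$geometry,
    seed = scenario$seed, truth_rate_hz = scenario$truth_rate_hz,
    surface_offset_dz_mm = scenario$surface_offset_dz_mm)
  manifest <- study$manifest
  manifest$board_file <- NA_character_
  manifest$plate_file <- NA_character_
  for (i in seq_along(study$trials)) {
    tr <- study$trials[[i]]
    stem <- sprintf("%s_%s_t%d", tr$meta$subject_id, tr$meta$device_id,
                    tr$meta$trial_index)
    bf <- file.path(out_dir, paste0(stem, "_board.csv"))
    pf <- file.path(out_dir, paste0(stem, "_forceplate.csv"))
    write_trial(tr$board, bf)
    write_trial(tr$plate, pf)
    sel <- manifest$subject_id == tr$meta$subject_id &
      manifest$device_id == tr$meta$device_id &
      manifest$trial_index == tr$meta$trial_index
    manifest$board_file[sel] <- basename(bf)
    manifest$plate_file[sel] <- basename(pf)
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  yaml::write_yaml(scenario_to_list(scenario),
                   file.path(out_dir, "scenario.yaml"), precision = 15)
  message(sprintf("simulated %d paired trials (seed %d) -> %s",
                  length(study$trials), scenario$seed, out_dir))
  invisible(manifest)
}

#' Compute the metrics table for a corpus directory
#'
#' Reads every trial CSV in `in_dir`, runs the conditioning chain and the
#' nine parameters, and writes one metrics row per recording (both device
#' roles) in the fixed parameter order. Any unreadable trial aborts the run
#' (no partial silent output).
#'
#' @param in_dir Corpus directory written by [run_simulate()] (or hand-made
#'   CSVs in the same dialect).
#' @param config A [run_config()].
#' @param out_path Output CSV path.
#' @return The metrics data frame, invisibly.
#' @export
run_metrics <- function(in_dir, config = run_config(), out_path) {
  files <- list.files(in_dir, pattern = "_(board|forceplate)\\.csv$",
                      full.names = TRUE)
  if (length(files) == 0) {
    sa_io_error(sprintf("no trials found in '%s'", in_dir))
  }
  rows <- lapply(sort(files), function(f) {
    rec <- tryCatch(read_trial(f), swayagree_error = function(e) {
      sa_stop(class(e)[1], sprintf("while reading '%s': %s", f,
                                   conditionMessage(e)))
    })
    met <- compute_sway_metrics(process_trial(rec, config),
                                ellipse_level = config$ellipse$level,
                                ellipse_scale = config$ellipse$scale,
                                dispersion_denominator = config$dispersion$denominator)
    cbind(data.frame(subject_id = rec$subject_id, device_id = rec$device_id,
                     trial_index = rec$trial_index, role = rec$kind,
                     stringsAsFactors = FALSE),
          as.data.frame(met))
  })
  out <- do.call(rbind, rows)
  write_metrics_table(out, out_path)
  message(sprintf("wrote %d metric rows -> %s", nrow(out), out_path))
  invisible(out)
}

#' Run the agreement battery over a metrics table and write report files
#'
#' Produces the three result tables of the analysis (ICC + Friedman;
#' out-of-limit contingency + chi-square; per-device Spearman), the
#' per-trial difference export for limits-of-agreement plotting, and a
#' machine-readable JSON summary.
#'
#' @param metrics_path Metrics CSV from [run_metrics()] (must contain both
#'   device roles for every trial key).
#' @param config A [run_config()].
#' @param out_dir Output directory.
#' @return The `agreement_report`, invisibly.
#' @export
run_agreement <- function(metrics_path, config = run_config(), out_dir) {
  df <- read_metrics_table(metrics_path)
  if (!"role" %in% names(df)) {
    sa_format_error("metrics table has no 'role' column (board/forceplate)")
  }
  fp <- df[df$role == "forceplate", , drop = FALSE]
  bd <- df[df$role == "board", , drop = FALSE]
  design <- study_design(
    n_subjects = length(unique(df$subject_id)),
    n_devices = length(unique(df$device_id)),
    n_trials_per_device = length(unique(df$trial_index)),
    trial_duration = 1)  # duration not used by the statistics
  report <- run_interchangeability_study(fp, bd, design = design,
                                         config = config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$icc, file.path(out_dir, "icc.csv"), row.names = FALSE)
  utils::write.csv(report$friedman, file.path(out_dir, "friedman.csv"),
                   row.names = FALSE)
  utils::write.csv(report$limits, file.path(out_dir, "limits.csv"),
                   row.names = FALSE)
  cont <- data.frame(parameter = rownames(report$contingency$counts),
                     report$contingency$counts,
                     total = report$contingency$row_totals,
                     check.names = FALSE)
  utils::write.csv(cont, file.path(out_dir, "contingency.csv"),
                   row.names = FALSE)
  utils::write.csv(report$spearman, file.path(out_dir, "spearman.csv"),
                   row.names = FALSE)
  utils::write.csv(report$differences, file.path(out_dir, "differences.csv"),
                   row.names = FALSE)
  summary <- list(
    design = unclass(report$design),
    icc_single_trial = stats::setNames(
      report$icc$estimate[report$icc$mode == "trial" &
                          report$icc$form == "single"],
      report$icc$parameter[report$icc$mode == "trial" &
                           report$icc$form == "single"]),
    friedman_p = stats::setNames(report$friedman$p_value,
                                 report$friedman$parameter),
    chisq = list(statistic = report$chisq$statistic, df = report$chisq$df,
                 p_value = report$chisq$p_value),
    outside_total = report$contingency$total,
    n_observations = sum(report$contingency$n_per_cell),
    mean_spearman_rho = mean(report$spearman$mean))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  message(sprintf("agreement report -> %s", out_dir))
  invisible(report)
}
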