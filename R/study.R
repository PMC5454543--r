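# The full interchangeability battery over a paired metric corpus.

# Build a rows x devices matrix of difference values for one parameter.
diff_matrix <- function(records, mode = c("trial", "subject_mean")) {
  mode <- match.arg(mode)
  devices <- sort(unique(records$device_id))
  if (mode == "subject_mean") {
    agg <- stats::aggregate(value ~ subject_id + device_id, data = records,
                            FUN = mean)
    rows <- sort(unique(agg$subject_id))
    m <- matrix(NA_real_, length(rows), length(devices),
                dimnames = list(rows, devices))
    m[cbind(match(agg$subject_id, rows), match(agg$device_id, devices))] <-
      agg$value
  } else {
    row_key <- paste(records$subject_id, records$trial_index, sep = "/")
    rows <- sort(unique(row_key))
    m <- matrix(NA_real_, length(rows), length(devices),
                dimnames = list(rows, devices))
    m[cbind(match(row_key, rows), match(records$device_id, devices))] <-
      records$value
  }
  if (anyNA(m)) {
    miss <- which(is.na(m), arr.ind = TRUE)
    sa_validation_error(sprintf(
      "incomplete design: missing cell(s) %s",
      paste(sprintf("(%s, %s)", rownames(m)[miss[, 1]],
                    colnames(m)[miss[, 2]]), collapse = "; ")))
  }
  m
}

#' Run the complete device-interchangeability analysis
#'
#' The full battery over a paired force-plate/board metric corpus:
#' per parameter, the FP - board differences feed
#' (i) two-way random ICC across devices, both single and average forms,
#' at both granularities (trial-level: subject x trial rows; subject-mean:
#' one row per subject, means over trials);
#' (ii) a Friedman test across devices (granularity per config);
#' (iii) pooled 95% limits of agreement with the out-of-limit contingency
#' table (parameter x device) and its chi-square test of independence; and
#' (iv) per-device Spearman correlations between the force-plate and board
#' values with their across-device mean and SD.
#'
#' All-zero contingency rows (parameters with no out-of-limit observation)
#' carry no information about device association and are dropped from the
#' chi-square computation; the dropped parameters are recorded in the
#' result. If fewer than two informative rows remain the chi-square is
#' reported as NA with a degenerate note.
#'
#' @param fp_metrics,board_metrics Keyed metric tables (one row per trial).
#' @param design A [study_design()]; the tables must cover it completely.
#' @param config A [run_config()].
#' @return Object of class `agreement_report`.
#' @export
run_interchangeability_study <- function(fp_metrics, board_metrics,
                                         design = study_design(),
                                         config = run_config()) {
  diffs <- paired_differences(fp_metrics, board_metrics)
  devices <- sort(unique(diffs$device_id))
  subjects <- sort(unique(diffs$subject_id))
  n_per_param <- design$n_subjects * design$n_devices * design$n_trials_per_device
  counts <- table(diffs$parameter)
  if (length(devices) != design$n_devices ||
      length(subjects) != design$n_subjects ||
      any(counts != n_per_param)) {
    sa_validation_error(sprintf(
      "metric tables do not cover the %dx%dx%d design (found %d subjects, %d devices, %s records/parameter)",
      design$n_subjects, design$n_devices, design$n_trials_per_device,
      length(subjects), length(devices),
      paste(unique(counts), collapse = "/")))
  }

  icc_rows <- list(); fried_rows <- list(); lim_rows <- list()
  sp_rows <- list(); limits <- list()
  for (p in metric_names()) {
    rec_p <- diffs[diffs$parameter == p, , drop = FALSE]
    for (mode in c("trial", "subject_mean")) {
      m <- diff_matrix(rec_p, mode)
      for (form in c("single", "average")) {
        ic <- icc_two_way(m, form = form)
        icc_rows[[length(icc_rows) + 1]] <- data.frame(
          parameter = p, mode = mode, form = form,
          estimate = ic$estimate, ci_lower = ic$ci_lower,
          ci_upper = ic$ci_upper, n_targets = ic$n_targets,
          k_raters = ic$k_raters, degenerate = ic$degenerate,
          stringsAsFactors = FALSE)
      }
    }
    fm <- diff_matrix(rec_p, config$agreement$friedman_mode)
    fr <- friedman_test(fm)
    fried_rows[[length(fried_rows) + 1]] <- data.frame(
      parameter = p, mode = config$agreement$friedman_mode,
      statistic = fr$statistic, df = fr$df, p_value = fr$p_value,
      stringsAsFactors = FALSE)

    lim <- agreement_limits(rec_p$value,
                            multiplier = config$agreement$loa_multiplier,
                            parameter = p)
    limits[[p]] <- lim
    lim_rows[[length(lim_rows) + 1]] <- data.frame(
      parameter = p, mean_diff = lim$mean_diff, sd_diff = lim$sd_diff,
      lower = lim$lower, upper = lim$upper, n_obs = lim$n_obs,
      stringsAsFactors = FALSE)

    # per-device FP vs board Spearman
    rhos <- vapply(devices, function(d) {
      sel_f <- fp_metrics$device_id == d
      sel_b <- board_metrics$device_id == d
      if (config$agreement$spearman_mode == "subject_mean") {
        xf <- stats::aggregate(fp_metrics[sel_f, p],
                               by = list(fp_metrics$subject_id[sel_f]), mean)$x
        xb <- stats::aggregate(board_metrics[sel_b, p],
                               by = list(board_metrics$subject_id[sel_b]), mean)$x
      } else {
        of <- order(fp_metrics$subject_id[sel_f], fp_metrics$trial_index[sel_f])
        ob <- order(board_metrics$subject_id[sel_b], board_metrics$trial_index[sel_b])
        xf <- fp_metrics[sel_f, p][of]
        xb <- board_metrics[sel_b, p][ob]
      }
      spearman_rho(xf, xb)
    }, numeric(1))
    sp_rows[[length(sp_rows) + 1]] <- data.frame(
      parameter = p, t(rhos), mean = mean(rhos), sd = stats::sd(rhos),
      stringsAsFactors = FALSE, check.names = FALSE)
  }

  cont <- outside_limit_counts(diffs, limits)
  keep <- cont$row_totals > 0
  dropped <- rownames(cont$counts)[!keep]
  chisq <- if (sum(keep) >= 2 && all(colSums(cont$counts[keep, , drop = FALSE]) > 0)) {
    chi_square_independence(cont$counts[keep, , drop = FALSE])
  } else {
    list(statistic = NA_real_, df = NA_real_, p_value = NA_real_,
         expected = NULL, note = "degenerate: too few informative rows/columns")
  }

  structure(list(
    icc = do.call(rbind, icc_rows),
    friedman = do.call(rbind, fried_rows),
    limits = do.call(rbind, lim_rows),
    contingency = cont,
    chisq = chisq,
    chisq_dropped_parameters = dropped,
    spearman = do.call(rbind, sp_rows),
    differences = diffs,
    design = design,
    config = config
  ), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("<agreement_report> %d subjects x %d devices x %d trials\n",
              x$design$n_subjects, x$design$n_devices,
              x$design$n_trials_per_device))
  head_icc <- x$icc[x$icc$mode == x$config$agreement$icc_mode &
                    x$icc$form == "single", ]
  cat("\nICC(2,1) on FP-board differences across devices:\n")
  for (i in seq_len(nrow(head_icc))) {
    r <- head_icc[i, ]
    cat(sprintf("  %-8s %6.3f [%6.3f, %6.3f]%s\n", r$parameter,
                max(-1, min(1, r$estimate)), r$ci_lower, r$ci_upper,
                if (isTRUE(r$degenerate)) " [degenerate]" else ""))
  }
  cat("\nFriedman across devices (p-values):\n")
  for (i in seq_len(nrow(x$friedman))) {
    cat(sprintf("  %-8s p = %.3f\n", x$friedman$parameter[i],
                x$friedman$p_value[i]))
  }
  cat(sprintf("\nOut-of-limit observations: %d of %d (%.1f%%); chi-square p = %s\n",
              x$contingency$total, sum(x$contingency$n_per_cell),
              100 * x$contingency$total / sum(x$contingency$n_per_cell),
              format(x$chisq$p_value, digits = 3)))
  cat(sprintf("Mean FP-board Spearman rho: %.3f\n", mean(x$spearman$mean)))
  invisible(x)
}
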