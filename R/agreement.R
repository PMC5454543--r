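# Device-agreement statistics: paired differences, limits of agreement,
# out-of-limit contingency + chi-square, two-way random ICC, Friedman,
# Spearman, and the full interchangeability battery.

key_cols <- c("subject_id", "device_id", "trial_index")

#' Per-trial force-plate minus board differences
#'
#' For every (subject, device, trial) key present in both tables and every
#' parameter, `value = FP metric - board metric`. Keys must match exactly
#' (the two devices record the same physical trial simultaneously).
#'
#' @param fp_metrics,board_metrics Data frames keyed by `subject_id`,
#'   `device_id`, `trial_index` with the nine metric columns.
#' @return Long data frame: key columns, `parameter`, `value`.
#' @export
paired_differences <- function(fp_metrics, board_metrics) {
  for (df in list(fp_metrics, board_metrics)) {
    miss <- setdiff(c(key_cols, metric_names()), names(df))
    if (length(miss) > 0) {
      sa_format_error(sprintf("metric table missing column(s): %s",
                              paste(miss, collapse = ", ")))
    }
  }
  key_of <- function(df) do.call(paste, c(df[key_cols], sep = "/"))
  kf <- key_of(fp_metrics); kb <- key_of(board_metrics)
  orphans <- c(setdiff(kf, kb), setdiff(kb, kf))
  if (length(orphans) > 0 || anyDuplicated(kf) || anyDuplicated(kb)) {
    sa_pairing_error(sprintf(
      "unmatched or duplicated trial key(s): %s",
      paste(unique(c(orphans, kf[duplicated(kf)], kb[duplicated(kb)])),
            collapse = "; ")),
      orphans = orphans)
  }
  board_metrics <- board_metrics[match(kf, kb), , drop = FALSE]
  out <- do.call(rbind, lapply(metric_names(), function(m) {
    data.frame(fp_metrics[key_cols],
               parameter = m,
               value = fp_metrics[[m]] - board_metrics[[m]],
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Mean difference over trials per (subject, device, parameter)
#'
#' @param records Long difference table from [paired_differences()].
#' @return Data frame `subject_id`, `device_id`, `parameter`, `value`
#'   (mean over trials).
#' @export
aggregate_by_device_mean <- function(records) {
  if (nrow(records) == 0) sa_validation_error("no difference records")
  agg <- stats::aggregate(
    value ~ subject_id + device_id + parameter, data = records, FUN = mean)
  agg[order(agg$parameter, agg$subject_id, agg$device_id), , drop = FALSE]
}

#' 95% limits of agreement for one parameter
#'
#' Mean difference with `mean +/- multiplier * SD` limits (SD with
#' denominator n-1); the conventional 95% band uses multiplier 1.96. Under
#' an approximately normal difference distribution about 5% of fresh
#' differences fall outside the band.
#'
#' @param values Numeric vector of differences (one parameter), n >= 3.
#' @param multiplier Half-width multiplier (default 1.96).
#' @param parameter Optional parameter name carried into the result.
#' @return List of class `agreement_limits`: `parameter`, `mean_diff`,
#'   `sd_diff`, `lower`, `upper`, `n_obs`.
#' @export
agreement_limits <- function(values, multiplier = 1.96, parameter = NA_character_) {
  values <- as.numeric(values)
  if (length(values) < 3) sa_too_short_error("need >= 3 differences")
  if (!all(is.finite(values))) sa_validation_error("differences must be finite")
  m <- mean(values); s <- stats::sd(values)
  structure(list(parameter = parameter, mean_diff = m, sd_diff = s,
                 lower = m - multiplier * s, upper = m + multiplier * s,
                 n_obs = length(values)),
            class = "agreement_limits")
}

#' Out-of-limit contingency table (parameter x device)
#'
#' Cell (p, d) counts the differences of parameter p on device d that fall
#' strictly outside `[lower_p, upper_p]` (a value exactly on a limit counts
#' as inside). Limits are pooled per parameter across all devices.
#'
#' @param records Long difference table from [paired_differences()].
#' @param limits Named list of [agreement_limits()], one per parameter.
#' @return List: `counts` (matrix parameter x device), `ratios`
#'   (count / per-cell observation count), `n_per_cell`, `row_totals`,
#'   `col_totals`, `total`.
#' @export
outside_limit_counts <- function(records, limits) {
  params <- intersect(metric_names(), unique(records$parameter))
  devices <- sort(unique(records$device_id))
  counts <- matrix(0L, nrow = length(params), ncol = length(devices),
                   dimnames = list(params, devices))
  ncell <- counts
  for (p in params) {
    lim <- limits[[p]]
    if (is.null(lim)) sa_validation_error(sprintf("no limits for parameter '%s'", p))
    sub <- records[records$parameter == p, , drop = FALSE]
    out <- sub$value < lim$lower | sub$value > lim$upper
    for (d in devices) {
      sel <- sub$device_id == d
      counts[p, d] <- sum(out[sel])
      ncell[p, d] <- sum(sel)
    }
  }
  list(counts = counts,
       ratios = ifelse(ncell > 0, counts / ncell, NA_real_),
       n_per_cell = ncell,
       row_totals = rowSums(counts),
       col_totals = colSums(counts),
       total = sum(counts))
}

#' Pearson chi-square test of independence
#'
#' `sum (O - E)^2 / E` with expected counts from the row/column margins,
#' df = (r-1)(c-1), upper-tail chi-square p-value (no continuity
#' correction). Zero row or column margins are rejected as degenerate.
#'
#' @param table Matrix of non-negative counts, at least 2 x 2.
#' @return List: `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0) || any(!is.finite(table))) {
    sa_validation_error("counts must be finite and non-negative")
  }
  if (sum(table) <= 0) sa_degenerate_error("grand total must be positive")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    sa_degenerate_error("zero row or column margin")
  }
  if (nrow(table) < 2 || ncol(table) < 2) {
    sa_validation_error("need at least a 2 x 2 table")
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p_value = res$p.value, expected = res$expected)
}

#' Two-way random-effects intraclass correlation (model 2)
#'
#' Both targets (rows) and raters (columns; here: devices) are treated as
#' random samples. From the two-way ANOVA mean squares (rows MSR, columns
#' MSC, error MSE):
#' single form `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`,
#' average form `(MSR - MSE) / (MSR + (MSC - MSE)/n)`.
#' 95% confidence bounds use the F-based construction for these forms
#' (Satterthwaite df for the single form; the average-form interval is the
#' Spearman-Brown transform of the single-form interval). Negative lower
#' bounds are reported as-is. The raw estimate is retained (not clamped);
#' the print method clamps to [-1, 1] for display only.
#'
#' @param m Numeric matrix, n targets x k raters, complete (no NA).
#' @param form `"single"` or `"average"`.
#' @param conf_level Confidence level (default 0.95).
#' @return Object of class `icc_result`: `form`, `estimate`, `ci_lower`,
#'   `ci_upper`, `n_targets`, `k_raters`, `ms` (rows/cols/error),
#'   `degenerate`.
#' @export
icc_two_way <- function(m, form = c("single", "average"), conf_level = 0.95) {
  form <- match.arg(form)
  m <- as.matrix(m)
  if (anyNA(m)) sa_validation_error("ICC matrix must be complete (no missing cells)")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) sa_validation_error("need >= 2 targets and >= 2 raters")
  gm <- mean(m)
  rm_ <- rowMeans(m); cm <- colMeans(m)
  SSR <- k * sum((rm_ - gm)^2)
  SSC <- n * sum((cm - gm)^2)
  SST <- sum((m - gm)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1); MSC <- SSC / (k - 1); MSE <- SSE / ((n - 1) * (k - 1))
  res <- function(est, lo, hi, degen) {
    structure(list(form = form, estimate = est, ci_lower = lo, ci_upper = hi,
                   n_targets = n, k_raters = k,
                   ms = list(rows = MSR, cols = MSC, error = MSE),
                   degenerate = degen),
              class = "icc_result")
  }
  if (SST <= .Machine$double.eps * abs(gm)^2 * n * k || SST == 0) {
    # all cells equal: perfect agreement, interval degenerate
    return(res(1, NA_real_, NA_real_, TRUE))
  }
  est_single <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  est_avg <- (MSR - MSE) / (MSR + (MSC - MSE) / n)
  if (MSE <= 1e-12 * SST / (n * k - 1)) {
    # zero residual variance (e.g. identical columns): point estimate is
    # exact but the F-based interval is undefined
    est <- if (form == "single") est_single else est_avg
    return(res(est, NA_real_, NA_real_, TRUE))
  }
  alpha <- 1 - conf_level
  # F-based interval for the single form (McGraw & Wong two-way random, A,1)
  single_ci <- function(icc) {
    if (MSE <= 0) return(c(NA_real_, NA_real_))
    Fj <- MSC / MSE
    vn <- (k - 1) * (n - 1) *
      (k * icc * Fj + n * (1 + (k - 1) * icc) - k * icc)^2
    vd <- (n - 1) * k^2 * icc^2 * Fj^2 +
      (n * (1 + (k - 1) * icc) - k * icc)^2
    v <- vn / vd
    FL <- stats::qf(1 - alpha / 2, n - 1, v)
    FU <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (MSR - FL * MSE) /
      (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    hi <- n * (FU * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
    c(lo, hi)
  }
  sb <- function(x) x * k / (1 + (k - 1) * x)  # Spearman-Brown step-up
  ci1 <- single_ci(est_single)
  if (form == "single") {
    res(est_single, ci1[1], ci1[2], FALSE)
  } else {
    res(est_avg, sb(ci1[1]), sb(ci1[2]), FALSE)
  }
}

#' @export
print.icc_result <- function(x, ...) {
  est <- max(-1, min(1, x$estimate))
  cat(sprintf(
    "ICC(2,%s) = %.3f [%.3f, %.3f]%s  (n = %d targets, k = %d raters)\n",
    if (x$form == "single") "1" else "k", est, x$ci_lower, x$ci_upper,
    if (isTRUE(x$degenerate)) " [degenerate]" else "", x$n_targets, x$k_raters))
  invisible(x)
}

#' Friedman repeated-measures rank test
#'
#' Within-block midranks with the tie-corrected statistic
#' `12 * sum((R_j - n(k+1)/2)^2) / (n k (k+1) - sum(t^3 - t)/(k-1))`,
#' df = k-1, upper-tail chi-square p. With `exact = TRUE` the permutation
#' p-value is computed by full enumeration of the `(k!)^n` within-block
#' permutations (only feasible for small designs; the statistic is
#' unchanged).
#'
#' @param m Numeric matrix, n blocks x k treatments, complete.
#' @param exact Logical; exact permutation p-value by enumeration.
#' @param max_perms Enumeration guard for `exact = TRUE`.
#' @return List: `statistic`, `df`, `p_value`, `mean_ranks`, `method`.
#' @export
friedman_test <- function(m, exact = FALSE, max_perms = 1e6) {
  m <- as.matrix(m)
  if (anyNA(m)) sa_validation_error("Friedman matrix must be complete")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) sa_validation_error("need >= 2 blocks and >= 2 treatments")
  r <- t(apply(m, 1, rank))
  stat_from_ranks <- function(r) {
    Rj <- colSums(r)
    ties <- apply(r, 1, function(row) {
      tb <- table(row)
      sum(tb^3 - tb)
    })
    denom <- n * k * (k + 1) - sum(ties) / (k - 1)
    if (denom <= 0) return(0)
    12 * sum((Rj - n * (k + 1) / 2)^2) / denom
  }
  stat <- stat_from_ranks(r)
  df <- k - 1
  if (!exact) {
    p <- if (stat == 0 && all(apply(r, 1, function(x) length(unique(x)) == 1))) {
      1
    } else {
      stats::pchisq(stat, df, lower.tail = FALSE)
    }
    return(list(statistic = stat, df = df, p_value = min(1, p),
                mean_ranks = colMeans(r), method = "chi-square"))
  }
  nperm <- factorial(k)^n
  if (nperm > max_perms) {
    sa_validation_error(sprintf(
      "exact enumeration needs %.3g permutations (> %g)", nperm, max_perms))
  }
  perms <- all_permutations(k)
  idx <- rep(list(seq_len(nrow(perms))), n)
  grid <- as.matrix(expand.grid(idx))
  stats_all <- apply(grid, 1, function(g) {
    rp <- t(vapply(seq_len(n), function(i) r[i, perms[g[i], ]], numeric(k)))
    stat_from_ranks(rp)
  })
  p <- mean(stats_all >= stat - 1e-12)
  list(statistic = stat, df = df, p_value = p,
       mean_ranks = colMeans(r), method = "exact-permutation")
}

all_permutations <- function(k) {
  if (k == 1) return(matrix(1, 1, 1))
  sub <- all_permutations(k - 1)
  out <- NULL
  for (i in seq_len(k)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  unname(out)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midrank-transformed values.
#'
#' @param x,y Paired numeric vectors, equal length n >= 3.
#' @return Correlation in [-1, 1].
#' @export
spearman_rho <- function(x, y) {
  n <- length(x)
  if (length(y) != n) sa_validation_error("x and y must have equal length")
  if (n < 3) sa_too_short_error("need >= 3 pairs")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    sa_degenerate_error("zero rank variance: correlation undefined")
  }
  stats::cor(rx, ry)
}
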