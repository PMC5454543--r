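# Delimited-text I/O for trial recordings and metric tables.
#
# Dialect: comma-separated, UTF-8, with "#"-prefixed metadata lines
# (subject, device, trial, kind) before the header row. Units are fixed:
# forces N, moments N·m, time s, CoP mm. Numeric round-trip is exact to
# better than 1e-9 (values written with 15 significant digits).

fmt_num <- function(x) {
  out <- sprintf("%.15g", x)
  out[!is.finite(x)] <- as.character(x[!is.finite(x)])
  out
}

#' Write a trial recording to CSV
#'
#' Writes metadata comment lines (`# subject:`, `# device:`, `# trial:`,
#' `# kind:`), then a header `t,<channels...>` and one row per sample.
#' Values are pass-through: no clipping or rounding beyond 15 significant
#' digits, so `read_trial(write_trial(x))` reproduces `x` within 1e-9.
#'
#' @param rec A [trial_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(rec, path) {
  if (!inherits(rec, "trial_recording")) {
    sa_validation_error("rec must be a trial_recording")
  }
  con <- tryCatch(file(path, open = "wb"), error = function(e) NULL,
                  warning = function(w) NULL)
  if (is.null(con)) sa_io_error(sprintf("cannot open '%s' for writing", path))
  on.exit(close(con))
  hdr <- c(
    sprintf("# subject: %s", rec$subject_id),
    sprintf("# device: %s", rec$device_id),
    sprintf("# trial: %d", rec$trial_index),
    sprintf("# kind: %s", rec$kind),
    paste(c("t", colnames(rec$channels)), collapse = ","))
  body <- do.call(paste, c(
    list(fmt_num(rec$timestamps)),
    lapply(seq_len(ncol(rec$channels)), function(j) fmt_num(rec$channels[, j])),
    sep = ","))
  writeLines(c(hdr, body), con = con, sep = "\n")
  invisible(path)
}

parse_meta <- function(lines) {
  meta <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.*?)\\s*$", ln))[[1]]
    if (length(m) == 3) meta[[tolower(m[2])]] <- m[3]
  }
  meta
}

#' Read a trial recording from CSV
#'
#' Counterpart of [write_trial()]. The header row must contain exactly the
#' columns expected for `kind` (board: `t,TL,TR,BL,BR`; force plate:
#' `t,Fx,Fy,Fz,Mx,My,Mz`); missing or extra columns raise a format error
#' naming the column. Non-monotonic timestamps raise a validation error with
#' the first offending index.
#'
#' @param path File to read.
#' @param kind `"board"` or `"forceplate"`; if `NULL`, taken from the file's
#'   `# kind:` metadata line.
#' @return A [trial_recording()].
#' @export
read_trial <- function(path, kind = NULL) {
  if (!file.exists(path)) sa_io_error(sprintf("file '%s' does not exist", path))
  lines <- readLines(path, warn = FALSE)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- parse_meta(meta_lines)
  if (is.null(kind)) {
    kind <- meta$kind
    if (is.null(kind)) {
      sa_format_error(sprintf("'%s' has no '# kind:' metadata and no kind given", path))
    }
  }
  kind <- match.arg(kind, c("board", "forceplate"))
  expected <- channel_names_for(kind)
  data_lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(data_lines) < 1) sa_format_error(sprintf("'%s' has no header row", path))
  header <- trimws(strsplit(data_lines[1], ",", fixed = TRUE)[[1]])
  want <- c("t", expected)
  missing_cols <- setdiff(want, header)
  if (length(missing_cols) > 0) {
    sa_format_error(sprintf("'%s' is missing column(s): %s", path,
                            paste(missing_cols, collapse = ", ")),
                    columns = missing_cols)
  }
  extra <- setdiff(header, want)
  if (length(extra) > 0) {
    sa_format_error(sprintf("'%s' has unexpected column(s): %s", path,
                            paste(extra, collapse = ", ")),
                    columns = extra)
  }
  body <- data_lines[-1]
  if (length(body) < 2) {
    sa_validation_error(sprintf("'%s' has fewer than 2 samples", path))
  }
  df <- utils::read.csv(text = paste(data_lines, collapse = "\n"),
                        header = TRUE, colClasses = "numeric")
  df <- df[, want, drop = FALSE]
  trial_recording(
    subject_id = meta$subject %||% "unknown",
    device_id = meta$device %||% "unknown",
    trial_index = as.integer(meta$trial %||% 1L),
    kind = kind,
    timestamps = df$t,
    channels = as.matrix(df[, expected, drop = FALSE]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the per-trial metrics table
#'
#' One row per trial, key columns first, then the nine parameter columns in
#' the fixed order of [metric_names()]. Duplicate
#' (subject, device, trial, role) keys are rejected.
#'
#' @param rows Data frame with columns `subject_id`, `device_id`,
#'   `trial_index`, optionally `role` (`board`/`forceplate`), and the nine
#'   metric columns.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_metrics_table <- function(rows, path) {
  if (!is.data.frame(rows) || nrow(rows) == 0) {
    sa_validation_error("rows must be a non-empty data frame")
  }
  keys <- c("subject_id", "device_id", "trial_index",
            if ("role" %in% names(rows)) "role")
  missing_cols <- setdiff(c(keys, metric_names()), names(rows))
  if (length(missing_cols) > 0) {
    sa_format_error(sprintf("metrics table missing column(s): %s",
                            paste(missing_cols, collapse = ", ")))
  }
  key_str <- do.call(paste, c(rows[keys], sep = "\r"))
  if (anyDuplicated(key_str)) {
    dup <- rows[duplicated(key_str), keys, drop = FALSE]
    sa_validation_error(sprintf(
      "duplicate trial key(s): %s",
      paste(apply(dup, 1, paste, collapse = "/"), collapse = "; ")))
  }
  out <- rows[, c(keys, metric_names()), drop = FALSE]
  for (m in metric_names()) out[[m]] <- fmt_num(out[[m]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a metrics table written by [write_metrics_table()]
#'
#' @param path CSV path.
#' @return Data frame with key columns and the nine metric columns.
#' @export
read_metrics_table <- function(path) {
  if (!file.exists(path)) sa_io_error(sprintf("file '%s' does not exist", path))
  df <- utils::read.csv(path, header = TRUE, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c("subject_id", "device_id", "trial_index", metric_names()),
                          names(df))
  if (length(missing_cols) > 0) {
    sa_format_error(sprintf("metrics table missing column(s): %s",
                            paste(missing_cols, collapse = ", ")))
  }
  for (m in metric_names()) {
    v <- df[[m]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (anyNA(vn) && !anyNA(v)) {
        bad <- which(is.na(vn))[1]
        sa_format_error(sprintf("non-numeric value in column '%s' at row %d", m, bad))
      }
      v <- vn
    }
    if (anyNA(v)) {
      sa_format_error(sprintf("missing value in column '%s' at row %d",
                              m, which(is.na(v))[1]))
    }
    df[[m]] <- v
  }
  df
}
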