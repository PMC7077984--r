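#' Session metadata for a plethysmography recording
#'
#' Describes one recording session: the animal, the drug condition, the gas
#' condition and the epoch relative to any viral-injection manipulation.
#'
#' @param animal_id Character scalar identifying the animal.
#' @param drug One of `"saline"`, `"morphine"`, `"fentanyl"`.
#' @param dose Dose in mg/kg. Must be 0 for saline.
#' @param gas One of `"normoxia"`, `"hypercapnia"`.
#' @param epoch One of `"pre_injection"`, `"post_injection_site1"`,
#'   `"post_injection_site2"`, `"sham"`.
#' @param duration_s Session duration in seconds (or `NA` if unknown).
#' @return A list of class `session_meta`.
#' @export
#' @examples
#' session_meta("m01", drug = "morphine", dose = 20, gas = "hypercapnia")
session_meta <- function(animal_id = "unknown",
                         drug = c("saline", "morphine", "fentanyl"),
                         dose = 0,
                         gas = c("normoxia", "hypercapnia"),
                         epoch = c("pre_injection", "post_injection_site1",
                                   "post_injection_site2", "sham"),
                         duration_s = NA_real_) {
  drug <- match.arg(drug)
  gas <- match.arg(gas)
  epoch <- match.arg(epoch)
  if (drug == "saline" && dose != 0) {
    stop("`dose` must be 0 for saline sessions.", call. = FALSE)
  }
  if (!is.na(duration_s) && duration_s <= 0) {
    stop("`duration_s` must be positive.", call. = FALSE)
  }
  structure(
    list(animal_id = as.character(animal_id), drug = drug, dose = dose,
         gas = gas, epoch = epoch, duration_s = duration_s),
    class = "session_meta"
  )
}

#' Construct an airflow trace
#'
#' An airflow trace is a tibble with columns `time` (seconds) and `flow`
#' (mL/s, inspiration negative) carrying the sampling rate and session
#' metadata as attributes. It is the raw input to breath segmentation.
#'
#' @param flow Numeric vector of airflow samples in mL/s.
#' @param sampling_rate Sampling rate in Hz.
#' @param start_time Time of the first sample in seconds.
#' @param meta A [session_meta()] object.
#' @return A tibble of class `airflow_trace` with columns `time`, `flow`.
#' @export
#' @examples
#' tr <- airflow_trace(sin(seq(0, 2 * pi, length.out = 100)), 1000)
#' sampling_rate(tr)
airflow_trace <- function(flow, sampling_rate = 1000, start_time = 0,
                          meta = session_meta()) {
  flow <- as.numeric(flow)
  if (length(flow) < 2) stop("An airflow trace needs at least 2 samples.", call. = FALSE)
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("`sampling_rate` must be a positive number.", call. = FALSE)
  }
  bad <- which(!is.finite(flow))
  if (length(bad)) {
    stop("Non-finite airflow samples at indices: ",
         paste(head(bad, 10), collapse = ", "),
         if (length(bad) > 10) sprintf(" (and %d more)", length(bad) - 10),
         call. = FALSE)
  }
  out <- tibble(
    time = start_time + (seq_along(flow) - 1) / sampling_rate,
    flow = flow
  )
  attr(out, "sampling_rate") <- as.numeric(sampling_rate)
  attr(out, "meta") <- meta
  class(out) <- c("airflow_trace", class(out))
  out
}

#' @rdname airflow_trace
#' @param x An `airflow_trace`.
#' @export
sampling_rate <- function(x) attr(x, "sampling_rate")

#' @rdname airflow_trace
#' @export
trace_meta <- function(x) attr(x, "meta")

#' @export
print.airflow_trace <- function(x, ...) {
  m <- trace_meta(x)
  cat(sprintf("<airflow_trace> %d samples @ %g Hz (%.1f s)\n",
              nrow(x), sampling_rate(x), nrow(x) / sampling_rate(x)))
  if (!is.null(m)) {
    cat(sprintf("  animal %s | %s | %s | %s\n",
                m$animal_id, m$drug, m$gas, m$epoch))
  }
  NextMethod()
}

meta_header_lines <- function(meta) {
  c(sprintf("# animal_id: %s", meta$animal_id),
    sprintf("# drug: %s", meta$drug),
    sprintf("# dose: %s", format(meta$dose, digits = 15)),
    sprintf("# gas: %s", meta$gas),
    sprintf("# epoch: %s", meta$epoch))
}

parse_meta_header <- function(lines) {
  kv <- sub("^#\\s*", "", lines)
  keys <- trimws(sub(":.*$", "", kv))
  vals <- trimws(sub("^[^:]*:\\s*", "", kv))
  fields <- as.list(setNames(vals, keys))
  session_meta(
    animal_id = fields$animal_id %||% "unknown",
    drug = fields$drug %||% "saline",
    dose = as.numeric(fields$dose %||% 0),
    gas = fields$gas %||% "normoxia",
    epoch = fields$epoch %||% "pre_injection"
  )
}

#' Read an airflow trace from delimited text
#'
#' Accepts either a two-column file (`time_s`, `flow_ml_s`) or a
#' single-column file of flow values with the rate given via
#' `sampling_rate`. Leading lines starting with `#` are parsed as a
#' `key: value` metadata header (`animal_id`, `drug`, `dose`, `gas`,
#' `epoch`); arguments override the header. Time stamps must be strictly
#' increasing and uniform to within `jitter_tol` relative jitter.
#'
#' @param path Path to a CSV file.
#' @param sampling_rate Sampling rate in Hz, required for single-column
#'   files; for two-column files it is inferred from the time stamps.
#' @param meta Optional [session_meta()] overriding any file header.
#' @param jitter_tol Maximum tolerated relative deviation of inter-sample
#'   intervals from their median (default 1%).
#' @return An [airflow_trace()].
#' @export
read_trace <- function(path, sampling_rate = NULL, meta = NULL,
                       jitter_tol = 0.01) {
  if (!file.exists(path)) stop("File not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- grepl("^#", lines)
  header_meta <- if (any(hdr)) parse_meta_header(lines[hdr]) else NULL
  body <- lines[!hdr]
  dat <- readr::read_csv(I(paste(body, collapse = "\n")),
                         show_col_types = FALSE, progress = FALSE)
  if (ncol(dat) >= 2) {
    time <- as.numeric(dat[[1]])
    flow <- as.numeric(dat[[2]])
    dt <- diff(time)
    if (any(dt <= 0)) stop("non-monotonic time", call. = FALSE)
    med <- median(dt)
    if (max(abs(dt - med)) > jitter_tol * med) {
      stop("Time stamps are not uniform within ",
           format(100 * jitter_tol), "% jitter.", call. = FALSE)
    }
    rate <- 1 / med
    start <- time[1]
  } else {
    flow <- as.numeric(dat[[1]])
    if (is.null(sampling_rate)) {
      stop("Single-column trace files need an explicit `sampling_rate`.",
           call. = FALSE)
    }
    rate <- sampling_rate
    start <- 0
  }
  bad <- which(!is.finite(flow))
  if (length(bad)) {
    stop("Non-finite airflow samples at indices: ",
         paste(head(bad, 10), collapse = ", "),
         if (length(bad) > 10) sprintf(" (and %d more)", length(bad) - 10),
         call. = FALSE)
  }
  airflow_trace(flow, sampling_rate = rate, start_time = start,
                meta = meta %||% header_meta %||% session_meta())
}

#' Write an airflow trace to delimited text
#'
#' Writes a `#`-prefixed metadata header followed by `time_s,flow_ml_s`
#' rows. [read_trace()] on the result reconstructs the trace (round trip).
#'
#' @param trace An [airflow_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "airflow_trace"))
  meta <- trace_meta(trace)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta_header_lines(meta), con)
  writeLines("time_s,flow_ml_s", con)
  writeLines(paste(format(trace$time, digits = 15, scientific = FALSE, trim = TRUE),
                   format(trace$flow, digits = 15, trim = TRUE), sep = ","), con)
  invisible(path)
}

breath_table_cols <- c("onset_s", "ti_ms", "te_ms", "pause_ms", "te_total_ms",
                       "period_ms", "freq_hz", "pif_ml_s", "pef_ml_s",
                       "tv_ul", "mv_ml_min", "has_pause", "qc_flags")

#' Write a breath table to CSV
#'
#' The breath table is the per-breath feature tibble produced by
#' [compute_features()]. Columns are written in a fixed order
#' (`onset_s, ti_ms, te_ms, pause_ms, te_total_ms, period_ms, freq_hz,
#' pif_ml_s, pef_ml_s, tv_ul, mv_ml_min, has_pause, qc_flags`) so files
#' are comparable across sessions; re-reading gives values equal to at
#' least 6 significant digits.
#'
#' @param table A breath-table tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_breath_table <- function(table, path) {
  missing_cols <- setdiff(breath_table_cols, names(table))
  if (length(missing_cols)) {
    stop("Breath table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  readr::write_csv(table[breath_table_cols], path, progress = FALSE)
  invisible(path)
}

#' @rdname write_breath_table
#' @export
read_breath_table <- function(path) {
  readr::read_csv(path,
                  col_types = readr::cols(
                    has_pause = readr::col_logical(),
                    qc_flags = readr::col_character(),
                    .default = readr::col_double()
                  ),
                  progress = FALSE) |>
    dplyr::mutate(qc_flags = dplyr::coalesce(.data$qc_flags, ""))
}

#' Read segmentation and pause configuration from YAML
#'
#' The YAML file may contain top-level keys `qc` (fields of [qc_config()])
#' and `pause` (fields of [pause_config()]); missing fields fall back to
#' the defaults.
#'
#' @param path Path to a YAML file.
#' @return A list with elements `qc` and `pause`.
#' @export
read_analysis_config <- function(path) {
  y <- yaml::read_yaml(path)
  list(
    qc = do.call(qc_config, y$qc %||% list()),
    pause = do.call(pause_config, y$pause %||% list())
  )
}
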