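#' Pause-detection configuration
#'
#' The pause is the third breath phase seen under opioids: expiratory-period
#' time after airflow drops below `flow_threshold`, lasting until the next
#' inspiration onset. Spans shorter than `min_pause_ms` are still measured
#' but not called pauses (`has_pause = FALSE`), because very short
#' sub-threshold tails occur even in unremarkable breaths.
#'
#' @param flow_threshold Airflow threshold in mL/s (default 0.5).
#' @param min_pause_ms Minimum sub-threshold span (ms) for `has_pause`
#'   (default 50).
#' @return A list of class `pause_config`.
#' @export
pause_config <- function(flow_threshold = 0.5, min_pause_ms = 50) {
  if (flow_threshold <= 0) stop("`flow_threshold` must be > 0.", call. = FALSE)
  if (min_pause_ms < 0) stop("`min_pause_ms` must be >= 0.", call. = FALSE)
  structure(list(flow_threshold = flow_threshold, min_pause_ms = min_pause_ms),
            class = "pause_config")
}

# Locate the pause onset within one segment. The search starts after the
# expiratory peak so the rising limb of expiration cannot trigger it; later
# re-excursions above threshold (hypercapnic active expiration) do not end
# the pause. Returns the 1-based sample index of pause onset, or `end` if
# flow never drops below threshold after the peak.
find_pause_onset <- function(flow, exp_onset, end, flow_threshold) {
  span <- exp_onset:(end - 1L)
  peak_rel <- which.max(flow[span])
  after <- span[span >= span[peak_rel]]
  below <- after[flow[after] < flow_threshold]
  if (!length(below)) end else below[1]
}

#' Pause length of one breath
#'
#' Time from the first sub-threshold sample after the expiratory peak to
#' the next inspiration onset. If the span is shorter than
#' `cfg$min_pause_ms` it is still returned but flagged `has_pause = FALSE`;
#' if flow never drops below threshold the pause is 0.
#'
#' @param trace An [airflow_trace()].
#' @param seg A one-row breath segment (list or one-row tibble with
#'   `insp_onset`, `exp_onset`, `end`).
#' @param cfg A [pause_config()].
#' @return A list with `pause_ms`, `has_pause`, `pause_onset`.
#' @export
pause_length <- function(trace, seg, cfg = pause_config()) {
  rate <- sampling_rate(trace)
  if (seg$end - seg$exp_onset < 1L) {
    return(list(pause_ms = NA_real_, has_pause = FALSE,
                pause_onset = NA_integer_, error = "no_expiration"))
  }
  onset <- find_pause_onset(trace$flow, seg$exp_onset, seg$end,
                            cfg$flow_threshold)
  pause_ms <- (seg$end - onset) / rate * 1000
  list(pause_ms = pause_ms,
       has_pause = pause_ms >= cfg$min_pause_ms && pause_ms > 0,
       pause_onset = as.integer(onset), error = NA_character_)
}

#' Approximated tidal volume of one breath
#'
#' Trapezoidal integral of `|flow|` over the inspiratory span
#' `[insp_onset, exp_onset]`, in microlitres. No humidity/temperature
#' correction is applied, so volumes are comparable within-animal between
#' conditions rather than absolute.
#'
#' @inheritParams pause_length
#' @return Tidal volume in uL.
#' @export
tidal_volume <- function(trace, seg) {
  rate <- sampling_rate(trace)
  y <- abs(trace$flow[seg$insp_onset:seg$exp_onset])
  if (length(y) < 2) return(0)
  sum((y[-1] + y[-length(y)]) / 2) / rate * 1000  # mL -> uL
}

#' Instantaneous respiratory frequency
#'
#' The inverse of the breath period.
#'
#' @param period_ms Breath period in ms.
#' @return Frequency in Hz.
#' @export
#' @examples
#' instantaneous_frequency(200) # 5 Hz
instantaneous_frequency <- function(period_ms) {
  if (any(period_ms <= 0)) stop("Breath period must be > 0.", call. = FALSE)
  1000 / period_ms
}

#' Minute ventilation
#'
#' Approximated tidal volume times respiratory rate.
#'
#' @param tv_ul Tidal volume in uL.
#' @param freq_hz Instantaneous frequency in Hz.
#' @return Minute ventilation in mL/min.
#' @export
#' @examples
#' minute_ventilation(150, 4) # 36 mL/min
minute_ventilation <- function(tv_ul, freq_hz) {
  stopifnot(all(tv_ul >= 0), all(freq_hz >= 0))
  tv_ul / 1000 * freq_hz * 60
}

#' Compute per-breath respiratory features
#'
#' Builds the breath table: one row per segment with phase durations
#' (`ti_ms`, `te_ms`, `pause_ms`; `te_total_ms = te_ms + pause_ms`), the
#' period and instantaneous frequency, peak inspiratory airflow (positive
#' magnitude) and peak expiratory airflow (before pause onset),
#' approximated tidal volume and minute ventilation. QC-flagged segments
#' keep their flags; per-breath feature failures are recorded in
#' `qc_flags`, never abort the table. Phase additivity holds by
#' construction: `ti_ms + te_ms + pause_ms = period_ms` to within one
#' sample.
#'
#' @param trace An [airflow_trace()].
#' @param segments Output of [segment_breaths()].
#' @param cfg A [pause_config()].
#' @return A breath-table tibble (see [write_breath_table()] for columns),
#'   plus `qc_pass`.
#' @export
compute_features <- function(trace, segments, cfg = pause_config()) {
  if (nrow(segments) == 0) {
    return(tibble(
      onset_s = numeric(), ti_ms = numeric(), te_ms = numeric(),
      pause_ms = numeric(), te_total_ms = numeric(), period_ms = numeric(),
      freq_hz = numeric(), pif_ml_s = numeric(), pef_ml_s = numeric(),
      tv_ul = numeric(), mv_ml_min = numeric(), has_pause = logical(),
      qc_flags = character(), qc_pass = logical()
    ))
  }
  rate <- sampling_rate(trace)
  flow <- trace$flow
  t0 <- trace$time[1]
  n <- nrow(segments)
  i0 <- segments$insp_onset
  i1 <- segments$exp_onset
  i2 <- segments$end
  pause_onset <- integer(n)
  pif <- pef <- tv <- numeric(n)
  feat_err <- character(n)
  for (k in seq_len(n)) {
    a <- i0[k]; b <- i1[k]; e <- i2[k]
    if (e - b < 1L) {
      pause_onset[k] <- e
      feat_err[k] <- "no_expiration"
      pef[k] <- NA_real_
    } else {
      pause_onset[k] <- find_pause_onset(flow, b, e, cfg$flow_threshold)
      feat_err[k] <- ""
      pef[k] <- max(flow[b:max(b, pause_onset[k] - 1L)])
    }
    pif[k] <- max(-flow[a:(b - 1L)])
    y <- abs(flow[a:b])
    tv[k] <- sum((y[-1] + y[-length(y)]) / 2) / rate * 1000
  }
  flags <- segments$qc_flags
  bad <- nzchar(feat_err)
  flags[bad] <- ifelse(nzchar(flags[bad]),
                       paste(flags[bad], feat_err[bad], sep = ";"),
                       feat_err[bad])
  period_ms <- (i2 - i0) / rate * 1000
  ti_ms <- (i1 - i0) / rate * 1000
  pause_ms <- ifelse(bad, 0, (i2 - pause_onset) / rate * 1000)
  te_ms <- (pause_onset - i1) / rate * 1000
  freq <- 1000 / period_ms
  tibble(
    onset_s = t0 + (i0 - 1L) / rate,
    ti_ms = ti_ms, te_ms = te_ms, pause_ms = pause_ms,
    te_total_ms = te_ms + pause_ms, period_ms = period_ms,
    freq_hz = freq, pif_ml_s = pif, pef_ml_s = pef, tv_ul = tv,
    mv_ml_min = tv / 1000 * freq * 60,
    has_pause = !bad & pause_ms >= cfg$min_pause_ms & pause_ms > 0,
    qc_flags = flags,
    qc_pass = !nzchar(flags)
  )
}

#' Segment a trace and compute its breath table in one call
#'
#' Convenience pipeline wrapper: [segment_breaths()] then
#' [compute_features()].
#'
#' @inheritParams compute_features
#' @param qc A [qc_config()].
#' @return A breath-table tibble.
#' @export
breath_table <- function(trace, qc = qc_config(), cfg = pause_config()) {
  compute_features(trace, segment_breaths(trace, qc), cfg)
}
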