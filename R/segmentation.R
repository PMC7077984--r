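#' Quality-control configuration for breath segmentation
#'
#' Defaults reject noise-born micro-crossings and implausibly short or
#' long candidate breaths while passing the slowest opioid-depressed
#' breaths (rate down to ~0.2 Hz with pauses of several hundred ms).
#'
#' @param hysteresis Minimum excursion (mL/s) the signal must reach on the
#'   far side of zero before a crossing is accepted.
#' @param min_breath_ms Shortest acceptable breath period (ms).
#' @param max_breath_ms Longest acceptable breath period (ms).
#' @param min_peak_insp_flow Smallest acceptable peak inspiratory airflow
#'   magnitude (mL/s).
#' @return A list of class `qc_config`.
#' @export
qc_config <- function(hysteresis = 0.05, min_breath_ms = 50,
                      max_breath_ms = 5000, min_peak_insp_flow = 0.2) {
  vals <- list(hysteresis = hysteresis, min_breath_ms = min_breath_ms,
               max_breath_ms = max_breath_ms,
               min_peak_insp_flow = min_peak_insp_flow)
  if (any(unlist(vals) < 0)) stop("QC parameters must be >= 0.", call. = FALSE)
  structure(vals, class = "qc_config")
}

#' Detect signed zero-crossings of airflow with hysteresis
#'
#' A crossing is emitted only once the signal, after crossing zero, reaches
#' at least `hysteresis` mL/s on the far side for two consecutive samples
#' (Schmitt-trigger logic with a short confirmation), so baseline noise
#' does not fragment breaths. The crossing sample is located
#' by linear interpolation between the last pair of samples straddling zero
#' before the far-side excursion, rounded to the nearest sample. Crossing
#' directions alternate by construction.
#'
#' @param trace An [airflow_trace()].
#' @param hysteresis Excursion threshold in mL/s.
#' @return A tibble with columns `index` (sample index, 1-based) and
#'   `direction` (`"pos_to_neg"` = inspiration onset, `"neg_to_pos"` =
#'   expiration onset).
#' @export
#' @examples
#' t <- seq(0, 1, by = 1e-3)
#' tr <- airflow_trace(-sin(2 * pi * t), 1000)
#' detect_crossings(tr)
detect_crossings <- function(trace, hysteresis = 0.05) {
  stopifnot(inherits(trace, "airflow_trace"))
  flow <- trace$flow
  n <- length(flow)
  pos <- flow >= hysteresis
  neg <- flow <= -hysteresis
  # a state is committed by two consecutive samples beyond the threshold,
  # so isolated noise spikes cannot flip it
  state <- integer(n)
  state[pos & c(FALSE, pos[-n])] <- 1L
  state[neg & c(FALSE, neg[-n])] <- -1L
  idx <- which(state != 0L)
  if (length(idx) < 2) {
    return(tibble(index = integer(), direction = character()))
  }
  s <- state[idx]
  flips <- which(s[-1] != s[-length(s)])
  if (!length(flips)) {
    return(tibble(index = integer(), direction = character()))
  }
  out_idx <- integer(length(flips))
  out_dir <- character(length(flips))
  for (k in seq_along(flips)) {
    a <- idx[flips[k]]        # last sample committed to the old sign
    b <- idx[flips[k] + 1L]   # first sample committed to the new sign
    span <- a:(b - 1L)
    if (s[flips[k]] > 0) {
      cand <- span[flow[span] >= 0 & flow[span + 1L] < 0]
      dir <- "pos_to_neg"
    } else {
      cand <- span[flow[span] <= 0 & flow[span + 1L] > 0]
      dir <- "neg_to_pos"
    }
    i <- if (length(cand)) cand[length(cand)] else a
    f0 <- flow[i]; f1 <- flow[i + 1L]
    frac <- if (f0 == f1) 0 else f0 / (f0 - f1)
    out_idx[k] <- i + as.integer(round(frac))
    out_dir[k] <- dir
  }
  tibble(index = out_idx, direction = out_dir)
}

#' Segment a trace into breaths
#'
#' One breath spans consecutive inspiration onsets (positive-to-negative
#' zero-crossings) with the intervening expiration onset
#' (negative-to-positive crossing). Segments are half-open
#' `[insp_onset, end)` and tile the covered span, so each segment's `end`
#' is the next segment's `insp_onset`. Segments failing quality control
#' (too short, too long, or with peak inspiratory flow below
#' `min_peak_insp_flow`) are flagged, not dropped: downstream averages
#' exclude them while the table keeps them visible.
#'
#' @param trace An [airflow_trace()].
#' @param qc A [qc_config()].
#' @return A tibble with columns `breath`, `insp_onset`, `exp_onset`,
#'   `end` (1-based sample indices), `qc_flags` (`";"`-joined flag string,
#'   `""` if clean) and `qc_pass`.
#' @export
segment_breaths <- function(trace, qc = qc_config()) {
  stopifnot(inherits(trace, "airflow_trace"))
  rate <- sampling_rate(trace)
  cr <- detect_crossings(trace, hysteresis = qc$hysteresis)
  p2n <- cr$index[cr$direction == "pos_to_neg"]
  if (length(p2n) < 2) {
    warning("Fewer than 2 inspiration onsets; no breaths segmented.",
            call. = FALSE)
    return(tibble(breath = integer(), insp_onset = integer(),
                  exp_onset = integer(), end = integer(),
                  qc_flags = character(), qc_pass = logical()))
  }
  n2p <- cr$index[cr$direction == "neg_to_pos"]
  flow <- trace$flow
  i0 <- p2n[-length(p2n)]
  i1 <- p2n[-1]
  # first expiration onset after each inspiration onset
  pos <- findInterval(i0, n2p) + 1L
  mid <- ifelse(pos <= length(n2p), n2p[pos], NA_integer_)
  keep <- !is.na(mid) & mid > i0 & mid < i1
  if (!any(keep)) {
    warning("No complete breaths found.", call. = FALSE)
    return(tibble(breath = integer(), insp_onset = integer(),
                  exp_onset = integer(), end = integer(),
                  qc_flags = character(), qc_pass = logical()))
  }
  out <- tibble(
    breath = seq_len(sum(keep)),
    insp_onset = as.integer(i0[keep]),
    exp_onset = as.integer(mid[keep]),
    end = as.integer(i1[keep])
  )
  dur_ms <- (out$end - out$insp_onset) / rate * 1000
  pif <- vapply(seq_len(nrow(out)), function(k) {
    max(-flow[out$insp_onset[k]:(out$exp_onset[k] - 1L)])
  }, numeric(1))
  flag_mat <- cbind(short = dur_ms < qc$min_breath_ms,
                    long = dur_ms > qc$max_breath_ms,
                    low_flow = pif < qc$min_peak_insp_flow)
  flags <- apply(flag_mat, 1, function(f) {
    paste(colnames(flag_mat)[f], collapse = ";")
  })
  out$qc_flags <- flags
  out$qc_pass <- flags == ""
  out
}
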