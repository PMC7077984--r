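#' Construct an in vitro slice recording
#'
#' An extracellular population recording (arbitrary units) from a
#' rhythmic brainstem slice, with an epoch table assigning spans of the
#' recording to bath conditions (baseline, agonist doses, antagonist).
#'
#' @param signal Numeric vector, arbitrary units.
#' @param sampling_rate Sampling rate in Hz (nominally 10000).
#' @param epochs A tibble with columns `label` (character), `dose_nm`
#'   (numeric; 0 for baseline), `start_s`, `end_s`. Epochs must be ordered,
#'   non-overlapping, and start with the baseline epoch.
#' @return A tibble of class `slice_trace` with columns `time`, `signal`.
#' @export
slice_trace <- function(signal, sampling_rate = 10000, epochs) {
  signal <- as.numeric(signal)
  stopifnot(length(signal) >= 2, sampling_rate > 0)
  epochs <- as_tibble(epochs)
  req <- c("label", "dose_nm", "start_s", "end_s")
  if (!all(req %in% names(epochs))) {
    stop("`epochs` needs columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  if (is.unsorted(epochs$start_s, strictly = TRUE) ||
      any(epochs$end_s[-nrow(epochs)] > epochs$start_s[-1] + 1e-9)) {
    stop("Epochs must be ordered and non-overlapping.", call. = FALSE)
  }
  if (epochs$dose_nm[1] != 0) {
    stop("First epoch must be the baseline (dose 0).", call. = FALSE)
  }
  out <- tibble(time = (seq_along(signal) - 1) / sampling_rate,
                signal = signal)
  attr(out, "sampling_rate") <- sampling_rate
  attr(out, "epochs") <- epochs
  class(out) <- c("slice_trace", class(out))
  out
}

#' @rdname slice_trace
#' @param x A `slice_trace`.
#' @export
slice_epochs <- function(x) attr(x, "epochs")

#' Filter and integrate a slice recording
#'
#' Band-pass filters the raw signal (Butterworth, default 3-400 Hz,
#' zero-phase via forward-backward filtering), full-wave rectifies it, and
#' smooths with a centered moving-average integration window. The result
#' is the integrated envelope on which bursts are detected.
#'
#' @param trace A [slice_trace()].
#' @param band Length-2 numeric, band edges in Hz.
#' @param smooth_ms Integration window in ms.
#' @param order Butterworth order per pass.
#' @return A `slice_trace` whose `signal` is the envelope; attribute
#'   `envelope = TRUE`.
#' @export
preprocess_slice <- function(trace, band = c(3, 400), smooth_ms = 50,
                             order = 2) {
  rate <- attr(trace, "sampling_rate")
  if (rate <= 2 * band[2]) {
    stop("Sampling rate too low for a ", band[2], " Hz band edge.",
         call. = FALSE)
  }
  bf <- signal::butter(order, band / (rate / 2), type = "pass")
  x <- signal::filtfilt(bf, trace$signal - mean(trace$signal))
  x <- abs(x)
  w <- max(1L, as.integer(round(smooth_ms / 1000 * rate)))
  if (w %% 2 == 0) w <- w + 1L
  env <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
  env[is.na(env)] <- 0
  out <- trace
  out$signal <- env
  attr(out, "envelope") <- TRUE
  out
}

epoch_of <- function(t, epochs) {
  i <- findInterval(t, epochs$start_s)
  ok <- i >= 1 & t <= epochs$end_s[pmax(i, 1)] + 1e-9
  lab <- rep(NA_character_, length(t))
  lab[ok] <- epochs$label[i[ok]]
  lab
}

#' Detect population bursts on an integrated envelope
#'
#' The detection threshold is data-driven: baseline-epoch median plus
#' `k_mad` robust standard deviations (MAD). Supra-threshold events closer
#' than `min_ibi_s` (onset gap) are merged. Amplitude is the envelope peak
#' above the baseline median; `area` (integral above baseline median) is
#' exported as an alternative size measure.
#'
#' @param envelope A preprocessed [slice_trace()] (see
#'   [preprocess_slice()]).
#' @param k_mad Threshold in MADs above the baseline median.
#' @param min_ibi_s Minimum inter-burst interval in seconds; closer events
#'   are merged.
#' @param min_duration_s Minimum total supra-threshold time within a
#'   merged event, in seconds; briefer excursions are treated as noise.
#' @return A tibble `onset_s`, `peak_s`, `duration_s`, `peak_amplitude`,
#'   `area`, `epoch`.
#' @export
detect_bursts <- function(envelope, k_mad = 5, min_ibi_s = 1,
                          min_duration_s = 0.1) {
  rate <- attr(envelope, "sampling_rate")
  epochs <- slice_epochs(envelope)
  env <- envelope$signal
  base_idx <- which(envelope$time >= epochs$start_s[1] &
                    envelope$time <= epochs$end_s[1])
  base_med <- median(env[base_idx])
  base_mad <- stats::mad(env[base_idx])
  thr <- base_med + k_mad * base_mad
  above <- env > thr
  if (!any(above)) {
    return(tibble(onset_s = numeric(), peak_s = numeric(),
                  duration_s = numeric(), peak_amplitude = numeric(),
                  area = numeric(), epoch = character()))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- starts[r$values]
  off <- ends[r$values]
  # merge events whose gap is below min_ibi_s
  if (length(on) > 1) {
    gap_s <- (on[-1] - off[-length(off)]) / rate
    grp <- cumsum(c(0, gap_s >= min_ibi_s))
  } else {
    grp <- 0
  }
  merged <- purrr::map(split(seq_along(on), grp), function(i) {
    a <- on[i[1]]; b <- off[i[length(i)]]
    seg <- env[a:b]
    peak_rel <- which.max(seg)
    tibble(
      onset_s = envelope$time[a],
      peak_s = envelope$time[a + peak_rel - 1L],
      duration_s = (b - a + 1L) / rate,
      above_s = sum(off[i] - on[i] + 1L) / rate,
      peak_amplitude = max(seg) - base_med,
      area = sum(pmax(seg - base_med, 0)) / rate
    )
  })
  out <- dplyr::bind_rows(merged)
  out <- out[order(out$onset_s), ]
  out <- out[out$above_s >= min_duration_s, , drop = FALSE]
  out$above_s <- NULL
  out$epoch <- epoch_of(out$onset_s, epochs)
  out
}

#' Dose-response curve normalized to baseline
#'
#' Per epoch, burst rate (bursts per second) and mean peak amplitude are
#' divided by the baseline-epoch values, so the baseline point is exactly
#' `(dose 0, 1, 1)`. Normalization is idempotent: renormalizing a
#' normalized curve returns it unchanged.
#'
#' @param bursts Burst table from [detect_bursts()].
#' @param epochs Epoch table (from [slice_epochs()]).
#' @param min_baseline_bursts Required bursts in the baseline epoch.
#' @return A tibble `label`, `dose_nm`, `n_bursts`, `rate_hz`, `mean_amp`,
#'   `rate_norm`, `amp_norm`.
#' @export
dose_response <- function(bursts, epochs, min_baseline_bursts = 3) {
  per <- epochs |>
    dplyr::mutate(duration_s = .data$end_s - .data$start_s) |>
    dplyr::left_join(
      bursts |>
        dplyr::group_by(.data$epoch) |>
        dplyr::summarise(n_bursts = dplyr::n(),
                         mean_amp = mean(.data$peak_amplitude)),
      by = c(label = "epoch")
    ) |>
    dplyr::mutate(
      n_bursts = dplyr::coalesce(.data$n_bursts, 0L),
      rate_hz = .data$n_bursts / .data$duration_s
    )
  base <- per[1, ]
  if (base$n_bursts < min_baseline_bursts) {
    stop("Baseline epoch has fewer than ", min_baseline_bursts,
         " bursts; cannot normalize.", call. = FALSE)
  }
  per |>
    dplyr::mutate(
      rate_norm = .data$rate_hz / base$rate_hz,
      amp_norm = ifelse(.data$n_bursts > 0,
                        .data$mean_amp / base$mean_amp, 0)
    ) |>
    dplyr::select("label", "dose_nm", "n_bursts", "rate_hz", "mean_amp",
                  "rate_norm", "amp_norm")
}

#' Classify rhythm cessation within an epoch
#'
#' An epoch shows rhythm cessation when no burst onset falls in its final
#' `window_s` seconds: the rhythm has stopped and stayed stopped, the
#' state that bath antagonist application subsequently reverses.
#'
#' @param bursts Burst table (already restricted or carrying an `epoch`
#'   column).
#' @param epoch_start_s,epoch_end_s Epoch span in seconds.
#' @param window_s Silent window required at the epoch end (default 300 s,
#'   the last 5 min of a 20-min epoch).
#' @return Logical: `TRUE` if the rhythm ceased.
#' @export
classify_cessation <- function(bursts, epoch_start_s, epoch_end_s,
                               window_s = 300) {
  if (epoch_end_s - epoch_start_s < 60) {
    stop("Epoch must last at least 60 s.", call. = FALSE)
  }
  window_s <- min(window_s, epoch_end_s - epoch_start_s)
  on <- bursts$onset_s
  on <- on[on >= epoch_start_s & on <= epoch_end_s]
  !any(on >= epoch_end_s - window_s)
}

#' Full slice pipeline
#'
#' [preprocess_slice()], [detect_bursts()], then [dose_response()] and a
#' per-epoch cessation call.
#'
#' @inheritParams preprocess_slice
#' @inheritParams detect_bursts
#' @inheritParams classify_cessation
#' @return A list with `envelope`, `bursts`, `dose_response`, and
#'   `cessation` (per-epoch tibble).
#' @export
analyze_slice <- function(trace, band = c(3, 400), smooth_ms = 50,
                          k_mad = 5, min_ibi_s = 1, min_duration_s = 0.1,
                          window_s = 300) {
  env <- preprocess_slice(trace, band = band, smooth_ms = smooth_ms)
  bursts <- detect_bursts(env, k_mad = k_mad, min_ibi_s = min_ibi_s,
                          min_duration_s = min_duration_s)
  epochs <- slice_epochs(trace)
  dr <- dose_response(bursts, epochs)
  cess <- epochs |>
    dplyr::mutate(cessation = purrr::map2_lgl(
      .data$start_s, .data$end_s,
      ~ classify_cessation(bursts, .x, .y, window_s = window_s)
    ))
  list(envelope = env, bursts = bursts, dose_response = dr,
       cessation = cess[c("label", "dose_nm", "cessation")])
}
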