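#' Parameters of one synthetic breath
#'
#' The waveform is built from half-sine lobes: a negative inspiratory lobe
#' (duration `ti_ms`, peak `-pif`), a positive expiratory lobe that decays
#' below the pause-detection threshold at the programmed end of `te_ms`,
#' and an optional pause of near-zero positive flow, optionally terminated
#' by an active-expiration transient. Half-sine lobes are chosen because
#' the programmed tidal volume has the closed form
#' `tv = (2/pi) * pif * ti` (uL when pif is mL/s and ti is ms).
#'
#' @param ti_ms,te_ms,pause_ms Phase durations in ms.
#' @param pif,pef Peak inspiratory / expiratory flow magnitudes, mL/s.
#' @param active_exp_amp Amplitude (mL/s) of the terminal expiratory
#'   transient during the pause (0 = none).
#' @return A list of class `breath_params`.
#' @export
breath_params <- function(ti_ms, te_ms, pause_ms = 0, pif = 1, pef = 1,
                          active_exp_amp = 0) {
  stopifnot(ti_ms > 0, te_ms > 0, pause_ms >= 0, pif > 0, pef > 0,
            active_exp_amp >= 0)
  structure(list(ti_ms = ti_ms, te_ms = te_ms, pause_ms = pause_ms,
                 pif = pif, pef = pef, active_exp_amp = active_exp_amp),
            class = "breath_params")
}

# Residual flow during a pause: strictly positive and well below the
# 0.5 mL/s detection threshold, so programmed pauses are detectable and
# noise cannot generate spurious zero-crossings.
PAUSE_RESIDUAL_FLOW <- 0.1

#' Generate the airflow samples of one breath
#'
#' @param params A [breath_params()].
#' @param rate Sampling rate in Hz.
#' @param flow_threshold Pause-detection threshold the expiratory lobe is
#'   shaped against (the lobe stays just above it until the programmed end
#'   of expiration, then drops to residual flow).
#' @return A list with `flow` (numeric vector) and `truth` (one-row tibble
#'   of programmed values, durations quantized to the sample grid).
#' @export
#' @examples
#' b <- gen_breath(breath_params(ti_ms = 100, te_ms = 100, pif = 1), 1000)
#' b$truth$tv_ul # (2/pi) * 1 * 100 = 63.66
gen_breath <- function(params, rate = 1000, flow_threshold = 0.5) {
  core <- gen_breath_core(params$ti_ms, params$te_ms, params$pause_ms,
                          params$pif, params$pef, params$active_exp_amp,
                          rate, flow_threshold)
  ti_q <- core$ti_q
  te_q <- core$te_q
  pa_q <- core$pa_q
  flow <- core$flow
  truth <- tibble(
    ti_ms = ti_q, te_ms = te_q, pause_ms = pa_q,
    period_ms = ti_q + te_q + pa_q,
    pif = params$pif, pef = params$pef,
    tv_ul = (2 / pi) * params$pif * ti_q,
    has_pause = pa_q > 0
  )
  list(flow = flow, truth = truth)
}

gen_breath_core <- function(ti_ms, te_ms, pause_ms, pif, pef,
                            active_exp_amp, rate, flow_threshold = 0.5) {
  n_ti <- max(2L, as.integer(round(ti_ms * rate / 1000)))
  n_te <- max(2L, as.integer(round(te_ms * rate / 1000)))
  n_pa <- as.integer(round(pause_ms * rate / 1000))
  insp <- -pif * sin(pi * (seq_len(n_ti) - 0.5) / n_ti)
  if (n_pa > 0) {
    # truncate the expiratory lobe so it sits just above threshold at the
    # programmed end of expiration, then drops to residual flow
    frac <- min(0.95, (flow_threshold + 0.05) / pef)
    lobe_n <- n_te / (1 - asin(frac) / pi)
    expn <- pef * sin(pi * (seq_len(n_te) - 0.5) / lobe_n)
    pause <- rep(PAUSE_RESIDUAL_FLOW, n_pa)
    if (active_exp_amp > 0) {
      w <- min(n_pa, max(2L, as.integer(round(0.03 * rate))))
      k <- seq_len(w)
      pause[n_pa - w + k] <- pause[n_pa - w + k] +
        active_exp_amp * sin(pi * (k - 0.5) / w)
    }
    flow <- c(insp, expn, pause)
  } else {
    expn <- pef * sin(pi * (seq_len(n_te) - 0.5) / n_te)
    flow <- c(insp, expn)
  }
  list(flow = flow, ti_q = n_ti / rate * 1000, te_q = n_te / rate * 1000,
       pa_q = n_pa / rate * 1000)
}

#' Breathing-regime presets
#'
#' A regime is a distributional recipe for i.i.d. breaths. Per breath, the
#' target tidal volume and peak inspiratory flow are drawn independently
#' and the inspiratory time follows from the volume-preserving rule
#' `ti = (pi/2) * tv / pif`, which (a) preserves tidal volume under opioid
#' airflow depression by construction and (b) programs the negative
#' Ti-vs-peak-flow correlation seen in real breathing. The presets encode
#' the study conditions: hypercapnic saline breathing at ~10 Hz
#' (Ti ~ Te ~ 50 ms); the morphine regime with peak inspiratory flow
#' scaled by 0.4, compensatory Ti lengthening, and log-normal pauses
#' (median 200 ms) occurring on 23.4% of breaths, which together halve
#' the mean instantaneous frequency; normoxic breathing at ~4 Hz with a
#' 60% rate reduction under morphine.
#'
#' @param name One of `"saline_hypercapnia"`, `"morphine_hypercapnia"`,
#'   `"saline_normoxia"`, `"morphine_normoxia"`.
#' @return A list of class `regime_spec` with fields `tv_ul`, `pif`,
#'   `pef`, `te_ms` (each `c(mean, cv)`), `pause_prob`, `pause_meanlog`,
#'   `pause_sdlog`, `active_exp_amp`, `noise_sd`.
#' @export
regime_preset <- function(name = c("saline_hypercapnia",
                                   "morphine_hypercapnia",
                                   "saline_normoxia",
                                   "morphine_normoxia")) {
  name <- match.arg(name)
  base_hyp <- list(
    name = name,
    tv_ul = c(mean = 127.3, cv = 0.10),
    pif = c(mean = 4.0, cv = 0.15),
    pef = c(mean = 2.5, cv = 0.15),
    te_ms = c(mean = 50, cv = 0.15),
    pause_prob = 0, pause_meanlog = log(200), pause_sdlog = 0.5,
    active_exp_amp = 0, noise_sd = 0.02
  )
  base_nor <- list(
    name = name,
    tv_ul = c(mean = 57.3, cv = 0.12),
    pif = c(mean = 1.5, cv = 0.18),
    pef = c(mean = 1.0, cv = 0.18),
    te_ms = c(mean = 190, cv = 0.18),
    pause_prob = 0, pause_meanlog = log(500), pause_sdlog = 0.6,
    active_exp_amp = 0, noise_sd = 0.02
  )
  spec <- switch(
    name,
    saline_hypercapnia = base_hyp,
    morphine_hypercapnia = {
      s <- base_hyp
      s$pif[["mean"]] <- 1.6      # 0.4x saline peak inspiratory flow
      s$pause_prob <- 0.234       # calibrated for a 50% rate reduction
      s$active_exp_amp <- 1.0     # hypercapnic active expiration
      s
    },
    saline_normoxia = base_nor,
    morphine_normoxia = {
      s <- base_nor
      s$pif[["mean"]] <- 0.6
      s$pause_prob <- 0.76        # calibrated for a 60% rate reduction
      s
    }
  )
  structure(spec, class = "regime_spec")
}

regime_meta <- function(regime, animal_id = "synthetic",
                        duration_s = NA_real_) {
  parts <- strsplit(regime$name, "_")[[1]]
  session_meta(animal_id = animal_id, drug = parts[1],
               dose = if (parts[1] == "morphine") 20 else 0,
               gas = parts[2], duration_s = duration_s)
}

draw_trunc_norm <- function(n, mean, cv) {
  pmax(mean * 0.05, rnorm(n, mean, cv * mean))
}

draw_regime_breaths <- function(regime, n) {
  tv <- draw_trunc_norm(n, regime$tv_ul[["mean"]], regime$tv_ul[["cv"]])
  pif <- draw_trunc_norm(n, regime$pif[["mean"]], regime$pif[["cv"]])
  pef <- pmax(0.7, draw_trunc_norm(n, regime$pef[["mean"]],
                                   regime$pef[["cv"]]))
  te <- draw_trunc_norm(n, regime$te_ms[["mean"]], regime$te_ms[["cv"]])
  ti <- (pi / 2) * tv / pif
  has_pause <- runif(n) < regime$pause_prob
  pause <- ifelse(has_pause,
                  rlnorm(n, regime$pause_meanlog, regime$pause_sdlog), 0)
  tibble(ti_ms = ti, te_ms = te, pause_ms = pause, pif = pif, pef = pef)
}

#' Expected mean instantaneous frequency of a regime
#'
#' Deterministic Monte-Carlo estimate (internal fixed seed) of the
#' population mean of `1/period` under a regime's breath distributions.
#' Used to express programmed rate effects on the same scale the pipeline
#' measures (an arithmetic mean of instantaneous frequencies).
#'
#' @param regime A [regime_preset()].
#' @param n Number of Monte-Carlo breaths.
#' @return Expected mean instantaneous frequency in Hz.
#' @export
regime_expected_rate <- function(regime, n = 2e5) {
  withr::with_seed(290114, {
    b <- draw_regime_breaths(regime, n)
    mean(1000 / (b$ti_ms + b$te_ms + b$pause_ms))
  })
}

#' Generate one synthetic plethysmography session
#'
#' Breaths are drawn i.i.d. from the regime until `duration_s` is filled,
#' concatenated, and white measurement noise of sd `regime$noise_sd` is
#' added. A short positive lead-in and a terminal partial inspiration
#' bracket the train so that every programmed breath is delimited by an
#' inspiration-onset crossing on both sides. The same `seed` gives a
#' bit-identical trace.
#'
#' @param regime A [regime_preset()] (or a modified copy).
#' @param duration_s Session duration in seconds (>= 10).
#' @param rate Sampling rate in Hz.
#' @param seed Integer seed (reproducibility contract).
#' @param animal_id Identifier stored in the trace metadata.
#' @return A list with `trace` (an [airflow_trace()]) and `truth` (a
#'   tibble of programmed per-breath values with `onset_s` and
#'   `onset_sample`).
#' @export
gen_session <- function(regime, duration_s = 600, rate = 1000, seed = 1,
                        animal_id = "synthetic") {
  stopifnot(duration_s >= 10)
  withr::with_seed(seed, {
    mean_period_s <- (regime$te_ms[["mean"]] +
                        (pi / 2) * regime$tv_ul[["mean"]] / regime$pif[["mean"]] +
                        regime$pause_prob *
                          exp(regime$pause_meanlog + regime$pause_sdlog^2 / 2)) / 1000
    n_guess <- ceiling(duration_s / mean_period_s * 1.25) + 20
    params <- draw_regime_breaths(regime, n_guess)
    lead <- rep(PAUSE_RESIDUAL_FLOW, as.integer(round(0.03 * rate)))
    flow <- vector("list", n_guess + 2L)
    flow[[1]] <- lead
    ti_q <- te_q <- pa_q <- numeric(n_guess)
    onset <- integer(n_guess)
    total <- length(lead)
    n_used <- 0L
    for (i in seq_len(n_guess)) {
      b <- gen_breath_core(params$ti_ms[i], params$te_ms[i],
                           params$pause_ms[i], params$pif[i],
                           params$pef[i], regime$active_exp_amp, rate)
      onset[i] <- total + 1L
      ti_q[i] <- b$ti_q; te_q[i] <- b$te_q; pa_q[i] <- b$pa_q
      flow[[i + 1L]] <- b$flow
      total <- total + length(b$flow)
      n_used <- i
      if (total / rate >= duration_s) break
    }
    # terminal partial inspiration delimits the last programmed breath
    n_tail <- max(2L, as.integer(round(0.02 * rate)))
    tail_dip <- -0.5 * regime$pif[["mean"]] *
      sin(pi * (seq_len(n_tail) - 0.5) / n_tail)
    flow[[n_used + 2L]] <- tail_dip
    flow <- unlist(flow[seq_len(n_used + 2L)], use.names = FALSE)
    flow <- flow + rnorm(length(flow), 0, regime$noise_sd)
    ix <- seq_len(n_used)
    truth <- tibble(
      breath = ix,
      onset_sample = onset[ix],
      onset_s = (onset[ix] - 1L) / rate,
      ti_ms = ti_q[ix], te_ms = te_q[ix], pause_ms = pa_q[ix],
      period_ms = ti_q[ix] + te_q[ix] + pa_q[ix],
      pif = params$pif[ix], pef = params$pef[ix],
      tv_ul = (2 / pi) * params$pif[ix] * ti_q[ix],
      has_pause = pa_q[ix] > 0
    )
    meta <- regime_meta(regime, animal_id,
                        duration_s = length(flow) / rate)
    list(trace = airflow_trace(flow, sampling_rate = rate, meta = meta),
         truth = truth)
  })
}

scale_regime <- function(regime, f_amp = 1, f_dur = 1) {
  regime$tv_ul[["mean"]] <- regime$tv_ul[["mean"]] * f_amp * f_dur
  regime$pif[["mean"]] <- regime$pif[["mean"]] * f_amp
  regime$pef[["mean"]] <- regime$pef[["mean"]] * f_amp
  regime$te_ms[["mean"]] <- regime$te_ms[["mean"]] * f_dur
  regime$pause_meanlog <- regime$pause_meanlog + log(f_dur)
  regime
}

#' Generate a paired synthetic cohort
#'
#' Emulates the within-animal crossover design: every animal contributes
#' one control (saline) and one drug (morphine) session, and a latent
#' per-animal scale (amplitude and duration factors, log-normal with CV
#' `animal_cv`) multiplies the regime means of *both* sessions, so the
#' drug/control ratio is unaffected by between-animal variability and the
#' programmed effects are recovered exactly in expectation.
#'
#' @param n_animals Number of animals (default 29).
#' @param gas `"hypercapnia"` or `"normoxia"`; selects the regime pair.
#' @param duration_s Per-session duration in seconds.
#' @param animal_cv Between-animal coefficient of variation of the latent
#'   scale factors.
#' @param rate Sampling rate in Hz.
#' @param seed Integer seed (mandatory).
#' @return A tibble with one row per session: `animal_id`, `drug`,
#'   `gas`, `trace` and `truth` (list-columns), `f_amp`, `f_dur`, and the
#'   programmed effect ratios `rate_ratio_true`, `pif_ratio_true`,
#'   `tv_ratio_true` (identical across animals by design).
#' @export
gen_paired_cohort <- function(n_animals = 29, gas = "hypercapnia",
                              duration_s = 600, animal_cv = 0.15,
                              rate = 1000, seed) {
  if (missing(seed)) stop("`seed` is mandatory.", call. = FALSE)
  stopifnot(n_animals >= 2)
  reg_s <- regime_preset(paste0("saline_", gas))
  reg_m <- regime_preset(paste0("morphine_", gas))
  rate_ratio <- regime_expected_rate(reg_m) / regime_expected_rate(reg_s)
  pif_ratio <- reg_m$pif[["mean"]] / reg_s$pif[["mean"]]
  tv_ratio <- reg_m$tv_ul[["mean"]] / reg_s$tv_ul[["mean"]]
  withr::with_seed(seed, {
    f_amp <- rlnorm(n_animals, -animal_cv^2 / 2, animal_cv)
    f_dur <- rlnorm(n_animals, -animal_cv^2 / 2, animal_cv)
    seeds <- matrix(sample.int(.Machine$integer.max - 1L, 2 * n_animals),
                    ncol = 2)
  })
  rows <- purrr::map(seq_len(n_animals), function(i) {
    id <- sprintf("animal_%02d", i)
    ses_s <- gen_session(scale_regime(reg_s, f_amp[i], f_dur[i]),
                         duration_s = duration_s, rate = rate,
                         seed = seeds[i, 1], animal_id = id)
    ses_m <- gen_session(scale_regime(reg_m, f_amp[i], f_dur[i]),
                         duration_s = duration_s, rate = rate,
                         seed = seeds[i, 2], animal_id = id)
    tibble(
      animal_id = id, drug = c("saline", "morphine"), gas = gas,
      trace = list(ses_s$trace, ses_m$trace),
      truth = list(ses_s$truth, ses_m$truth),
      f_amp = f_amp[i], f_dur = f_dur[i],
      rate_ratio_true = rate_ratio, pif_ratio_true = pif_ratio,
      tv_ratio_true = tv_ratio
    )
  })
  dplyr::bind_rows(rows)
}

#' Epoch schedule for a simulated slice experiment
#'
#' @param baseline_s Baseline duration in seconds.
#' @param dose_s Duration of each agonist epoch in seconds.
#' @param doses Agonist doses in nM.
#' @param rate_mult,amp_mult Per-dose multipliers applied to the baseline
#'   burst rate and amplitude (0 = rhythm silenced).
#' @return A tibble `label`, `dose_nm`, `duration_s`, `rate_mult`,
#'   `amp_mult`.
#' @export
slice_epoch_schedule <- function(baseline_s = 1200, dose_s = 1200,
                                 doses = c(50, 100, 500),
                                 rate_mult = c(0.6, 0.3, 0),
                                 amp_mult = c(0.7, 0.4, 0)) {
  stopifnot(length(doses) == length(rate_mult),
            length(doses) == length(amp_mult))
  dose_labels <- if (length(doses)) paste0("damgo_", doses, "nM") else
    character(0)
  tibble(
    label = c("baseline", dose_labels),
    dose_nm = c(0, doses),
    duration_s = c(baseline_s, rep(dose_s, length(doses))),
    rate_mult = c(1, rate_mult),
    amp_mult = c(1, amp_mult)
  )
}

# 1/f ("pink") background noise via FFT spectral shaping
pink_noise <- function(n, sd) {
  m <- stats::nextn(n, c(2, 3, 5))
  x <- rnorm(m)
  xf <- fft(x)
  f <- c(1, seq_len(m - 1))
  f <- pmin(f, m - f + 1)  # symmetric frequency index
  xf <- xf / sqrt(f)
  y <- Re(fft(xf, inverse = TRUE)) / m
  y <- y[seq_len(n)]
  y * sd / sd(y)
}

#' Generate a synthetic slice recording
#'
#' Bursts are triangular envelopes (linear rise to a sharp peak at the
#' packet centre, linear decay) riding a band-internal oscillatory
#' carrier (default 100 Hz) with mild multiplicative noise, at programmed
#' times; at baseline the inter-burst intervals are uniform on `ibi_range`
#' (5-10 s by default), and each epoch's `rate_mult` and `amp_mult` scale
#' the burst rate and amplitude (`rate_mult = 0` silences the rhythm).
#' The background is 1/f noise. The mostly deterministic carrier keeps the
#' integrated-envelope peak at the programmed burst centre, so detection
#' accuracy can be scored against ground truth.
#'
#' @param schedule An epoch schedule from [slice_epoch_schedule()].
#' @param sampling_rate Sampling rate in Hz.
#' @param ibi_range Baseline inter-burst interval range in seconds.
#' @param burst_dur_s Burst duration in seconds.
#' @param burst_amp Baseline burst amplitude (a.u., sd of the packet
#'   carrier at its envelope peak).
#' @param noise_sd Background noise sd (a.u.).
#' @param amp_jitter_cv Log-normal CV of per-burst amplitude jitter.
#' @param carrier_hz Carrier frequency of the burst packets (must lie
#'   inside the analysis band).
#' @param seed Integer seed.
#' @return A list with `trace` (a [slice_trace()]) and `truth` (tibble of
#'   programmed bursts: `epoch`, `onset_s`, `peak_s`, `amp`).
#' @export
gen_slice <- function(schedule = slice_epoch_schedule(),
                      sampling_rate = 2000, ibi_range = c(5, 10),
                      burst_dur_s = 0.6, burst_amp = 1, noise_sd = 0.05,
                      amp_jitter_cv = 0.1, carrier_hz = 100, seed = 1) {
  withr::with_seed(seed, {
    starts <- cumsum(c(0, schedule$duration_s))
    total_s <- starts[length(starts)]
    n <- as.integer(round(total_s * sampling_rate))
    sig <- pink_noise(n, noise_sd)
    truth <- list()
    n_burst_samp <- as.integer(round(burst_dur_s * sampling_rate))
    env <- 1 - abs(2 * (seq_len(n_burst_samp) - 0.5) / n_burst_samp - 1)
    carrier <- sin(2 * pi * carrier_hz * (seq_len(n_burst_samp) - 1) /
                     sampling_rate)
    for (e in seq_len(nrow(schedule))) {
      rm_ <- schedule$rate_mult[e]
      if (rm_ <= 0) next
      t <- starts[e] + runif(1, ibi_range[1], ibi_range[2]) / rm_
      ends_at <- starts[e + 1]
      while (t + burst_dur_s < ends_at) {
        amp <- burst_amp * schedule$amp_mult[e] *
          rlnorm(1, -amp_jitter_cv^2 / 2, amp_jitter_cv)
        i0 <- as.integer(round(t * sampling_rate)) + 1L
        idx <- i0:min(n, i0 + n_burst_samp - 1L)
        m <- length(idx)
        sig[idx] <- sig[idx] + amp * env[seq_len(m)] *
          (carrier[seq_len(m)] + 0.1 * rnorm(m))
        truth[[length(truth) + 1L]] <- tibble(
          epoch = schedule$label[e], onset_s = t,
          peak_s = t + burst_dur_s / 2, amp = amp
        )
        t <- t + runif(1, ibi_range[1], ibi_range[2]) / rm_
      }
    }
    epochs <- tibble(
      label = schedule$label, dose_nm = schedule$dose_nm,
      start_s = starts[-length(starts)], end_s = starts[-1]
    )
    list(trace = slice_trace(sig, sampling_rate = sampling_rate,
                             epochs = epochs),
         truth = if (length(truth)) dplyr::bind_rows(truth) else
           tibble(epoch = character(), onset_s = numeric(),
                  peak_s = numeric(), amp = numeric()))
  })
}
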