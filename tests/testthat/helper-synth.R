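# Deterministic, noise-free breath trains built from the generator's
# single-breath primitive. Parameter vectors are recycled to the longest.
make_train <- function(ti_ms = 100, te_ms = 100, pause_ms = 0, pif = 2,
                       pef = 1.5, active = 0, n = NULL, rate = 1000) {
  len <- max(length(ti_ms), length(te_ms), length(pause_ms),
             length(pif), length(pef), if (is.null(n)) 0 else n)
  ti_ms <- rep_len(ti_ms, len); te_ms <- rep_len(te_ms, len)
  pause_ms <- rep_len(pause_ms, len); pif <- rep_len(pif, len)
  pef <- rep_len(pef, len)
  lead <- rep(0.1, 30)
  flows <- list(lead)
  truth <- vector("list", len)
  total <- length(lead)
  for (i in seq_len(len)) {
    b <- gen_breath(breath_params(ti_ms[i], te_ms[i], pause_ms[i],
                                  pif[i], pef[i], active), rate)
    b$truth$onset_sample <- total + 1L
    flows[[i + 1L]] <- b$flow
    truth[[i]] <- b$truth
    total <- total + length(b$flow)
  }
  dip <- -max(pif) * sin(pi * (seq_len(20) - 0.5) / 20)
  flows[[len + 2L]] <- dip
  list(trace = airflow_trace(unlist(flows), rate),
       truth = dplyr::bind_rows(truth))
}

# short single-epoch slice schedule
baseline_only <- function(duration_s) {
  slice_epoch_schedule(baseline_s = duration_s, dose_s = 0,
                       doses = numeric(0), rate_mult = numeric(0),
                       amp_mult = numeric(0))
}
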