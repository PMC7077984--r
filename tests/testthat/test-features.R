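test_that("pause length follows the sub-threshold definition", {
  # 300 ms sub-threshold tail -> pause 300 ms, has_pause TRUE
  tr <- make_train(ti_ms = 100, te_ms = 100, pause_ms = 300, n = 1)
  seg <- segment_breaths(tr$trace)[1, ]
  p <- pause_length(tr$trace, seg)
  expect_lte(abs(p$pause_ms - 300), 2)
  expect_true(p$has_pause)

  # expiration above threshold until next inspiration -> pause ~0
  tr2 <- make_train(ti_ms = 100, te_ms = 100, pause_ms = 0, pef = 3, n = 1)
  p2 <- pause_length(tr2$trace, segment_breaths(tr2$trace)[1, ])
  expect_lt(p2$pause_ms, 10)
  expect_false(p2$has_pause)

  # 40 ms sub-threshold span with min_pause_ms 50 -> measured, not called
  tr3 <- make_train(ti_ms = 100, te_ms = 100, pause_ms = 40, n = 1)
  p3 <- pause_length(tr3$trace, segment_breaths(tr3$trace)[1, ])
  expect_lte(abs(p3$pause_ms - 40), 2)
  expect_false(p3$has_pause)

  # re-excursions above threshold (active expiration) do not end the pause
  tr4 <- make_train(ti_ms = 100, te_ms = 100, pause_ms = 250, active = 1,
                    n = 1)
  p4 <- pause_length(tr4$trace, segment_breaths(tr4$trace)[1, ])
  expect_lte(abs(p4$pause_ms - 250), 2)
  expect_true(p4$has_pause)
})

test_that("programmed morphine pauses are recovered to within 2 samples", {
  ses <- gen_session(regime_preset("morphine_hypercapnia"),
                     duration_s = 120, seed = 37)
  bt <- breath_table(ses$trace)
  expect_equal(nrow(bt), nrow(ses$truth))
  paused <- ses$truth$has_pause
  expect_gt(sum(paused), 40)
  err <- abs(bt$pause_ms[paused] - ses$truth$pause_ms[paused])
  expect_gte(mean(err <= 2), 0.95)
  expect_identical(bt$has_pause, ses$truth$has_pause)
})

test_that("tidal volume matches the half-sine closed form", {
  # half-sine inspiration, peak 1 mL/s, Ti 100 ms -> (2/pi)*1*100 uL
  flow <- c(rep(0.1, 10), -sin(pi * (0:100) / 100), rep(0.5, 10))
  tr <- airflow_trace(flow, 1000)
  seg <- list(insp_onset = 11L, exp_onset = 112L)
  expect_equal(tidal_volume(tr, seg), 2 / pi * 100, tolerance = 0.01)

  # zero-flow inspiration -> 0
  tr0 <- airflow_trace(rep(0, 200), 1000)
  expect_equal(tidal_volume(tr0, list(insp_onset = 10L, exp_onset = 100L)),
               0)

  # generator breath with programmed volume recovered within 1%
  pif <- 150 / (2 / pi * 100)  # peak flow giving 150 uL at Ti = 100 ms
  trg <- make_train(ti_ms = 100, te_ms = 100, pif = pif, n = 1)
  bt <- breath_table(trg$trace)
  expect_equal(bt$tv_ul, 150, tolerance = 150 * 0.01)
})

test_that("instantaneous frequency is the reciprocal period", {
  expect_equal(instantaneous_frequency(200), 5)
  # hypercapnic saline breath: Ti = Te = 50 ms, no pause -> 10 Hz
  expect_equal(instantaneous_frequency(50 + 50), 10)
  expect_equal(instantaneous_frequency(1000), 1)
  expect_error(instantaneous_frequency(0), "period")
})

test_that("minute ventilation is volume times rate", {
  expect_equal(minute_ventilation(150, 4), 36)
  expect_equal(minute_ventilation(0, 7), 0)

  # session mean MV agrees with ground-truth volumes and periods within 1%
  ses <- gen_session(regime_preset("saline_hypercapnia"), duration_s = 60,
                     seed = 41)
  bt <- breath_table(ses$trace)
  mv_truth <- mean(ses$truth$tv_ul / 1000 * (1000 / ses$truth$period_ms) * 60)
  expect_equal(mean(bt$mv_ml_min), mv_truth, tolerance = mv_truth * 0.01)
})

test_that("single ideal breaths produce consistent records", {
  tr <- make_train(ti_ms = 100, te_ms = 100, pef = 3, n = 1)
  bt <- breath_table(tr$trace)
  expect_lte(abs(bt$period_ms - 200), 1.5)
  expect_equal(bt$freq_hz, 5, tolerance = 0.03)
  expect_lt(bt$pause_ms, 10)
  expect_false(bt$has_pause)

  # 300 ms sub-threshold tail: Ti + Te + pause = period
  tr2 <- make_train(ti_ms = 100, te_ms = 100, pause_ms = 300, n = 1)
  bt2 <- breath_table(tr2$trace)
  expect_lte(abs(bt2$ti_ms + bt2$te_ms + bt2$pause_ms - bt2$period_ms), 1.5)
  expect_equal(bt2$te_total_ms, bt2$te_ms + bt2$pause_ms)
})

test_that("per-breath features track generator ground truth on a morphine session", {
  ses <- gen_session(regime_preset("morphine_hypercapnia"),
                     duration_s = 120, seed = 43)
  bt <- breath_table(ses$trace)
  expect_gt(cor(bt$ti_ms, ses$truth$ti_ms), 0.95)
  expect_gt(cor(bt$pif_ml_s, ses$truth$pif), 0.95)
  expect_gt(cor(bt$tv_ul, ses$truth$tv_ul), 0.95)
  expect_gt(cor(bt$pause_ms, ses$truth$pause_ms), 0.95)
})

test_that("phase additivity holds for every breath", {
  for (regime in c("saline_hypercapnia", "morphine_hypercapnia")) {
    ses <- gen_session(regime_preset(regime), duration_s = 60, seed = 47)
    bt <- breath_table(ses$trace)
    rate <- sampling_rate(ses$trace)
    expect_true(all(abs(bt$ti_ms + bt$te_ms + bt$pause_ms - bt$period_ms)
                    <= 1000 / rate + 1e-9))
  }
})

test_that("Ti and peak inspiratory flow are negatively correlated", {
  ses <- gen_session(regime_preset("saline_hypercapnia"),
                     duration_s = 60, seed = 53)
  bt <- breath_table(ses$trace)
  expect_lt(cor(bt$ti_ms, bt$pif_ml_s), 0)
})

test_that("the morphine regime preserves tidal volume", {
  ss <- gen_session(regime_preset("saline_hypercapnia"), duration_s = 60,
                    seed = 59)
  sm <- gen_session(regime_preset("morphine_hypercapnia"), duration_s = 60,
                    seed = 61)
  ratio <- mean(breath_table(sm$trace)$tv_ul) /
    mean(breath_table(ss$trace)$tv_ul)
  expect_gte(ratio, 0.9)
  expect_lte(ratio, 1.2)
})

test_that("amplitude scaling scales flows and volumes, not timings", {
  ses <- gen_session(regime_preset("saline_hypercapnia"), duration_s = 30,
                     seed = 67)
  k <- 2.5
  qc_k <- qc_config(hysteresis = 0.05 * k, min_peak_insp_flow = 0.2 * k)
  cfg_k <- pause_config(flow_threshold = 0.5 * k)
  bt <- breath_table(ses$trace)
  scaled <- airflow_trace(ses$trace$flow * k, sampling_rate(ses$trace))
  bt_k <- compute_features(scaled, segment_breaths(scaled, qc_k), cfg_k)
  expect_equal(bt_k$pif_ml_s, k * bt$pif_ml_s, tolerance = 1e-9)
  expect_equal(bt_k$pef_ml_s, k * bt$pef_ml_s, tolerance = 1e-9)
  expect_equal(bt_k$tv_ul, k * bt$tv_ul, tolerance = 1e-9)
  expect_equal(bt_k$mv_ml_min, k * bt$mv_ml_min, tolerance = 1e-9)
  expect_equal(bt_k$ti_ms, bt$ti_ms)
  expect_equal(bt_k$te_ms, bt$te_ms)
  expect_equal(bt_k$pause_ms, bt$pause_ms)
  expect_equal(bt_k$freq_hz, bt$freq_hz)
})
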