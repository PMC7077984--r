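test_that("session summaries average unflagged breaths", {
  tr <- make_train(ti_ms = 100, te_ms = 100, pef = 3, n = 10)
  bt <- breath_table(tr$trace)
  s <- summarize_session(bt, session_meta("m1"))
  expect_equal(s$n_breaths, 10)
  expect_equal(s$mean_rate, 5, tolerance = 0.005)
  expect_equal(s$mean_tv, bt$tv_ul[1], tolerance = 1e-9)

  # two breaths at 4 and 6 Hz -> mean rate 5 Hz
  tr2 <- make_train(ti_ms = c(100, 100), te_ms = c(150, 400 / 6),
                    pef = 3)
  s2 <- summarize_session(breath_table(tr2$trace))
  expect_equal(s2$mean_rate, 5, tolerance = 0.05)

  expect_error(summarize_session(bt[0, ]), "No unflagged")
})

test_that("a programmed 2.5 Hz session is summarized within 2%", {
  regime <- regime_preset("saline_normoxia")
  # low-dispersion regime built around a 400 ms period
  regime$tv_ul <- c(mean = 2 / pi * 1.5 * 100, cv = 0.05)
  regime$pif <- c(mean = 1.5, cv = 0.05)
  regime$te_ms <- c(mean = 300, cv = 0.05)
  ses <- gen_session(regime, duration_s = 240, seed = 71)
  expect_gt(nrow(ses$truth), 500)
  s <- summarize_session(breath_table(ses$trace))
  expect_equal(s$mean_rate, 2.5, tolerance = 2.5 * 0.02)
})

test_that("morphine/saline ratios require matched sessions", {
  tr <- make_train(ti_ms = 100, te_ms = 100, pef = 3, n = 5)
  bt <- breath_table(tr$trace)
  s_sal <- summarize_session(bt, session_meta("m1", gas = "hypercapnia"))
  s_mor <- summarize_session(bt, session_meta("m1", drug = "morphine",
                                              dose = 20,
                                              gas = "hypercapnia"))
  expect_equal(morphine_saline_ratio(s_mor, s_sal, "rate")$ratio, 1)

  s_half <- s_mor
  s_half$mean_rate <- s_sal$mean_rate / 2
  expect_equal(morphine_saline_ratio(s_half, s_sal, "rate")$ratio, 0.5)

  s_other <- summarize_session(bt, session_meta("m2"))
  expect_error(morphine_saline_ratio(s_mor, s_other, "rate"),
               "different animals")
})

test_that("a paired cohort recovers its programmed effects", {
  coh <- gen_paired_cohort(n_animals = 8, duration_s = 30, seed = 73)
  summ <- purrr::map2_dfr(coh$trace, coh$truth, function(tr, th) {
    summarize_session(breath_table(tr), trace_meta(tr))
  })
  r <- paired_ratios(summ, metrics = c("rate", "pif", "tv"))
  means <- tapply(r$ratio, r$metric, mean)
  expect_lt(abs(means[["rate"]] - coh$rate_ratio_true[1]), 0.05)
  expect_lt(abs(means[["pif"]] - 0.4), 0.05)
  expect_gte(means[["tv"]], 0.9)
  expect_lte(means[["tv"]], 1.2)
})

test_that("the normality gate selects the right paired test", {
  vals <- withr::with_seed(101, {
    s <- rnorm(12, 10, 1)
    list(s = s, m = s - 3 + rnorm(12, 0, 0.5))
  })
  r <- gated_paired_test(vals$s, vals$m)
  expect_equal(r$test_used, "paired_t")
  expect_lt(r$p_value, 0.01)
  # statistic agrees with the closed-form paired t
  d <- vals$m - vals$s
  expect_equal(r$statistic, mean(d) / (sd(d) / sqrt(length(d))),
               tolerance = 1e-12)

  skewed <- withr::with_seed(202, {
    s <- rnorm(15, 10, 0.2)
    list(s = s, m = s - exp(rnorm(15, 0, 1))^2)
  })
  r2 <- gated_paired_test(skewed$s, skewed$m)
  expect_equal(r2$test_used, "wilcoxon_signed_rank")
  expect_lt(r2$normality_p, 0.05)

  r3 <- gated_paired_test(skewed$s, skewed$s)
  expect_equal(r3$flags, "zero_differences")
  expect_true(is.na(r3$cohens_d))
  expect_equal(r3$p_value, 1)

  expect_s3_class(tidy(r), "tbl_df")
  expect_equal(glance(r)$test_used, "paired_t")
})

test_that("paired Cohen's d matches hand arithmetic and is scale invariant", {
  expect_equal(cohens_d_paired(c(1, 2, 3)), 2)
  d <- withr::with_seed(7, rnorm(20, 1, 2))
  expect_equal(cohens_d_paired(d * 13.7), cohens_d_paired(d),
               tolerance = 1e-12)
  # brute-force two-pass oracle
  two_pass <- function(x) {
    m <- sum(x) / length(x)
    v <- sum((x - m)^2) / (length(x) - 1)
    m / sqrt(v)
  }
  for (s in 1:5) {
    x <- withr::with_seed(s, rnorm(15, 0.5))
    expect_equal(cohens_d_paired(x), two_pass(x), tolerance = 1e-12)
  }
  expect_error(cohens_d_paired(rep(2, 5)), "Zero standard deviation")
})

test_that("paired-test p-values are invariant to common affine rescaling", {
  vals <- withr::with_seed(83, {
    s <- rnorm(12, 8); list(s = s, m = s * 0.6 + rnorm(12, 0, 0.3))
  })
  r1 <- gated_paired_test(vals$s, vals$m)
  r2 <- gated_paired_test(3 * vals$s + 2, 3 * vals$m + 2)
  expect_equal(r2$p_value, r1$p_value, tolerance = 1e-9)
  expect_equal(r2$test_used, r1$test_used)
})

test_that("mixed RM-ANOVA matches a hand-rolled sums-of-squares oracle", {
  # identical values everywhere -> all F reported as 0
  d0 <- tidyr::expand_grid(subject = paste0("s", 1:6),
                           time = c("pre", "post"))
  d0$group <- rep(c("a", "b"), each = 3)[match(d0$subject,
                                               paste0("s", 1:6))]
  d0$value <- 5
  a0 <- tidy(mixed_rm_anova(d0, subject, group, time, value))
  expect_equal(a0$statistic, c(0, 0, 0))

  # balanced seeded dataset vs explicit SS formulas, to 1e-6
  subj <- paste0("t", 1:10)
  d <- tidyr::expand_grid(subject = subj, time = c("pre", "post"))
  d$group <- rep(c("a", "b"), each = 5)[match(d$subject, subj)]
  d$value <- withr::with_seed(2, rnorm(20, 1))
  got <- tidy(mixed_rm_anova(d, subject, group, time, value))

  y <- d$value
  G <- factor(d$group); TT <- factor(d$time); S <- factor(d$subject)
  grand <- mean(y)
  ssg <- sum(tapply(y, G, function(v) length(v) * (mean(v) - grand)^2))
  subjm <- tapply(y, S, mean)
  subg <- tapply(as.character(d$group), d$subject, `[`, 1)
  sssub <- 2 * sum((subjm - tapply(y, G, mean)[subg[names(subjm)]])^2)
  sst <- sum(tapply(y, TT, function(v) length(v) * (mean(v) - grand)^2))
  cellm <- tapply(y, list(G, TT), mean)
  gm <- tapply(y, G, mean); tm <- tapply(y, TT, mean)
  ssint <- 5 * sum((cellm - outer(gm - grand, tm - grand, "+") - grand)^2)
  sserr <- sum((y - grand)^2) - ssg - sssub - sst - ssint
  oracle <- c(group = (ssg / 1) / (sssub / 8),
              time = (sst / 1) / (sserr / 8),
              interaction = (ssint / 1) / (sserr / 8))
  expect_equal(got$statistic, unname(oracle), tolerance = 1e-6)

  # 6 + 7 animals -> between-group df structure (1, 11)
  subj2 <- paste0("u", 1:13)
  d2 <- tidyr::expand_grid(subject = subj2, time = c("pre", "post"))
  d2$group <- rep(c("cre", "sham"), c(6, 7))[match(d2$subject, subj2)]
  d2$value <- withr::with_seed(3, rnorm(26))
  got2 <- tidy(mixed_rm_anova(d2, subject, group, time, value))
  expect_equal(got2$df_num[got2$effect == "group"], 1)
  expect_equal(got2$df_den[got2$effect == "group"], 11)
})

test_that("pause densities integrate to one on both scales", {
  # single value -> unit mass in one bin
  p1 <- pause_pdf(150, bins = 5)
  expect_equal(sum(p1$count), 1)
  expect_equal(sum(p1$density * (p1$bin_hi - p1$bin_lo)), 1)

  # uniform pauses on [100, 200] -> flat density near 0.01/ms
  u <- withr::with_seed(5, runif(20000, 100, 200))
  pu <- pause_pdf(u, bins = 10)
  expect_equal(sum(pu$density * (pu$bin_hi - pu$bin_lo)), 1,
               tolerance = 1e-12)
  inner <- pu$density[2:9]
  expect_true(all(abs(inner - 0.01) < 0.002))

  # log-spaced bins also integrate to one
  pl <- pause_pdf(u, scale = "log", bins = 12)
  expect_equal(sum(pl$density * (pl$bin_hi - pl$bin_lo)), 1,
               tolerance = 1e-12)

  expect_warning(pause_pdf(numeric(0)), "pause values")
})

test_that("morphine pauses have a heavier right tail than saline", {
  ss <- gen_session(regime_preset("saline_hypercapnia"), duration_s = 60,
                    seed = 89)
  sm <- gen_session(regime_preset("morphine_hypercapnia"),
                    duration_s = 60, seed = 97)
  tail_mass <- function(ses) {
    bt <- breath_table(ses$trace)
    mean(bt$pause_ms > 100)
  }
  expect_gt(tail_mass(sm), tail_mass(ss))
})
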