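#' Summarize a session's breath table
#'
#' Arithmetic means of the per-breath features over unflagged breaths
#' (`qc_pass`), together with the pause prevalence. Pause means are given
#' both including zeros for pause-free breaths (`mean_pause`) and over
#' paused breaths only (`mean_pause_paused`), since either convention can
#' be meant by "average pause length".
#'
#' @param table A breath-table tibble from [compute_features()].
#' @param meta A [session_meta()] (optional; identifies the row).
#' @return A one-row tibble with `animal_id`, `drug`, `gas`, `epoch`,
#'   `n_breaths`, `mean_rate`, `mean_pif`, `mean_pef`, `mean_tv`,
#'   `mean_mv`, `mean_pause`, `mean_pause_paused`, `pause_rate`.
#' @export
summarize_session <- function(table, meta = NULL) {
  ok <- table[table$qc_pass, , drop = FALSE]
  if (nrow(ok) < 1) stop("No unflagged breaths to summarize.", call. = FALSE)
  meta <- meta %||% session_meta()
  paused <- ok$pause_ms[ok$has_pause]
  tibble(
    animal_id = meta$animal_id, drug = meta$drug, gas = meta$gas,
    epoch = meta$epoch,
    n_breaths = nrow(ok),
    mean_rate = mean(ok$freq_hz),
    mean_pif = mean(ok$pif_ml_s),
    mean_pef = mean(ok$pef_ml_s),
    mean_tv = mean(ok$tv_ul),
    mean_mv = mean(ok$mv_ml_min),
    mean_pause = mean(ok$pause_ms),
    mean_pause_paused = if (length(paused)) mean(paused) else 0,
    pause_rate = mean(ok$has_pause)
  )
}

summary_metric_col <- function(metric) {
  cols <- c(rate = "mean_rate", pif = "mean_pif", pef = "mean_pef",
            tv = "mean_tv", mv = "mean_mv", pause = "mean_pause")
  col <- cols[metric]
  if (any(is.na(col))) {
    stop("Unknown metric: ", paste(metric[is.na(col)], collapse = ", "),
         call. = FALSE)
  }
  unname(col)
}

#' Morphine-to-saline ratio of a session-mean metric
#'
#' Within-animal ratio of the morphine-session mean to the saline-session
#' mean, the display statistic of the paired design (each animal is its
#' own control).
#'
#' @param s_morphine,s_saline One-row session summaries from
#'   [summarize_session()] for the same animal and gas condition.
#' @param metric One of `"rate"`, `"pif"`, `"pef"`, `"tv"`, `"mv"`,
#'   `"pause"`.
#' @return A one-row tibble `animal_id`, `metric`, `ratio`.
#' @export
morphine_saline_ratio <- function(s_morphine, s_saline, metric = "rate") {
  metric <- match.arg(metric, c("rate", "pif", "pef", "tv", "mv", "pause"))
  if (s_morphine$animal_id != s_saline$animal_id) {
    stop("Sessions are from different animals.", call. = FALSE)
  }
  if (s_morphine$gas != s_saline$gas) {
    stop("Sessions are from different gas conditions.", call. = FALSE)
  }
  col <- summary_metric_col(metric)
  denom <- s_saline[[col]]
  if (denom == 0) stop("Saline mean is zero; ratio undefined.", call. = FALSE)
  tibble(animal_id = s_morphine$animal_id, metric = metric,
         ratio = s_morphine[[col]] / denom)
}

#' Per-animal drug/control ratios across a cohort
#'
#' Pivots a stack of session summaries (one row per animal x drug) into
#' per-animal morphine/saline ratios for the requested metrics.
#'
#' @param summaries A tibble of rows from [summarize_session()] containing
#'   both drug conditions for each animal.
#' @param metrics Character vector of metrics (see
#'   [morphine_saline_ratio()]).
#' @param drug_levels Length-2 character vector `c(numerator, denominator)`.
#' @return A tibble `animal_id`, `metric`, `ratio`.
#' @export
paired_ratios <- function(summaries, metrics = c("rate", "pif", "tv", "mv"),
                          drug_levels = c("morphine", "saline")) {
  cols <- summary_metric_col(metrics)
  long <- summaries |>
    dplyr::filter(.data$drug %in% drug_levels) |>
    dplyr::select(dplyr::all_of(c("animal_id", "drug", cols))) |>
    tidyr::pivot_longer(dplyr::all_of(cols), names_to = "col",
                        values_to = "value") |>
    dplyr::mutate(metric = metrics[match(.data$col, cols)]) |>
    dplyr::select(-"col") |>
    tidyr::pivot_wider(names_from = "drug", values_from = "value")
  long$ratio <- long[[drug_levels[1]]] / long[[drug_levels[2]]]
  long[c("animal_id", "metric", "ratio")]
}

#' Paired Cohen's d
#'
#' Effect size for a within-subject comparison: `mean(diffs) / sd(diffs)`
#' with the sample (n-1) standard deviation. This paired form is the one
#' consistent with effect sizes of ~5-6 seen when every animal responds in
#' the same direction.
#'
#' @param diffs Numeric vector of paired differences.
#' @return Dimensionless effect size.
#' @export
#' @examples
#' cohens_d_paired(c(1, 2, 3)) # 2
cohens_d_paired <- function(diffs) {
  if (length(diffs) < 2) stop("Need at least 2 differences.", call. = FALSE)
  s <- sd(diffs)
  if (s == 0) stop("Zero standard deviation; effect size undefined.",
                   call. = FALSE)
  mean(diffs) / s
}

#' Normality-gated paired comparison
#'
#' Shapiro-Wilk normality test on the paired differences decides the test:
#' paired Student's t if `normality_p >= alpha`, otherwise the Wilcoxon
#' signed-rank test. Two-sided p-values; paired Cohen's d attached. If all
#' differences are zero the result is flagged and the effect size is `NA`.
#'
#' @param saline,morphine Equal-length paired numeric vectors of per-animal
#'   values (control first).
#' @param alpha Normality gate (default 0.05).
#' @param metric Optional label carried into the result.
#' @return An object of class `gated_paired_test`; see [tidy()] and
#'   [glance()] methods.
#' @export
gated_paired_test <- function(saline, morphine, alpha = 0.05,
                              metric = NA_character_) {
  if (length(saline) != length(morphine)) {
    stop("Paired vectors must have equal length.", call. = FALSE)
  }
  n <- length(saline)
  if (n < 3) stop("Need at least 3 pairs.", call. = FALSE)
  diffs <- morphine - saline
  flags <- character()
  if (all(diffs == 0)) {
    res <- structure(
      list(metric = metric, n = n, normality_p = NA_real_,
           test_used = "none", statistic = NA_real_, p_value = 1,
           cohens_d = NA_real_, flags = "zero_differences"),
      class = "gated_paired_test")
    return(res)
  }
  normality_p <- shapiro.test(diffs)$p.value
  if (normality_p >= alpha) {
    ht <- t.test(morphine, saline, paired = TRUE)
    test_used <- "paired_t"
  } else {
    ht <- suppressWarnings(wilcox.test(morphine, saline, paired = TRUE))
    test_used <- "wilcoxon_signed_rank"
  }
  d <- tryCatch(cohens_d_paired(diffs), error = function(e) {
    flags <<- c(flags, "effect_size_undefined")
    NA_real_
  })
  structure(
    list(metric = metric, n = n, normality_p = normality_p,
         test_used = test_used, statistic = unname(ht$statistic),
         p_value = ht$p.value, cohens_d = d,
         flags = paste(flags, collapse = ";")),
    class = "gated_paired_test")
}

#' @export
print.gated_paired_test <- function(x, ...) {
  cat(sprintf("<gated_paired_test>%s n = %d\n",
              if (!is.na(x$metric)) paste0(" [", x$metric, "]") else "", x$n))
  cat(sprintf("  Shapiro-Wilk p = %s -> %s\n",
              format(x$normality_p, digits = 3), x$test_used))
  cat(sprintf("  statistic = %s, p = %s, Cohen's d = %s\n",
              format(x$statistic, digits = 4),
              format(x$p_value, digits = 3),
              format(x$cohens_d, digits = 3)))
  if (nzchar(x$flags)) cat("  flags:", x$flags, "\n")
  invisible(x)
}

#' Mixed repeated-measures two-way ANOVA
#'
#' Two-group (between-subjects) by two-time (within-subjects) mixed design,
#' as used to compare receptor-deleted versus sham cohorts measured before
#' and after manipulation. Fit via `aov` with a subject error stratum; with
#' one between factor and a time factor balanced within every subject, the
#' group and time effects are orthogonal, so these sums of squares equal
#' the Type-II ones even with unequal group sizes. With only two within
#' levels no sphericity correction is needed. The between-group denominator
#' df is `n_subjects - 2`. Effects whose sum of squares is exactly zero
#' report `F = 0`.
#'
#' @param data A data frame with one row per subject x time.
#' @param subject,group,time,value Column names (tidy-eval) for subject id,
#'   between factor (2 levels), within factor (2 levels), and response.
#' @return An object of class `rm_anova` with a `table` tibble
#'   (`effect`, `df_num`, `df_den`, `statistic`, `p_value`).
#' @export
mixed_rm_anova <- function(data, subject, group, time, value) {
  df <- tibble(
    subject = factor(dplyr::pull(data, {{ subject }})),
    group = factor(dplyr::pull(data, {{ group }})),
    time = factor(dplyr::pull(data, {{ time }})),
    value = as.numeric(dplyr::pull(data, {{ value }}))
  )
  if (nlevels(df$group) != 2) stop("Need exactly 2 groups.", call. = FALSE)
  if (nlevels(df$time) != 2) stop("Need exactly 2 time levels.", call. = FALSE)
  per_group <- tapply(df$subject, df$group, function(s) length(unique(s)))
  if (any(per_group < 2)) {
    stop("Each group needs at least 2 subjects.", call. = FALSE)
  }
  counts <- table(df$subject, df$time)
  if (any(counts != 1)) {
    stop("Every subject needs exactly one value per time level.",
         call. = FALSE)
  }
  if (sd(df$value) <= 1e-12 * (abs(mean(df$value)) + 1)) {
    tab <- tibble(effect = c("group", "time", "group:time"),
                  df_num = 1,
                  df_den = c(length(unique(df$subject)) - 2,
                             rep(length(unique(df$subject)) - 2, 2)),
                  statistic = 0, p_value = 1)
    return(structure(list(table = tab,
                          n_subjects = length(unique(df$subject)),
                          group_sizes = as.integer(per_group)),
                     class = "rm_anova"))
  }
  fit <- aov(value ~ group * time + Error(subject), data = df)
  sm <- summary(fit)
  between <- as.data.frame(sm[["Error: subject"]][[1]])
  within <- as.data.frame(sm[["Error: Within"]][[1]])
  pick <- function(tab, effect, label) {
    row <- trimws(rownames(tab)) == effect
    err <- trimws(rownames(tab)) == "Residuals"
    ss <- tab[row, "Sum Sq"]
    ms_err <- tab[err, "Mean Sq"]
    df_num <- tab[row, "Df"]
    df_den <- tab[err, "Df"]
    f <- if (ss == 0) 0 else (ss / df_num) / ms_err
    p <- if (ss == 0) 1 else stats::pf(f, df_num, df_den, lower.tail = FALSE)
    tibble(effect = label, df_num = df_num, df_den = df_den,
           statistic = f, p_value = p)
  }
  tab <- dplyr::bind_rows(
    pick(between, "group", "group"),
    pick(within, "time", "time"),
    pick(within, "group:time", "group:time")
  )
  structure(list(table = tab, n_subjects = length(unique(df$subject)),
                 group_sizes = as.integer(per_group)),
            class = "rm_anova")
}

#' @export
print.rm_anova <- function(x, ...) {
  cat(sprintf("<rm_anova> mixed 2x2 design, %d subjects (%s per group)\n",
              x$n_subjects, paste(x$group_sizes, collapse = "/")))
  print(x$table)
  invisible(x)
}

#' Probability density of pause lengths
#'
#' Histogram density (area 1) of per-breath pause lengths on linear or
#' log10-spaced bins. The log scale resolves the heavy right tail that
#' opioids produce; only positive pauses contribute there.
#'
#' @param pause_ms Numeric vector of pause lengths in ms.
#' @param scale `"linear"` or `"log"`.
#' @param bins Number of bins.
#' @param range Optional length-2 bin range (ms); defaults to the data
#'   range.
#' @return A tibble `bin_lo`, `bin_hi`, `bin_mid`, `count`, `density`
#'   (per ms; `sum(density * (bin_hi - bin_lo)) == 1`).
#' @export
pause_pdf <- function(pause_ms, scale = c("linear", "log"), bins = 30,
                      range = NULL) {
  scale <- match.arg(scale)
  x <- pause_ms[is.finite(pause_ms)]
  if (scale == "log") x <- x[x > 0]
  if (!length(x)) {
    warning("No ", if (scale == "log") "positive " else "",
            "pause values; empty density.", call. = FALSE)
    return(tibble(bin_lo = numeric(), bin_hi = numeric(),
                  bin_mid = numeric(), count = integer(),
                  density = numeric()))
  }
  if (is.null(range)) range <- base::range(x)
  if (diff(range) == 0) range <- range + c(-0.5, 0.5)
  breaks <- if (scale == "linear") {
    seq(range[1], range[2], length.out = bins + 1)
  } else {
    10^seq(log10(range[1]), log10(range[2]), length.out = bins + 1)
  }
  counts <- as.integer(table(cut(x, breaks, include.lowest = TRUE)))
  widths <- diff(breaks)
  tibble(
    bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
    bin_mid = (breaks[-length(breaks)] + breaks[-1]) / 2,
    count = counts,
    density = counts / (sum(counts) * widths)
  )
}
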