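#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a normality-gated paired test
#'
#' @param x A `gated_paired_test`.
#' @param ... Unused.
#' @return A one-row tibble: `metric`, `test_used`, `statistic`,
#'   `p_value`, `cohens_d`, `normality_p`, `n`, `flags`.
#' @method tidy gated_paired_test
#' @export
tidy.gated_paired_test <- function(x, ...) {
  tibble(metric = x$metric, test_used = x$test_used,
         statistic = x$statistic, p_value = x$p_value,
         cohens_d = x$cohens_d, normality_p = x$normality_p,
         n = x$n, flags = x$flags)
}

#' @rdname tidy.gated_paired_test
#' @method glance gated_paired_test
#' @export
glance.gated_paired_test <- function(x, ...) {
  tibble(test_used = x$test_used, p_value = x$p_value,
         cohens_d = x$cohens_d, n = x$n)
}

#' Tidy a mixed repeated-measures ANOVA
#'
#' @param x An `rm_anova`.
#' @param ... Unused.
#' @return The factor table: one row per effect (`group`, `time`,
#'   `group:time`) with `df_num`, `df_den`, `statistic`, `p_value`.
#' @method tidy rm_anova
#' @export
tidy.rm_anova <- function(x, ...) x$table

#' @rdname tidy.rm_anova
#' @method glance rm_anova
#' @export
glance.rm_anova <- function(x, ...) {
  tibble(n_subjects = x$n_subjects,
         n_group_1 = x$group_sizes[1], n_group_2 = x$group_sizes[2])
}
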