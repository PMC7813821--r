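# broom-style tidiers for redunet result objects.

#' @describeIn permutation_ancova Tidy method: one row with statistic, dfs
#'   and p-value.
#' @param x A `redunet_perm_test`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.redunet_perm_test <- function(x, ...) {
  tibble::tibble(term = x$term, statistic = x$statistic,
                 df1 = x$df[["df1"]], df2 = x$df[["df2"]],
                 p.value = x$p_value)
}

#' @describeIn permutation_ancova Glance method: permutation bookkeeping.
#' @exportS3Method generics::glance
glance.redunet_perm_test <- function(x, ...) {
  tibble::tibble(n = x$n, n_permutations = x$n_permutations,
                 seed = x$seed %||% NA_integer_,
                 covariates = paste(x$covariates, collapse = ","))
}

#' @describeIn cohens_d Tidy method: estimate and confidence bounds.
#' @param x A `redunet_effect_size`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.redunet_effect_size <- function(x, ...) {
  tibble::tibble(estimate = x$estimate, conf.low = x$ci_low,
                 conf.high = x$ci_high, n1 = x$n1, n2 = x$n2)
}

#' @describeIn ratio_null_test Tidy method: one row per test.
#' @param x A `redunet_ratio_test`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.redunet_ratio_test <- function(x, ...) {
  tibble::tibble(comparison = paste(x$comparison, collapse = ":"),
                 observed_mean = x$observed_mean, null_mean = x$null_mean,
                 null_se = x$null_se, p.value = x$p_value,
                 n_null_pairs = x$n_null_pairs)
}

#' @describeIn anova_tukey Tidy method: omnibus row plus Tukey pairwise rows.
#' @param x A `redunet_anova`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.redunet_anova <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$omnibus, contrast = "omnibus"),
    dplyr::rename(x$pairwise, contrast = "pair"))
}
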