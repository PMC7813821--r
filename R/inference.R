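# Group inference: Freedman-Lane permutation ANCOVA, pairwise post hocs with
# Benjamini-Hochberg correction and Cohen's d, and parametric ANOVA + Tukey
# HSD for auxiliary (connectivity / cognition) comparisons.

#' Permutation ANCOVA (Freedman-Lane) for a group term
#'
#' Tests a factor term in a linear model `y ~ group + covariates` by
#' permutation, without distributional assumptions on `y`. The null
#' distribution of the group F statistic is built by the Freedman-Lane
#' scheme: residuals of the covariate-only (reduced) model are permuted and
#' added back to its fitted values, and the full-model F is recomputed for
#' each permuted response. With no covariates this reduces to the ordinary
#' permutation one-way ANOVA. The p-value uses the add-one rule
#' `(b + 1) / (m + 1)` so it can never be exactly zero.
#'
#' @param data A data frame with the response, group and covariate columns.
#' @param formula Model formula, e.g. `y ~ group + education`.
#' @param term Name of the tested term; defaults to the first term on the
#'   right-hand side. Must resolve to a factor/character variable with at
#'   least two levels and at least two observations per level.
#' @param n_permutations Number of permutations (default 10000).
#' @param seed RNG seed for the permutation draw; recorded in the result.
#' @return A `redunet_perm_test` object with the observed F, degrees of
#'   freedom, permutation p-value, permutation count and seed. `tidy()` and
#'   `glance()` methods are available.
#' @examples
#' d <- data.frame(y = rnorm(60), g = rep(c("a", "b", "c"), 20))
#' permutation_ancova(d, y ~ g, n_permutations = 199, seed = 1)
#' @export
permutation_ancova <- function(data, formula, term = NULL,
                               n_permutations = 10000, seed = NULL) {
  mf <- model.frame(formula, data = data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  if (!is.numeric(y) || any(!is.finite(y)))
    abort_validation("response must be numeric and finite.")
  if (var(y) == 0)
    abort_validation("response is constant; the F statistic is undefined.")
  term_labels <- attr(terms(mf), "term.labels")
  if (length(term_labels) == 0) abort_validation("formula has no model terms.")
  term <- term %||% term_labels[1L]
  if (!term %in% term_labels)
    abort_validation(sprintf("term '%s' is not in the formula.", term))
  gvar <- mf[[term]]
  if (is.character(gvar)) gvar <- factor(gvar)
  if (is.factor(gvar)) {
    tab <- table(droplevels(gvar))
    if (length(tab) < 2) abort_validation("tested term needs at least 2 groups.")
    if (any(tab < 2))
      abort_validation(sprintf("group(s) with fewer than 2 subjects: %s",
                               paste(names(tab)[tab < 2], collapse = ", ")))
  }

  X_full <- model.matrix(terms(mf), mf)
  drop_cols <- attr(X_full, "assign") == match(term, term_labels)
  Z <- X_full[, !drop_cols, drop = FALSE]
  qz <- qr(Z)
  qx <- qr(X_full)
  n <- length(y)
  df1 <- qx$rank - qz$rank
  df2 <- n - qx$rank
  if (df1 < 1 || df2 < 1) abort_validation("insufficient degrees of freedom.")

  rss <- function(q, Y) colSums(qr.resid(q, Y)^2)
  f_stat <- function(Y) {
    Y <- as.matrix(Y)
    ((rss(qz, Y) - rss(qx, Y)) / df1) / (rss(qx, Y) / df2)
  }
  f_obs <- f_stat(y)

  fitted_z <- qr.fitted(qz, y)
  resid_z <- qr.resid(qz, y)
  m <- as.integer(n_permutations)
  perms <- with_seed(seed, replicate(m, sample.int(n)))
  y_star <- fitted_z + matrix(resid_z[perms], n, m)
  f_null <- f_stat(y_star)
  b <- sum(f_null >= f_obs)

  structure(
    list(statistic = unname(f_obs), df = c(df1 = df1, df2 = df2),
         p_value = (b + 1) / (m + 1), n_permutations = m, seed = seed,
         term = term, covariates = setdiff(term_labels, term), n = n),
    class = "redunet_perm_test")
}

#' @export
print.redunet_perm_test <- function(x, ...) {
  cat(sprintf("Permutation ANCOVA (Freedman-Lane): F(%d, %d) = %.3f, p = %.4g [%d permutations]\n",
              x$df[["df1"]], x$df[["df2"]], x$statistic, x$p_value, x$n_permutations))
  if (length(x$covariates))
    cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' Cohen's d with confidence interval
#'
#' Standardized mean difference `(mean(x) - mean(y)) / s_pooled` with the
#' pooled standard deviation on `n1 + n2 - 2` degrees of freedom (plain d,
#' no small-sample correction). The confidence interval uses the asymptotic
#' standard error `sqrt((n1 + n2)/(n1 n2) + d^2 / (2 (n1 + n2 - 2)))` with
#' t quantiles.
#'
#' @param x,y Numeric vectors (each length >= 2).
#' @param conf_level Confidence level (default 0.95).
#' @return A `redunet_effect_size` object with `estimate`, `ci_low`,
#'   `ci_high`, sample sizes and the confidence level.
#' @examples
#' cohens_d(c(0, 1, 2), c(1, 2, 3))  # d = -1
#' @export
cohens_d <- function(x, y, conf_level = 0.95) {
  if (length(x) < 2 || length(y) < 2)
    abort_validation("each sample needs at least 2 observations.")
  n1 <- length(x); n2 <- length(y)
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / df)
  if (sp == 0) abort_validation("pooled standard deviation is zero; d undefined.")
  d <- (mean(x) - mean(y)) / sp
  se <- sqrt((n1 + n2) / (n1 * n2) + d^2 / (2 * df))
  q <- qt(1 - (1 - conf_level) / 2, df)
  structure(
    list(estimate = d, ci_low = d - q * se, ci_high = d + q * se,
         n1 = n1, n2 = n2, conf_level = conf_level),
    class = "redunet_effect_size")
}

#' @export
print.redunet_effect_size <- function(x, ...) {
  cat(sprintf("Cohen's d = %.3f, %d%% CI [%.3f, %.3f] (n = %d, %d)\n",
              x$estimate, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$n1, x$n2))
  invisible(x)
}

#' Pairwise permutation post hocs with BH correction
#'
#' Runs a two-group permutation test for each requested group pair, with a
#' per-pair covariate policy (e.g. education only in the eMCI-lMCI
#' comparison, when only those groups differ in education), and adjusts the
#' pairwise p-values across the tested family by the Benjamini-Hochberg
#' procedure. Cohen's d (first group minus second) with its confidence
#' interval accompanies every pair.
#'
#' @param data Data frame with response, group and covariate columns.
#' @param response,group Column names (strings) of the response and group.
#' @param pairs List of length-2 character vectors of group levels; default
#'   all pairwise combinations in level order.
#' @param covariate_policy Named list mapping `"A:B"` pair labels to
#'   character vectors of covariate column names; pairs not named get no
#'   covariates.
#' @param n_permutations,seed Passed to [permutation_ancova()]; each pair
#'   receives its own seed derived from `seed`.
#' @return A tibble with one row per pair: F statistic, dfs, raw and
#'   BH-adjusted permutation p-values, Cohen's d with CI, covariates used.
#' @export
pairwise_posthoc <- function(data, response, group, pairs = NULL,
                             covariate_policy = NULL, n_permutations = 10000,
                             seed = NULL) {
  g <- factor(data[[group]])
  levs <- levels(g)
  if (is.null(pairs))
    pairs <- utils::combn(levs, 2, simplify = FALSE)
  seeds <- if (is.null(seed)) vector("list", length(pairs))
           else as.list(derive_seeds(seed, length(pairs)))
  res <- purrr::imap(pairs, function(pr, i) {
    lab <- paste(pr, collapse = ":")
    covs <- covariate_policy[[lab]] %||% covariate_policy[[paste(rev(pr), collapse = ":")]] %||% character()
    sub <- data[g %in% pr, , drop = FALSE]
    sub[[group]] <- droplevels(factor(sub[[group]], levels = levs))
    fml <- as.formula(paste(response, "~", paste(c(group, covs), collapse = " + ")))
    pt <- permutation_ancova(sub, fml, term = group,
                             n_permutations = n_permutations, seed = seeds[[i]])
    es <- cohens_d(sub[[response]][sub[[group]] == pr[1]],
                   sub[[response]][sub[[group]] == pr[2]])
    tibble::tibble(pair = lab, f_statistic = pt$statistic,
                   df1 = pt$df[["df1"]], df2 = pt$df[["df2"]],
                   p_value = pt$p_value, cohens_d = es$estimate,
                   ci_low = es$ci_low, ci_high = es$ci_high,
                   n_permutations = pt$n_permutations,
                   covariates = paste(covs, collapse = ","))
  })
  out <- dplyr::bind_rows(res)
  dplyr::mutate(out, p_adjusted = p.adjust(.data$p_value, method = "BH"),
                .after = "p_value")
}

#' One-way ANOVA with Tukey HSD post hocs
#'
#' Parametric omnibus comparison (optionally covariate-adjusted) followed by
#' Tukey's honest significant difference test on the group term; used for
#' the auxiliary comparisons (overall connectivity, cognition scores,
#' white-matter-hyperintensity-style volumetrics) where permutation testing
#' is not required.
#'
#' @param data Data frame.
#' @param formula Model formula, e.g. `y ~ group + education`; the tested
#'   factor is `term`.
#' @param term Name of the factor term (default: first term).
#' @return A list of class `redunet_anova` with `omnibus` (one-row tibble:
#'   F, dfs, p) and `pairwise` (Tukey-adjusted differences and p-values).
#' @export
anova_tukey <- function(data, formula, term = NULL) {
  term_labels <- attr(terms(formula), "term.labels")
  term <- term %||% term_labels[1L]
  data[[term]] <- factor(data[[term]])
  fit <- aov(formula, data = data)
  at <- stats::anova(fit)
  i <- match(term, rownames(at))
  if (is.na(i)) abort_validation(sprintf("term '%s' not in the fitted model.", term))
  omni <- tibble::tibble(
    term = term, f_statistic = at[i, "F value"], df1 = at[i, "Df"],
    df2 = at["Residuals", "Df"], p_value = at[i, "Pr(>F)"])
  tk <- TukeyHSD(fit, which = term)[[term]]
  pairwise <- tibble::tibble(
    pair = rownames(tk), diff = tk[, "diff"], ci_low = tk[, "lwr"],
    ci_high = tk[, "upr"], p_adjusted = tk[, "p adj"])
  structure(list(omnibus = omni, pairwise = pairwise, fit = fit),
            class = "redunet_anova")
}

#' @export
print.redunet_anova <- function(x, ...) {
  o <- x$omnibus
  cat(sprintf("ANOVA: F(%d, %d) = %.3f, p = %.4g\n", o$df1, o$df2,
              o$f_statistic, o$p_value))
  print(x$pairwise)
  invisible(x)
}
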