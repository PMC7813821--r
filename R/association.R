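# Redundancy-cognition and redundancy-efficiency regressions: OLS with
# standardized coefficients, confirmed by Huber robust regression with a
# Wald test.

std_reg_prep <- function(data, outcome, predictor, covariates) {
  cols <- c(outcome, predictor, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols))
    abort_validation(sprintf("column(s) not found: %s", paste(missing_cols, collapse = ", ")))
  d <- data[, cols, drop = FALSE]
  cc <- complete.cases(d)
  if (sum(!cc) > 0)
    rlang::inform(sprintf("Dropping %d incomplete case(s) for %s ~ %s.",
                          sum(!cc), outcome, predictor))
  d <- d[cc, , drop = FALSE]
  p <- 1L + length(covariates)
  if (nrow(d) < p + 2)
    abort_validation(sprintf("too few complete cases (n = %d) for %d predictor(s).",
                             nrow(d), p))
  if (sd(d[[predictor]]) == 0)
    abort_validation(sprintf("predictor '%s' is constant.", predictor))
  if (sd(d[[outcome]]) == 0)
    abort_validation(sprintf("outcome '%s' is constant.", outcome))
  d$.y <- as.numeric(scale(d[[outcome]]))
  d$.x <- as.numeric(scale(d[[predictor]]))
  fml <- as.formula(paste(".y ~ .x",
                          if (length(covariates)) paste("+", paste(covariates, collapse = " + ")) else ""))
  list(data = d, formula = fml, n = nrow(d))
}

#' Standardized OLS regression of an outcome on a focal predictor
#'
#' Both the outcome and the focal predictor are z-scored before fitting (so
#' with no covariates the slope equals the Pearson correlation); covariates
#' enter on their raw scale. Reports the standardized coefficient for the
#' focal predictor, its two-sided p-value, and the adjusted R-squared of the
#' fit.
#'
#' @param data Data frame.
#' @param outcome,predictor Column names of the dependent variable and the
#'   focal predictor.
#' @param covariates Optional character vector of covariate column names.
#' @return A one-row tibble: `beta`, `p_value`, `adj_r2`, `n`, `method`
#'   (`"ols"`), `covariates`.
#' @examples
#' d <- data.frame(mem = rnorm(50)); d$red <- d$mem + rnorm(50)
#' standardized_regression(d, "mem", "red")
#' @export
standardized_regression <- function(data, outcome, predictor, covariates = NULL) {
  prep <- std_reg_prep(data, outcome, predictor, covariates)
  fit <- lm(prep$formula, data = prep$data)
  sm <- summary(fit)
  tibble::tibble(
    outcome = outcome, predictor = predictor, method = "ols",
    beta = unname(coef(fit)[".x"]),
    p_value = sm$coefficients[".x", "Pr(>|t|)"],
    adj_r2 = sm$adj.r.squared, n = prep$n,
    covariates = paste(covariates %||% character(), collapse = ","))
}

#' Huber robust regression with Wald test
#'
#' Iteratively reweighted least squares with Huber's loss (tuning constant
#' 1.345, giving 95% efficiency under normality), on the same standardized
#' scale as [standardized_regression()]. Significance of the focal
#' coefficient is assessed with a Wald t test using the robust standard
#' error. Resistant to response outliers; agrees with OLS on clean data.
#'
#' @inheritParams standardized_regression
#' @param k Huber tuning constant (default 1.345).
#' @param maxit Maximum IRLS iterations (default 40).
#' @return A one-row tibble with the same columns as
#'   [standardized_regression()] and `method = "huber"`; `adj_r2` is a
#'   pseudo value based on the squared correlation of fitted and observed.
#' @export
robust_regression_huber <- function(data, outcome, predictor, covariates = NULL,
                                    k = 1.345, maxit = 40) {
  prep <- std_reg_prep(data, outcome, predictor, covariates)
  fit <- MASS::rlm(prep$formula, data = prep$data, psi = MASS::psi.huber,
                   k = k, maxit = maxit)
  if (!fit$converged)
    rlang::abort(sprintf("Huber IRLS did not converge after %d iterations.", maxit),
                 class = "redunet_convergence_error")
  sm <- summary(fit)
  est <- sm$coefficients[".x", "Value"]
  se <- sm$coefficients[".x", "Std. Error"]
  df_res <- prep$n - length(coef(fit))
  r2 <- cor(fitted(fit), prep$data$.y)^2
  p_terms <- length(coef(fit)) - 1L
  tibble::tibble(
    outcome = outcome, predictor = predictor, method = "huber",
    beta = unname(est),
    p_value = 2 * pt(-abs(est / se), df_res),
    adj_r2 = 1 - (1 - r2) * (prep$n - 1) / df_res, n = prep$n,
    covariates = paste(covariates %||% character(), collapse = ","))
}

one_assoc <- function(data, outcome, predictor, covariates, methods) {
  dplyr::bind_rows(
    if ("ols" %in% methods)
      standardized_regression(data, outcome, predictor, covariates),
    if ("huber" %in% methods)
      robust_regression_huber(data, outcome, predictor, covariates))
}

#' Full redundancy-cognition / redundancy-efficiency association suite
#'
#' Runs the regression grid linking ROI redundancy to cognition and global
#' efficiency: for each ROI, memory (MEM) and executive function (EF)
#' composites are regressed on redundancy, pooled across groups and within
#' each group; global efficiency is regressed on redundancy (education as a
#' covariate in the pooled fit only); and within the MCI subjects redundancy
#' is regressed on MMSE (direction reversed, as an alternative staging of
#' impairment). Every regression is fitted by OLS and, as an outlier check,
#' by Huber robust regression. Subjects with missing cognitive scores are
#' dropped from cognition regressions only.
#'
#' @param subject_metrics Data frame with one row per subject containing the
#'   grouping column `group`, covariate `education`, outcome columns among
#'   `mem`, `ef`, `mmse`, `e_global`, and one redundancy column per ROI.
#' @param rois Character vector: names of the ROI redundancy columns.
#' @param outcomes Which outcome families to run (default all four).
#' @param mci_groups Group labels pooled for the MMSE analysis
#'   (default `c("eMCI", "lMCI")`).
#' @param methods Fitting methods (default OLS and Huber).
#' @return A tibble with one row per ROI x outcome x grouping x method:
#'   `roi`, `group` (`"pooled"` or a group label), standardized `beta`,
#'   `p_value`, `adj_r2`, `n`, `covariates`.
#' @export
run_association_suite <- function(subject_metrics, rois,
                                  outcomes = c("mem", "ef", "mmse", "e_global"),
                                  mci_groups = c("eMCI", "lMCI"),
                                  methods = c("ols", "huber")) {
  outcomes <- match.arg(outcomes, several.ok = TRUE)
  missing_rois <- setdiff(rois, names(subject_metrics))
  if (length(missing_rois))
    abort_validation(sprintf("ROI column(s) missing: %s", paste(missing_rois, collapse = ", ")))
  groups <- unique(as.character(subject_metrics$group))
  rows <- list()
  for (roi in rois) {
    for (oc in intersect(outcomes, c("mem", "ef"))) {
      rows[[length(rows) + 1L]] <-
        one_assoc(subject_metrics, oc, roi, NULL, methods) |>
        dplyr::mutate(roi = roi, group = "pooled")
      for (g in groups) {
        rows[[length(rows) + 1L]] <-
          one_assoc(subject_metrics[subject_metrics$group == g, ], oc, roi,
                    NULL, methods) |>
          dplyr::mutate(roi = roi, group = g)
      }
    }
    if ("e_global" %in% outcomes) {
      rows[[length(rows) + 1L]] <-
        one_assoc(subject_metrics, "e_global", roi, "education", methods) |>
        dplyr::mutate(roi = roi, group = "pooled")
      for (g in groups) {
        rows[[length(rows) + 1L]] <-
          one_assoc(subject_metrics[subject_metrics$group == g, ], "e_global",
                    roi, NULL, methods) |>
          dplyr::mutate(roi = roi, group = g)
      }
    }
    if ("mmse" %in% outcomes) {
      mci <- subject_metrics[subject_metrics$group %in% mci_groups, ]
      rows[[length(rows) + 1L]] <-
        one_assoc(mci, roi, "mmse", NULL, methods) |>
        dplyr::mutate(roi = roi, group = "MCI")
    }
  }
  dplyr::bind_rows(rows) |>
    dplyr::relocate("roi", "outcome", "group", "method")
}
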