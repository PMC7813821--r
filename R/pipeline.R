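# End-to-end pipeline driver: cohort -> QC -> connectomes -> metrics ->
# group comparisons -> nodal ratios -> regressions, with a machine-readable
# report.

#' Pipeline configuration
#'
#' Collects every knob the end-to-end analysis needs. Fully serializable:
#' a config plus its seeds reproduces a run bit-for-bit.
#'
#' @param cohort Either a `redunet_cohort_config` (the cohort is simulated),
#'   a `redunet_cohort`, or a directory path for [read_cohort()].
#' @param densities Density grid (default 2.5%-25% in 2.5% steps).
#' @param max_length Maximum route length L for redundancy (default 4).
#' @param counting_mode `"walks"` or `"simple_paths"`.
#' @param roi_pattern Regex on the parcellation `roi_group` selecting the
#'   ROIs analysed in group comparisons and regressions.
#' @param target_pattern Regex selecting the target ("posterior
#'   hippocampal") nodes for the ratio null test.
#' @param bandpass Apply [bandpass_filter()] before correlation? Default
#'   `FALSE`: the synthetic generator emits spectrally flat series, so
#'   filtering only discards degrees of freedom. Enable for real scans.
#' @param tr_seconds,low_hz,high_hz Filter settings when `bandpass = TRUE`.
#' @param max_outlier_fraction Motion QC exclusion threshold.
#' @param n_permutations Permutations per group test.
#' @param n_null_pairs Draws for the ratio null test.
#' @param covariates Covariate column(s) for omnibus tests (default
#'   `"education"`).
#' @param posthoc_covariate_policy Named list: pair label -> covariates for
#'   that post hoc (default education only in `"eMCI:lMCI"`, the groups
#'   that differ in education).
#' @param seed Master seed for all analysis randomness.
#' @return A list of class `redunet_pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            densities = density_grid(),
                            max_length = 4,
                            counting_mode = "walks",
                            roi_pattern = "^hippocampus",
                            target_pattern = "^hippocampus_posterior",
                            bandpass = FALSE,
                            tr_seconds = 3, low_hz = 0.008, high_hz = 0.09,
                            max_outlier_fraction = 0.5,
                            n_permutations = 10000,
                            n_null_pairs = 10000,
                            covariates = "education",
                            posthoc_covariate_policy = list(`eMCI:lMCI` = "education"),
                            seed = 1) {
  structure(as.list(environment()), class = "redunet_pipeline_config")
}

#' Connectivity and graph metrics for every subject in a cohort
#'
#' Runs the connectome stage (optional band-pass, Fisher-z correlation,
#' density stack) and [metrics_over_stack()] for each subject, returning one
#' long tibble.
#'
#' @param cohort A `redunet_cohort` (after motion QC, typically).
#' @param config A [pipeline_config()].
#' @return A tibble: `subject_id`, `density`, `metric`, `node`, `value`.
#' @export
cohort_metrics <- function(cohort, config = pipeline_config()) {
  purrr::imap(cohort$timeseries, function(ts, id) {
    if (isTRUE(config$bandpass))
      ts <- bandpass_filter(ts, config$tr_seconds, config$low_hz, config$high_hz)
    conn <- correlation_matrix(ts, subject_id = id)
    stk <- density_stack(conn, grid = config$densities)
    metrics_over_stack(stk, max_length = config$max_length,
                       counting_mode = config$counting_mode)
  }) |>
    dplyr::bind_rows()
}

roi_nodes <- function(parcellation, pattern) {
  parcellation$node[grepl(pattern, parcellation$roi_group)]
}

#' Run the full redundancy analysis pipeline
#'
#' Executes simulate (or load) -> motion QC -> connectomes -> graph metrics
#' -> permutation group comparisons (redundancy and degree per ROI, with BH
#' corrected post hocs and Cohen's d) -> nodal ratio sets with the
#' random-node-pair null test -> the association suite, and returns all
#' results as tibbles in a `redunet_report`. Optionally writes the report to
#' disk as TSV + JSON.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return A `redunet_report`: list with `subjects`, `excluded`,
#'   `metrics_avg`, `group_tests`, `posthoc`, `ratio_sets`, `ratio_tests`,
#'   `associations`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  cohort <- config$cohort
  if (inherits(cohort, "redunet_cohort_config")) cohort <- generate_cohort(cohort)
  else if (is.character(cohort)) cohort <- read_cohort(cohort)
  if (!inherits(cohort, "redunet_cohort"))
    abort_config("cohort must be a config, cohort object, or directory",
                 field = "cohort")

  qc <- exclude_high_motion(cohort, config$max_outlier_fraction)
  kept <- qc$kept
  rlang::inform(sprintf("Stage connectome: %d subjects in.", nrow(kept$subjects)))

  metrics <- cohort_metrics(kept, config)
  avg <- average_densities(metrics)
  parc <- kept$parcellation
  rois <- roi_nodes(parc, config$roi_pattern)
  targets <- roi_nodes(parc, config$target_pattern)
  groups <- levels(kept$subjects$group)

  roi_avg <- avg |>
    dplyr::filter(.data$metric == "roi_redundancy", .data$node %in% rois) |>
    dplyr::left_join(kept$subjects, by = "subject_id")
  deg_avg <- avg |>
    dplyr::filter(.data$metric == "degree", .data$node %in% rois) |>
    dplyr::left_join(kept$subjects, by = "subject_id")

  seeds <- derive_seeds(config$seed, 2L * length(rois) + length(rois) + 10L)
  si <- 0L
  next_seed <- function() { si <<- si + 1L; seeds[si] }

  omnibus_for <- function(tbl, metric_name) {
    purrr::map(split(tbl, tbl$node), function(d) {
      fml <- as.formula(paste("value ~ group",
                              if (length(config$covariates))
                                paste("+", paste(config$covariates, collapse = " + "))
                              else ""))
      pt <- permutation_ancova(d, fml, term = "group",
                               n_permutations = config$n_permutations,
                               seed = next_seed())
      tibble::tibble(metric = metric_name, node = d$node[1],
                     roi_group = parc$roi_group[match(d$node[1], parc$node)],
                     f_statistic = pt$statistic, df1 = pt$df[["df1"]],
                     df2 = pt$df[["df2"]], p_value = pt$p_value)
    }) |> dplyr::bind_rows()
  }
  group_tests <- dplyr::bind_rows(
    omnibus_for(roi_avg, "roi_redundancy"),
    omnibus_for(deg_avg, "degree"))

  posthoc <- purrr::map(split(roi_avg, roi_avg$node), function(d) {
    pairwise_posthoc(d, "value", "group",
                     covariate_policy = config$posthoc_covariate_policy,
                     n_permutations = config$n_permutations,
                     seed = next_seed()) |>
      dplyr::mutate(metric = "roi_redundancy", node = d$node[1], .before = 1)
  }) |> dplyr::bind_rows()

  nodal_avg <- avg |>
    dplyr::filter(.data$metric == "nodal_redundancy") |>
    dplyr::left_join(kept$subjects[, c("subject_id", "group")], by = "subject_id")
  pairs <- utils::combn(groups, 2, simplify = FALSE)
  ratio_sets <- lapply(pairs, function(pr)
    ratio_set(nodal_avg, pr[1], pr[2]))
  names(ratio_sets) <- vapply(pairs, paste, character(1), collapse = ":")
  ratio_tests <- purrr::map(ratio_sets, function(rs)
    ratio_null_test(rs, targets, n_null_pairs = config$n_null_pairs,
                    seed = next_seed())) |>
    purrr::map(tidy) |> dplyr::bind_rows()

  eff <- avg |> dplyr::filter(.data$metric == "global_efficiency") |>
    dplyr::select("subject_id", e_global = "value")
  subj_wide <- roi_avg |>
    dplyr::select("subject_id", "node", "value") |>
    tidyr::pivot_wider(names_from = "node", values_from = "value") |>
    dplyr::left_join(kept$subjects, by = "subject_id") |>
    dplyr::left_join(eff, by = "subject_id")
  associations <- run_association_suite(subj_wide, rois = rois,
                                        mci_groups = setdiff(groups, groups[1]))

  report <- structure(
    list(subjects = kept$subjects, excluded = qc$excluded,
         metrics_avg = avg, group_tests = group_tests, posthoc = posthoc,
         ratio_sets = ratio_sets, ratio_tests = ratio_tests,
         associations = associations, config = config),
    class = "redunet_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write a pipeline report to disk
#'
#' @param report A `redunet_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(report$group_tests, file.path(dir, "group_tests.tsv"), progress = FALSE)
  readr::write_tsv(report$posthoc, file.path(dir, "posthoc.tsv"), progress = FALSE)
  readr::write_tsv(report$associations, file.path(dir, "associations.tsv"), progress = FALSE)
  readr::write_tsv(report$metrics_avg, file.path(dir, "metrics_avg.tsv"), progress = FALSE)
  for (nm in names(report$ratio_sets))
    readr::write_tsv(report$ratio_sets[[nm]],
                     file.path(dir, paste0("ratios_", gsub(":", "_", nm), ".tsv")),
                     progress = FALSE)
  jsonlite::write_json(
    list(excluded = report$excluded,
         ratio_tests = report$ratio_tests,
         seed = report$config$seed,
         n_permutations = report$config$n_permutations,
         n_null_pairs = report$config$n_null_pairs),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.redunet_report <- function(x, ...) {
  cat(sprintf("<redunet_report> %d subjects analysed, %d excluded\n",
              nrow(x$subjects), length(x$excluded)))
  cat("\nGroup omnibus tests (permutation ANCOVA):\n")
  print(x$group_tests, n = 20)
  cat("\nTarget-node ratio tests:\n")
  print(x$ratio_tests)
  invisible(x)
}
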