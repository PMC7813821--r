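# Plain-text I/O: per-subject time-series TSVs, subject and parcellation
# tables, and a JSON manifest carrying the config and seed.

#' Read a ROI time-series TSV
#'
#' Expects a tab-separated file with a header row of node ids and one row
#' per time point. If a parcellation table is supplied, columns are matched
#' to its node order (reordering with a message if needed) and missing or
#' unknown nodes raise descriptive errors.
#'
#' @param path File path.
#' @param parcellation Optional parcellation tibble with a `node` column.
#' @return A numeric matrix (time points x nodes) with node-id column names.
#' @export
read_timeseries <- function(path, parcellation = NULL) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  bad <- names(tbl)[!vapply(tbl, is.numeric, logical(1))]
  if (length(bad))
    abort_validation(sprintf("non-numeric column(s) in %s: %s", path,
                             paste(bad, collapse = ", ")))
  m <- as.matrix(tbl)
  if (!is.null(parcellation)) {
    want <- parcellation$node
    missing_nodes <- setdiff(want, colnames(m))
    if (length(missing_nodes))
      abort_validation(sprintf("time series %s lacks node column(s): %s", path,
                               paste(missing_nodes, collapse = ", ")))
    extra <- setdiff(colnames(m), want)
    if (length(extra))
      abort_validation(sprintf("time series %s has unknown node column(s): %s",
                               path, paste(extra, collapse = ", ")))
    if (!identical(colnames(m), want)) {
      rlang::inform(sprintf("Reordering columns of %s to parcellation order.", path))
      m <- m[, want, drop = FALSE]
    }
  }
  m
}

#' Write a cohort to a directory of plain-text files
#'
#' Emits `subjects.tsv` (including outlier flags encoded as a 0/1 string),
#' `parcellation.tsv`, `cohort.json` (config + seed), and one
#' `timeseries/<subject_id>.tsv` per subject.
#'
#' @param cohort A `redunet_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "redunet_cohort"))
  dir.create(file.path(dir, "timeseries"), recursive = TRUE, showWarnings = FALSE)
  subj <- cohort$subjects
  subj$outlier_flags <- vapply(cohort$outlier_flags[subj$subject_id],
                               function(f) paste(as.integer(f), collapse = ""),
                               character(1))
  readr::write_tsv(subj, file.path(dir, "subjects.tsv"), progress = FALSE)
  readr::write_tsv(cohort$parcellation, file.path(dir, "parcellation.tsv"),
                   progress = FALSE)
  cfg <- cohort$config
  jsonlite::write_json(
    list(config = unclass(cfg)[!vapply(cfg, is.function, logical(1))],
         seed = cohort$seed),
    file.path(dir, "cohort.json"), auto_unbox = TRUE, digits = NA)
  for (id in subj$subject_id) {
    readr::write_tsv(tibble::as_tibble(cohort$timeseries[[id]]),
                     file.path(dir, "timeseries", paste0(id, ".tsv")),
                     progress = FALSE)
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing `subjects.tsv`, `parcellation.tsv` and a
#'   `timeseries/` folder.
#' @return A `redunet_cohort` (config restored from `cohort.json` when
#'   present, without revalidation).
#' @export
read_cohort <- function(dir) {
  subj <- readr::read_tsv(file.path(dir, "subjects.tsv"), show_col_types = FALSE,
                          progress = FALSE)
  parc <- readr::read_tsv(file.path(dir, "parcellation.tsv"),
                          show_col_types = FALSE, progress = FALSE)
  flags <- lapply(setNames(subj$outlier_flags, subj$subject_id), function(s)
    as.logical(as.integer(strsplit(as.character(s), "")[[1]])))
  subj$outlier_flags <- NULL
  if ("group" %in% names(subj)) subj$group <- factor(subj$group, levels = unique(subj$group))
  ts <- lapply(setNames(subj$subject_id, subj$subject_id), function(id)
    read_timeseries(file.path(dir, "timeseries", paste0(id, ".tsv")), parc))
  cfg_path <- file.path(dir, "cohort.json")
  meta <- if (file.exists(cfg_path)) jsonlite::read_json(cfg_path, simplifyVector = TRUE) else NULL
  structure(
    list(subjects = tibble::as_tibble(subj), timeseries = ts,
         outlier_flags = flags, parcellation = parc,
         config = meta$config, seed = meta$seed),
    class = "redunet_cohort")
}
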