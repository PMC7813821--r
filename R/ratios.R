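# Nodal redundancy ratio sets between diagnostic groups and the
# random-node-pair null test for designated target nodes.

#' Between-group nodal redundancy ratio set
#'
#' For every node, the ratio of the group-mean nodal redundancy in group A to
#' that in group B. A ratio of 1 indicates equivalent redundancies; ratios
#' above 1 indicate higher redundancy in the numerator group. Nodes are
#' ranked by descending ratio (rank 1 = largest; ties share the smaller
#' rank). Nodes whose denominator mean is zero are flagged and excluded from
#' ranking.
#'
#' @param metric_table Long tibble with columns `subject_id`, `node`,
#'   `value` holding per-subject nodal redundancy (typically averaged across
#'   densities, see [average_densities()]), plus a group column.
#' @param group_a,group_b Group labels: numerator and denominator.
#' @param subjects Optional subject table (`subject_id`, group column) if the
#'   metric table lacks one.
#' @param group_col Name of the group column (default `"group"`).
#' @return A tibble of class `redunet_ratio_set` with columns `node`,
#'   `mean_a`, `mean_b`, `ratio`, `rank`, `flagged`; the comparison labels
#'   are stored in the `"comparison"` attribute.
#' @export
ratio_set <- function(metric_table, group_a, group_b, subjects = NULL,
                      group_col = "group") {
  tbl <- metric_table
  if (!group_col %in% names(tbl)) {
    if (is.null(subjects))
      abort_validation(sprintf("no '%s' column; supply `subjects`.", group_col))
    tbl <- dplyr::left_join(tbl, subjects[, c("subject_id", group_col)],
                            by = "subject_id")
  }
  g <- tbl[[group_col]]
  for (lab in c(group_a, group_b)) {
    if (!any(g == lab))
      abort_validation(sprintf("group '%s' has no subjects in the metric table.", lab))
  }
  means <- tbl |>
    dplyr::filter(.data[[group_col]] %in% c(group_a, group_b)) |>
    dplyr::group_by(.data$node) |>
    dplyr::summarise(
      mean_a = mean(.data$value[.data[[group_col]] == group_a]),
      mean_b = mean(.data$value[.data[[group_col]] == group_b]),
      .groups = "drop")
  out <- means |>
    dplyr::mutate(
      flagged = .data$mean_b == 0,
      ratio = dplyr::if_else(.data$flagged, NA_real_, .data$mean_a / .data$mean_b))
  if (any(out$flagged))
    rlang::warn(sprintf("%d node(s) with zero denominator mean flagged and excluded from ranking.",
                        sum(out$flagged)))
  out$rank <- NA_integer_
  ok <- !out$flagged
  out$rank[ok] <- rank(-out$ratio[ok], ties.method = "min")
  out <- dplyr::select(out, "node", "mean_a", "mean_b", "ratio", "rank", "flagged")
  structure(out, class = c("redunet_ratio_set", class(out)),
            comparison = c(group_a, group_b))
}

#' Random-node-pair null test for target-node ratios
#'
#' The observed statistic is the mean ratio of the target nodes (e.g. the
#' left and right posterior hippocampal nodes averaged into one value). The
#' null distribution is built by repeatedly drawing two distinct non-target
#' nodes uniformly at random (with replacement across draws) and averaging
#' their ratios, mirroring the two-node target average. The test is
#' one-sided: it asks whether the target ratio exceeds what random node
#' pairs produce, with p = (#\{null >= observed\} + 1) / (n_null_pairs + 1).
#'
#' @param ratios A [ratio_set()] result.
#' @param target_nodes Character vector of at least two target node ids;
#'   these are excluded from the null pool.
#' @param n_null_pairs Number of null draws (default 10000).
#' @param seed RNG seed; recorded in the result.
#' @return A `redunet_ratio_test` object: observed mean, null mean, null
#'   standard error (of the null mean), p-value, draw count and seed.
#' @export
ratio_null_test <- function(ratios, target_nodes, n_null_pairs = 10000,
                            seed = NULL) {
  stopifnot(inherits(ratios, "redunet_ratio_set"))
  if (length(target_nodes) < 2)
    abort_validation("need at least 2 target nodes to form the target average.")
  tgt <- ratios$ratio[match(target_nodes, ratios$node)]
  if (any(is.na(tgt)))
    abort_validation("target node missing from the ratio set or flagged.")
  pool <- ratios$ratio[!ratios$node %in% target_nodes & !ratios$flagged]
  K <- length(pool)
  if (K < 2)
    abort_validation("fewer than 2 non-target nodes available for the null pool.")
  observed <- mean(tgt)
  m <- as.integer(n_null_pairs)
  null_vals <- with_seed(seed, {
    i1 <- sample.int(K, m, replace = TRUE)
    i2 <- sample.int(K - 1L, m, replace = TRUE)
    i2 <- i2 + (i2 >= i1)               # second node distinct from the first
    (pool[i1] + pool[i2]) / 2
  })
  p <- (sum(null_vals >= observed) + 1) / (m + 1)
  structure(
    list(observed_mean = observed, null_mean = mean(null_vals),
         null_se = sd(null_vals) / sqrt(m), n_null_pairs = m,
         p_value = p, seed = seed, target_nodes = target_nodes,
         comparison = attr(ratios, "comparison")),
    class = "redunet_ratio_test")
}

#' @export
print.redunet_ratio_test <- function(x, ...) {
  cmp <- paste(x$comparison, collapse = ":")
  cat(sprintf("Target-node ratio test (%s): observed %.3f vs null %.3f (SE %.4f), p = %.4g [%d pairs]\n",
              cmp, x$observed_mean, x$null_mean, x$null_se, x$p_value,
              x$n_null_pairs))
  invisible(x)
}
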