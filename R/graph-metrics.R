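# Graph metrics: pairwise redundancy (walk or simple-path counts up to a
# maximum length), degree, and global efficiency, per density and averaged
# across the density grid.

#' Per-length walk counts between all node pairs
#'
#' For a binary undirected graph, the number of walks of length `l` between
#' nodes i and j is the (i, j) entry of the l-th power of the adjacency
#' matrix. Counts are exact integers (held in doubles, well below 2^53 for
#' any graph this package targets).
#'
#' @param adjacency Symmetric 0/1 matrix with zero diagonal.
#' @param max_length Maximum walk length L (default 4).
#' @return A list of `max_length` matrices; element `l` holds walk counts of
#'   length `l`.
#' @examples
#' A <- 1 - diag(4)               # complete graph K4
#' walk_counts(A, 2)[[2]][1, 2]   # 2 walks of length 2 between distinct nodes
#' @export
walk_counts <- function(adjacency, max_length = 4) {
  check_adjacency(adjacency)
  if (max_length < 1) abort_config("max_length must be >= 1", field = "max_length")
  out <- vector("list", max_length)
  P <- adjacency
  out[[1L]] <- P
  for (l in seq_len(max_length)[-1L]) {
    P <- P %*% adjacency
    out[[l]] <- P
  }
  out
}

# Self-avoiding path counts from one source node by bounded depth-first
# search; returns an L x n matrix of counts by length.
simple_paths_from <- function(neighbors, start, max_length, n) {
  counts <- matrix(0, max_length, n)
  visited <- logical(n)
  visited[start] <- TRUE
  recurse <- function(v, depth) {
    for (w in neighbors[[v]]) {
      if (!visited[w]) {
        counts[depth, w] <<- counts[depth, w] + 1
        if (depth < max_length) {
          visited[w] <<- TRUE
          recurse(w, depth + 1L)
          visited[w] <<- FALSE
        }
      }
    }
  }
  if (length(neighbors[[start]])) recurse(start, 1L)
  counts
}

#' Per-length self-avoiding path counts
#'
#' Counts simple (node-repetition-free) paths of each length up to
#' `max_length` between all node pairs by bounded depth-first enumeration.
#' Exponential in `max_length`; refused for graphs above 500 nodes.
#'
#' @inheritParams walk_counts
#' @return A list of `max_length` matrices of simple-path counts.
#' @export
simple_path_counts <- function(adjacency, max_length = 4) {
  check_adjacency(adjacency)
  n <- nrow(adjacency)
  if (n > 500)
    rlang::abort("simple-path counting is limited to graphs with <= 500 nodes.",
                 class = "redunet_resource_error")
  neighbors <- lapply(seq_len(n), function(i) which(adjacency[i, ] == 1))
  per_source <- lapply(seq_len(n), function(i)
    simple_paths_from(neighbors, i, max_length, n))
  lapply(seq_len(max_length), function(l) {
    M <- t(vapply(per_source, function(cnt) cnt[l, ], numeric(n)))
    dimnames(M) <- dimnames(adjacency)
    M
  })
}

#' Pairwise redundancy matrix
#'
#' Redundancy between nodes i and j is the number of direct and indirect
#' routes connecting them: the sum over lengths l = 1..L of the per-length
#' route counts p(i, j, l). In `"walks"` mode (the default, and the only mode
#' tractable at whole-brain scale) p counts walks, i.e. entries of adjacency
#' powers; in `"simple_paths"` mode p counts self-avoiding paths, enumerated
#' exhaustively for small graphs.
#'
#' @inheritParams walk_counts
#' @param counting_mode `"walks"` or `"simple_paths"`.
#' @return A `redunet_redundancy` object with fields `counts` (symmetric
#'   integer-valued matrix, zero diagonal), `per_length`, `max_length`,
#'   `counting_mode`.
#' @examples
#' A <- 1 - diag(4)
#' redundancy_matrix(A)$counts[1, 2]                              # 30
#' redundancy_matrix(A, counting_mode = "simple_paths")$counts[1, 2]  # 5
#' @export
redundancy_matrix <- function(adjacency, max_length = 4,
                              counting_mode = c("walks", "simple_paths")) {
  counting_mode <- match.arg(counting_mode)
  per_length <- switch(counting_mode,
    walks = walk_counts(adjacency, max_length),
    simple_paths = simple_path_counts(adjacency, max_length))
  counts <- Reduce(`+`, per_length)
  diag(counts) <- 0
  structure(
    list(counts = counts, per_length = per_length, max_length = max_length,
         counting_mode = counting_mode),
    class = "redunet_redundancy")
}

#' @export
print.redunet_redundancy <- function(x, ...) {
  cat(sprintf("<redunet_redundancy> %d nodes, L = %d, mode = %s\n",
              nrow(x$counts), x$max_length, x$counting_mode))
  invisible(x)
}

redundancy_counts <- function(R) {
  if (inherits(R, "redunet_redundancy")) R$counts else R
}

node_index <- function(node, M) {
  idx <- if (is.character(node)) match(node, rownames(M)) else as.integer(node)
  if (any(is.na(idx)) || any(idx < 1) || any(idx > nrow(M)))
    abort_validation(sprintf("node '%s' out of range.", paste(node, collapse = ", ")))
  idx
}

#' ROI redundancy: mean redundancy over a node's partner pairs
#'
#' The redundancy of an ROI is summarized as the mean R(i, j) over its
#' n - 1 partner nodes (299 pairs in a 300-node parcellation).
#'
#' @param R A `redunet_redundancy` object or redundancy count matrix.
#' @param roi Node id or index.
#' @return A single numeric value.
#' @export
roi_redundancy <- function(R, roi) {
  M <- redundancy_counts(R)
  i <- node_index(roi, M)
  mean(M[i, -i])
}

#' Nodal redundancy: row sum of the redundancy matrix
#'
#' @inheritParams roi_redundancy
#' @param node Node id or index.
#' @return A single numeric value; equals `(n - 1) * roi_redundancy`.
#' @export
nodal_redundancy <- function(R, node) {
  M <- redundancy_counts(R)
  i <- node_index(node, M)
  sum(M[i, -i])
}

#' Node degree in a binary graph
#'
#' Number of binarized edges incident to a node (row sum of the adjacency);
#' identical to the length-1 term of nodal redundancy.
#'
#' @inheritParams walk_counts
#' @param node Node id or index; if `NULL`, degrees of all nodes.
#' @return Integer degree(s).
#' @export
node_degree <- function(adjacency, node = NULL) {
  check_adjacency(adjacency)
  k <- rowSums(adjacency)
  if (is.null(node)) return(k)
  k[node_index(node, adjacency)]
}

#' Global efficiency of a binary graph
#'
#' Mean inverse shortest-path length over all ordered node pairs; pairs with
#' no connecting path contribute 0 (relevant at sparse densities where
#' thresholded graphs can be disconnected). Lies in \[0, 1\], reaching 1 only
#' for the complete graph.
#'
#' @inheritParams walk_counts
#' @return A single numeric value.
#' @examples
#' P <- matrix(0, 3, 3); P[1, 2] <- P[2, 1] <- P[2, 3] <- P[3, 2] <- 1
#' global_efficiency(P)  # 5/6
#' @export
global_efficiency <- function(adjacency) {
  check_adjacency(adjacency)
  n <- nrow(adjacency)
  if (n < 2) abort_validation("global efficiency needs at least 2 nodes.")
  g <- igraph::graph_from_adjacency_matrix(adjacency, mode = "undirected")
  D <- igraph::distances(g)
  inv <- 1 / D
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

# Fast walks-mode ROI redundancy for a handful of nodes: row sums of the
# redundancy matrix via matrix-vector products only (O(L n^2) per node),
# using e_i' A^l e_i identities for the diagonal terms at L <= 4.
roi_redundancy_nodes <- function(adjacency, idx, max_length = 4) {
  if (max_length > 4) {
    R <- redundancy_matrix(adjacency, max_length, "walks")
    return(vapply(idx, function(i) roi_redundancy(R, i), numeric(1)))
  }
  n <- nrow(adjacency)
  ones <- rep(1, n)
  rs <- vector("list", max_length)       # row sums of A^l
  v <- ones
  for (l in seq_len(max_length)) {
    v <- as.numeric(adjacency %*% v)
    rs[[l]] <- v
  }
  vapply(idx, function(i) {
    u <- adjacency[, i]                          # A e_i
    w <- as.numeric(adjacency %*% u)             # A^2 e_i
    dg <- c(0, sum(u * u), sum(u * w), sum(w * w))[seq_len(max_length)]
    tot <- sum(vapply(seq_len(max_length), function(l) rs[[l]][i], numeric(1)) - dg)
    tot / (n - 1)
  }, numeric(1))
}

# Fast walks-mode nodal redundancy for every node: row sums of the
# redundancy matrix with the diagonal removed, via matrix-vector products
# plus diag(A^l) identities, avoiding full powers beyond A^ceiling(L/2).
nodal_redundancy_all <- function(adjacency, max_length = 4) {
  n <- nrow(adjacency)
  hmax <- ceiling(max_length / 2)
  pows <- vector("list", hmax)
  pows[[1L]] <- adjacency
  if (hmax >= 2) for (h in 2:hmax) pows[[h]] <- pows[[h - 1L]] %*% adjacency
  ones <- rep(1, n)
  total <- numeric(n)
  v <- ones
  for (l in seq_len(max_length)) {
    v <- as.numeric(adjacency %*% v)          # row sums of A^l
    a <- min(l - 1L, hmax)
    b <- l - a
    dg <- if (l == 1L) numeric(n) else rowSums(pows[[a]] * pows[[b]])
    total <- total + v - dg
  }
  names(total) <- rownames(adjacency)
  total
}

#' Metrics across a density stack
#'
#' Computes, for every density in a [density_stack()], nodal redundancy and
#' ROI redundancy for every node, degree, and subject-level global
#' efficiency, returned as one long tibble. In walks mode the per-node
#' aggregates are computed from adjacency-power identities without
#' materializing the full redundancy matrix.
#'
#' @param stack A `redunet_graph_stack`.
#' @param rois Optional node ids: restricts the per-node rows (nodal/ROI
#'   redundancy and degree) to these nodes. Global efficiency is always one
#'   row per density with `node = NA`.
#' @param max_length Maximum route length L (default 4).
#' @param counting_mode `"walks"` (default) or `"simple_paths"`.
#' @param metrics Which metrics to compute.
#' @return A tibble with columns `subject_id`, `density`, `metric`, `node`,
#'   `value`.
#' @export
metrics_over_stack <- function(stack, rois = NULL, max_length = 4,
                               counting_mode = c("walks", "simple_paths"),
                               metrics = c("nodal_redundancy", "roi_redundancy",
                                           "degree", "global_efficiency")) {
  counting_mode <- match.arg(counting_mode)
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (!inherits(stack, "redunet_graph_stack") || length(stack$densities) == 0)
    abort_validation("`stack` must be a non-empty redunet_graph_stack.")
  ids <- stack$node_ids
  n <- length(ids)
  subj <- stack$subject_id %||% NA_character_
  want_red <- any(c("nodal_redundancy", "roi_redundancy") %in% metrics)

  rows <- purrr::map2(stack$adjacencies, stack$densities, function(A, d) {
    out <- list()
    if (want_red) {
      nr <- if (counting_mode == "walks") {
        nodal_redundancy_all(A, max_length)
      } else {
        M <- redundancy_counts(redundancy_matrix(A, max_length, counting_mode))
        rowSums(M)
      }
      if ("nodal_redundancy" %in% metrics)
        out$nodal <- tibble::tibble(metric = "nodal_redundancy", node = ids, value = unname(nr))
      if ("roi_redundancy" %in% metrics)
        out$roi <- tibble::tibble(metric = "roi_redundancy", node = ids,
                                  value = unname(nr) / (n - 1))
    }
    if ("degree" %in% metrics)
      out$deg <- tibble::tibble(metric = "degree", node = ids, value = rowSums(A))
    if ("global_efficiency" %in% metrics)
      out$eff <- tibble::tibble(metric = "global_efficiency", node = NA_character_,
                                value = global_efficiency(A))
    dplyr::bind_rows(out) |> dplyr::mutate(density = d, .before = 1)
  })
  tbl <- dplyr::bind_rows(rows) |>
    dplyr::mutate(subject_id = subj, .before = 1)
  if (!is.null(rois))
    tbl <- dplyr::filter(tbl, is.na(.data$node) | .data$node %in% rois |
                           .data$metric == "nodal_redundancy")
  tbl
}

#' Average metrics across densities
#'
#' Arithmetic mean of each metric over the density grid, the granularity at
#' which the group comparisons, ratio sets and regressions operate.
#'
#' @param metric_tbl Long tibble from [metrics_over_stack()] (one or many
#'   subjects bound together).
#' @return A tibble with columns `subject_id`, `metric`, `node`, `value`
#'   (mean over densities) and `n_densities`.
#' @export
average_densities <- function(metric_tbl) {
  metric_tbl |>
    dplyr::group_by(.data$subject_id, .data$metric, .data$node) |>
    dplyr::summarise(value = mean(.data$value),
                     n_densities = dplyr::n(), .groups = "drop")
}
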