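# Redundancy, degree and global efficiency against closed forms, hand
# computations, and exhaustive enumeration oracles.

test_that("walk counts match closed forms and hand enumeration", {
  K4 <- complete_graph(4)
  wc <- walk_counts(K4, 4)
  # K_n off-diagonal walk counts: ((n-1)^l - (-1)^l) / n, here n = 4
  for (l in 1:4) {
    expect_equal(wc[[l]][1, 2], (3^l - (-1)^l) / 4)
  }
  expect_equal(wc[[2]][1, 2], 2)

  P3 <- path_graph(3)
  expect_equal(walk_counts(P3, 2)[[2]][1, 3], 1)

  empty <- matrix(0, 4, 4)
  for (l in 1:4) expect_true(all(walk_counts(empty, 4)[[l]] == 0))
})

test_that("walk_counts validates its input", {
  A <- matrix(c(0, 2, 2, 0), 2, 2)
  expect_error(walk_counts(A), class = "redunet_validation_error")
  B <- matrix(c(0, 1, 0, 0), 2, 2)
  expect_error(walk_counts(B), class = "redunet_validation_error")
  C <- diag(2)
  expect_error(walk_counts(C), class = "redunet_validation_error")
})

test_that("redundancy matches K4 closed forms in both counting modes", {
  K4 <- complete_graph(4)
  Rw <- redundancy_matrix(K4, 4, "walks")
  expect_equal(Rw$counts[1, 2], 1 + 2 + 7 + 20)  # 30
  expect_true(all(Rw$counts[upper.tri(Rw$counts)] == 30))
  Rs <- redundancy_matrix(K4, 4, "simple_paths")
  expect_equal(Rs$counts[1, 2], 1 + 2 + 2 + 0)   # 5
  expect_equal(roi_redundancy(Rw, 1), 30)
  expect_equal(nodal_redundancy(Rw, 1), 90)
})

test_that("redundancy of disconnected pair and empty graph is zero", {
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 1] <- 1
  R <- redundancy_matrix(A, 4)
  expect_equal(R$counts[3, 4], 0)
  expect_equal(roi_redundancy(redundancy_matrix(matrix(0, 4, 4), 4), 1), 0)
})

test_that("star graph hand computation: center-leaf redundancy at L = 2", {
  S4 <- star_graph(4)       # center is node 1
  R <- redundancy_matrix(S4, 2, "walks")
  # (A^2)[center, leaf] = 0, so R(center, leaf) = adjacency only
  expect_true(all(R$counts[1, -1] == 1))
  expect_equal(roi_redundancy(R, 1), 1)
})

test_that("walks and simple-path modes match exhaustive enumeration oracles", {
  set.seed(42)
  n_graphs <- 60
  for (g in seq_len(n_graphs)) {
    n <- sample(4:7, 1)
    A <- random_graph(n, p = runif(1, 0.2, 0.8))
    L <- sample(1:4, 1)
    wc <- walk_counts(A, L)
    sc <- simple_path_counts(A, L)
    i <- sample(n, 1); j <- sample(setdiff(seq_len(n), i), 1)
    for (l in seq_len(L)) {
      expect_equal(wc[[l]][i, j], oracle_count_walks(A, i, j, l))
      expect_equal(sc[[l]][i, j], oracle_count_simple_paths(A, i, j, l))
    }
  }
})

test_that("redundancy matrices are symmetric with zero diagonal", {
  set.seed(7)
  for (rep in 1:10) {
    A <- random_graph(8, 0.5)
    for (mode in c("walks", "simple_paths")) {
      R <- redundancy_matrix(A, 4, mode)$counts
      expect_equal(R, t(R))
      expect_true(all(diag(R) == 0))
      expect_true(all(R >= A))            # length-1 term included
      expect_true(all(R == round(R)))     # exact integer counts
    }
  }
})

test_that("degree equals the length-1 redundancy term and sums to 2|E|", {
  set.seed(9)
  for (rep in 1:10) {
    A <- random_graph(10, 0.4)
    expect_equal(node_degree(A), walk_counts(A, 1)[[1]] %*% rep(1, 10) |> as.numeric() |> setNames(NULL))
    expect_equal(sum(node_degree(A)), sum(A))
  }
  expect_equal(node_degree(complete_graph(4), 1), 3)
  A <- matrix(0, 3, 3); A[1, 2] <- A[2, 1] <- 1
  expect_equal(node_degree(A, 3), 0)
})

test_that("global efficiency matches hand values and the Floyd-Warshall oracle", {
  expect_equal(global_efficiency(complete_graph(5)), 1)
  expect_equal(global_efficiency(path_graph(3)), 5 / 6)
  # isolated node: strictly below 1, finite
  A <- complete_graph(4); A[4, ] <- A[, 4] <- 0
  e <- global_efficiency(A)
  expect_lt(e, 1)
  expect_true(is.finite(e))
  expect_error(global_efficiency(matrix(0, 1, 1)), class = "redunet_validation_error")
  set.seed(21)
  for (rep in 1:20) {
    A <- random_graph(sample(4:9, 1), runif(1, 0.15, 0.7))
    expect_equal(global_efficiency(A), oracle_global_efficiency(A))
  }
})

test_that("fast all-node nodal redundancy equals the full-matrix route", {
  set.seed(33)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    A <- random_graph(n, runif(1, 0.1, 0.8))
    L <- sample(1:4, 1)
    full <- rowSums(redundancy_matrix(A, L, "walks")$counts)
    fast <- redunet:::nodal_redundancy_all(A, L)
    expect_equal(unname(fast), unname(full))
  }
})

test_that("metrics_over_stack aggregates correctly and averages are means", {
  set.seed(5)
  z <- correlation_matrix(matrix(rnorm(60 * 12), 60, 12))
  stk <- density_stack(z, grid = c(0.1, 0.2, 0.3))
  tbl <- metrics_over_stack(stk)
  # single node, single density: cross-check against direct computation
  A2 <- stk$adjacencies[[2]]
  R2 <- redundancy_matrix(A2, 4)
  got <- tbl$value[tbl$density == 0.2 & tbl$metric == "roi_redundancy" &
                     tbl$node == "ROI005"]
  expect_equal(got, roi_redundancy(R2, "ROI005"), ignore_attr = TRUE)
  expect_equal(tbl$value[tbl$density == 0.2 & tbl$metric == "global_efficiency"],
               global_efficiency(A2), ignore_attr = TRUE)
  # nodal = (n-1) * roi redundancy
  wide <- tidyr::pivot_wider(tbl[!is.na(tbl$node), ],
                             names_from = "metric", values_from = "value")
  expect_equal(wide$nodal_redundancy, wide$roi_redundancy * 11)
  # averaged value equals the arithmetic mean of per-density values
  avg <- average_densities(tbl)
  one <- avg$value[avg$metric == "roi_redundancy" & avg$node == "ROI003"]
  per <- tbl$value[tbl$metric == "roi_redundancy" & tbl$node == "ROI003"]
  expect_equal(one, mean(per))
  expect_true(all(avg$n_densities == 3))
})

test_that("redundancy and degree are monotone in density; labels equivariant", {
  set.seed(88)
  z <- correlation_matrix(matrix(rnorm(50 * 10), 50, 10))
  stk <- density_stack(z, grid = c(0.1, 0.2, 0.4))
  tbl <- metrics_over_stack(stk)
  for (m in c("roi_redundancy", "degree")) {
    by_node <- split(tbl[tbl$metric == m, ], tbl$node[tbl$metric == m])
    for (d in by_node) expect_true(all(diff(d$value[order(d$density)]) >= 0))
  }
  # permuting node labels permutes per-node outputs identically
  A <- stk$adjacencies[[2]]
  perm <- sample(10)
  Ap <- A[perm, perm]
  expect_equal(unname(redunet:::nodal_redundancy_all(Ap, 4)),
               unname(redunet:::nodal_redundancy_all(A, 4)[perm]))
})

test_that("simple-path counting refuses oversized graphs", {
  A <- matrix(0, 501, 501)
  expect_error(simple_path_counts(A), class = "redunet_resource_error")
})
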