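# Fisher-z correlation, density binarization, band-pass filtering, motion
# exclusion and overall-connectivity controls.

test_that("correlation matrix applies the Fisher z transform", {
  set.seed(1)
  n <- 2000
  x <- rnorm(n)
  y <- 0.5 * x + sqrt(1 - 0.25) * rnorm(n)
  ts <- cbind(a = x, b = y, c = rnorm(n))
  cm <- correlation_matrix(ts)
  r <- cor(x, y)
  expect_equal(cm$values["a", "b"], atanh(r))
  expect_equal(cm$values, t(cm$values))
  expect_true(all(diag(cm$values) == 0))
  # closed form: r = 0.5 -> z ~ 0.5493
  expect_equal(atanh(0.5), 0.549306, tolerance = 1e-6)
})

test_that("degenerate inputs are caught or clipped", {
  ts <- matrix(rnorm(20), 10, 2)
  expect_error(correlation_matrix(ts[1:2, ]), class = "redunet_validation_error")
  ts_const <- cbind(a = rnorm(10), b = rep(1, 10))
  expect_error(correlation_matrix(ts_const), regexp = "b")
  # duplicated column: clipped to finite z with a warning
  dup <- cbind(a = rnorm(30), b = rnorm(30))
  dup <- cbind(dup, c = dup[, 1])
  expect_warning(cm <- correlation_matrix(dup), regexp = "clipped")
  expect_true(all(is.finite(cm$values)))
  expect_equal(cm$values[1, 3], atanh(1 - 1e-7))
})

test_that("binarization retains exactly round(density * n(n-1)/2) edges", {
  set.seed(2)
  z <- correlation_matrix(matrix(rnorm(40 * 5), 40, 5))
  A <- binarize_at_density(z, 0.2)
  expect_equal(sum(A) / 2, 2)   # round(0.2 * 10)
  # the retained edges are the two largest z values
  vals <- z$values
  up <- which(upper.tri(vals))
  top2 <- sort(vals[up], decreasing = TRUE)[1:2]
  expect_setequal(vals[A == 1 & upper.tri(vals)], top2)
  expect_equal(binarize_at_density(z, 1), complete_graph(5), ignore_attr = TRUE)
  expect_error(binarize_at_density(z, 0.001), class = "redunet_config_error")
})

test_that("ties break by ascending (i, j) lexicographic order", {
  m <- matrix(1, 5, 5); diag(m) <- 0
  A <- binarize_at_density(m, 0.2)
  expect_equal(which(A[1, ] == 1), c(2, 3))
  expect_equal(sum(A) / 2, 2)
})

test_that("edge counts are exact and stacks nested on random matrices", {
  set.seed(3)
  grid <- density_grid()
  for (rep in 1:25) {
    n <- sample(10:25, 1)
    m <- matrix(rnorm(n * n), n, n)
    m <- (m + t(m)) / 2; diag(m) <- 0
    stk <- density_stack(m, grid)
    counts <- vapply(stk$adjacencies, function(A) sum(A) / 2, numeric(1))
    expect_equal(counts, round(grid * n * (n - 1) / 2))
    expect_true(all(diff(counts) > 0))
    for (k in seq_along(grid)[-1]) {
      expect_true(all(stk$adjacencies[[k - 1]] <= stk$adjacencies[[k]]))
    }
  }
})

test_that("binarizing on z equals binarizing on raw r (monotone transform)", {
  set.seed(4)
  ts <- matrix(rnorm(60 * 8), 60, 8)
  r <- cor(ts); diag(r) <- 0
  z <- correlation_matrix(ts)
  expect_equal(binarize_at_density(z, 0.2), binarize_at_density(r, 0.2),
               ignore_attr = TRUE)
})

test_that("binarization is equivariant under node relabeling", {
  set.seed(6)
  n <- 12
  m <- matrix(rnorm(n * n), n, n); m <- (m + t(m)) / 2; diag(m) <- 0
  # perturb to remove ties so the tie-break never enters
  A <- binarize_at_density(m, 0.2)
  for (rep in 1:5) {
    perm <- sample(n)
    expect_equal(unname(binarize_at_density(m[perm, perm], 0.2)),
                 unname(A[perm, perm]))
  }
})

test_that("band-pass keeps in-band power, removes DC and slow drift", {
  tr <- 3
  t <- seq(0, by = tr, length.out = 1200)
  inband <- sin(2 * pi * 0.05 * t)
  slow <- sin(2 * pi * 0.005 * t)
  const <- rep(5, length(t))
  ts <- cbind(inband = inband, slow = slow, const = const)
  filt <- bandpass_filter(ts, tr_seconds = tr)
  expect_lt(max(abs(filt[, "const"])), 1e-8)
  expect_gte(var(filt[, "inband"]) / var(inband), 0.9)
  expect_lte(var(filt[, "slow"]) / var(slow), 0.1)
  expect_error(bandpass_filter(ts, tr_seconds = 3, high_hz = 0.2),
               class = "redunet_config_error")
})

test_that("motion exclusion uses a strict threshold and censors volumes", {
  cfg <- tiny_cohort_config(seed = 15)
  co <- generate_cohort(cfg)
  nv <- cfg$n_volumes
  ids <- co$subjects$subject_id
  co$outlier_flags[[ids[1]]] <- rep(FALSE, nv)                      # clean
  co$outlier_flags[[ids[2]]] <- rep(c(TRUE, FALSE), nv / 2)         # exactly 50%
  co$outlier_flags[[ids[3]]] <- c(rep(TRUE, nv / 2 + 1),
                                  rep(FALSE, nv / 2 - 1))           # just over
  res <- suppressMessages(exclude_high_motion(co))
  expect_false(ids[1] %in% res$excluded)
  expect_false(ids[2] %in% res$excluded)   # exactly 50% retained
  expect_true(ids[3] %in% res$excluded)
  expect_equal(res$kept$timeseries[[ids[1]]], co$timeseries[[ids[1]]])
  expect_equal(nrow(res$kept$timeseries[[ids[2]]]), nv / 2)
  expect_false(ids[3] %in% names(res$kept$timeseries))
  expect_equal(nrow(res$kept$subjects), nrow(co$subjects) - 1)
})

test_that("overall connectivity modes behave per contract", {
  vals <- matrix(0, 3, 3)
  vals[1, 2] <- vals[2, 1] <- 0.4
  vals[1, 3] <- vals[3, 1] <- -0.4
  expect_equal(overall_connectivity(vals, 1, "absolute"), 0.4)
  expect_equal(overall_connectivity(vals, 1, "positive_only"), 0.4)
  all_pos <- abs(vals)
  expect_equal(overall_connectivity(all_pos, 1, "positive_only"),
               mean(all_pos[1, -1]))
  neg <- -abs(vals)
  expect_warning(v <- overall_connectivity(neg, 1, "positive_only"),
                 regexp = "no positive")
  expect_equal(v, 0)
})
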