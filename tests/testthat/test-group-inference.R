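# Permutation ANCOVA, post hocs with BH adjustment, Cohen's d, and the
# parametric ANOVA + Tukey path.

make_groups <- function(n_per = 15, shift = c(0, 0, 0), seed = 1) {
  set.seed(seed)
  data.frame(
    y = rnorm(3 * n_per) + rep(shift, each = n_per),
    group = rep(c("a", "b", "c"), each = n_per),
    cov1 = rnorm(3 * n_per))
}

test_that("permutation ANCOVA matches the parametric F and is deterministic", {
  d <- make_groups(shift = c(0, 1, 2), seed = 5)
  pt <- permutation_ancova(d, y ~ group + cov1, n_permutations = 500, seed = 9)
  # observed statistic equals the classical ANCOVA F for the group term
  full <- lm(y ~ group + cov1, data = d)
  red <- lm(y ~ cov1, data = d)
  f_ref <- anova(red, full)$F[2]
  expect_equal(pt$statistic, f_ref)
  expect_identical(pt$df, c(df1 = 2L, df2 = 41L))
  # determinism
  pt2 <- permutation_ancova(d, y ~ group + cov1, n_permutations = 500, seed = 9)
  expect_identical(pt$p_value, pt2$p_value)
  # tidy/glance
  expect_equal(tidy(pt)$p.value, pt$p_value)
  expect_equal(glance(pt)$n_permutations, 500L)
})

test_that("huge effects give the minimum attainable p-value", {
  d <- make_groups(n_per = 20, shift = c(0, 3, 6), seed = 2)
  d$y <- d$y * 0.3 + rep(c(0, 3, 6), each = 20)   # d >> 3
  pt <- permutation_ancova(d, y ~ group, n_permutations = 400, seed = 1)
  expect_equal(pt$p_value, 1 / 401)
})

test_that("permutation p-values are never zero nor below 1/(m+1)", {
  d <- make_groups(seed = 3)
  for (s in 1:5) {
    pt <- permutation_ancova(d, y ~ group, n_permutations = 99, seed = s)
    expect_gte(pt$p_value, 1 / 100)
    expect_lte(pt$p_value, 1)
  }
})

test_that("observed F is invariant to joint row reordering", {
  d <- make_groups(shift = c(0, 0.5, 1), seed = 7)
  perm <- sample(nrow(d))
  pt1 <- permutation_ancova(d, y ~ group + cov1, n_permutations = 200, seed = 4)
  pt2 <- permutation_ancova(d[perm, ], y ~ group + cov1, n_permutations = 200, seed = 4)
  expect_equal(pt1$statistic, pt2$statistic)
  expect_identical(pt1$df, pt2$df)
})

test_that("degenerate inputs error cleanly", {
  d <- make_groups()
  d0 <- d; d0$y <- 1
  expect_error(permutation_ancova(d0, y ~ group), class = "redunet_validation_error")
  d1 <- d[c(1, 16:45), ]   # group "a" has a single subject
  expect_error(permutation_ancova(d1, y ~ group), regexp = "fewer than 2")
})

test_that("type-I error of the permutation ANCOVA is near nominal", {
  set.seed(61)
  n_rep <- 200
  rej <- logical(n_rep)
  base <- make_groups(n_per = 12)
  for (r in seq_len(n_rep)) {
    base$y <- rnorm(nrow(base)) + 0.5 * base$cov1
    pt <- permutation_ancova(base, y ~ group + cov1, n_permutations = 200,
                             seed = r)
    rej[r] <- pt$p_value < 0.05
  }
  # binomial 99% bounds around 0.05 for 200 replicates: ~[0.013, 0.095]
  expect_gt(mean(rej), 0.012)
  expect_lt(mean(rej), 0.10)
})

test_that("Cohen's d matches hand arithmetic and flips sign on swap", {
  es <- cohens_d(c(0, 1, 2), c(1, 2, 3))
  expect_equal(es$estimate, -1)          # pooled SD = 1
  expect_equal(cohens_d(c(1, 2, 3), c(0, 1, 2))$estimate, 1)
  expect_true(es$ci_low <= es$estimate && es$estimate <= es$ci_high)
  same <- cohens_d(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$estimate, 0)
  expect_true(same$ci_low < 0 && same$ci_high > 0)
  expect_error(cohens_d(c(1, 1), c(1, 1)), class = "redunet_validation_error")
  expect_error(cohens_d(1, c(1, 2)), class = "redunet_validation_error")
})

test_that("pairwise post hocs apply BH and the covariate policy", {
  d <- make_groups(n_per = 14, shift = c(0, 1.2, 1.2), seed = 11)
  res <- pairwise_posthoc(d, "y", "group",
                          covariate_policy = list(`b:c` = "cov1"),
                          n_permutations = 300, seed = 8)
  expect_equal(nrow(res), 3)
  expect_equal(res$p_adjusted, p.adjust(res$p_value, "BH"))
  expect_equal(res$covariates[res$pair == "b:c"], "cov1")
  expect_equal(res$covariates[res$pair == "a:b"], "")
  # covariate changes the residual df for that pair only
  expect_equal(res$df2[res$pair == "b:c"], res$df2[res$pair == "a:b"] - 1)
  # d sign: first group minus second
  expect_lt(res$cohens_d[res$pair == "a:b"], 0)
})

test_that("BH adjustment reproduces the hand-computed example", {
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "BH"), c(0.03, 0.03, 0.04))
})

test_that("anova_tukey: k = 2 equals the t-test; constructed 3-group case", {
  d <- make_groups(n_per = 12, seed = 13)
  two <- d[d$group != "c", ]
  at <- anova_tukey(two, y ~ group)
  tt <- t.test(y ~ group, data = two, var.equal = TRUE)
  expect_equal(at$pairwise$p_adjusted, tt$p.value, tolerance = 1e-10)
  # one group shifted far away: its two contrasts significant, third not
  d3 <- make_groups(n_per = 12, shift = c(0, 0, 5), seed = 14)
  at3 <- anova_tukey(d3, y ~ group)
  expect_lt(at3$omnibus$p_value, 0.001)
  pw <- at3$pairwise
  expect_lt(pw$p_adjusted[pw$pair == "c-a"], 0.001)
  expect_lt(pw$p_adjusted[pw$pair == "c-b"], 0.001)
  expect_gt(pw$p_adjusted[pw$pair == "b-a"], 0.05)
  expect_equal(nrow(tidy(at3)), 4)
})
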