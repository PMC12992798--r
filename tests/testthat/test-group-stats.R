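# Group-statistics layer: ANOVA/MANOVA against brute-force oracles, rank
# correlations, effect-size conversions, power approximations, corrections,
# and the cluster permutation test.

test_that("one-way ANOVA matches a direct sums-of-squares computation", {
  vals <- c(24, 26, 27, 31, 29, 33, 35, 34, 30, 28, 21, 20, 25, 23, 22)
  grp <- rep(c("a", "b", "c"), each = 5)
  ts <- anova_oneway(vals, grp)
  # brute-force oracle
  gm <- mean(vals)
  ssb <- sum(tapply(vals, grp, function(x) length(x) * (mean(x) - gm)^2))
  ssw <- sum(unlist(tapply(vals, grp, function(x) (x - mean(x))^2)))
  f_ref <- (ssb / 2) / (ssw / 12)
  expect_equal(ts$statistic, f_ref, tolerance = 1e-8)
  expect_equal(ts$df, c(2, 12))
  expect_equal(ts$p, pf(f_ref, 2, 12, lower.tail = FALSE), tolerance = 1e-8)

  set.seed(1)
  same <- anova_oneway(rnorm(60), rep(c("a", "b"), 30))
  expect_gt(same$p, 0.05)
  expect_error(anova_oneway(rep(1, 10), rep(c("a", "b"), 5)),
               class = "mertopo_config_error")
})

test_that("two-way Type-II ANOVA matches the balanced-design oracle and isolates effects", {
  set.seed(3)
  n <- 40
  A <- rep(c("x", "y"), each = n / 2)
  B <- rep(c("u", "v"), times = n / 2)
  y <- rnorm(n) + ifelse(B == "v", 1.5, 0)
  res <- anova_twoway(y, A, B)
  # balanced design: Type II equals classical sequential sums of squares
  ref <- anova(lm(y ~ factor(A) * factor(B)))
  expect_equal(res$factorA$statistic, ref$`F value`[1], tolerance = 1e-8)
  expect_equal(res$factorB$statistic, ref$`F value`[2], tolerance = 1e-8)
  expect_equal(res$interaction$statistic, ref$`F value`[3], tolerance = 1e-8)

  # injected main effect only in B: interaction stays null in >= 9/10 runs
  set.seed(17)
  null_int <- vapply(1:10, function(i) {
    y2 <- rnorm(n) + ifelse(B == "v", 1.5, 0)
    anova_twoway(y2, A, B)$interaction$p > 0.05
  }, logical(1))
  expect_gte(sum(null_int), 9)
})

test_that("MANOVA Wilks lambda matches the scatter-matrix oracle", {
  set.seed(5)
  n <- 30
  g <- rep(c("a", "b", "c"), each = n)
  X <- matrix(rnorm(3 * n * 3), ncol = 3)
  X[g == "c", 3] <- X[g == "c", 3] + 3  # groups separated on z only
  ts <- manova_groups(X, g)

  # brute force: W and B scatter matrices
  gm <- colMeans(X)
  W <- matrix(0, 3, 3); B <- matrix(0, 3, 3)
  for (lev in unique(g)) {
    Xi <- X[g == lev, , drop = FALSE]
    ci <- colMeans(Xi)
    W <- W + crossprod(sweep(Xi, 2, ci))
    B <- B + nrow(Xi) * tcrossprod(ci - gm)
  }
  expect_equal(ts$statistic, det(W) / det(W + B), tolerance = 1e-8)
  expect_lt(ts$statistic, 0.5)
  expect_lt(ts$p, 0.001)

  # same data relabelled evenly: lambda near 1
  set.seed(6)
  ts_null <- manova_groups(matrix(rnorm(270), ncol = 3), g)
  expect_gt(ts_null$statistic, 0.9)
})

test_that("Spearman correlation handles monotone data and ties exactly", {
  expect_equal(spearman_cor(1:10, (1:10)^3)$statistic, 1)
  expect_equal(spearman_cor(1:10, rev(1:10))$statistic, -1)

  x <- c(1, 2, 2, 3, 4, 4, 4, 5)
  y <- c(2, 1, 3, 3, 5, 4, 6, 7)
  # brute-force oracle: Pearson correlation of average ranks
  rho_ref <- cor(rank(x), rank(y))
  expect_equal(spearman_cor(x, y)$statistic, rho_ref, tolerance = 1e-12)

  expect_error(spearman_cor(rep(1, 5), 1:5), class = "mertopo_config_error")
  # Bonferroni multiplication, capped at 1
  set.seed(4)
  xx <- 1:20 + rnorm(20, sd = 6)
  s1 <- spearman_cor(xx, 1:20)
  s2 <- spearman_cor(xx, 1:20, n_comparisons = 4)
  expect_equal(s2$p, min(1, 4 * s1$p))
})

test_that("effect-size conversions reproduce printed statistic pairs", {
  expect_equal(round(d_from_r(0.278), 2), 0.58)
  expect_equal(round(d_from_r(0.322), 2), 0.68)
  expect_equal(round(d_from_r(0.363), 2), 0.78)
  expect_equal(d_from_r(0), 0)
  expect_error(d_from_r(1), class = "mertopo_config_error")

  expect_equal(round(d_from_f(21.27, 1, 579), 3), 0.383)
  expect_equal(round(d_from_f(68.85, 2, 527), 2), 1.02)
  expect_equal(round(d_from_f(54.95, 1, 580), 2), 0.62)
  expect_equal(round(d_from_f(10.77, 1, 579), 2), 0.27)
  expect_equal(round(d_from_wilks(0.71, 3, 3), 2), 0.86)
})

test_that("power approximations behave correctly and saturate", {
  expect_equal(power_correlation(0, 100, 0.05), 0.05, tolerance = 1e-10)
  expect_gt(power_correlation(0.9, 100), 0.9999)
  expect_equal(power_two_sample(0, 50, 50), 0.05, tolerance = 1e-10)
  # monotone in effect size and n
  expect_true(all(diff(sapply(c(0.1, 0.3, 0.5), power_two_sample,
                              n1 = 40, n2 = 40)) > 0))
  expect_true(all(diff(sapply(c(20, 60, 200), function(n)
    power_two_sample(0.3, n, n))) > 0))
  expect_error(power_correlation(0.5, 3), class = "mertopo_config_error")
})

test_that("multiple-comparison corrections follow the standard rules", {
  expect_equal(bonferroni(c(0.01, 0.04), m = 4), c(0.04, 0.16))
  expect_equal(bonferroni(0.6, m = 3), 1)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.03), 0.03)
  # monotonicity
  set.seed(9)
  p <- sort(runif(20))
  expect_true(all(diff(bh_fdr(p)[order(p)]) >= -1e-12))
  expect_true(all(diff(bonferroni(p, 20)) >= 0))
})

test_that("two-sample Cohen's d matches its definition and large-sample value", {
  expect_equal(cohen_d_two_sample(c(1, 2, 3), c(2, 3, 1)), 0)
  expect_error(cohen_d_two_sample(c(0, 0), c(1, 1)), class = "mertopo_config_error")
  set.seed(13)
  expect_equal(cohen_d_two_sample(rnorm(1e5), rnorm(1e5, 1)), 1,
               tolerance = 0.02)
})

test_that("cluster permutation test finds injected differences and not null ones", {
  grid <- seq(6, 0, by = -0.3)
  set.seed(31)
  A <- matrix(rnorm(30 * length(grid), 1, 0.3), nrow = 30)
  # identical groups: no significant clusters
  same <- cluster_permutation_test(A, A, grid, n_perm = 500, seed = 1)
  expect_false(any(same$clusters$significant))

  # offset injected only on depths [3.6, 1.2]
  B <- A + 2 * outer(rep(1, 30), as.numeric(grid <= 3.6 & grid >= 1.2))
  res <- cluster_permutation_test(A, B, grid, n_perm = 1000, seed = 2)
  sig <- res$clusters[res$clusters$significant, ]
  expect_gte(nrow(sig), 1)
  main <- sig[which.max(sig$mass), ]
  covered <- grid[grid <= main$depth_start & grid >= main$depth_end]
  injected <- grid[grid <= 3.6 & grid >= 1.2]
  expect_gte(length(intersect(covered, injected)) / length(injected), 0.8)
})

test_that("paired cluster mode flips pair differences", {
  grid <- seq(4, 0, by = -0.5)
  set.seed(41)
  A <- matrix(rnorm(20 * length(grid)), nrow = 20)
  B <- A + matrix(rnorm(20 * length(grid), 0, 0.1), nrow = 20) + 1
  res <- cluster_permutation_test(A, B, grid, n_perm = 500, seed = 3,
                                  paired = TRUE)
  expect_true(any(res$clusters$significant))
  expect_error(cluster_permutation_test(A, B[1:10, ], grid, paired = TRUE),
               class = "mertopo_config_error")
})
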