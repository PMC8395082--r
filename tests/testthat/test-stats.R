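test_that("rank-sum test: degenerate, exact and asymptotic behaviour", {
  expect_equal(ranksum_test(c(2, 2, 2), c(2, 2))$p_value, 1)
  expect_equal(ranksum_test(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  # exact two-sided p for complete separation of 3 vs 3: 2/20
  r <- ranksum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)
  expect_match(r$method, "exact")
  # strongly shifted large samples
  set.seed(91)
  big <- ranksum_test(rnorm(200), rnorm(200, 1))
  expect_lt(big$p_value, 1e-6)
  expect_match(big$method, "normal")
})

test_that("rank-sum exact p matches full enumeration of rank assignments", {
  # oracle: enumerate all C(7,3) splits of the pooled ranks
  x <- c(1.2, 3.4, 7.7); y <- c(2.1, 5.5, 8.8, 9.9)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[1:3]) - 3 * 4 / 2  # Mann-Whitney U of x
  combos <- combn(7, 3)
  u_null <- apply(combos, 2, function(i) sum(r[i]) - 6)
  mu <- 3 * 4 / 2
  p_exact <- mean(abs(u_null - mu) >= abs(w_obs - mu) - 1e-12)
  expect_equal(ranksum_test(x, y)$p_value, p_exact)
})

test_that("rank-sum p is invariant under strictly monotone transforms", {
  set.seed(92)
  x <- runif(10, 1, 5); y <- runif(12, 2, 6)
  p0 <- ranksum_test(x, y)$p_value
  expect_equal(ranksum_test(exp(x), exp(y))$p_value, p0)
  expect_equal(ranksum_test(log(x), log(y))$p_value, p0)
})

test_that("Kruskal-Wallis H matches the hand-computed rank formula", {
  g <- list(a = c(1, 2), b = c(3, 4), c = c(5, 6))
  k <- kruskal_wallis(g)
  # ranks 1..6; H = 12/(6*7) * sum n_i (Rbar_i - 3.5)^2 = 32/7
  expect_equal(k$statistic, 32 / 7, tolerance = 1e-12)
  expect_equal(k$p_value, pchisq(32 / 7, df = 2, lower.tail = FALSE))
  same <- kruskal_wallis(list(a = 1:3, b = 1:3, c = 1:3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  expect_error(kruskal_wallis(list(a = 1, b = 2)), ">= 3 groups")
  expect_error(kruskal_wallis(list(a = 1, b = 2, c = numeric(0))),
               "empty")
})

test_that("Kruskal-Wallis p-values are approximately uniform under the null", {
  set.seed(93)
  ps <- replicate(400, {
    kruskal_wallis(list(rnorm(10), rnorm(10), rnorm(10)))$p_value
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("DSCF Monte-Carlo: identical groups give p near 1, seeds reproduce", {
  g <- list(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), c = c(1, 2, 3, 4))
  r <- dscf_montecarlo(g, n_iter = 500, seed = 1)
  expect_true(all(r$pairwise$p_value > 0.5))
  r2 <- dscf_montecarlo(g, n_iter = 500, seed = 1)
  expect_identical(r$pairwise, r2$pairwise)
  expect_true(all(r$pairwise$p_value >= 1 / 501))
})

test_that("DSCF Monte-Carlo p matches exhaustive permutation on (2,2,2) groups", {
  g <- list(a = c(1.1, 2.3), b = c(3.2, 4.9), c = c(5.5, 6.1))
  pooled <- unlist(g)
  prs <- combn(3, 2)
  stat_max <- function(lab) {
    max(abs(dtctrack:::pairwise_dscf_stats(pooled, lab, 3, prs)))
  }
  obs <- abs(dtctrack:::pairwise_dscf_stats(
    pooled, rep(1:3, each = 2), 3, prs))
  # enumerate all 90 distinct partitions of six values into groups of two
  all_orders <- combn(6, 2, simplify = FALSE)
  null_max <- c()
  for (i1 in all_orders) {
    rest <- setdiff(1:6, i1)
    for (i2 in combn(rest, 2, simplify = FALSE)) {
      lab <- integer(6)
      lab[i1] <- 1L; lab[i2] <- 2L; lab[setdiff(rest, i2)] <- 3L
      null_max <- c(null_max, stat_max(lab))
    }
  }
  expect_length(null_max, 90)
  p_exact <- vapply(obs, function(t0) mean(null_max >= t0 - 1e-12),
                    numeric(1))
  mc <- dscf_montecarlo(g, n_iter = 10000, seed = 2)
  expect_lt(max(abs(mc$pairwise$p_value - p_exact)), 0.02)
})

test_that("DSCF adjusted p dominates the unadjusted pairwise rank-sum p", {
  set.seed(94)
  g <- list(a = rnorm(8), b = rnorm(8, 1), c = rnorm(8, 2))
  r <- dscf_montecarlo(g, n_iter = 4000, seed = 3)
  for (k in seq_len(nrow(r$pairwise))) {
    un <- ranksum_test(g[[r$pairwise$group1[k]]],
                       g[[r$pairwise$group2[k]]])$p_value
    expect_gte(r$pairwise$p_value[k], un - 0.02)
  }
  expect_true(all(r$pairwise$p_value >= 0 & r$pairwise$p_value <= 1))
})

test_that("group helpers accept data frames and summarize boxplot elements", {
  df <- data.frame(group = rep(c("a", "b", "c"), each = 4),
                   value = c(1:4, 3:6, 10:13))
  k <- kruskal_wallis(df)
  expect_s3_class(k, "dtc_test")
  s <- group_summary(df)
  expect_equal(s$group, c("a", "b", "c"))
  expect_equal(s$median[1], 2.5)
  expect_equal(s$q1[3], quantile(10:13, 0.25, names = FALSE))
  expect_true(all(s$n == 4))
})
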