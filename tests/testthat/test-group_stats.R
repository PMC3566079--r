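# Robust heteroscedastic group statistics.

test_that("trimmed statistics follow the floor rule", {
  ts <- trimmed_stats(1:10, 0.15)
  expect_equal(ts$g, 1)
  expect_equal(ts$tmean, mean(2:9))
  expect_equal(ts$h, 8)

  # symmetric sample: trimmed mean equals the untrimmed mean
  x <- c(-3, -1, 0, 1, 3)
  expect_equal(trimmed_stats(x, 0.2)$tmean, mean(x))

  # trim 0: ordinary mean and variance
  set.seed(1); y <- rnorm(12)
  t0 <- trimmed_stats(y, 0)
  expect_equal(t0$tmean, mean(y))
  expect_equal(t0$wvar, var(y))
  expect_equal(t0$h, 12)

  expect_error(trimmed_stats(1:3, 0.15), "at least 4")
  expect_error(trimmed_stats(1:10, 0.3), "0.25")
})

test_that("the Welch-Yuen omnibus has nu1 = k - 1 and the Welch t^2 limit", {
  set.seed(2)
  g4 <- list(rnorm(7), rnorm(6, 1), rnorm(7, 2, 2), rnorm(6, 0, 3))
  o <- wy_omnibus(g4, 0.15)
  expect_equal(o$nu1, 3)
  expect_gt(o$nu2, 0)
  expect_true(o$p >= 0 && o$p <= 1)

  a <- rnorm(9); b <- rnorm(11, 0.8, 2)
  o2 <- wy_omnibus(list(a, b), trim = 0)
  w <- t.test(a, b)
  expect_equal(o2$Ft, unname(w$statistic)^2, tolerance = 1e-9)
  expect_equal(o2$nu2, unname(w$parameter), tolerance = 1e-9)

  # invariance to group order and joint affine transforms
  o3 <- wy_omnibus(rev(g4), 0.15)
  expect_equal(o3$Ft, o$Ft, tolerance = 1e-12)
  o4 <- wy_omnibus(lapply(g4, function(x) 3 * x - 7), 0.15)
  expect_equal(o4$Ft, o$Ft, tolerance = 1e-9)

  expect_error(wy_omnibus(list(c(1, 1, 1, 1, 1), rnorm(5))), "winsorized")
})

test_that("pairwise comparisons cover all pairs with familywise control", {
  set.seed(3)
  g4 <- list(A = rnorm(7), B = rnorm(6), C = rnorm(7), D = rnorm(6))
  pw <- pairwise_t3(g4, trim = 0.15, nsim = 5000)
  expect_equal(nrow(pw), 6)
  expect_true(all(pw$p_adj >= pw$p_raw - 1e-12))
  expect_true(all(pw$ci_lo <= pw$diff & pw$diff <= pw$ci_hi))

  # near-identical large samples: adjusted p stays large
  set.seed(4)
  x <- rnorm(300)
  pw2 <- pairwise_t3(list(x, x + rnorm(300, 0, 1e-3)), trim = 0, nsim = 5000)
  expect_gt(pw2$p_adj[1], 0.9)

  # one group shifted by 10 pooled SDs: tiny adjusted p
  hits <- 0
  for (i in 1:20) {
    set.seed(100 + i)
    g <- list(rnorm(8), rnorm(8) + 10)
    p <- pairwise_t3(g, trim = 0.15, nsim = 5000)$p_adj[1]
    if (p < 0.001) hits <- hits + 1
  }
  expect_gte(hits, 20 * 0.99 - 1)
})

test_that("Cliff's delta matches enumeration and its invariances hold", {
  expect_equal(cliffs_method(1:3, 4:6)$delta, -1)
  expect_equal(cliffs_method(c(1, 2, 3), c(1, 2, 3))$delta, 0)
  expect_equal(cliffs_method(c(1, 3), c(2, 4))$delta, -0.5)

  set.seed(5)
  for (i in 1:50) {
    x <- sample(-5:5, sample(3:8, 1), replace = TRUE)
    y <- sample(-5:5, sample(3:8, 1), replace = TRUE)
    r <- cliffs_method(x, y)
    expect_equal(r$delta, oracle_cliff_delta(x, y))
    # antisymmetry
    expect_equal(r$delta, -cliffs_method(y, x)$delta, tolerance = 1e-14)
    # invariance under a strictly monotone transform
    tr <- function(v) exp(v) + 3 * v
    expect_equal(cliffs_method(tr(x), tr(y))$delta, r$delta,
                 tolerance = 1e-14)
  }

  # complete separation: minimal achievable level, flagged
  r <- cliffs_method(1:4, 5:8)
  expect_true(r$degenerate)
  expect_equal(r$p, 2 / choose(8, 4))
})

test_that("the dual-significance rule uses <= in both tests", {
  expect_true(dual_significance(0.03, 0.04, 0.05))
  expect_false(dual_significance(0.03, 0.06, 0.05))
  expect_true(dual_significance(0.05, 0.05, 0.05))   # boundary
  # intersection rule: never more liberal than either test alone
  set.seed(6)
  p1 <- runif(200); p2 <- runif(200)
  d <- dual_significance(p1, p2, 0.05)
  expect_true(all(d <= (p1 <= 0.05)))
  expect_true(all(d <= (p2 <= 0.05)))
})

test_that("variability profiles use type-7 quartiles and 1.5 IQR whiskers", {
  pr <- variability_profile(c(1, 2, 3, 4, 5), rep("a", 5))
  expect_equal(pr$median, 3)
  expect_equal(pr$q1, 2)
  expect_equal(pr$q3, 4)
  expect_equal(pr$iqr, 2)
  expect_equal(pr$whisker_lo, 1)
  expect_equal(pr$whisker_hi, 5)

  pr2 <- variability_profile(rep(7, 4), rep("a", 4))
  expect_equal(pr2$iqr, 0)
  expect_equal(pr2$whisker_lo, 7)
  expect_equal(pr2$whisker_hi, 7)

  # an extreme value beyond 1.5 IQR is excluded from the whisker
  pr3 <- variability_profile(c(1, 2, 3, 4, 50), rep("a", 5))
  expect_equal(pr3$whisker_hi, 4)
})

test_that("group_compare assembles omnibus, pairwise, Cliff and dual flags", {
  set.seed(7)
  vals <- c(rnorm(7, 0), rnorm(6, 0.2), rnorm(7, 5), rnorm(6, 5.2))
  grp <- rep(c("G", "GO", "LO", "L"), c(7, 6, 7, 6))
  gc <- group_compare(vals, grp, variable = "demo", nsim = 5000)
  expect_equal(gc$omnibus$nu1, 3)
  expect_equal(nrow(gc$pairwise), 6)
  expect_true(all(c("delta", "p_cm", "dual_significant") %in%
                    names(gc$pairwise)))
  # the far-apart pair is dual-significant, the near pair is not
  far <- gc$pairwise$group1 == "G" & gc$pairwise$group2 == "LO"
  near <- gc$pairwise$group1 == "G" & gc$pairwise$group2 == "GO"
  expect_true(gc$pairwise$dual_significant[far])
  expect_false(gc$pairwise$dual_significant[near])
})
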