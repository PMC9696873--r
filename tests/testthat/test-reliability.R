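test_that("mean squares match hand-computable matrices", {
  ms <- mean_squares(rbind(c(1, 1), c(2, 2), c(3, 3)))
  expect_equal(ms$msr, 2)
  expect_equal(ms$msc, 0)
  expect_equal(ms$mse, 0)
  expect_equal(c(ms$df_r, ms$df_c, ms$df_e), c(2, 1, 2))
  # 2x2 with identical rows: all variance is between columns
  ms2 <- mean_squares(rbind(c(0, 1), c(0, 1)))
  ora <- oracle_ss(rbind(c(0, 1), c(0, 1)))
  expect_equal(ms2$msr, ora$msr)
  expect_equal(ms2$msc, ora$msc)
  expect_equal(ms2$mse, ora$mse)
  expect_equal(ms2$msr, 0)
  expect_equal(ms2$msc, 1)  # n * sum((colmean - grand)^2) / (k-1) = 2 * 0.5
})

test_that("sums of squares decompose the total on random matrices", {
  set.seed(101)
  for (i in 1:50) {
    m <- random_matrix(sample(3:12, 1), sample(2:5, 1),
                       sb = runif(1, 0.5, 3), sc = runif(1, 0, 1),
                       se = runif(1, 0.1, 2))
    ms <- mean_squares(m)
    ora <- oracle_ss(m)
    sst <- ms$msr * ms$df_r + ms$msc * ms$df_c + ms$mse * ms$df_e
    expect_equal(sst, ora$sst, tolerance = 1e-9)
    expect_equal(ms$msr, ora$msr, tolerance = 1e-12)
    expect_equal(ms$msc, ora$msc, tolerance = 1e-12)
    expect_equal(ms$mse, ora$mse, tolerance = 1e-12)
  }
})

test_that("mean squares agree with an aov() fit", {
  set.seed(7)
  m <- matrix(sample(1:40, 15), 5, 3)  # 5x3 integer fixture
  ms <- mean_squares(m)
  aovms <- oracle_ms_aov(m)
  expect_equal(ms$msr, aovms$msr)
  expect_equal(ms$msc, aovms$msc)
  expect_equal(ms$mse, aovms$mse)
})

test_that("perfect agreement yields ICC 1 with a collapsed interval", {
  m <- rbind(c(1, 1), c(2, 2), c(3, 3), c(4, 4))
  suppressMessages({
    i1 <- icc(m, "single")
    ik <- icc(m, "mean")
  })
  expect_equal(i1$estimate, 1)
  expect_equal(c(i1$ci_low, i1$ci_high), c(1, 1))
  expect_equal(ik$estimate, 1)
  expect_equal(i1$classification, "excellent")
})

test_that("zero subject variance with noise gives a nonpositive, poor ICC", {
  set.seed(3)
  m <- matrix(rnorm(20), 10, 2)  # no subject effect at all
  i1 <- icc(m, "single")
  expect_lte(i1$estimate, 0.1)
  # forced negative numerator: identical row means, nonzero residual
  m2 <- rbind(c(1, 2), c(2, 1), c(1.5, 1.5), c(2.5, 0.5))
  i2 <- icc(m2, "single")
  expect_lte(i2$estimate, 0)
  expect_equal(i2$classification, "poor")
})

test_that("an all-constant matrix has no defined ICC", {
  expect_error(icc(matrix(5, 4, 3)), class = "relsens_degenerate_matrix")
})

test_that("single and mean forms satisfy the Spearman-Brown identity", {
  set.seed(202)
  for (i in 1:40) {
    k <- sample(2:4, 1)
    m <- random_matrix(sample(4:10, 1), k)
    i1 <- icc(m, "single"); ik <- icc(m, "mean")
    expect_equal(ik$estimate, k * i1$estimate / (1 + (k - 1) * i1$estimate),
                 tolerance = 1e-9)
    expect_equal(ik$ci_low, k * i1$ci_low / (1 + (k - 1) * i1$ci_low),
                 tolerance = 1e-9)
    if (i1$estimate >= 0) expect_gte(ik$estimate, i1$estimate)
    expect_lte(i1$ci_low, i1$estimate)
    expect_gte(i1$ci_high, i1$estimate)
  }
})

test_that("the Koo-Li bands classify boundary values as specified", {
  expect_equal(classify_icc(c(0.988, 0.49, 0.50, 0.75, 0.751, 0.90, 0.901, -0.3)),
               c("excellent", "poor", "moderate", "moderate", "good", "good",
                 "excellent", "poor"))
})

test_that("CV% averages per-subject coefficient of variation", {
  expect_equal(cv_percent(rbind(c(9, 11), c(9, 11))),
               sd(c(9, 11)) / 10 * 100)
  expect_equal(cv_percent(rbind(c(5, 5, 5), c(8, 8, 8))), 0)
  set.seed(5)
  m <- random_matrix(17, 3, sb = 2, sc = 0, se = 0.5, mu = 50)
  manual <- mean(apply(m, 1, function(r) sd(r) / mean(r))) * 100
  expect_equal(cv_percent(m), manual)
  expect_error(cv_percent(rbind(c(-1, 1), c(2, 2))),
               class = "relsens_integrity_error")
})

test_that("rmANOVA detects session shifts and matches a brute-force oracle", {
  m <- cbind(a = c(4, 7, 9), b = c(4, 7, 9))
  bt <- rm_anova(m)
  expect_equal(bt$f_stat, 0)
  expect_equal(bt$p_value, 1)
  expect_false(bt$significant)
  # constant +1 column shift, no noise: infinite-F degenerate case
  suppressMessages(bt2 <- rm_anova(rbind(c(0, 1), c(2, 3), c(4, 5))))
  expect_true(bt2$degenerate)
  expect_equal(bt2$p_value, 0)
  expect_true(bt2$significant)
  set.seed(11)
  m3 <- random_matrix(8, 3, sc = 0.8)
  bt3 <- rm_anova(m3)
  ora <- oracle_ss(m3)
  f <- ora$msc / ora$mse
  expect_equal(bt3$f_stat, f, tolerance = 1e-12)
  expect_equal(bt3$p_value, pf(f, 2, 14, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("for two sessions the rmANOVA equals the paired t-test", {
  set.seed(21)
  for (i in 1:20) {
    m <- random_matrix(sample(5:15, 1), 2, sc = 0.5)
    bt <- rm_anova(m)
    tt <- t.test(m[, 1], m[, 2], paired = TRUE)
    expect_equal(bt$f_stat, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(bt$p_value, tt$p.value, tolerance = 1e-9)
  }
})

test_that("shift invariance and scale behavior of the reliability statistics", {
  set.seed(31)
  m <- random_matrix(10, 3, mu = 30)
  shifted <- m + 7
  scaled <- m * 3
  expect_equal(icc(shifted, "single")$estimate, icc(m, "single")$estimate)
  expect_equal(icc(scaled, "mean")$estimate, icc(m, "mean")$estimate)
  expect_equal(rm_anova(shifted)$p_value, rm_anova(m)$p_value)
  expect_equal(rm_anova(scaled)$f_stat, rm_anova(m)$f_stat)
  ms <- mean_squares(m); mss <- mean_squares(scaled)
  expect_equal(mss$mse, 9 * ms$mse)
})

test_that("distribution gates flag outliers and pass homogeneous data", {
  set.seed(41)
  m <- random_matrix(17, 3, mu = 20)
  g <- distribution_gates(m)
  expect_equal(nrow(g), 4)  # 3 Shapiro columns + 1 Levene
  m_out <- m; m_out[1, 2] <- 1e6
  g_out <- suppressWarnings(suppressMessages(distribution_gates(m_out)))
  expect_false(g_out$passed[g_out$test == "shapiro_wilk" & g_out$session == "S2"])
  # equal columns: Levene statistic 0
  eq <- cbind(S1 = c(1, 5, 9, 2), S2 = c(1, 5, 9, 2))
  # leveneTest warns about the perfect fit; only the statistic matters here
  g_eq <- suppressWarnings(distribution_gates(eq))
  expect_equal(g_eq$statistic[g_eq$test == "levene"], 0)
  # the tiny 2x2 also triggers leveneTest's perfect-fit warning; only the
  # skipped-normality-gate warning is under test
  suppressWarnings(
    expect_warning(distribution_gates(rbind(c(1, 2), c(3, 4))),
                   class = "relsens_gate_warning"))
})

test_that("mean- and median-centered Levene variants both run", {
  set.seed(51)
  m <- random_matrix(12, 3)
  g1 <- distribution_gates(m, center = "mean")
  g2 <- distribution_gates(m, center = "median")
  l1 <- g1$statistic[g1$test == "levene"]
  l2 <- g2$statistic[g2$test == "levene"]
  expect_false(isTRUE(all.equal(l1, l2)))
})
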