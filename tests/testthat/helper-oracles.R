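# Independent oracles used by the test suite. These deliberately avoid the
# package's own code paths: sums of squares by explicit loops, mean squares
# via aov(), ICC by direct transcription of the variance-component formulas,
# and a vectorized parametric bootstrap for interval cross-checks.

# brute-force two-way sums of squares, elementwise loops
oracle_ss <- function(m) {
  n <- nrow(m); k <- ncol(m)
  g <- mean(m)
  ssr <- 0; ssc <- 0; sse <- 0; sst <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      ri <- mean(m[i, ]); cj <- mean(m[, j])
      sse <- sse + (m[i, j] - ri - cj + g)^2
      sst <- sst + (m[i, j] - g)^2
    }
  }
  for (i in seq_len(n)) ssr <- ssr + k * (mean(m[i, ]) - g)^2
  for (j in seq_len(k)) ssc <- ssc + n * (mean(m[, j]) - g)^2
  list(ssr = ssr, ssc = ssc, sse = sse, sst = sst,
       msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)))
}

# mean squares through stats::aov, a fully separate fitting route
oracle_ms_aov <- function(m) {
  d <- data.frame(y = as.vector(m),
                  subject = factor(rep(seq_len(nrow(m)), ncol(m))),
                  session = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  tab <- summary(stats::aov(y ~ subject + session, data = d))[[1]]
  # terms appear in formula order: subject, session, Residuals
  list(msr = tab[1, "Mean Sq"], msc = tab[2, "Mean Sq"],
       mse = tab[3, "Mean Sq"])
}

# direct transcription of the absolute-agreement point estimates
oracle_icc_a1 <- function(msr, msc, mse, n, k) {
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}
oracle_icc_ak <- function(msr, msc, mse, n, k) {
  (msr - mse) / (msr + (msc - mse) / n)
}

# parametric bootstrap of the ICC(A,1)/(A,k) estimators: resample the fitted
# two-way random-effects model and return percentile intervals of the
# re-estimates; fully vectorized over replicates
oracle_icc_bootstrap <- function(m, R = 1e5, alpha = 0.05, seed = 1) {
  n <- nrow(m); k <- ncol(m)
  ms <- oracle_ss(m)
  s2r <- max((ms$msr - ms$mse) / k, 0)
  s2c <- max((ms$msc - ms$mse) / n, 0)
  s2e <- ms$mse
  set.seed(seed)
  B <- matrix(rnorm(n * R, 0, sqrt(s2r)), n, R)
  C <- matrix(rnorm(k * R, 0, sqrt(s2c)), k, R)
  E <- matrix(rnorm(n * k * R, 0, sqrt(s2e)), n * k, R)
  subj <- rep(seq_len(n), k); sess <- rep(seq_len(k), each = n)
  ebar_i <- rowsum(E, subj) / k            # n x R
  ebar_j <- rowsum(E, sess) / n            # k x R
  ebar <- colMeans(E)
  u <- B + ebar_i                          # subject means minus constants
  v <- C + ebar_j                          # session means minus constants
  msr <- k * colSums(sweep(u, 2, colMeans(u))^2) / (n - 1)
  msc <- n * colSums(sweep(v, 2, colMeans(v))^2) / (k - 1)
  sse <- colSums(E^2) - k * colSums(ebar_i^2) - n * colSums(ebar_j^2) +
    n * k * ebar^2
  mse <- sse / ((n - 1) * (k - 1))
  a1 <- oracle_icc_a1(msr, msc, mse, n, k)
  ak <- oracle_icc_ak(msr, msc, mse, n, k)
  q <- c(alpha / 2, 1 - alpha / 2)
  list(single = unname(stats::quantile(a1, q)),
       mean = unname(stats::quantile(ak, q)))
}

# random complete score matrix with controllable variance components
random_matrix <- function(n, k, sb = 1, sc = 0.2, se = 0.5, mu = 10) {
  b <- rnorm(n, 0, sb); cc <- rnorm(k, 0, sc)
  m <- mu + outer(b, rep(1, k)) + outer(rep(1, n), cc) +
    matrix(rnorm(n * k, 0, se), n, k)
  m
}

# score-level generator used by recovery/power studies: session-average
# scores under the additive model, bypassing nothing the pipeline tests need
# (the acceptance suite itself goes through generate_trials)
expect_between <- function(x, lo, hi) {
  testthat::expect_gte(x, lo)
  testthat::expect_lte(x, hi)
}
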