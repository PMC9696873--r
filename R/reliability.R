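#' Two-way ANOVA mean squares of a score matrix
#'
#' Decomposes a complete subjects-by-sessions matrix into the row (subject),
#' column (session), and residual mean squares of the two-way model without
#' replication — the building blocks of the absolute-agreement ICC and the
#' repeated-measures ANOVA bias test.
#'
#' @param Y A complete numeric matrix (subjects in rows, sessions in columns),
#'   e.g. a [score_matrix()].
#' @return An object of class `mean_squares`: list with `msr`, `msc`, `mse`,
#'   degrees of freedom `df_r`, `df_c`, `df_e`, `grand_mean`, `n`, `k`.
#' @export
mean_squares <- function(Y) {
  m <- as.matrix(Y)
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2 || anyNA(m)) {
    abort("mean_squares needs a complete matrix with n >= 2 and k >= 2",
          class = "relsens_insufficient_data")
  }
  gm <- mean(m)
  rm_ <- rowMeans(m); cm_ <- colMeans(m)
  ssr <- k * sum((rm_ - gm)^2)
  ssc <- n * sum((cm_ - gm)^2)
  sse <- sum((m - outer(rm_, rep(1, k)) - outer(rep(1, n), cm_) + gm)^2)
  structure(list(
    msr = ssr / (n - 1), msc = ssc / (k - 1), mse = sse / ((n - 1) * (k - 1)),
    df_r = n - 1, df_c = k - 1, df_e = (n - 1) * (k - 1),
    grand_mean = gm, n = n, k = k
  ), class = "mean_squares")
}

#' @export
print.mean_squares <- function(x, ...) {
  cat(sprintf("<mean_squares> n=%d k=%d  MSR=%.6g MSC=%.6g MSE=%.6g\n",
              x$n, x$k, x$msr, x$msc, x$mse))
  invisible(x)
}

as_mean_squares <- function(x) {
  if (inherits(x, "mean_squares")) x else mean_squares(x)
}

#' Classify an ICC estimate on the Koo-Li scale
#'
#' Below 0.50 is poor, 0.50-0.75 moderate, above 0.75 up to 0.90 good, and
#' above 0.90 excellent. The boundaries 0.50 and 0.75 fall into the lower of
#' the two adjacent bands' labels (moderate and moderate respectively), and
#' 0.90 is good, reading the band edges literally.
#'
#' @param estimate Numeric vector of ICC estimates (may be negative).
#' @return Character vector: `"poor"`, `"moderate"`, `"good"`, `"excellent"`.
#' @export
#' @examples
#' classify_icc(c(0.49, 0.5, 0.75, 0.76, 0.9, 0.91))
classify_icc <- function(estimate) {
  stopifnot(all(estimate <= 1 + 1e-12))
  out <- character(length(estimate))
  out[estimate < 0.50] <- "poor"
  out[estimate >= 0.50 & estimate <= 0.75] <- "moderate"
  out[estimate > 0.75 & estimate <= 0.90] <- "good"
  out[estimate > 0.90] <- "excellent"
  out
}

#' Intraclass correlation, two-way model, absolute agreement
#'
#' Computes the McGraw-Wong absolute-agreement ICC from a score matrix or its
#' mean squares: `form = "single"` gives ICC(A,1) — commonly written ICC(2,1)
#' — for single measurements, and `form = "mean"` gives ICC(A,k) — ICC(2,k) —
#' for the mean of the k sessions. The 95% confidence interval uses the
#' F-based method with a Satterthwaite approximation for the denominator
#' degrees of freedom; the mean-form interval is the Spearman-Brown transform
#' of the single-form bounds. Negative estimates are reported as computed,
#' never clamped.
#'
#' @param x A [score_matrix()] (or plain complete matrix) or a
#'   [mean_squares()] object.
#' @param form `"single"` for ICC(A,1), `"mean"` for ICC(A,k).
#' @param alpha Two-sided confidence level is `1 - alpha` (default 0.05).
#' @param n,k Required only when `x` is a `mean_squares` object.
#' @return An object of class `icc_result`: list with `estimate`, `ci_low`,
#'   `ci_high`, `form`, `alpha`, `classification`, plus the mean squares used.
#' @export
#' @examples
#' Y <- cbind(s1 = c(10, 12, 19, 8), s2 = c(11, 13, 18, 9))
#' icc(Y, form = "single")
icc <- function(x, form = c("single", "mean"), alpha = 0.05,
                n = NULL, k = NULL) {
  form <- match.arg(form)
  if (inherits(x, "mean_squares")) {
    ms <- x
    if (is.null(n)) n <- ms$n
    if (is.null(k)) k <- ms$k
  } else {
    ms <- mean_squares(x)
    n <- ms$n; k <- ms$k
  }
  msr <- ms$msr; msc <- ms$msc; mse <- ms$mse
  if (msr + mse <= 0 && msc <= 0) {
    abort("ICC undefined: matrix has no variance at all",
          class = "relsens_degenerate_matrix")
  }
  est1 <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  if (mse == 0 && msc == 0) {
    # perfect agreement: interval collapses
    log_note("perfect agreement (MSE = MSC = 0); ICC = 1 with degenerate CI")
    lo1 <- hi1 <- est1 <- 1
  } else {
    ci <- icc_a1_ci(est1, msr, msc, mse, n, k, alpha)
    lo1 <- ci[1]; hi1 <- ci[2]
  }
  if (form == "single") {
    est <- est1; lo <- lo1; hi <- hi1
  } else {
    est <- (msr - mse) / (msr + (msc - mse) / n)
    lo <- spearman_brown(lo1, k)
    hi <- spearman_brown(hi1, k)
  }
  structure(list(estimate = est, ci_low = min(lo, est), ci_high = max(hi, est),
                 form = form, alpha = alpha,
                 classification = classify_icc(min(est, 1)),
                 ms = ms, n = n, k = k),
            class = "icc_result")
}

# F-based interval for ICC(A,1) with Satterthwaite df (McGraw & Wong 1996)
icc_a1_ci <- function(est, msr, msc, mse, n, k, alpha) {
  a <- (k * est) / (n * (1 - est))
  b <- 1 + (k * est * (n - 1)) / (n * (1 - est))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  v <- max(v, 1)
  f_lo <- qf(1 - alpha / 2, n - 1, v)
  f_hi <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_lo * mse) /
    (f_lo * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_hi * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_hi * msr)
  c(lower, upper)
}

spearman_brown <- function(r, k) k * r / (1 + (k - 1) * r)

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,%s) = %.3f  %g%% CI [%.3f, %.3f]  (%s)\n",
              if (x$form == "single") "1" else "k", x$estimate,
              100 * (1 - x$alpha), x$ci_low, x$ci_high, x$classification))
  invisible(x)
}

#' Within-subject coefficient of variation
#'
#' Absolute reliability as SD/mean x 100, computed within each subject across
#' the matrix's sessions (sample SD) and then averaged across subjects. A
#' pooled alternative uses the root-mean within-subject variance divided by
#' the grand mean, which weights subjects by their variance rather than by
#' their relative error.
#'
#' @param Y A complete score matrix.
#' @param method `"subject_mean"` (default) or `"pooled"`.
#' @return The CV as a percentage.
#' @export
#' @examples
#' cv_percent(rbind(c(9, 11), c(18, 22)))  # every subject at CV 14.1%
cv_percent <- function(Y, method = c("subject_mean", "pooled")) {
  method <- match.arg(method)
  m <- as.matrix(Y)
  mu <- rowMeans(m)
  if (any(mu <= 0)) {
    abort("CV undefined: a subject mean is <= 0",
          class = "relsens_integrity_error")
  }
  s <- apply(m, 1, sd)
  switch(method,
         subject_mean = mean(s / mu) * 100,
         pooled = sqrt(mean(s^2)) / mean(m) * 100)
}

#' Repeated-measures ANOVA test for systematic bias between sessions
#'
#' Tests whether session means differ (a learning or time effect) using the
#' session mean square over the subject-by-session residual: F = MSC/MSE on
#' (k-1) and (n-1)(k-1) degrees of freedom. For k = 2 this is exactly the
#' squared paired t statistic. A zero residual with a nonzero session effect
#' is reported as an infinite-F degenerate case with p = 0.
#'
#' @param Y A complete score matrix.
#' @param alpha Significance level (default 0.05).
#' @return An object of class `bias_test`: list with `f_stat`, `df1`, `df2`,
#'   `p_value`, `significant`, `degenerate`.
#' @export
rm_anova <- function(Y, alpha = 0.05) {
  ms <- as_mean_squares(Y)
  if (ms$mse == 0) {
    if (ms$msc == 0) {
      f <- 0; p <- 1; degen <- FALSE
    } else {
      log_note("rm_anova: zero residual with a session effect (infinite F)")
      f <- Inf; p <- 0; degen <- TRUE
    }
  } else {
    f <- ms$msc / ms$mse
    p <- pf(f, ms$df_c, ms$df_e, lower.tail = FALSE)
    degen <- FALSE
  }
  structure(list(f_stat = f, df1 = ms$df_c, df2 = ms$df_e, p_value = p,
                 significant = p < alpha, alpha = alpha, degenerate = degen),
            class = "bias_test")
}

#' @export
print.bias_test <- function(x, ...) {
  cat(sprintf("rmANOVA F(%d, %d) = %.3f, p = %.4g%s\n", x$df1, x$df2,
              x$f_stat, x$p_value,
              if (x$significant) "  (significant)" else ""))
  invisible(x)
}

#' Distributional gates: Shapiro-Wilk normality and Levene homogeneity
#'
#' Advisory pre-checks on a score matrix: Shapiro-Wilk per session column and
#' Levene's test of equal variances across sessions (classic mean-centered by
#' default; median-centering, i.e. the Brown-Forsythe variant, via
#' `center = "median"`). Gates are logged, never abort the pipeline.
#'
#' @param Y A complete score matrix.
#' @param alpha Significance level; a gate passes when p >= alpha.
#' @param center Centering for Levene's test: `"mean"` or `"median"`.
#' @return A tibble with columns `test`, `session`, `statistic`, `p_value`,
#'   `passed`.
#' @export
distribution_gates <- function(Y, alpha = 0.05,
                               center = c("mean", "median")) {
  center <- match.arg(center)
  m <- as.matrix(Y)
  n <- nrow(m); k <- ncol(m)
  cols <- colnames(m)
  if (is.null(cols)) cols <- paste0("S", seq_len(k))
  rows <- list()
  if (n >= 3) {
    for (j in seq_len(k)) {
      sw <- tryCatch(shapiro.test(m[, j]),
                     error = function(e) list(statistic = NA_real_,
                                              p.value = NA_real_))
      rows[[length(rows) + 1]] <- tibble::tibble(
        test = "shapiro_wilk", session = cols[j],
        statistic = unname(sw$statistic), p_value = sw$p.value,
        passed = !is.na(sw$p.value) && sw$p.value >= alpha)
    }
  } else {
    warn("normality gate skipped: fewer than 3 subjects",
         class = "relsens_gate_warning")
  }
  long <- data.frame(value = as.vector(m),
                     session = factor(rep(cols, each = n)))
  if (sd(long$value) == 0) {
    lev <- list(stat = 0, p = 1)  # identical data: trivially homogeneous
  } else {
    lt <- car::leveneTest(value ~ session, data = long,
                          center = if (center == "mean") mean else stats::median)
    lev <- list(stat = lt[1, "F value"], p = lt[1, "Pr(>F)"])
  }
  rows[[length(rows) + 1]] <- tibble::tibble(
    test = "levene", session = "all", statistic = lev$stat, p_value = lev$p,
    passed = is.na(lev$p) || lev$p >= alpha)
  out <- dplyr::bind_rows(rows)
  failed <- out[!out$passed, ]
  if (nrow(failed) > 0) {
    log_note("distribution gate(s) failed: ",
             paste(unique(failed$test), collapse = ", "))
  }
  out
}
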