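#' Pooled SD and mean of a score matrix
#'
#' The "pooled" moments entering the sensitivity chain: by default the pooled
#' SD is the root of the mean per-session sample variance (the standard
#' equal-n pooled SD of the sessions being compared) and the pooled mean is
#' the mean of the per-session means. An alternative pools across all cells
#' after removing each session's mean.
#'
#' @param Y A complete score matrix restricted to the sessions being compared.
#' @param method `"per_session"` (default) or `"centered_cells"`.
#' @return An object of class `pooled_moments`: list with `sd_pooled`,
#'   `mean_pooled`, `sessions_used`.
#' @export
pooled_moments <- function(Y, method = c("per_session", "centered_cells")) {
  method <- match.arg(method)
  m <- as.matrix(Y)
  vars <- apply(m, 2, var)
  sd_pooled <- switch(method,
    per_session = sqrt(mean(vars)),
    centered_cells = {
      centred <- sweep(m, 2, colMeans(m))
      sqrt(sum(centred^2) / (length(m) - ncol(m)))
    })
  structure(list(sd_pooled = sd_pooled, mean_pooled = mean(colMeans(m)),
                 sessions_used = colnames(m)),
            class = "pooled_moments")
}

#' Standard error of measurement from pooled SD and ICC
#'
#' SEm = SD_pooled * sqrt(1 - ICC); its percentage form divides by the pooled
#' mean. Negative ICC estimates are admitted — the SEm then exceeds the
#' pooled SD, as it should for data noisier than the between-subject spread.
#'
#' @param pm A [pooled_moments()] object (or a number taken as `sd_pooled`,
#'   in which case `mean_pooled` must be supplied for the percentage).
#' @param icc_estimate ICC point estimate (<= 1); an `icc_result` is accepted.
#' @param mean_pooled Pooled mean, only needed when `pm` is a bare number.
#' @return List with `sem` and `sem_pct`.
#' @export
#' @examples
#' compute_sem(pooled_moments(cbind(c(1, 2, 30), c(2, 3, 29))), 0.96)
compute_sem <- function(pm, icc_estimate, mean_pooled = NULL) {
  if (inherits(icc_estimate, "icc_result")) icc_estimate <- icc_estimate$estimate
  stopifnot(icc_estimate <= 1)
  if (inherits(pm, "pooled_moments")) {
    sd_pooled <- pm$sd_pooled
    mean_pooled <- pm$mean_pooled
  } else {
    sd_pooled <- pm
  }
  sem <- sd_pooled * sqrt(1 - icc_estimate)
  if (is.null(mean_pooled) || mean_pooled == 0) {
    abort("SEm% undefined: pooled mean is zero or missing",
          class = "relsens_integrity_error")
  }
  list(sem = sem, sem_pct = sem / mean_pooled * 100)
}

#' Smallest worthwhile change
#'
#' SWC = SD_pooled x multiplier; the default multiplier 0.2 standardizes a
#' "small" effect on the between-subject SD (Hopkins convention).
#'
#' @inheritParams compute_sem
#' @param multiplier Positive effect-size multiplier, default 0.2.
#' @return The SWC in the variable's units.
#' @export
compute_swc <- function(pm, multiplier = 0.2) {
  stopifnot(multiplier > 0)
  sd_pooled <- if (inherits(pm, "pooled_moments")) pm$sd_pooled else pm
  sd_pooled * multiplier
}

#' Minimal difference (smallest detectable difference)
#'
#' MD = SEm x 1.96 x sqrt(2): the change between two measurements that
#' exceeds measurement error at 95% confidence. The percentage form divides
#' by the pooled mean.
#'
#' @param sem Standard error of measurement (>= 0).
#' @param mean_pooled Pooled mean; omit to get `md_pct = NA`.
#' @return List with `md` and `md_pct`.
#' @export
compute_md <- function(sem, mean_pooled = NULL) {
  stopifnot(sem >= 0)
  md <- sem * MD_FACTOR
  list(md = md,
       md_pct = if (is.null(mean_pooled)) NA_real_ else md / mean_pooled * 100)
}

#' Sensitivity verdict
#'
#' A measurement is sensitive when its noise floor lies strictly below the
#' smallest worthwhile change: SEm < SWC.
#'
#' @param sem,swc Nonnegative reals.
#' @return Logical.
#' @export
sensitivity_verdict <- function(sem, swc) {
  stopifnot(sem >= 0, swc >= 0)
  sem < swc
}

#' Full sensitivity chain for one score matrix
#'
#' Computes pooled moments, SEm (from the ICC form matching the score rule:
#' mean-form for `avg` scores, single-form for best-value scores), SWC, MD,
#' and the SEm < SWC verdict.
#'
#' @param Y A complete [score_matrix()] for the sessions being compared.
#' @param icc_form `"mean"` or `"single"`; defaults by the matrix's rule
#'   (`avg` -> mean, `highest`/`lowest` -> single).
#' @param swc_multiplier See [compute_swc()].
#' @param alpha Passed to [icc()].
#' @param pooling Passed to [pooled_moments()].
#' @return A one-row tibble: `variable`, `rule`, `comparison`, `icc`,
#'   `sem`, `sem_pct`, `swc`, `md`, `md_pct`, `sensitive`.
#' @export
sensitivity_chain <- function(Y, icc_form = NULL, swc_multiplier = 0.2,
                              alpha = 0.05,
                              pooling = c("per_session", "centered_cells")) {
  rule <- attr(Y, "rule")
  if (is.null(icc_form)) {
    icc_form <- if (identical(rule, "avg")) "mean" else "single"
  }
  ic <- icc(Y, form = icc_form, alpha = alpha)
  pm <- pooled_moments(Y, method = match.arg(pooling))
  se <- compute_sem(pm, ic$estimate)
  mdiff <- compute_md(se$sem, pm$mean_pooled)
  swc_val <- compute_swc(pm, swc_multiplier)
  tibble::tibble(
    variable = attr(Y, "variable") %||% NA_character_,
    rule = rule %||% NA_character_,
    comparison = paste(colnames(Y), collapse = "-"),
    icc = ic$estimate, sem = se$sem, sem_pct = se$sem_pct, swc = swc_val,
    md = mdiff$md, md_pct = mdiff$md_pct,
    sensitive = sensitivity_verdict(se$sem, swc_val)
  )
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
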