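#' Published reference tables from a nine-week test-retest study
#'
#' Summary tables (session means and SDs, ICC with 95% CI, CV%, and the
#' sensitivity chain SEm/SWC/MD with percentage forms) as printed by a
#' published 17-subject, three-session study of the four tests this package
#' models. Values are stored exactly as printed, as character strings, so the
#' number of printed decimals is preserved for rounding-aware arithmetic.
#'
#' @param which `"reliability"` (descriptives, ICC, CV) or `"sensitivity"`
#'   (SEm, SWC, MD).
#' @return A tibble of character columns, one row per variable x rule.
#' @export
reference_tables <- function(which = c("reliability", "sensitivity")) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0("reference_", which, ".csv"),
                      package = "relsens", mustWork = TRUE)
  tibble::as_tibble(read.csv(path, colClasses = "character",
                             check.names = FALSE))
}

# printed precision helpers: dp("0.94") = 2, ulp("0.94") = 0.01
printed_dp <- function(s) {
  ifelse(grepl("\\.", s), nchar(sub("^[^.]*\\.", "", s)), 0L)
}
printed_ulp <- function(s) 10^(-printed_dp(s))

#' Recompute the arithmetic relations among the published table cells
#'
#' The published sensitivity cells are linked to one another and to the
#' descriptives by closed-form arithmetic: MD = SEm x 1.96 x sqrt(2), SEm% =
#' SEm / pooled mean x 100, MD% = MD / pooled mean x 100, and SWC = 0.2 x
#' pooled SD, where the pooled mean and SD are taken over the sessions of
#' each comparison. This function recomputes every such cell from the other
#' printed cells and reports whether the printed value agrees within the
#' tolerance implied by the printed rounding (half a unit of last place on
#' every input, propagated through the formula, plus half a unit on the
#' output).
#'
#' A few printed cells are inconsistent with the tables' own arithmetic (see
#' `consistent` = `FALSE` rows); they are reported as computed, not patched.
#'
#' @param swc_multiplier The SWC effect-size multiplier (0.2 as published).
#' @return A tibble with one row per (variable, rule, comparison, quantity):
#'   `printed`, `recomputed`, `tol`, `consistent`.
#' @export
#' @examples
#' rel <- reference_relations()
#' table(rel$quantity, rel$consistent)
reference_relations <- function(swc_multiplier = 0.2) {
  rel <- reference_tables("reliability")
  sen <- reference_tables("sensitivity")
  comps <- list(all = 1:3, s1s2 = c(1, 2), s1s3 = c(1, 3), s2s3 = c(2, 3))
  out <- vector("list", 0)
  for (i in seq_len(nrow(sen))) {
    v <- sen$variable[i]; r <- sen$rule[i]
    rrow <- rel[rel$variable == v & rel$rule == r, ]
    means <- c(rrow$mean_s1, rrow$mean_s2, rrow$mean_s3)
    sds <- c(rrow$sd_s1, rrow$sd_s2, rrow$sd_s3)
    for (cn in names(comps)) {
      ss <- comps[[cn]]
      mp <- mean(as.numeric(means[ss]))
      e_mp <- mean(0.5 * printed_ulp(means[ss]))
      sdp <- sqrt(mean(as.numeric(sds[ss])^2))
      e_sdp <- 0.5 * max(printed_ulp(sds[ss]))
      cell <- function(f) sen[[paste0(f, "_", cn)]][i]
      sem <- cell("sem"); md <- cell("md"); swc <- cell("swc")
      sem_pct <- cell("sem_pct"); md_pct <- cell("md_pct")
      row <- function(q, printed, recomputed, tol) {
        tibble::tibble(variable = v, rule = r, comparison = cn, quantity = q,
                       printed = as.numeric(printed), recomputed = recomputed,
                       tol = tol,
                       consistent = abs(as.numeric(printed) - recomputed) <= tol)
      }
      out[[length(out) + 1]] <- dplyr::bind_rows(
        row("md", md, as.numeric(sem) * MD_FACTOR,
            MD_FACTOR * 0.5 * printed_ulp(sem) + 0.5 * printed_ulp(md)),
        row("sem_pct", sem_pct, as.numeric(sem) / mp * 100,
            100 * (0.5 * printed_ulp(sem) / mp +
                     as.numeric(sem) * e_mp / mp^2) +
              0.5 * printed_ulp(sem_pct)),
        row("md_pct", md_pct, as.numeric(md) / mp * 100,
            100 * (0.5 * printed_ulp(md) / mp +
                     as.numeric(md) * e_mp / mp^2) +
              0.5 * printed_ulp(md_pct)),
        row("swc", swc, swc_multiplier * sdp,
            swc_multiplier * e_sdp + 0.5 * printed_ulp(swc))
      )
    }
  }
  dplyr::bind_rows(out)
}
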