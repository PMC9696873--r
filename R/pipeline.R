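#' Run the full reliability and sensitivity analysis
#'
#' Orchestrates the whole chain for every requested variable: collapse hop
#' records to set scores, aggregate trials to session scores under each
#' applicable rule (`avg` plus the variable's best-value rule), run the
#' distributional gates, and compute — for the all-sessions comparison and
#' every session pair — the systematic-bias rmANOVA, the absolute-agreement
#' ICC (mean form for `avg` scores, single form for best-value scores) with
#' 95% CI and Koo-Li class, the within-subject CV%, and the sensitivity chain
#' SEm, SEm%, SWC, MD, MD%, and verdict. No multiple-comparison correction is
#' applied across variables or comparisons.
#'
#' @param dataset A [trial_dataset()].
#' @param variables Variables to analyze; defaults to all present.
#' @param comparisons List of session subsets (each length >= 2); defaults to
#'   all sessions plus every pair, in chronological order.
#' @param alpha Significance level for gates, bias tests, and ICC intervals.
#' @param swc_multiplier Effect-size multiplier for the SWC.
#' @param pooling Pooled-SD definition, see [pooled_moments()].
#' @param cv_method See [cv_percent()].
#' @param max_contact_time Optional contact-time validity cut, see
#'   [collapse_hops()].
#' @return An object of class `run_report`: list of tibbles `descriptives`,
#'   `gates`, `reliability`, `sensitivity`, plus the settings used.
#' @export
#' @examples
#' sim <- simulated_study(seed = 42)
#' rep <- run_analysis(sim$dataset, variables = "grip_force")
#' rep$reliability
run_analysis <- function(dataset, variables = NULL, comparisons = NULL,
                         alpha = 0.05, swc_multiplier = 0.2,
                         pooling = "per_session",
                         cv_method = "subject_mean",
                         max_contact_time = Inf) {
  stopifnot(inherits(dataset, "trial_dataset"))
  dataset <- collapse_hops(dataset, max_contact_time = max_contact_time)
  present <- unique(dataset$records$variable)
  if (is.null(variables)) variables <- intersect(known_variables(), present)
  missing_vars <- setdiff(variables, present)
  if (length(missing_vars) > 0) {
    abort(paste0("variable(s) not in dataset: ",
                 paste(missing_vars, collapse = ", ")),
          class = "relsens_config_error")
  }
  sessions <- dataset$session_order
  if (is.null(comparisons)) comparisons <- default_comparisons(sessions)
  for (cmp in comparisons) {
    if (length(cmp) < 2 || !all(cmp %in% sessions)) {
      abort("each comparison must be >= 2 known sessions",
            class = "relsens_config_error")
    }
  }
  desc <- list(); gates <- list(); reli <- list(); sens <- list()
  for (v in variables) {
    for (rule in rules_for_variable(v)) {
      scores <- session_scores(dataset, v, rule)
      Y_all <- build_matrix(scores, sessions = sessions)
      desc[[length(desc) + 1]] <- describe_sessions(Y_all)
      g <- distribution_gates(Y_all, alpha = alpha)
      g$variable <- v; g$rule <- rule
      gates[[length(gates) + 1]] <- g
      for (cmp in comparisons) {
        Y <- subset_sessions(Y_all, cmp)
        cmp_label <- paste(cmp, collapse = "-")
        bias <- rm_anova(Y, alpha = alpha)
        form <- if (rule == "avg") "mean" else "single"
        ic <- icc(Y, form = form, alpha = alpha)
        reli[[length(reli) + 1]] <- tibble::tibble(
          variable = v, rule = rule, comparison = cmp_label,
          n = nrow(Y), k = ncol(Y), icc_form = form,
          icc = ic$estimate, ci_low = ic$ci_low, ci_high = ic$ci_high,
          classification = ic$classification,
          cv_pct = cv_percent(Y, method = cv_method),
          f_stat = bias$f_stat, bias_p = bias$p_value,
          bias_significant = bias$significant)
        sc <- sensitivity_chain(Y, icc_form = form,
                                swc_multiplier = swc_multiplier,
                                alpha = alpha, pooling = pooling)
        sens[[length(sens) + 1]] <- sc
      }
    }
  }
  reli <- dplyr::bind_rows(reli)
  structure(list(
    descriptives = dplyr::bind_rows(desc),
    gates = dplyr::bind_rows(gates),
    reliability = add_bias_markers(reli, sessions),
    sensitivity = dplyr::bind_rows(sens),
    settings = list(alpha = alpha, swc_multiplier = swc_multiplier,
                    pooling = pooling, cv_method = cv_method,
                    sessions = sessions,
                    comparisons = vapply(comparisons, paste,
                                         "", collapse = "-"))
  ), class = "run_report")
}

default_comparisons <- function(sessions) {
  pairs <- utils::combn(sessions, 2, simplify = FALSE)
  c(list(sessions), pairs)
}

describe_sessions <- function(Y) {
  tibble::tibble(
    variable = attr(Y, "variable"), rule = attr(Y, "rule"),
    session = colnames(Y), n = nrow(Y),
    mean = colMeans(Y), sd = apply(Y, 2, sd))
}

# the report tables flag significant pairwise bias the way the published
# tables do: '#' for the S1-S3 pair, '&' for S2-S3
add_bias_markers <- function(reli, sessions) {
  if (nrow(reli) == 0 || length(sessions) != 3) {
    reli$markers <- rep("", nrow(reli))
    return(reli)
  }
  p13 <- paste(sessions[c(1, 3)], collapse = "-")
  p23 <- paste(sessions[c(2, 3)], collapse = "-")
  sig <- reli[reli$bias_significant, c("variable", "rule", "comparison")]
  mk <- function(v, r) {
    m <- c(if (any(sig$variable == v & sig$rule == r & sig$comparison == p13)) "#",
           if (any(sig$variable == v & sig$rule == r & sig$comparison == p23)) "&")
    paste(m, collapse = ", ")
  }
  reli$markers <- mapply(mk, reli$variable, reli$rule, USE.NAMES = FALSE)
  reli
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat("  variables:", paste(unique(x$reliability$variable), collapse = ", "),
      "\n")
  cat("  comparisons:", paste(x$settings$comparisons, collapse = "; "), "\n")
  cat("  reliability rows:", nrow(x$reliability),
      " sensitivity rows:", nrow(x$sensitivity), "\n")
  invisible(x)
}

round_to <- function(x, digits) formatC(round(x, digits), format = "f",
                                        digits = digits)

#' Write a report table in the published layout
#'
#' `layout = "reliability"` writes one row per variable x rule with, for each
#' comparison, `ICC (95% CI)` and `CV%` columns; `layout = "sensitivity"`
#' writes `SEm (SEm%)`, `SWC`, `MD (MD%)` columns. Values are rounded the way
#' the published tables round (ICC to 3 decimals, percentages to 1, units at
#' the variable's precision); use [write_report()] to also get the
#' full-precision machine-readable sidecar.
#'
#' @param rows The `reliability` or `sensitivity` tibble of a `run_report`.
#' @param path Output CSV path.
#' @param layout `"reliability"` or `"sensitivity"`.
#' @return The path, invisibly.
#' @export
write_report_table <- function(rows, path,
                               layout = c("reliability", "sensitivity")) {
  layout <- match.arg(layout)
  need <- if (layout == "reliability") "icc" else "sem"
  if (!need %in% names(rows)) {
    abort(sprintf("rows do not match the '%s' layout", layout),
          class = "relsens_config_error")
  }
  reg <- variable_registry()
  if (nrow(rows) == 0) {
    writeLines("variable,rule,comparison", path)
    return(invisible(path))
  }
  rows <- dplyr::arrange(rows, match(.data$variable, reg$variable),
                         .data$rule, .data$comparison)
  digits <- reg$digits[match(rows$variable, reg$variable)]
  out <- if (layout == "reliability") {
    tibble::tibble(
      variable = rows$variable, rule = rows$rule,
      comparison = rows$comparison,
      icc_95ci = sprintf("%s (%s-%s)", round_to(rows$icc, 3),
                         round_to(rows$ci_low, 3), round_to(rows$ci_high, 3)),
      cv_pct = round_to(rows$cv_pct, 1),
      bias_p = round_to(rows$bias_p, 3),
      markers = rows$markers)
  } else {
    tibble::tibble(
      variable = rows$variable, rule = rows$rule,
      comparison = rows$comparison,
      sem = sprintf("%s (%s%%)",
                    mapply(round_to, rows$sem, digits),
                    round_to(rows$sem_pct, 1)),
      swc = mapply(round_to, rows$swc, digits),
      md = sprintf("%s (%s%%)",
                   mapply(round_to, rows$md, digits),
                   round_to(rows$md_pct, 1)),
      sensitive = rows$sensitive)
  }
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write all report files for a run
#'
#' Writes the rounded reliability and sensitivity tables, the per-session
#' descriptives and gate results, and full-precision sidecars of every table
#' (for machine consumption) into a directory.
#'
#' @param report A `run_report` from [run_analysis()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_report_table(report$reliability, file.path(dir, "reliability.csv"),
                     "reliability")
  write_report_table(report$sensitivity, file.path(dir, "sensitivity.csv"),
                     "sensitivity")
  write.csv(report$descriptives, file.path(dir, "descriptives.csv"),
            row.names = FALSE)
  write.csv(report$gates, file.path(dir, "gates.csv"), row.names = FALSE)
  for (tab in c("reliability", "sensitivity")) {
    jsonlite::write_json(report[[tab]],
                         file.path(dir, paste0(tab, "_full.json")),
                         digits = NA, dataframe = "rows")
  }
  log_note("report written to ", dir)
  invisible(dir)
}
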