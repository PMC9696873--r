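#' Summarize one reactive-hop set
#'
#' Collapses the valid hops of one subject-session-set to the two set-level
#' outcomes: peak force, the highest force produced during any valid hop of
#' the set, and average contact time (ACT), the mean ground-contact time of
#' the valid hops. Hops invalidated by heel contact contribute to neither.
#'
#' @param contact_time Numeric vector of per-hop ground-contact times (s).
#' @param peak_force Numeric vector of per-hop peak forces (kN).
#' @param valid Logical vector; `FALSE` marks heel-contact hops.
#' @param max_contact_time Optional upper cut on contact time (s). Hops above
#'   it are treated as invalid. Off (`Inf`) by default: the standard
#'   protocol only removes heel contacts, but a fast stretch-shortening-cycle
#'   criterion such as 0.25 s can be imposed here.
#' @return A list with `peak_force`, `avg_contact_time`, `n_valid`.
#' @export
#' @examples
#' hop_set_summary(c(0.18, 0.20, 0.50), c(3.0, 3.5, 3.2),
#'                 valid = c(TRUE, TRUE, FALSE))
hop_set_summary <- function(contact_time, peak_force,
                            valid = rep(TRUE, length(contact_time)),
                            max_contact_time = Inf) {
  stopifnot(length(contact_time) == length(peak_force),
            length(valid) == length(contact_time))
  keep <- valid & contact_time <= max_contact_time
  if (!any(keep)) {
    abort("no valid hops in set", class = "relsens_degenerate_set")
  }
  list(peak_force = max(peak_force[keep]),
       avg_contact_time = mean(contact_time[keep]),
       n_valid = sum(keep))
}

#' Collapse hop-level records into set-level trial records
#'
#' Each (subject, session, set) becomes two trial records — `hop_peak_force`
#' and `hop_contact_time` with `trial_index` equal to the set index — so the
#' two set summaries act as the "trials" of a session for all downstream
#' aggregation.
#'
#' @param dataset A [trial_dataset()] with hop records.
#' @inheritParams hop_set_summary
#' @return A [trial_dataset()] whose records include the set-level rows (hop
#'   records are retained unchanged).
#' @export
collapse_hops <- function(dataset, max_contact_time = Inf) {
  h <- dataset$hops
  if (is.null(h) || nrow(h) == 0) return(dataset)
  sets <- dplyr::group_by(h, .data$subject_id, .data$session_id, .data$set_index)
  sets <- dplyr::group_modify(sets, function(d, key) {
    s <- tryCatch(
      hop_set_summary(d$contact_time, d$peak_force, d$valid, max_contact_time),
      relsens_degenerate_set = function(e) {
        abort(sprintf("no valid hops for subject %s, session %s, set %d",
                      key$subject_id, key$session_id, key$set_index),
              class = "relsens_degenerate_set")
      })
    tibble::tibble(peak_force = s$peak_force,
                   avg_contact_time = s$avg_contact_time)
  })
  sets <- dplyr::ungroup(sets)
  long <- tidyr::pivot_longer(sets, c("peak_force", "avg_contact_time"),
                              names_to = "variable", values_to = "value")
  long$variable <- ifelse(long$variable == "peak_force",
                          "hop_peak_force", "hop_contact_time")
  rec <- tibble::tibble(
    subject_id = long$subject_id, session_id = long$session_id,
    test = "reactive_hops", variable = long$variable,
    trial_index = as.integer(long$set_index), value = long$value
  )
  trial_dataset(records = dplyr::bind_rows(dataset$records, rec),
                hops = dataset$hops, session_order = dataset$session_order)
}

#' Collapse trial values to a single session score
#'
#' The three session-score rules: `avg` (arithmetic mean of the session's
#' trials), `highest` (best value, used for force/torque/height/power), and
#' `lowest` (best value for contact time, where lower is better).
#'
#' @param values Numeric vector of trial values from one subject-session.
#' @param rule One of `"avg"`, `"highest"`, `"lowest"`.
#' @return A list with `score` and `n_trials_used`.
#' @export
#' @examples
#' session_score(c(10, 12, 14), "avg")$score      # 12
#' session_score(c(10, 12, 14), "highest")$score  # 14
session_score <- function(values, rule = c("avg", "highest", "lowest")) {
  rule <- match.arg(rule)
  if (length(values) == 0 || anyNA(values)) {
    abort("session_score needs at least one non-missing trial value",
          class = "relsens_integrity_error")
  }
  score <- switch(rule, avg = mean(values), highest = max(values),
                  lowest = min(values))
  list(score = score, n_trials_used = length(values))
}

# guard the rule/variable pairing: lowest is only meaningful for contact
# time, and highest never is
check_rule_for_variable <- function(variable, rule) {
  if (variable == "hop_contact_time" && rule == "highest") {
    abort("rule 'highest' is not valid for hop_contact_time (use 'lowest')",
          class = "relsens_config_error")
  }
  if (variable != "hop_contact_time" && rule == "lowest") {
    abort(paste0("rule 'lowest' is only valid for hop_contact_time, not ",
                 variable), class = "relsens_config_error")
  }
  invisible(TRUE)
}

#' Per-subject, per-session scores for one variable under one rule
#'
#' @param dataset A [trial_dataset()] (hop records must already be collapsed
#'   with [collapse_hops()] for hop variables).
#' @param variable A variable name from [variable_registry()].
#' @param rule Session-score rule, see [session_score()].
#' @return A tibble with `subject_id`, `session_id`, `variable`, `rule`,
#'   `score`, `n_trials_used`.
#' @export
session_scores <- function(dataset, variable, rule) {
  rule <- match.arg(rule, c("avg", "highest", "lowest"))
  check_rule_for_variable(variable, rule)
  r <- dataset$records[dataset$records$variable == variable, ]
  if (nrow(r) == 0) {
    abort(paste0("no records for variable ", variable),
          class = "relsens_insufficient_data")
  }
  out <- dplyr::summarise(
    dplyr::group_by(r, .data$subject_id, .data$session_id),
    score = session_score(.data$value, rule)$score,
    n_trials_used = length(.data$value), .groups = "drop")
  out$variable <- variable
  out$rule <- rule
  out[c("subject_id", "session_id", "variable", "rule", "score",
        "n_trials_used")]
}

#' Construct a complete subjects-by-sessions score matrix
#'
#' Builds the n x k matrix that every reliability and sensitivity statistic
#' operates on. Subjects missing any requested session are dropped with a
#' warning so the matrix is always complete.
#'
#' @param scores Output of [session_scores()].
#' @param sessions Ordered character vector (length >= 2) of session labels to
#'   include; defaults to all sessions present, in `session_order` if given.
#' @param session_order Optional full chronological order used to order the
#'   requested sessions.
#' @return A `score_matrix`: a numeric matrix with subject rownames and
#'   session colnames, carrying `variable` and `rule` attributes.
#' @export
build_matrix <- function(scores, sessions = NULL, session_order = NULL) {
  if (is.null(sessions)) {
    sessions <- unique(as.character(scores$session_id))
    sessions <- if (is.null(session_order)) sort(sessions)
                else session_order[session_order %in% sessions]
  }
  if (length(sessions) < 2) {
    abort("at least two sessions are required", class = "relsens_config_error")
  }
  s <- scores[as.character(scores$session_id) %in% sessions, ]
  wide <- tidyr::pivot_wider(s[c("subject_id", "session_id", "score")],
                             names_from = "session_id", values_from = "score")
  miss <- setdiff(sessions, names(wide))
  if (length(miss) > 0) {
    abort(paste0("no scores for session(s): ", paste(miss, collapse = ", ")),
          class = "relsens_insufficient_data")
  }
  m <- as.matrix(wide[sessions])
  rownames(m) <- wide$subject_id
  complete <- stats::complete.cases(m)
  if (any(!complete)) {
    warn(sprintf("dropping %d subject(s) without all requested sessions: %s",
                 sum(!complete),
                 paste(wide$subject_id[!complete], collapse = ", ")),
         class = "relsens_incomplete_warning")
    m <- m[complete, , drop = FALSE]
  }
  score_matrix(m, variable = scores$variable[1], rule = scores$rule[1])
}

#' @param values Complete numeric matrix (subjects x sessions).
#' @param variable,rule Metadata carried along for reporting.
#' @rdname build_matrix
#' @export
score_matrix <- function(values, variable = NA_character_,
                         rule = NA_character_) {
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  if (nrow(m) < 2 || ncol(m) < 2) {
    abort("score matrix needs at least 2 subjects and 2 sessions",
          class = "relsens_insufficient_data")
  }
  if (anyNA(m)) {
    abort("score matrix must be complete", class = "relsens_integrity_error")
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("sub", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("S", seq_len(ncol(m)))
  structure(m, variable = variable, rule = rule,
            class = c("score_matrix", "matrix", "array"))
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> %s [%s]: %d subjects x %d sessions\n",
              attr(x, "variable"), attr(x, "rule"), nrow(x), ncol(x)))
  print(unclass(x))
  invisible(x)
}

# column projection used for pairwise comparisons
subset_sessions <- function(Y, sessions) {
  stopifnot(all(sessions %in% colnames(Y)))
  score_matrix(unclass(Y)[, sessions, drop = FALSE],
               variable = attr(Y, "variable"), rule = attr(Y, "rule"))
}
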