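#' Column-name mappings for trial- and hop-level input files
#'
#' Input files are long-format delimited text with a header row: one row per
#' trial (or per hop). The schema maps the canonical field names used
#' internally to the column names present in the file, so files from other
#' labs can be read without renaming columns first.
#'
#' @param subject,session,test,variable,trial,value Column names in the input
#'   file holding, respectively, the subject label, session label, test name,
#'   variable name, trial (or set) index, and measured value.
#' @return A named character vector mapping canonical names to file columns.
#' @export
#' @examples
#' trial_schema(value = "measurement")
trial_schema <- function(subject = "subject_id", session = "session_id",
                         test = "test", variable = "variable",
                         trial = "trial_index", value = "value") {
  c(subject_id = subject, session_id = session, test = test,
    variable = variable, trial_index = trial, value = value)
}

#' @param set,hop,contact_time,peak_force,valid Column names for the hop-level
#'   fields: set index (1-2), hop index within the set (1-10), ground-contact
#'   time in seconds, peak vertical force in kN, and the validity flag
#'   (`FALSE` marks a hop invalidated by heel contact).
#' @rdname trial_schema
#' @export
hop_schema <- function(subject = "subject_id", session = "session_id",
                       set = "set_index", hop = "hop_index",
                       contact_time = "contact_time",
                       peak_force = "peak_force", valid = "valid") {
  c(subject_id = subject, session_id = session, set_index = set,
    hop_index = hop, contact_time = contact_time, peak_force = peak_force,
    valid = valid)
}

#' Assemble a validated trial-level dataset
#'
#' The central input container: trial-level records of the strength/power
#' tests, optional hop-level records for reactive-hop sets, and the session
#' order. All readers and the synthetic generator return this class;
#' aggregation consumes it.
#'
#' @param records Data frame of trial records with columns `subject_id`,
#'   `session_id`, `test`, `variable`, `trial_index`, `value`.
#' @param hops Optional data frame of hop records with columns `subject_id`,
#'   `session_id`, `set_index`, `hop_index`, `contact_time`, `peak_force`,
#'   `valid`.
#' @param session_order Character vector giving the chronological order of
#'   session labels. Defaults to the lexically sorted distinct labels.
#' @return An object of class `trial_dataset`.
#' @export
trial_dataset <- function(records = NULL, hops = NULL, session_order = NULL) {
  records <- if (is.null(records)) empty_records() else tibble::as_tibble(records)
  if (!is.null(hops)) hops <- tibble::as_tibble(hops)
  if (is.null(session_order)) {
    session_order <- sort(unique(c(
      as.character(records$session_id),
      if (!is.null(hops)) as.character(hops$session_id)
    )))
  }
  x <- structure(
    list(records = records, hops = hops,
         session_order = as.character(session_order)),
    class = "trial_dataset"
  )
  validate_trial_dataset(x)
}

empty_records <- function() {
  tibble::tibble(subject_id = character(), session_id = character(),
                 test = character(), variable = character(),
                 trial_index = integer(), value = double())
}

validate_trial_dataset <- function(x) {
  r <- x$records
  needed <- names(trial_schema())
  miss <- setdiff(needed, names(r))
  if (length(miss) > 0) {
    abort(paste0("records is missing column(s): ", paste(miss, collapse = ", ")),
          class = "relsens_schema_error")
  }
  if (any(!is.finite(r$value))) {
    abort("records contain non-finite values", class = "relsens_parse_error")
  }
  if (any(r$value < 0)) {
    abort("measurement values must be nonnegative", class = "relsens_integrity_error")
  }
  if (any(r$trial_index < 1)) {
    abort("trial_index must be >= 1", class = "relsens_integrity_error")
  }
  key <- paste(r$subject_id, r$session_id, r$test, r$variable, r$trial_index,
               sep = "\r")
  if (anyDuplicated(key)) {
    first <- r[duplicated(key), ][1, ]
    abort(sprintf(
      "duplicate trial record: subject %s, session %s, %s/%s, trial %d",
      first$subject_id, first$session_id, first$test, first$variable,
      first$trial_index), class = "relsens_integrity_error")
  }
  bad <- setdiff(unique(r$variable), known_variables())
  if (length(bad) > 0) {
    abort(paste0("unknown variable(s): ", paste(bad, collapse = ", ")),
          class = "relsens_schema_error")
  }
  extra <- setdiff(unique(as.character(r$session_id)), x$session_order)
  if (length(extra) > 0) {
    abort(paste0("session(s) absent from session_order: ",
                 paste(extra, collapse = ", ")),
          class = "relsens_integrity_error")
  }
  if (!is.null(x$hops)) validate_hops(x$hops, x$session_order)
  x
}

validate_hops <- function(h, session_order) {
  needed <- names(hop_schema())
  miss <- setdiff(needed, names(h))
  if (length(miss) > 0) {
    abort(paste0("hops is missing column(s): ", paste(miss, collapse = ", ")),
          class = "relsens_schema_error")
  }
  if (any(h$contact_time <= 0) || any(h$peak_force <= 0)) {
    abort("hop contact_time and peak_force must be > 0",
          class = "relsens_integrity_error")
  }
  if (!is.logical(h$valid)) {
    abort("hop validity flag must be logical", class = "relsens_parse_error")
  }
  cnt <- dplyr::count(h, .data$subject_id, .data$session_id, .data$set_index)
  if (any(cnt$n > 10)) {
    abort("more than 10 hops recorded for one set",
          class = "relsens_integrity_error")
  }
  extra <- setdiff(unique(as.character(h$session_id)), session_order)
  if (length(extra) > 0) {
    abort(paste0("hop session(s) absent from session_order: ",
                 paste(extra, collapse = ", ")),
          class = "relsens_integrity_error")
  }
  invisible(h)
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat("<trial_dataset>\n")
  cat("  sessions:", paste(x$session_order, collapse = " < "), "\n")
  cat("  trial records:", nrow(x$records), "  subjects:",
      length(unique(c(x$records$subject_id,
                      if (!is.null(x$hops)) x$hops$subject_id))), "\n")
  if (!is.null(x$hops)) cat("  hop records:", nrow(x$hops), "\n")
  if (nrow(x$records) > 0) {
    cat("  variables:", paste(sort(unique(x$records$variable)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

# shared reader core: header + column mapping + numeric coercion with
# file line numbers in parse errors (line 1 is the header)
read_mapped_csv <- function(path, schema, numeric_cols) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "relsens_schema_error")
  }
  raw <- read.csv(path, check.names = FALSE, colClasses = "character",
                  strip.white = TRUE)
  miss <- setdiff(unname(schema), names(raw))
  if (length(miss) > 0) {
    abort(paste0("input file lacks required column(s): ",
                 paste(miss, collapse = ", ")),
          class = "relsens_schema_error")
  }
  out <- raw[unname(schema)]
  names(out) <- names(schema)
  for (col in numeric_cols) {
    v <- suppressWarnings(as.numeric(out[[col]]))
    bad <- which(is.na(v) & !is.na(out[[col]]) & nzchar(out[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("non-numeric value '%s' in column '%s' on line %d of %s",
                    out[[col]][bad[1]], col, bad[1] + 1L, path),
            class = "relsens_parse_error")
    }
    if (anyNA(v)) {
      abort(sprintf("missing value in column '%s' on line %d of %s",
                    col, which(is.na(v))[1] + 1L, path),
            class = "relsens_parse_error")
    }
    out[[col]] <- v
  }
  tibble::as_tibble(out)
}

#' Read long-format trial-level measurements
#'
#' Reads a comma-separated file with one row per trial, validates it, and
#' returns a [trial_dataset()]. Trial counts that deviate from the expected
#' number of trials per session for a test are reported as warnings, never
#' errors, since protocols occasionally lose a trial.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Column mapping from [trial_schema()].
#' @param session_order Optional chronological order of session labels;
#'   defaults to the sorted distinct labels found in the file.
#' @param expected_trials Named integer vector of expected trials per session
#'   for each variable (defaults: 3 per session for trial-based tests, 2 set
#'   summaries for hop variables). Set to `NULL` to skip the check.
#' @return A validated [trial_dataset()].
#' @export
read_trials <- function(path, schema = trial_schema(), session_order = NULL,
                        expected_trials = default_expected_trials()) {
  rec <- read_mapped_csv(path, schema, numeric_cols = c("trial_index", "value"))
  rec$trial_index <- as.integer(rec$trial_index)
  ds <- trial_dataset(records = rec, session_order = session_order)
  if (!is.null(expected_trials)) warn_trial_counts(ds$records, expected_trials)
  ds
}

default_expected_trials <- function() {
  c(peak_torque = 3L, grip_force = 3L, jump_height = 3L, peak_power = 3L,
    hop_peak_force = 2L, hop_contact_time = 2L)
}

warn_trial_counts <- function(records, expected) {
  cnt <- dplyr::count(records, .data$subject_id, .data$session_id,
                      .data$variable)
  cnt$expected <- unname(expected[cnt$variable])
  off <- cnt[!is.na(cnt$expected) & cnt$n != cnt$expected, ]
  if (nrow(off) > 0) {
    warn(sprintf(
      "%d subject-session group(s) deviate from the expected trial count (e.g. %s/%s %s: %d instead of %d)",
      nrow(off), off$subject_id[1], off$session_id[1], off$variable[1],
      off$n[1], off$expected[1]), class = "relsens_count_warning")
  }
  invisible(records)
}

#' Read hop-level records for reactive-hop sets
#'
#' @param hops_path Path to a CSV file with one row per hop.
#' @inheritParams read_trials
#' @return A [trial_dataset()] carrying only hop records.
#' @export
read_hops <- function(hops_path, schema = hop_schema(), session_order = NULL) {
  h <- read_mapped_csv(hops_path, schema,
                       numeric_cols = c("set_index", "hop_index",
                                        "contact_time", "peak_force"))
  h$set_index <- as.integer(h$set_index)
  h$hop_index <- as.integer(h$hop_index)
  h$valid <- parse_flag(h$valid)
  trial_dataset(records = NULL, hops = h, session_order = session_order)
}

parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  v <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(v))
  out[v %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[v %in% c("FALSE", "F", "0", "NO")] <- FALSE
  if (anyNA(out)) {
    abort(sprintf("unparseable validity flag '%s'", x[which(is.na(out))[1]]),
          class = "relsens_parse_error")
  }
  out
}

#' Write raw trial or hop records back to CSV
#'
#' The raw-data writers are exact: `read_trials(write_trials(ds))` reproduces
#' every record value bit-for-bit (values are serialized at full precision).
#'
#' @param dataset A [trial_dataset()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trials <- function(dataset, path) {
  df <- as.data.frame(dataset$records)
  df$value <- format(df$value, digits = 17, trim = TRUE, scientific = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
write_hops <- function(dataset, path) {
  stopifnot(!is.null(dataset$hops))
  df <- as.data.frame(dataset$hops)
  for (col in c("contact_time", "peak_force")) {
    df[[col]] <- format(df[[col]], digits = 17, trim = TRUE, scientific = FALSE)
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Merge two datasets (e.g. trial-level and hop-level files)
#'
#' @param x,y [trial_dataset()] objects.
#' @return A [trial_dataset()] with the union of records and hops.
#' @export
merge_datasets <- function(x, y) {
  hops <- dplyr::bind_rows(x$hops, y$hops)
  if (nrow(hops) == 0) hops <- NULL
  trial_dataset(
    records = dplyr::bind_rows(x$records, y$records),
    hops = hops,
    session_order = unique(c(x$session_order, y$session_order))
  )
}
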