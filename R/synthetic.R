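#' Configuration for the variance-components trial generator
#'
#' The generator draws trial-level values from the additive model
#' \deqn{y_{ijt} = \mu + \delta_j + b_i + s_{ij} + e_{ijt}}
#' with independent Gaussian components: subject effects `b_i ~ N(0,
#' sigma_subject^2)`, subject-by-session interaction `s_ij ~ N(0,
#' sigma_interaction^2)`, and trial noise `e_ijt ~ N(0, sigma_trial^2)`.
#' Session effects `delta_j` are fixed shifts, mirroring the systematic-bias
#' (learning) concept that the repeated-measures ANOVA targets.
#'
#' At the session-average score level (T trials averaged), the implied true
#' absolute-agreement ICC for single sessions is
#' `sigma_subject^2 / (sigma_subject^2 + theta_delta^2 + sigma_interaction^2 +
#' sigma_trial^2 / T)` where `theta_delta^2` is the sample variance of the
#' `delta_j` (denominator k-1); the mean-form value follows by
#' Spearman-Brown.
#'
#' @param variable Variable name from [variable_registry()].
#' @param n_subjects Number of subjects (default 17).
#' @param sessions Session labels in chronological order.
#' @param trials_per_session Trials per session (default 3).
#' @param mu Grand mean in the variable's units.
#' @param sigma_subject Between-subject SD.
#' @param session_effects Fixed per-session shifts, one per session.
#' @param sigma_interaction Subject-by-session SD.
#' @param sigma_trial Within-session trial SD.
#' @param noise `"gaussian"` (default) or `"lognormal"` for skewed trial
#'   noise (same SD, used to exercise the normality gate).
#' @param center_subjects If `TRUE`, subject effects are centered so the
#'   realized cohort mean sits at `mu` (used by the study fixture to pin the
#'   sample at a published scale); leave `FALSE` for unconditional draws.
#' @param seed Integer seed; the full output stream is a deterministic
#'   function of it, and each variable draws from its own substream so adding
#'   a variable never perturbs another's values.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(variable = "jump_height", n_subjects = 17,
                             sessions = c("S1", "S2", "S3"),
                             trials_per_session = 3, mu = 100,
                             sigma_subject = 10,
                             session_effects = rep(0, length(sessions)),
                             sigma_interaction = 0, sigma_trial = 5,
                             noise = c("gaussian", "lognormal"),
                             center_subjects = FALSE, seed = 1L) {
  noise <- match.arg(noise)
  if (length(session_effects) != length(sessions)) {
    abort("session_effects must have one entry per session",
          class = "relsens_config_error")
  }
  if (any(c(sigma_subject, sigma_interaction, sigma_trial) < 0)) {
    abort("all SDs must be >= 0", class = "relsens_config_error")
  }
  if (n_subjects < 2 || length(sessions) < 2 || trials_per_session < 1) {
    abort("need n_subjects >= 2, >= 2 sessions, >= 1 trial per session",
          class = "relsens_config_error")
  }
  structure(list(variable = variable, n_subjects = as.integer(n_subjects),
                 sessions = as.character(sessions),
                 trials_per_session = as.integer(trials_per_session),
                 mu = mu, sigma_subject = sigma_subject,
                 session_effects = session_effects,
                 sigma_interaction = sigma_interaction,
                 sigma_trial = sigma_trial, noise = noise,
                 center_subjects = center_subjects,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# deterministic per-name substream seed below 2^31
substream_seed <- function(seed, name) {
  p <- 2147483629
  h <- 0
  for (ch in utf8ToInt(name)) h <- (h * 131 + ch) %% p
  as.integer((abs(as.numeric(seed)) %% p + h) %% p)
}

# trial noise draws with exact mean 0 and SD sigma by construction of the
# distribution (not empirically recentered)
draw_noise <- function(n, sigma, noise) {
  if (sigma == 0) return(rep(0, n))
  if (noise == "gaussian") return(rnorm(n, 0, sigma))
  sdlog <- 0.8  # fixed skew; scaled to the requested SD
  raw <- stats::rlnorm(n, 0, sdlog)
  (raw - exp(sdlog^2 / 2)) * sigma / sqrt((exp(sdlog^2) - 1) * exp(sdlog^2))
}

#' Generate a trial-level dataset with known truth
#'
#' @param cfg A [generator_config()].
#' @return A list with `dataset` (a [trial_dataset()]) and `truth`, a record
#'   of the generating values: the config, `true_icc_single` and
#'   `true_icc_mean` at the session-average score level, `true_sem`, and the
#'   expected per-session means.
#' @export
#' @examples
#' sim <- generate_trials(generator_config(seed = 7))
#' sim$truth$true_icc_single
generate_trials <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  n <- cfg$n_subjects; k <- length(cfg$sessions)
  n_tr <- cfg$trials_per_session
  set.seed(substream_seed(cfg$seed, cfg$variable))
  b <- rnorm(n, 0, cfg$sigma_subject)
  if (cfg$center_subjects && n > 1) b <- b - mean(b)
  s <- matrix(rnorm(n * k, 0, cfg$sigma_interaction), n, k)
  e <- array(draw_noise(n * k * n_tr, cfg$sigma_trial, cfg$noise),
             c(n, k, n_tr))
  subj <- sprintf("sub%02d", seq_len(n))
  reg <- variable_registry()
  test <- reg$test[match(cfg$variable, reg$variable)]
  idx <- expand.grid(i = seq_len(n), j = seq_len(k), t = seq_len(n_tr))
  value <- cfg$mu + cfg$session_effects[idx$j] + b[idx$i] +
    s[cbind(idx$i, idx$j)] + e[as.matrix(idx)]
  value <- pmax(value, .Machine$double.eps)  # physical scores are nonnegative
  rec <- tibble::tibble(
    subject_id = subj[idx$i], session_id = cfg$sessions[idx$j],
    test = test, variable = cfg$variable, trial_index = as.integer(idx$t),
    value = value)
  ds <- trial_dataset(records = rec, session_order = cfg$sessions)
  list(dataset = ds, truth = truth_record(cfg))
}

#' @rdname generate_trials
#' @export
truth_record <- function(cfg) {
  k <- length(cfg$sessions)
  theta2 <- if (k > 1) var(cfg$session_effects) else 0
  sw2 <- cfg$sigma_interaction^2 + cfg$sigma_trial^2 / cfg$trials_per_session
  sb2 <- cfg$sigma_subject^2
  icc1 <- sb2 / (sb2 + theta2 + sw2)
  list(config = cfg,
       true_icc_single = icc1,
       true_icc_mean = spearman_brown(icc1, k),
       true_sem = sqrt(sb2 + sw2) * sqrt(1 - icc1),
       expected_session_means = setNames(cfg$mu + cfg$session_effects,
                                         cfg$sessions))
}

#' Configuration for the reactive-hop generator
#'
#' Hop-level contact times and peak forces follow the same additive
#' variance-components model on their own scales, at the subject-session
#' level, plus independent per-hop noise; the set summaries (peak force = max
#' over valid hops, ACT = mean over valid hops) then act as the session's two
#' trials. Each hop is independently invalidated (heel contact) with
#' probability `invalid_prob`; a set whose hops are all invalid is redrawn
#' with a logged note.
#'
#' @param n_subjects,sessions,seed As in [generator_config()].
#' @param n_sets Sets per session (default 2).
#' @param hops_per_set Hops per set (default 10).
#' @param invalid_prob Heel-contact probability per hop, in [0, 0.5].
#' @param force,contact_time Lists of model parameters for each outcome:
#'   `mu`, `sigma_subject`, `session_effects`, `sigma_interaction`,
#'   `sigma_hop` (per-hop noise SD).
#' @param center_subjects As in [generator_config()].
#' @return An object of class `hop_generator_config`.
#' @export
hop_generator_config <- function(n_subjects = 17,
                                 sessions = c("S1", "S2", "S3"),
                                 n_sets = 2, hops_per_set = 10,
                                 invalid_prob = 0.05,
                                 force = list(mu = 3.3, sigma_subject = 1,
                                              session_effects = c(0, 0.10, 0.33),
                                              sigma_interaction = 0.22,
                                              sigma_hop = 0.12),
                                 contact_time = list(mu = 0.180,
                                                     sigma_subject = 0.014,
                                                     session_effects = c(0, 0, 0),
                                                     sigma_interaction = 0.013,
                                                     sigma_hop = 0.02),
                                 center_subjects = FALSE, seed = 1L) {
  if (invalid_prob < 0 || invalid_prob > 0.5) {
    abort("invalid_prob must lie in [0, 0.5]", class = "relsens_config_error")
  }
  for (par in list(force, contact_time)) {
    if (length(par$session_effects) != length(sessions) ||
        any(c(par$sigma_subject, par$sigma_interaction, par$sigma_hop) < 0)) {
      abort("bad hop outcome parameters", class = "relsens_config_error")
    }
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 sessions = as.character(sessions),
                 n_sets = as.integer(n_sets),
                 hops_per_set = as.integer(hops_per_set),
                 invalid_prob = invalid_prob, force = force,
                 contact_time = contact_time,
                 center_subjects = center_subjects, seed = as.integer(seed)),
            class = "hop_generator_config")
}

#' Generate hop-level records
#'
#' @param cfg A [hop_generator_config()].
#' @return A [trial_dataset()] carrying hop records only (collapse with
#'   [collapse_hops()]).
#' @export
generate_hops <- function(cfg) {
  stopifnot(inherits(cfg, "hop_generator_config"))
  n <- cfg$n_subjects; k <- length(cfg$sessions)
  m <- cfg$n_sets * cfg$hops_per_set
  set.seed(substream_seed(cfg$seed, "reactive_hops"))
  latent <- function(par) {
    b <- rnorm(n, 0, par$sigma_subject)
    if (cfg$center_subjects && n > 1) b <- b - mean(b)
    s <- matrix(rnorm(n * k, 0, par$sigma_interaction), n, k)
    outer(b, rep(1, k)) + s + outer(rep(1, n), par$session_effects) + par$mu
  }
  lf <- latent(cfg$force)
  lt <- latent(cfg$contact_time)
  rows <- vector("list", n * k)
  subj <- sprintf("sub%02d", seq_len(n))
  r <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) {
    force <- lf[i, j] + rnorm(m, 0, cfg$force$sigma_hop)
    ct <- lt[i, j] + rnorm(m, 0, cfg$contact_time$sigma_hop)
    valid <- stats::runif(m) >= cfg$invalid_prob
    set_of <- rep(seq_len(cfg$n_sets), each = cfg$hops_per_set)
    for (st in seq_len(cfg$n_sets)) {
      while (!any(valid[set_of == st])) {
        log_note("redrawing all-invalid hop set (subject ", subj[i],
                 ", session ", cfg$sessions[j], ", set ", st, ")")
        valid[set_of == st] <- stats::runif(cfg$hops_per_set) >= cfg$invalid_prob
      }
    }
    r <- r + 1
    rows[[r]] <- tibble::tibble(
      subject_id = subj[i], session_id = cfg$sessions[j],
      set_index = set_of, hop_index = rep(seq_len(cfg$hops_per_set), cfg$n_sets),
      contact_time = pmax(ct, 1e-6), peak_force = pmax(force, 1e-6),
      valid = valid)
  }
  trial_dataset(records = NULL, hops = dplyr::bind_rows(rows),
                session_order = cfg$sessions)
}

#' Simulated nine-week study fixture
#'
#' A fixed-seed dataset emulating a 17-subject, three-session test-retest
#' study of four tests (isometric knee-extension MVC, handgrip MVC,
#' countermovement jump with jump height and peak power, and 2 x 10 reactive
#' hops): between-subject spreads and session means at the published scale of
#' the study the package's reference tables come from, trial noise placed so
#' session-level CVs land in the 2-8% band, a fixed learning shift on hop
#' peak force across sessions, and an interaction-dominated (low-ICC) regime
#' for hop contact time. Subject effects are centered so the cohort mean sits
#' at the published scale.
#'
#' @param seed Master seed (each variable uses its own substream).
#' @return A list with `dataset` (trial records for the four trial-based
#'   variables plus hop records) and `truth`, a list of truth records per
#'   variable (hop truths describe the latent subject-session level).
#' @export
simulated_study <- function(seed = 1L) {
  specs <- list(
    generator_config("peak_torque", mu = 256.2, sigma_subject = 90,
                     sigma_interaction = 12, sigma_trial = 16,
                     center_subjects = TRUE, seed = seed),
    generator_config("grip_force", mu = 45.5, sigma_subject = 12,
                     sigma_interaction = 1.0, sigma_trial = 1.5,
                     center_subjects = TRUE, seed = seed),
    generator_config("jump_height", mu = 44.2, sigma_subject = 10.5,
                     sigma_interaction = 0.9, sigma_trial = 1.3,
                     center_subjects = TRUE, seed = seed),
    generator_config("peak_power", mu = 46.7, sigma_subject = 10,
                     sigma_interaction = 0.8, sigma_trial = 1.2,
                     center_subjects = TRUE, seed = seed)
  )
  sims <- lapply(specs, generate_trials)
  ds <- Reduce(merge_datasets, lapply(sims, `[[`, "dataset"))
  hcfg <- hop_generator_config(center_subjects = TRUE, seed = seed)
  ds <- merge_datasets(ds, generate_hops(hcfg))
  truth <- lapply(sims, `[[`, "truth")
  names(truth) <- vapply(specs, `[[`, "", "variable")
  truth$reactive_hops <- list(config = hcfg)
  list(dataset = ds, truth = truth)
}

#' Parameter-recovery study for the ICC estimator
#'
#' Simulates repeated studies at known true single-measure ICCs (session-
#' average level), runs the full pipeline path (trial generation, session
#' aggregation, matrix construction, ICC with CI) on each replicate, and
#' summarizes estimator bias and 95% CI coverage. The within-subject
#' variance implied by each target ICC is split evenly between the
#' interaction and the trial-average component.
#'
#' @param true_icc Vector of target true ICC(A,1) values in (0, 1).
#' @param n_rep Replicates per target.
#' @param n_subjects,sessions,trials_per_session Study dimensions.
#' @param seed Master seed for the whole study.
#' @return A tibble with one row per target: `true_icc`, `n_rep`,
#'   `mean_estimate`, `bias`, `coverage`.
#' @export
recovery_study <- function(true_icc = c(0.5, 0.9, 0.97), n_rep = 500,
                           n_subjects = 17,
                           sessions = c("S1", "S2", "S3"),
                           trials_per_session = 3, seed = 1L) {
  stopifnot(all(true_icc > 0 & true_icc < 1), n_rep >= 1)
  set.seed(seed)
  out <- lapply(true_icc, function(rho) {
    w2 <- 1 / rho - 1  # within-subject variance at the score level
    res <- vapply(seq_len(n_rep), function(r) {
      cfg <- generator_config(
        "jump_height", n_subjects = n_subjects, sessions = sessions,
        trials_per_session = trials_per_session, mu = 10,
        sigma_subject = 1, sigma_interaction = sqrt(w2 / 2),
        sigma_trial = sqrt(trials_per_session * w2 / 2),
        seed = sample.int(.Machine$integer.max - 1, 1))
      sim <- generate_trials(cfg)
      sc <- session_scores(sim$dataset, "jump_height", "avg")
      ic <- icc(build_matrix(sc, sessions = sessions), "single")
      c(ic$estimate, ic$ci_low <= rho && rho <= ic$ci_high)
    }, numeric(2))
    tibble::tibble(true_icc = rho, n_rep = n_rep,
                   mean_estimate = mean(res[1, ]),
                   bias = mean(res[1, ]) - rho, coverage = mean(res[2, ]))
  })
  dplyr::bind_rows(out)
}

#' Serialize a truth record as a JSON sidecar
#'
#' @param truth A truth record (or list of them) from the generators.
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  invisible(path)
}
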