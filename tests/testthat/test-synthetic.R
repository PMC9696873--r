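test_that("the generator is deterministic under its seed", {
  cfg <- generator_config("jump_height", seed = 123)
  a <- generate_trials(cfg)
  b <- generate_trials(cfg)
  expect_identical(a$dataset$records, b$dataset$records)
  c_ <- generate_trials(generator_config("jump_height", seed = 124))
  expect_false(identical(a$dataset$records$value, c_$dataset$records$value))
})

test_that("variables draw from independent substreams", {
  jh1 <- generate_trials(generator_config("jump_height", seed = 9))
  # generating another variable in between must not perturb the stream
  invisible(generate_trials(generator_config("grip_force", seed = 9)))
  jh2 <- generate_trials(generator_config("jump_height", seed = 9))
  expect_identical(jh1$dataset$records, jh2$dataset$records)
  gf <- generate_trials(generator_config("grip_force", seed = 9))
  expect_false(identical(jh1$dataset$records$value,
                         gf$dataset$records$value))
})

test_that("noise-free data recover ICC of exactly 1", {
  cfg <- generator_config("grip_force", sigma_interaction = 0,
                          sigma_trial = 0, sigma_subject = 8, seed = 2)
  sim <- generate_trials(cfg)
  sc <- session_scores(sim$dataset, "grip_force", "avg")
  suppressMessages(ic <- icc(build_matrix(sc), "single"))
  expect_equal(ic$estimate, 1, tolerance = 1e-12)
  expect_equal(sim$truth$true_icc_single, 1)
})

test_that("the closed-form truth matches its variance components", {
  cfg <- generator_config("peak_torque", sigma_subject = 30,
                          sigma_interaction = 8, sigma_trial = 10,
                          trials_per_session = 3, seed = 1)
  tr <- truth_record(cfg)
  expect_equal(tr$true_icc_single, 900 / (900 + 64 + 100 / 3))
  expect_equal(round(tr$true_icc_single, 3), 0.902)
  expect_equal(tr$true_icc_mean,
               3 * tr$true_icc_single / (1 + 2 * tr$true_icc_single))
  # fixed session shifts enter the agreement denominator
  cfg2 <- generator_config("peak_torque", sigma_subject = 30,
                           sigma_interaction = 8, sigma_trial = 10,
                           session_effects = c(0, 10, 20), seed = 1)
  tr2 <- truth_record(cfg2)
  expect_equal(tr2$true_icc_single, 900 / (900 + 100 + 64 + 100 / 3))
  expect_lt(tr2$true_icc_single, tr$true_icc_single)
})

test_that("large-sample moments match the generating values", {
  cfg <- generator_config("jump_height", n_subjects = 2000, mu = 100,
                          sigma_subject = 30, sigma_interaction = 8,
                          sigma_trial = 10,
                          session_effects = c(0, 1, 3), seed = 1)
  sim <- generate_trials(cfg)
  sc <- session_scores(sim$dataset, "jump_height", "avg")
  Y <- build_matrix(sc, sessions = c("S1", "S2", "S3"))
  ms <- mean_squares(Y)
  sb_hat <- sqrt((ms$msr - ms$mse) / 3)
  expect_equal(sb_hat, 30, tolerance = 0.02)
  shifts <- colMeans(Y) - mean(colMeans(Y))
  centered_delta <- c(0, 1, 3) - mean(c(0, 1, 3))
  # session shifts recovered to within 2% of the grand mean's scale
  expect_lt(max(abs(shifts - centered_delta)), 0.02 * cfg$mu)
})

test_that("skewed trial noise keeps mean and SD but breaks normality at scale", {
  cfg <- generator_config("jump_height", n_subjects = 800, mu = 100,
                          sigma_subject = 0, sigma_interaction = 0,
                          sigma_trial = 5, trials_per_session = 1,
                          noise = "lognormal", seed = 6)
  sim <- generate_trials(cfg)
  v <- sim$dataset$records$value
  expect_lt(abs(mean(v) - 100), 0.75)
  # a heavy-tailed draw estimates its own SD noisily; only the scale is checked
  expect_equal(sd(v), 5, tolerance = 0.25)
  expect_lt(shapiro.test(v)$p.value, 0.05)
})

test_that("hop generation respects validity probabilities and set structure", {
  hops <- generate_hops(hop_generator_config(invalid_prob = 0, seed = 3))
  expect_true(all(hops$hops$valid))
  cnt <- dplyr::count(hops$hops, subject_id, session_id, set_index)
  expect_true(all(cnt$n == 10))
  expect_error(hop_generator_config(invalid_prob = 0.6),
               class = "relsens_config_error")
  big <- generate_hops(hop_generator_config(n_subjects = 60, seed = 4))
  valid_per_set <- dplyr::count(big$hops[big$hops$valid, ],
                                subject_id, session_id, set_index)
  expect_equal(mean(valid_per_set$n), 9.5, tolerance = 0.02)
})

test_that("the simulated study fixture sits at the published scale", {
  sim <- simulated_study(seed = 1)
  ds <- collapse_hops(sim$dataset)
  ke <- session_scores(ds, "peak_torque", "avg")
  Y <- build_matrix(ke, sessions = c("S1", "S2", "S3"))
  expect_equal(nrow(Y), 17)
  expect_lt(abs(mean(unclass(Y)[, "S1"]) - 256.2), 10)
  for (v in c("peak_torque", "grip_force", "jump_height", "peak_power")) {
    sc <- session_scores(ds, v, "avg")
    ic <- icc(build_matrix(sc), "mean")
    expect_gt(ic$estimate, 0.90)
  }
  act <- session_scores(ds, "hop_contact_time", "avg")
  ic_act <- icc(build_matrix(act), "single")
  expect_lt(ic_act$estimate, 0.75)
})

test_that("truth records serialize to a JSON sidecar", {
  sim <- generate_trials(generator_config("grip_force", seed = 12))
  path <- tempfile(fileext = ".json")
  write_truth(sim$truth, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$true_icc_single, sim$truth$true_icc_single)
})
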