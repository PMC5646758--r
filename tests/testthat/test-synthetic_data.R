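test_that("a fixed seed reproduces a cohort exactly", {
  cfg <- sim_config(n_participants = 3, trials_per_condition = 2, seed = 77)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1, c2)
  c3 <- simulate_cohort(sim_config(n_participants = 3, trials_per_condition = 2,
                                   seed = 78))
  expect_false(identical(c1$truth, c3$truth))
})

test_that("generated streams round-trip through CSV and pass stream invariants", {
  cfg <- sim_config(n_participants = 1, trials_per_condition = 1, seed = 5)
  co <- simulate_cohort(cfg)
  for (entry in c(co$participants[[1]]$ge_trials, co$participants[[1]]$fv_trials)) {
    st <- entry$trial$stream
    expect_true(all(diff(st$t) > 0))
    expect_equal(median(diff(st$t)), 2)
    path <- withr::local_tempfile(fileext = ".csv")
    write_gaze_csv(st, path)
    back <- read_gaze_csv(path)
    expect_equal(back$x, st$x, tolerance = 1e-8)
    expect_equal(back$valid, st$valid)
  }
})

test_that("latency generators bounded inside the window produce no latency exclusions", {
  cfg <- sim_config(seed = 9, latency_bounds_ms = c(80, 450), blink_rate = 0,
                    dropout_prob = 0)
  set.seed(900)
  reasons <- replicate(40, {
    sim <- simulate_ge_trial(cfg, participant_bias_deg = 1)
    ge_trial_statistic(sim$trial)$excluded_reason
  })
  expect_true(all(is.na(reasons)))
})

test_that("participant-level deviation bias is recovered through the raw pipeline", {
  cfg <- sim_config(seed = 11)
  set.seed(911)
  for (bias in c(0, 1.5)) {
    devs <- replicate(40, ge_trial_statistic(
      simulate_ge_trial(cfg, participant_bias_deg = bias)$trial)$deviation_deg)
    mc_se <- sd(devs, na.rm = TRUE) / sqrt(sum(!is.na(devs)))
    expect_lt(abs(mean(devs, na.rm = TRUE) - bias), 3 * mc_se)
  }
})

test_that("freeview dwell proportion is recovered through the raw pipeline", {
  cfg <- sim_config(seed = 12)
  set.seed(912)
  for (p in c(0.5, 0.57)) {
    props <- replicate(40, fv_trial_statistic(
      simulate_fv_trial(cfg, p)$trial)$proportion_social)
    mc_se <- sd(props, na.rm = TRUE) / sqrt(sum(!is.na(props)))
    expect_lt(abs(mean(props, na.rm = TRUE) - p), 3 * mc_se)
  }
})

test_that("summary mode matches the raw-stream statistical model", {
  # same generator model without kinematics: cohort grand means agree
  cfg_raw <- sim_config(n_participants = 12, trials_per_condition = 20, seed = 31)
  raw <- run_pipeline(simulate_cohort(cfg_raw, raw_streams = TRUE))
  cfg_sum <- sim_config(n_participants = 60, trials_per_condition = 40, seed = 32)
  summ <- run_pipeline(simulate_cohort(cfg_sum, raw_streams = FALSE))
  # both estimate the same truth; compare at 3 combined SEs
  for (field in c("test_unscrambled", "test_scrambled")) {
    se <- sqrt(raw$fv[[field]]$se^2 + summ$fv[[field]]$se^2)
    expect_lt(abs(raw$fv[[field]]$mean - summ$fv[[field]]$mean), 3 * se)
    se_ge <- sqrt(raw$ge[[field]]$se^2 + summ$ge[[field]]$se^2)
    expect_lt(abs(raw$ge[[field]]$mean - summ$ge[[field]]$mean), 3 * se_ge)
  }
})

test_that("EQ scores are integers on the 0-80 scale with configured missingness", {
  cfg <- sim_config(n_participants = 200, trials_per_condition = 1, seed = 41)
  co <- simulate_cohort(cfg, tasks = character(0))
  eq <- co$truth$eq_score
  expect_true(all(is.na(eq) | (eq == round(eq) & eq >= 0 & eq <= 80)))
  expect_lt(abs(mean(is.na(eq)) - cfg$eq_missing_prob), 0.08)
})

test_that("EQ-dwell correlation is recovered at the null and at 0.278 (summary mode)", {
  rs0 <- numeric(60); rs278 <- numeric(60)
  for (k in 1:60) {
    co0 <- simulate_cohort(sim_config(n_participants = 68, rho_eq_dwell = 0,
                                      eq_missing_prob = 0, seed = 5000 + k),
                           tasks = "fv", raw_streams = FALSE)
    rs0[k] <- run_pipeline(co0)$fv$eq_r_unscrambled$r
    co1 <- simulate_cohort(sim_config(n_participants = 68, rho_eq_dwell = 0.278,
                                      eq_missing_prob = 0, seed = 6000 + k),
                           tasks = "fv", raw_streams = FALSE)
    rs278[k] <- run_pipeline(co1)$fv$eq_r_unscrambled$r
  }
  expect_lt(abs(mean(rs0)), 3 * sd(rs0) / sqrt(60))
  expect_lt(abs(mean(rs278) - 0.278), 3 * sd(rs278) / sqrt(60))
})
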