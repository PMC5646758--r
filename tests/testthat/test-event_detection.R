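test_that("velocity trace is zero for constant position and exact for linear motion", {
  st <- gaze_stream(seq(0, 100, by = 2), rep(1, 51), rep(-1, 51))
  tr <- velocity_acceleration_trace(st)
  expect_true(all(tr$velocity[!is.na(tr$velocity)] == 0))

  # 0.1 deg per 2 ms sample -> 50 deg/s pointwise
  st2 <- gaze_stream(seq(0, 100, by = 2), seq(0, 5, by = 0.1), rep(0, 51))
  tr2 <- velocity_acceleration_trace(st2)
  mid <- 10:40
  expect_equal(tr2$velocity[mid], rep(50, length(mid)), tolerance = 1e-10)
})

test_that("trace refuses streams shorter than the differentiation window", {
  expect_error(velocity_acceleration_trace(gaze_stream(c(0, 2), 0:1, 0:1)),
               "at least 3")
})

test_that("peak velocity of an analytic Gaussian-profile saccade is recovered within 2%", {
  st <- gaussian_saccade_stream(vpeak = 300, sigma_ms = 12)
  tr <- velocity_acceleration_trace(st)
  expect_lt(abs(max(tr$velocity, na.rm = TRUE) - 300) / 300, 0.02)
})

test_that("slow fixational drift at 0.05 deg RMS yields no saccades", {
  set.seed(202)
  st <- smooth_fixation_stream(2000, rms = 0.05)
  expect_equal(nrow(detect_saccades(st)), 0)
})

test_that("a single 6-degree saccade is detected with endpoints within 0.25 deg", {
  # amplitude = vpeak * sigma * sqrt(2*pi): 300 deg/s peak, 6 deg amplitude
  sigma_ms <- 6 / (300 * sqrt(2 * pi)) * 1000
  st <- gaussian_saccade_stream(vpeak = 300, sigma_ms = sigma_ms, t0_ms = 200)
  sac <- detect_saccades(st)
  expect_equal(nrow(sac), 1)
  expect_lt(abs(sac$start_x - 0), 0.25)
  expect_lt(abs(sac$end_x - 6), 0.25)
  expect_lt(abs(sac$start_y), 0.25)
  expect_gte(sac$peak_velocity, 22)
})

test_that("an all-invalid stream yields no saccades and one blink", {
  st <- gaze_stream(seq(0, 100, by = 2), rep(NA_real_, 51), rep(NA_real_, 51),
                    valid = rep(FALSE, 51))
  expect_equal(nrow(detect_blinks(st)), 1)
  expect_error(detect_saccades(st), "valid")
})

test_that("a 5 s steady fixation parses as one ~5000 ms fixation", {
  st <- fixation_stream(5000)
  ev <- parse_events(st)
  expect_equal(nrow(ev$saccades), 0)
  expect_equal(nrow(ev$fixations), 1)
  expect_equal(ev$fixations$duration_ms, 5002)  # inclusive of both endpoints
  expect_equal(ev$fixations$centroid_x, 0)
})

test_that("the 32 ms minimum keeps 16-sample spans and drops 15-sample spans", {
  # valid span of exactly k samples at 500 Hz bracketed by blinks
  span_stream <- function(k) {
    n_pad <- 30
    t <- seq(0, (2 * n_pad + k - 1) * 2, by = 2)
    valid <- c(rep(FALSE, n_pad), rep(TRUE, k), rep(FALSE, n_pad))
    gaze_stream(t, ifelse(valid, 1, NA), ifelse(valid, 0, NA), valid)
  }
  cfg <- detection_config(blink_margin_ms = 0)
  f16 <- detect_fixations(span_stream(16), config = cfg)
  expect_equal(nrow(f16), 1)
  expect_equal(f16$duration_ms, 32)
  f15 <- detect_fixations(span_stream(15), config = cfg)
  expect_equal(nrow(f15), 0)
})

test_that("event spans partition the stream: no sample is in two events", {
  cfg <- sim_config(seed = 1)
  for (s in 1:5) {
    set.seed(300 + s)
    sim <- simulate_ge_trial(cfg, participant_bias_deg = 1)
    st <- sim$trial$stream
    ev <- parse_events(st)
    membership <- rep(0L, nrow(st))
    claim <- function(on, off) {
      idx <- which(st$t >= on & st$t <= off)
      membership[idx] <<- membership[idx] + 1L
    }
    if (nrow(ev$saccades)) for (k in seq_len(nrow(ev$saccades)))
      claim(ev$saccades$onset_ms[k], ev$saccades$offset_ms[k])
    if (nrow(ev$fixations)) for (k in seq_len(nrow(ev$fixations)))
      claim(ev$fixations$onset_ms[k], ev$fixations$offset_ms[k])
    if (nrow(ev$blinks)) for (k in seq_len(nrow(ev$blinks)))
      claim(ev$blinks$onset_ms[k], ev$blinks$offset_ms[k])
    expect_lte(max(membership), 1L)
  }
})

test_that("raising the velocity threshold never increases the saccade count", {
  cfg <- sim_config(seed = 1)
  set.seed(400)
  sim <- simulate_fv_trial(cfg, 0.6)
  st <- sim$trial$stream
  counts <- vapply(c(15, 22, 40, 80, 160), function(vth)
    nrow(detect_saccades(st, detection_config(velocity_threshold = vth))),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detected event boundaries match a brute-force per-sample scan", {
  set.seed(500)
  for (rep in 1:4) {
    # <= 200 samples: fixation, saccade, fixation (well separated, no blink)
    sigma <- runif(1, 8, 14)
    vpeak <- runif(1, 150, 400)
    st <- gaussian_saccade_stream(vpeak = vpeak, sigma_ms = sigma,
                                  t0_ms = 180, total_ms = 390)
    expect_lte(nrow(st), 200)
    got <- detect_saccades(st)
    want <- oracle_saccade_runs(st)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$onset_ms, want$onset_ms)
    expect_equal(got$offset_ms, want$offset_ms)
  }
})
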