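test_that("CSV round-trip preserves samples and dropout flags", {
  set.seed(101)
  st <- fixation_stream(100, pos = c(1.5, -2.25), jitter_sd = 0.1)
  st$valid[10:12] <- FALSE
  st$x[10:12] <- NA; st$y[10:12] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write_gaze_csv(st, path)
  back <- read_gaze_csv(path)
  expect_equal(back$t, st$t)
  expect_equal(back$valid, st$valid)
  expect_equal(back$x, st$x, tolerance = 1e-8)
  expect_equal(back$y, st$y, tolerance = 1e-8)
})

test_that("constant-center CSV yields valid samples at (0,0) deg", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t_ms,x,y", "0,0,0", "2,0,0", "4,0,0"), path)
  st <- read_gaze_csv(path)
  expect_s3_class(st, "gaze_stream")
  expect_equal(nrow(st), 3)
  expect_true(all(st$valid))
  expect_equal(st$x, c(0, 0, 0))
})

test_that("a row with missing x is flagged invalid without shortening the stream", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t_ms,x,y", "0,0,0", "2,,0", "4,0,0"), path)
  st <- read_gaze_csv(path)
  expect_equal(nrow(st), 3)
  expect_equal(st$valid, c(TRUE, FALSE, TRUE))
})

test_that("non-monotone timestamps are rejected", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t_ms,x,y", "0,0,0", "4,0,0", "2,0,0"), path)
  expect_error(read_gaze_csv(path), "monotone")
})

test_that("pixel-coded input maps through the visual-angle formula", {
  geom <- test_geometry()
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t_ms,x,y", "0,500,500", "2,700,500", "4,500,300"), path)
  st <- read_gaze_csv(path, units = "px", geometry = geom)
  expect_equal(st$x[1], 0); expect_equal(st$y[1], 0)
  # 200 px right of center at 0.5 mm/px, 1 m: atan(100/1000) rad
  expect_equal(st$x[2], atan(100 / 1000) * 180 / pi, tolerance = 1e-10)
  expect_equal(st$y[2], 0)
  # 200 px up (pixel y decreases upward in image coordinates)
  expect_equal(st$y[3], atan(100 / 1000) * 180 / pi, tolerance = 1e-10)
})

test_that("pixel-degree-pixel round trip is exact to < 0.01 px everywhere", {
  geom <- test_geometry()
  grid <- as.matrix(expand.grid(x = seq(0, 1000, by = 50),
                                y = seq(0, 1000, by = 50)))
  back <- deg_to_px(px_to_deg(grid, geom), geom)
  expect_lt(max(abs(back - grid)), 0.01)
})

test_that("ASC-like dialect honors blinks, dropout and the onset message", {
  geom <- test_geometry()
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(c(
    "MSG 10000 TRIALSTART",
    "10000 500 500 900",
    "10002 500 500 901",
    "MSG 10004 STIMULUS_ONSET",
    "10004 500 500 899",
    "10006 . . 0",
    "SBLINK R",
    "10008 500 500 0",
    "EBLINK R",
    "10010 700 500 900"), path)
  st <- read_gaze_asc(path, geom)
  expect_equal(st$t, c(-4, -2, 0, 2, 4, 6))
  expect_equal(st$valid, c(TRUE, TRUE, TRUE, FALSE, FALSE, TRUE))
  expect_equal(st$x[6], atan(100 / 1000) * 180 / pi, tolerance = 1e-10)
})

test_that("ASC parser reports the offending line", {
  geom <- test_geometry()
  path <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("10000 500 500 900", "??bad 1 2 3"), path)
  expect_error(read_gaze_asc(path, geom), "line 2")
})

test_that("exclusion log arithmetic reconciles with its inputs", {
  none <- exclusion_log(data.frame(), 80, 1)
  expect_equal(none$n_trials_excluded, 0)
  expect_equal(none$percent_trials_excluded, 0)

  ex <- data.frame(participant = rep("P1", 5), unit = "trial",
                   reason = "latency")
  log5 <- exclusion_log(ex, 80, 1)
  expect_equal(log5$percent_trials_excluded, 6.25)

  # 92 trial exclusions over 67 participants -> mean 1.373 per participant
  ex92 <- data.frame(participant = sprintf("P%02d", (1:92) %% 67 + 1),
                     unit = "trial", reason = "latency")
  log92 <- exclusion_log(ex92, 5360, 67)
  expect_equal(round(log92$mean_trials_excluded_per_participant, 3), 1.373)
  expect_equal(round(log92$percent_trials_excluded, 3), 1.716)

  path <- withr::local_tempfile(fileext = ".txt")
  exclusion_log(ex92, 5360, 67, path = path)
  expect_true(any(grepl("1.373", readLines(path), fixed = TRUE)))
})

test_that("YAML config carries detection defaults and geometry", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("detection:",
               "  velocity_threshold: 30",
               "geometry:",
               "  resolution_px: [800, 600]",
               "  viewing_distance_m: 1",
               "  pixel_pitch_mm: 0.4"), path)
  cfg <- read_config(path)
  expect_equal(cfg$detection$velocity_threshold, 30)
  expect_equal(cfg$detection$acceleration_threshold, 8000)  # default kept
  expect_equal(cfg$geometry$resolution_px, c(800, 600))
})
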