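# fixation with slow (low-pass) drift of a given RMS amplitude, emulating
# ocular drift rather than white sensor noise
smooth_fixation_stream <- function(duration_ms = 1000, pos = c(0, 0),
                                   rms = 0.05, k = 50, rate_hz = 500,
                                   t_start = 0) {
  t <- seq(t_start, t_start + duration_ms, by = 1000 / rate_hz)
  n <- length(t)
  drift <- function() {
    w <- rnorm(n + k - 1)
    as.numeric(stats::filter(w, rep(1 / k, k), sides = 1))[k:(n + k - 1)] *
      rms * sqrt(k)
  }
  gaze_stream(t, pos[1] + drift(), pos[2] + drift(), nominal_rate_hz = rate_hz)
}

# default geometry used in IO tests: square pixels, values chosen so the
# conversion trig is exercised away from the small-angle regime
test_geometry <- function() screen_geometry(c(1000, 1000), 1, 0.5)

# quick constructor for a one-row saccade record
saccade_row <- function(x0, y0, x1, y1, onset = 100, offset = 140) {
  data.frame(onset_ms = onset, offset_ms = offset, start_x = x0, start_y = y0,
             end_x = x1, end_y = y1,
             amplitude_deg = sqrt((x1 - x0)^2 + (y1 - y0)^2),
             peak_velocity = 300, latency_ms = onset)
}
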