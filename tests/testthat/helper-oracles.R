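# Independent oracles coded from first principles; these deliberately avoid
# the package's internal helpers so a defect cannot cancel out.

# Brute-force saccade labeling: explicit per-sample loops computing central
# differences, 3-sample speed smoothing and threshold labels, then merging
# consecutive labeled samples into runs.  Valid only for simple streams
# (no blinks, events separated by > the merge gap).
oracle_saccade_runs <- function(stream, vth = 22, ath = 8000) {
  t <- stream$t; x <- stream$x; y <- stream$y
  n <- length(t)
  v <- rep(NA_real_, n)
  for (i in 2:(n - 1)) {
    dt <- (t[i + 1] - t[i - 1]) / 1000
    v[i] <- sqrt(((x[i + 1] - x[i - 1]) / dt)^2 + ((y[i + 1] - y[i - 1]) / dt)^2)
  }
  vs <- rep(NA_real_, n)
  for (i in 2:(n - 1)) {
    nb <- c(v[i - 1], v[i], v[i + 1])
    vs[i] <- mean(nb[!is.na(nb)])
  }
  a <- rep(NA_real_, n)
  for (i in 3:(n - 2))
    a[i] <- (vs[i + 1] - vs[i - 1]) / ((t[i + 1] - t[i - 1]) / 1000)
  lab <- logical(n)
  for (i in seq_len(n)) {
    lab[i] <- (!is.na(vs[i]) && vs[i] >= vth) ||
      (!is.na(a[i]) && abs(a[i]) >= ath)
  }
  runs <- NULL
  i <- 1
  while (i <= n) {
    if (lab[i]) {
      j <- i
      while (j < n && lab[j + 1]) j <- j + 1
      runs <- rbind(runs, data.frame(onset_ms = t[i], offset_ms = t[j]))
      i <- j + 1
    } else i <- i + 1
  }
  if (is.null(runs)) data.frame(onset_ms = numeric(0), offset_ms = numeric(0))
  else runs
}

# Independent coding of the pooled-r Fisher Z test for dependent
# correlations sharing one variable.
oracle_steiger_z <- function(r_jk, r_jh, r_kh, n) {
  fisher <- function(r) 0.5 * log((1 + r) / (1 - r))
  rb <- mean(c(r_jk, r_jh))
  num <- r_kh * (1 - rb^2 - rb^2) - 0.5 * rb^2 * (1 - rb^2 - rb^2 - r_kh^2)
  cov_z <- num / (1 - rb^2)^2
  (fisher(r_jk) - fisher(r_jh)) / sqrt((2 - 2 * cov_z) / (n - 3))
}

# Gaussian-velocity-profile saccade along +x with analytic positions:
# v(t) = vpeak * exp(-(t - t0)^2 / (2 sigma^2)),
# x(t) = vpeak * sigma * sqrt(2*pi) * pnorm((t - t0) / sigma).
# Amplitude = vpeak * sigma * sqrt(2*pi).
gaussian_saccade_stream <- function(vpeak = 300, sigma_ms = 12, t0_ms = 200,
                                    total_ms = 600, rate_hz = 500) {
  t <- seq(0, total_ms, by = 1000 / rate_hz)
  sigma_s <- sigma_ms / 1000
  x <- vpeak * sigma_s * sqrt(2 * pi) * pnorm((t - t0_ms) / sigma_ms)
  gaze_stream(t, x, rep(0, length(t)), nominal_rate_hz = rate_hz)
}

# steady fixation with optional white jitter
fixation_stream <- function(duration_ms = 1000, pos = c(0, 0), jitter_sd = 0,
                            rate_hz = 500, t_start = 0) {
  t <- seq(t_start, t_start + duration_ms, by = 1000 / rate_hz)
  n <- length(t)
  gaze_stream(t, pos[1] + rnorm(n, 0, jitter_sd),
              pos[2] + rnorm(n, 0, jitter_sd), nominal_rate_hz = rate_hz)
}
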