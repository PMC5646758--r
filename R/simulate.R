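#' Simulation configuration for synthetic gaze cohorts
#'
#' Parameters of the synthetic 500 Hz gaze generator.  Defaults reproduce
#' the study design both tasks share (40 trials per scramble condition, 6
#' deg target eccentricity, 5 s freeview trials) and are anchored to the
#' cohort-level quantities the tasks are known to produce: mean first-
#' saccade deviation 1.433 deg toward social images for unscrambled stimuli
#' (about 0 for scrambled), mean social dwell proportion 0.57 (0.523
#' scrambled), an EQ-dwell correlation of 0.278, and a first-saccade
#' latency distribution whose tails outside the 70-500 ms window discard
#' about 1.7% of trials.  Between-participant SDs are solved so that the
#' SD of participant means matches the cohort values (1.395 / 0.913 deg for
#' deviation, 0.092 / 0.046 for dwell proportion) once the per-trial noise
#' contribution at 40 trials is added.
#'
#' @param n_participants cohort size (67 completed the saccade task with
#'   usable data, 76 the freeview task).
#' @param trials_per_condition trials per scramble condition (default 40).
#' @param true_deviation_deg length-2 named vector, mean deviation bias in
#'   deg for `unscrambled` and `scrambled` stimuli.
#' @param deviation_between_sd between-participant SD of the deviation bias
#'   per condition, deg.
#' @param deviation_trial_sd within-participant trial-to-trial angular
#'   noise SD, deg.
#' @param true_dwell_proportion mean social dwell proportion per condition.
#' @param dwell_between_sd between-participant SD of the dwell proportion
#'   per condition.
#' @param dwell_trial_kappa concentration of the beta-distributed per-trial
#'   dwell bias around the participant proportion.
#' @param eq_mean,eq_sd Empathy Quotient distribution (0-80 integer scale).
#' @param rho_eq_dwell target pipeline-level correlation between EQ and the
#'   unscrambled dwell proportion.
#' @param rho_eq_dwell_scrambled same for scrambled stimuli (default 0).
#' @param eq_missing_prob probability a participant has no EQ score.
#' @param latency_mean_ms,latency_sd_ms,latency_bounds_ms first-saccade
#'   latency: truncated normal parameters, ms.
#' @param fixation_jitter_sd_deg RMS amplitude of slow fixational drift.
#' @param blink_rate probability of one blink per trial.
#' @param dropout_prob per-sample probability of sporadic tracker loss.
#' @param sample_rate_hz sampling rate (default 500).
#' @param ge_trial_duration_ms,ge_pre_onset_ms saccade-task stream extent.
#' @param fv_trial_duration_ms freeview trial duration (default 5000).
#' @param fixation_meanlog,fixation_sdlog,fixation_min_ms lognormal
#'   freeview fixation-duration model, ms.
#' @param target_eccentricity_deg saccade-target eccentricity (default 6).
#' @param seed integer seed; mandatory, every draw flows from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_participants = 76,
                       trials_per_condition = 40,
                       true_deviation_deg = c(unscrambled = 1.433, scrambled = 0),
                       deviation_between_sd = c(unscrambled = 1.24, scrambled = 0.65),
                       deviation_trial_sd = 4,
                       true_dwell_proportion = c(unscrambled = 0.57, scrambled = 0.523),
                       dwell_between_sd = c(unscrambled = 0.088, scrambled = 0.038),
                       dwell_trial_kappa = 50,
                       eq_mean = 40, eq_sd = 12,
                       rho_eq_dwell = 0.278,
                       rho_eq_dwell_scrambled = 0,
                       eq_missing_prob = 0.1,
                       latency_mean_ms = 230, latency_sd_ms = 75,
                       latency_bounds_ms = c(10, 600),
                       fixation_jitter_sd_deg = 0.05,
                       blink_rate = 0.05,
                       dropout_prob = 5e-5,
                       sample_rate_hz = 500,
                       ge_trial_duration_ms = 1000,
                       ge_pre_onset_ms = 200,
                       fv_trial_duration_ms = 5000,
                       fixation_meanlog = log(280), fixation_sdlog = 0.4,
                       fixation_min_ms = 100,
                       target_eccentricity_deg = 6,
                       seed) {
  stopifnot(n_participants >= 1, trials_per_condition >= 1,
            all(true_dwell_proportion > 0 & true_dwell_proportion < 1),
            deviation_trial_sd >= 0, dwell_trial_kappa > 0,
            blink_rate >= 0, dropout_prob >= 0, sample_rate_hz > 0,
            abs(rho_eq_dwell) < 1, abs(rho_eq_dwell_scrambled) < 1)
  if (missing(seed)) stop("sim_config: a seed is mandatory")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# inverse-CDF truncated normal draw
.trunc_norm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# slow fixational drift: moving-average-filtered white noise rescaled to
# RMS = sd (window 50 samples ~ 4 Hz bandwidth at 500 Hz)
.smooth_jitter <- function(n, sd, k = 50) {
  if (sd == 0 || n == 0) return(numeric(n))
  w <- stats::rnorm(n + k - 1)
  j <- as.numeric(stats::filter(w, rep(1 / k, k), sides = 1))[k:(n + k - 1)]
  j * sd * sqrt(k)
}

# minimum-jerk displacement fraction at normalized time tau in [0,1]
.minjerk_s <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

# main-sequence saccade duration, ms
.saccade_duration_ms <- function(amplitude_deg) 2.2 * amplitude_deg + 21

#' Simulate one global-effect trial
#'
#' Builds a raw 500 Hz stream: fixational drift at the origin through the
#' pre-onset period and the saccade latency, a single minimum-jerk saccade
#' whose direction is rotated away from the direct origin-target path by the
#' trial's true deviation (participant bias plus trial noise, rotated
#' toward the social image for positive values), then fixation at the
#' landing point.  An optional blink and sporadic dropout are superimposed
#' after the primary saccade.
#'
#' @param config a [sim_config()].
#' @param participant_bias_deg the participant's true mean deviation, deg.
#' @param target_side,social_position,scrambled trial layout.
#' @param deviation_deg override the drawn trial deviation (used to pin
#'   exact ground truth in tests).
#' @param latency_ms override the drawn latency.
#' @return list with `trial` (a [ge_trial()]) and `truth` (list with
#'   `deviation_deg`, `latency_ms`).
#' @export
simulate_ge_trial <- function(config, participant_bias_deg = 0,
                              target_side = "right", social_position = "top",
                              scrambled = FALSE, deviation_deg = NULL,
                              latency_ms = NULL) {
  if (is.null(deviation_deg))
    deviation_deg <- participant_bias_deg +
      stats::rnorm(1, 0, config$deviation_trial_sd)
  if (is.null(latency_ms))
    latency_ms <- .trunc_norm(1, config$latency_mean_ms, config$latency_sd_ms,
                              config$latency_bounds_ms[1],
                              config$latency_bounds_ms[2])
  ecc <- config$target_eccentricity_deg
  sgn_x <- if (target_side == "right") 1 else -1
  target <- c(sgn_x * ecc, 0)
  # rotation moving the endpoint toward the social image by deviation_deg
  up_for_positive <- (social_position == "top")
  ccw_is_up <- (target_side == "right")
  phi <- deviation_deg * (if (up_for_positive) 1 else -1) *
    (if (ccw_is_up) 1 else -1) * pi / 180
  landing <- c(cos(phi) * target[1] - sin(phi) * target[2],
               sin(phi) * target[1] + cos(phi) * target[2])
  # amplitude jitter along the saccade direction (angle-preserving)
  landing <- landing * (1 + stats::rnorm(1, 0, 0.03))

  dt <- 1000 / config$sample_rate_hz
  t <- seq(-config$ge_pre_onset_ms, config$ge_trial_duration_ms, by = dt)
  n <- length(t)
  sdur <- .saccade_duration_ms(sqrt(sum(landing^2)))
  s <- .minjerk_s((t - latency_ms) / sdur)
  x <- landing[1] * s + .smooth_jitter(n, config$fixation_jitter_sd_deg)
  y <- landing[2] * s + .smooth_jitter(n, config$fixation_jitter_sd_deg)

  valid <- rep(TRUE, n)
  if (stats::runif(1) < config$blink_rate) {
    b0 <- latency_ms + sdur + 150 + stats::runif(1, 0, 200)
    valid[t >= b0 & t <= b0 + 100] <- FALSE
  }
  valid[stats::runif(n) < config$dropout_prob] <- FALSE

  stream <- gaze_stream(t, x, y, valid, config$sample_rate_hz)
  list(trial = ge_trial(stream, target_side, social_position, scrambled,
                        target_eccentricity_deg = ecc),
       truth = list(deviation_deg = deviation_deg, latency_ms = latency_ms))
}

# freeview fixation schedule: durations, sides and within-AOI positions
.fv_schedule <- function(config, p_trial) {
  total <- config$fv_trial_duration_ms
  # initial fixation on the former cross location
  dur <- c(stats::runif(1, 200, 300))
  side <- c(NA)  # center
  while (sum(dur) < total) {
    d <- max(config$fixation_min_ms,
             stats::rlnorm(1, config$fixation_meanlog, config$fixation_sdlog))
    dur <- c(dur, d)
    side <- c(side, stats::runif(1) < p_trial)  # TRUE = social
  }
  list(dur = dur, side = side)
}

#' Simulate one freeview trial
#'
#' Builds a raw 500 Hz stream of alternating fixations on the left and
#' right image regions over the 5 s presentation.  The trial's dwell bias
#' is a beta draw around the participant's true proportion (concentration
#' `dwell_trial_kappa`); each fixation is assigned to the social image with
#' that probability, lands uniformly inside the image with fixational
#' drift, and fixations are joined by minimum-jerk saccades.  Expected
#' social share of dwell time equals the participant proportion.
#'
#' @param config a [sim_config()].
#' @param participant_proportion the participant's true social dwell
#'   proportion in \[0, 1\].
#' @param social_side,scrambled trial layout.
#' @return list with `trial` (an [fv_trial()]) and `truth` (list with
#'   `p_trial`).
#' @export
simulate_fv_trial <- function(config, participant_proportion = 0.5,
                              social_side = "left", scrambled = FALSE) {
  p <- participant_proportion
  p_trial <- if (p <= 0 || p >= 1) p else
    stats::rbeta(1, config$dwell_trial_kappa * p,
                 config$dwell_trial_kappa * (1 - p))
  sched <- .fv_schedule(config, p_trial)

  # AOI geometry from a template trial
  dt <- 1000 / config$sample_rate_hz
  t <- seq(0, config$fv_trial_duration_ms - dt, by = dt)
  template <- fv_trial(gaze_stream(0:2, c(0, 0, 0), c(0, 0, 0)),
                       social_side, scrambled)
  aoi_of <- function(is_social) {
    left_is_social <- social_side == "left"
    if (is.na(is_social)) return(NULL)  # center
    if (xor(is_social, !left_is_social)) template$aoi_left else template$aoi_right
  }
  fix_pos <- t(vapply(sched$side, function(s) {
    a <- aoi_of(s)
    if (is.null(a)) return(c(0, 0))
    c(stats::runif(1, a[1] + 0.5, a[2] - 0.5),
      stats::runif(1, a[3] + 0.5, a[4] - 0.5))
  }, numeric(2)))

  # piecewise path: fixation k, then min-jerk saccade to fixation k+1
  x <- numeric(length(t)); y <- numeric(length(t))
  t0 <- 0
  for (k in seq_along(sched$dur)) {
    t1 <- t0 + sched$dur[k]
    in_fix <- t >= t0 & t < t1
    x[in_fix] <- fix_pos[k, 1]; y[in_fix] <- fix_pos[k, 2]
    if (k < length(sched$dur)) {
      amp <- sqrt(sum((fix_pos[k + 1, ] - fix_pos[k, ])^2))
      sdur <- .saccade_duration_ms(amp)
      in_sac <- t >= t1 & t < t1 + sdur
      s <- .minjerk_s((t[in_sac] - t1) / sdur)
      x[in_sac] <- fix_pos[k, 1] + (fix_pos[k + 1, 1] - fix_pos[k, 1]) * s
      y[in_sac] <- fix_pos[k, 2] + (fix_pos[k + 1, 2] - fix_pos[k, 2]) * s
      t0 <- t1 + sdur
    }
  }
  n <- length(t)
  x <- x + .smooth_jitter(n, config$fixation_jitter_sd_deg)
  y <- y + .smooth_jitter(n, config$fixation_jitter_sd_deg)

  valid <- rep(TRUE, n)
  if (stats::runif(1) < config$blink_rate) {
    b0 <- stats::runif(1, 500, config$fv_trial_duration_ms - 700)
    valid[t >= b0 & t <= b0 + 100] <- FALSE
  }
  valid[stats::runif(n) < config$dropout_prob] <- FALSE

  stream <- gaze_stream(t, x, y, valid, config$sample_rate_hz)
  list(trial = fv_trial(stream, social_side, scrambled),
       truth = list(p_trial = p_trial))
}

# summary-mode draws: same statistical model, no kinematics ------------------

# the generator does not know the analysis config; summary mode applies the
# standard 70/500 ms window for its exclusion draw
.ge_summary_window <- c(70, 500)

.draw_fv_trial_summary <- function(config, p) {
  p_trial <- if (p <= 0 || p >= 1) p else
    stats::rbeta(1, config$dwell_trial_kappa * p,
                 config$dwell_trial_kappa * (1 - p))
  sched <- .fv_schedule(config, p_trial)
  keep <- !is.na(sched$side)
  dur <- sched$dur[keep]; social <- as.logical(sched$side[keep])
  social_proportion(sum(dur[social]), sum(dur[!social]))
}

#' Simulate a full cohort with ground truth
#'
#' Draws a cohort of participants — EQ scores (rounded, 0-80), per-condition
#' dwell proportions and deviation biases with the configured between-
#' participant spread and EQ-dwell correlation (Gaussian copula; the latent
#' correlation is inflated by the analytically estimated trial-noise
#' attenuation so the pipeline-level correlation hits `rho_eq_dwell`) —
#' and generates their trials for one or both tasks.  Layout factors
#' (target side, social position/side, scramble) are counterbalanced within
#' participant.  Ground truth is returned alongside the data so recovery
#' can be tested at every level.
#'
#' @param config a [sim_config()]; its `seed` drives every draw.
#' @param tasks subset of `c("ge", "fv")`.
#' @param raw_streams if TRUE (default) every trial carries a raw 500 Hz
#'   [gaze_stream()]; if FALSE, trials carry per-trial statistics drawn
#'   from the identical statistical model without kinematics (fast mode
#'   for many-replicate calibration studies).
#' @return A `gaze_cohort`: list with `participants` (each a list with
#'   `id`, `eq_score`, `ge_trials`, `fv_trials`), `truth` (data.frame of
#'   per-participant true parameters), `raw_streams`, `config`.
#' @export
simulate_cohort <- function(config, tasks = c("ge", "fv"),
                            raw_streams = TRUE) {
  set.seed(config$seed)
  np <- config$n_participants
  ntc <- config$trials_per_condition

  # latent Gaussian copula for (EQ, dwell_unscr, dwell_scr)
  att_u <- .dwell_attenuation(config, "unscrambled")
  att_s <- .dwell_attenuation(config, "scrambled")
  rho_u <- min(config$rho_eq_dwell / att_u, 0.99)
  rho_s <- min(config$rho_eq_dwell_scrambled / att_s, 0.99)
  z_eq <- stats::rnorm(np)
  z_u <- rho_u * z_eq + sqrt(1 - rho_u^2) * stats::rnorm(np)
  z_s <- rho_s * z_eq + sqrt(1 - rho_s^2) * stats::rnorm(np)

  eq <- round(pmin(pmax(config$eq_mean + config$eq_sd * z_eq, 0), 80))
  eq[stats::runif(np) < config$eq_missing_prob] <- NA
  p_u <- pmin(pmax(config$true_dwell_proportion[["unscrambled"]] +
                     config$dwell_between_sd[["unscrambled"]] * z_u, 0.02), 0.98)
  p_s <- pmin(pmax(config$true_dwell_proportion[["scrambled"]] +
                     config$dwell_between_sd[["scrambled"]] * z_s, 0.02), 0.98)
  bias_u <- stats::rnorm(np, config$true_deviation_deg[["unscrambled"]],
                         config$deviation_between_sd[["unscrambled"]])
  bias_s <- stats::rnorm(np, config$true_deviation_deg[["scrambled"]],
                         config$deviation_between_sd[["scrambled"]])

  participants <- vector("list", np)
  for (i in seq_len(np)) {
    part <- list(id = sprintf("P%03d", i), eq_score = eq[i],
                 ge_trials = NULL, fv_trials = NULL)
    if ("ge" %in% tasks)
      part$ge_trials <- .simulate_ge_trials(config, ntc, bias_u[i], bias_s[i],
                                            raw_streams)
    if ("fv" %in% tasks)
      part$fv_trials <- .simulate_fv_trials(config, ntc, p_u[i], p_s[i],
                                            raw_streams)
    participants[[i]] <- part
  }
  structure(list(participants = participants,
                 truth = data.frame(id = sprintf("P%03d", seq_len(np)),
                                    eq_score = eq,
                                    dwell_unscrambled = p_u,
                                    dwell_scrambled = p_s,
                                    deviation_unscrambled = bias_u,
                                    deviation_scrambled = bias_s),
                 raw_streams = raw_streams, config = config),
            class = "gaze_cohort")
}

# expected attenuation of a participant-level dwell correlation caused by
# trial noise at n trials: between_sd / SD of measured participant means.
# Trial variance ~ beta noise + duration-weighted assignment noise with an
# effective fixation count of ~12 per 5 s trial.
.dwell_attenuation <- function(config, cond) {
  p <- config$true_dwell_proportion[[cond]]
  b <- config$dwell_between_sd[[cond]]
  trial_var <- p * (1 - p) * (1 / (config$dwell_trial_kappa + 1) + 1 / 12)
  b / sqrt(b^2 + trial_var / config$trials_per_condition)
}

.simulate_ge_trials <- function(config, ntc, bias_u, bias_s, raw_streams) {
  layout <- expand.grid(target_side = c("left", "right"),
                        social_position = c("top", "bottom"),
                        stringsAsFactors = FALSE)
  out <- list()
  for (scrambled in c(FALSE, TRUE)) {
    bias <- if (scrambled) bias_s else bias_u
    for (k in seq_len(ntc)) {
      lay <- layout[(k - 1) %% nrow(layout) + 1, ]
      if (raw_streams) {
        sim <- simulate_ge_trial(config, bias, lay$target_side,
                                 lay$social_position, scrambled)
        out[[length(out) + 1]] <- list(trial = sim$trial, truth = sim$truth,
                                       scrambled = scrambled)
      } else {
        deviation <- bias + stats::rnorm(1, 0, config$deviation_trial_sd)
        latency <- .trunc_norm(1, config$latency_mean_ms, config$latency_sd_ms,
                               config$latency_bounds_ms[1],
                               config$latency_bounds_ms[2])
        excluded <- latency < .ge_summary_window[1] |
          latency > .ge_summary_window[2]
        out[[length(out) + 1]] <- list(
          deviation_deg = if (excluded) NA_real_ else deviation,
          latency_ms = latency,
          excluded_reason = if (excluded) "latency" else NA_character_,
          scrambled = scrambled)
      }
    }
  }
  out
}

.simulate_fv_trials <- function(config, ntc, p_u, p_s, raw_streams) {
  out <- list()
  for (scrambled in c(FALSE, TRUE)) {
    p <- if (scrambled) p_s else p_u
    for (k in seq_len(ntc)) {
      side <- if (k %% 2 == 0) "left" else "right"
      if (raw_streams) {
        sim <- simulate_fv_trial(config, p, side, scrambled)
        out[[length(out) + 1]] <- list(trial = sim$trial, truth = sim$truth,
                                       scrambled = scrambled)
      } else {
        out[[length(out) + 1]] <- list(
          proportion_social = .draw_fv_trial_summary(config, p),
          scrambled = scrambled)
      }
    }
  }
  out
}
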