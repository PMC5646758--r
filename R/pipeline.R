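#' Run the full analysis pipeline on a cohort
#'
#' Orchestrates the complete analysis for one or both tasks: per-trial
#' event detection and metrics (first-saccade deviation angle; social dwell
#' proportion), the latency and capture-rate exclusion rules, participant
#' summaries, and the cohort-level inferential statistics — one-sample t
#' tests of the mean deviation against 0 and of the dwell proportion
#' against 0.5 (per scramble condition, with Cohen's d), the paired
#' unscrambled-vs-scrambled comparison, Cousineau within-subject standard
#' errors, Pearson correlations with trait empathy (EQ) on the
#' complete-case subset, and Steiger's Z comparing the two dependent
#' EQ-dwell correlations.  All tests are two-tailed and no multiple-testing
#' correction is applied; the result records how many tests were run.
#'
#' Accepts cohorts with raw gaze streams (each trial re-analyzed from
#' samples) or summary-mode cohorts carrying per-trial statistics.
#'
#' @param cohort a `gaze_cohort` from [simulate_cohort()], or any list with
#'   the same shape built from ingested data.
#' @param config a [detection_config()].
#' @return A `cohort_result` list with elements `ge`, `fv` (NULL when the
#'   task is absent), each holding participant tables, per-condition tests,
#'   paired test, EQ correlations (and for `fv` the Steiger comparison),
#'   Cousineau SEs; plus `exclusions` (audit) and `n_tests`.
#' @export
run_pipeline <- function(cohort, config = detection_config()) {
  participants <- cohort$participants
  if (length(participants) == 0) stop("run_pipeline: empty cohort")
  raw <- isTRUE(cohort$raw_streams)
  excl <- data.frame(participant = character(0), unit = character(0),
                     reason = character(0), stringsAsFactors = FALSE)
  n_tests <- 0L

  has_ge <- !is.null(participants[[1]]$ge_trials)
  has_fv <- !is.null(participants[[1]]$fv_trials)

  ge <- NULL
  if (has_ge) {
    ptab <- list()
    for (p in participants) {
      dev <- vapply(p$ge_trials, function(e) {
        if (raw) {
          st <- ge_trial_statistic(e$trial, config)
          if (!is.na(st$excluded_reason))
            excl <<- rbind(excl, data.frame(participant = p$id, unit = "trial",
                                            reason = st$excluded_reason))
          st$deviation_deg
        } else {
          if (!is.na(e$excluded_reason))
            excl <<- rbind(excl, data.frame(participant = p$id, unit = "trial",
                                            reason = e$excluded_reason))
          e$deviation_deg
        }
      }, numeric(1))
      scr <- vapply(p$ge_trials, function(e) e$scrambled, logical(1))
      s <- summarize_ge_participant(dev, scr, config)
      if (!s$included)
        excl <- rbind(excl, data.frame(participant = p$id, unit = "participant",
                                       reason = s$excluded_reason))
      ptab[[length(ptab) + 1]] <- data.frame(
        id = p$id, eq_score = p$eq_score,
        mean_deviation_unscrambled = s$mean_deviation_unscrambled,
        mean_deviation_scrambled = s$mean_deviation_scrambled,
        captured_fraction_unscrambled = s$captured_fraction_unscrambled,
        captured_fraction_scrambled = s$captured_fraction_scrambled,
        included = s$included)
    }
    ptab <- do.call(rbind, ptab)
    inc <- ptab[ptab$included, , drop = FALSE]
    if (nrow(inc) == 0) stop("run_pipeline: no participants survive GE exclusions")
    ge <- list(
      participants = ptab,
      n_included = nrow(inc),
      test_unscrambled = one_sample_t(inc$mean_deviation_unscrambled, 0),
      test_scrambled = one_sample_t(inc$mean_deviation_scrambled, 0),
      test_paired = paired_t(inc$mean_deviation_unscrambled,
                             inc$mean_deviation_scrambled),
      cousineau_se = cousineau_se(cbind(
        unscrambled = inc$mean_deviation_unscrambled,
        scrambled = inc$mean_deviation_scrambled)),
      eq_r_unscrambled = .maybe_cor(inc$eq_score, inc$mean_deviation_unscrambled),
      eq_r_scrambled = .maybe_cor(inc$eq_score, inc$mean_deviation_scrambled))
    n_tests <- n_tests + 3L +
      (!is.null(ge$eq_r_unscrambled)) + (!is.null(ge$eq_r_scrambled))
  }

  fv <- NULL
  if (has_fv) {
    ptab <- list()
    for (p in participants) {
      prop <- vapply(p$fv_trials, function(e) {
        if (raw) fv_trial_statistic(e$trial, config)$proportion_social
        else e$proportion_social
      }, numeric(1))
      scr <- vapply(p$fv_trials, function(e) e$scrambled, logical(1))
      miss <- sum(is.na(prop))
      if (miss > 0)
        excl <- rbind(excl, data.frame(participant = rep(p$id, miss),
                                       unit = "trial", reason = "no_aoi_gaze"))
      s <- summarize_fv_participant(prop, scr, config)
      if (!s$included)
        excl <- rbind(excl, data.frame(participant = p$id, unit = "participant",
                                       reason = s$excluded_reason))
      ptab[[length(ptab) + 1]] <- data.frame(
        id = p$id, eq_score = p$eq_score,
        mean_proportion_unscrambled = s$mean_proportion_unscrambled,
        mean_proportion_scrambled = s$mean_proportion_scrambled,
        captured_fraction_scrambled = s$captured_fraction_scrambled,
        included = s$included)
    }
    ptab <- do.call(rbind, ptab)
    inc <- ptab[ptab$included, , drop = FALSE]
    if (nrow(inc) == 0) stop("run_pipeline: no participants survive FV exclusions")
    fv <- list(
      participants = ptab,
      n_included = nrow(inc),
      test_unscrambled = one_sample_t(inc$mean_proportion_unscrambled, 0.5),
      test_scrambled = one_sample_t(inc$mean_proportion_scrambled, 0.5),
      test_paired = paired_t(inc$mean_proportion_unscrambled,
                             inc$mean_proportion_scrambled),
      cousineau_se = cousineau_se(cbind(
        unscrambled = inc$mean_proportion_unscrambled,
        scrambled = inc$mean_proportion_scrambled)),
      eq_r_unscrambled = .maybe_cor(inc$eq_score, inc$mean_proportion_unscrambled),
      eq_r_scrambled = .maybe_cor(inc$eq_score, inc$mean_proportion_scrambled))
    n_tests <- n_tests + 3L +
      (!is.null(fv$eq_r_unscrambled)) + (!is.null(fv$eq_r_scrambled))
    # Steiger's Z on the complete-case (EQ present) subset
    cc <- inc[!is.na(inc$eq_score), , drop = FALSE]
    if (nrow(cc) > 3 && !is.null(fv$eq_r_unscrambled) &&
        !is.null(fv$eq_r_scrambled)) {
      r_kh <- stats::cor(cc$mean_proportion_unscrambled,
                         cc$mean_proportion_scrambled)
      fv$steiger <- steiger_z(fv$eq_r_unscrambled$r, fv$eq_r_scrambled$r,
                              r_kh, nrow(cc))
      n_tests <- n_tests + 1L
    }
  }

  n_trial_total <-
    (if (has_ge) sum(vapply(participants, function(p) length(p$ge_trials), 0L)) else 0L) +
    (if (has_fv) sum(vapply(participants, function(p) length(p$fv_trials), 0L)) else 0L)
  audit <- exclusion_log(excl, n_trial_total, length(participants))

  structure(list(ge = ge, fv = fv, exclusions = audit,
                 exclusion_records = excl, n_tests = n_tests),
            class = "cohort_result")
}

.maybe_cor <- function(eq, values) {
  keep <- !is.na(eq) & !is.na(values)
  if (sum(keep) < 3) return(NULL)
  pearson_r(eq, values)
}

.fmt_test <- function(tt, label) {
  sprintf("%s: mean = %.3f (SD %.3f, SE %.3f), t(%d) = %.3f, p = %.4g, d = %.3f",
          label, tt$mean, tt$sd, tt$se, tt$df, tt$statistic, tt$p, tt$d)
}

#' Human-readable report for a pipeline result
#'
#' Prints each statistic with its test, df, two-tailed p and effect size,
#' plus the exclusion audit, mirroring how the analyses of these paradigms
#' are conventionally reported.
#'
#' @param result a `cohort_result` from [run_pipeline()].
#' @return Character vector of report lines, invisibly printed.
#' @export
report_text <- function(result) {
  ln <- character(0)
  add <- function(...) ln <<- c(ln, sprintf(...))
  if (!is.null(result$ge)) {
    add("== Global effect task (saccadic deviation toward social images) ==")
    add("included participants: %d", result$ge$n_included)
    ln <- c(ln, .fmt_test(result$ge$test_unscrambled, "unscrambled vs 0 deg"),
            .fmt_test(result$ge$test_scrambled, "scrambled vs 0 deg"),
            .fmt_test(result$ge$test_paired, "unscrambled - scrambled"))
    add("Cousineau within-subject SE: unscrambled %.4f, scrambled %.4f",
        result$ge$cousineau_se[["unscrambled"]],
        result$ge$cousineau_se[["scrambled"]])
    for (cond in c("unscrambled", "scrambled")) {
      r <- result$ge[[paste0("eq_r_", cond)]]
      if (!is.null(r))
        add("EQ correlation (%s): r(%d) = %.3f, p = %.4g", cond, r$df, r$r, r$p)
    }
  }
  if (!is.null(result$fv)) {
    add("== Freeview task (social dwell proportion) ==")
    add("included participants: %d", result$fv$n_included)
    ln <- c(ln, .fmt_test(result$fv$test_unscrambled, "unscrambled vs 0.5"),
            .fmt_test(result$fv$test_scrambled, "scrambled vs 0.5"),
            .fmt_test(result$fv$test_paired, "unscrambled - scrambled"))
    add("Cousineau within-subject SE: unscrambled %.4f, scrambled %.4f",
        result$fv$cousineau_se[["unscrambled"]],
        result$fv$cousineau_se[["scrambled"]])
    for (cond in c("unscrambled", "scrambled")) {
      r <- result$fv[[paste0("eq_r_", cond)]]
      if (!is.null(r))
        add("EQ correlation (%s): r(%d) = %.3f, p = %.4g", cond, r$df, r$r, r$p)
    }
    if (!is.null(result$fv$steiger))
      add("Steiger's Z (EQ-dwell, unscrambled vs scrambled): Z = %.3f, p = %.4g",
          result$fv$steiger$z, result$fv$steiger$p)
  }
  ex <- result$exclusions
  add("== Exclusion audit ==")
  add("trials excluded: %d (%.3f%%), mean %.3f per participant",
      ex$n_trials_excluded, ex$percent_trials_excluded,
      ex$mean_trials_excluded_per_participant)
  add("participants excluded: %d", ex$n_participants_excluded)
  if (length(ex$counts))
    for (nm in names(ex$counts)) add("  %s: %d", nm, ex$counts[[nm]])
  add("tests run (no multiplicity correction applied): %d", result$n_tests)
  ln
}

#' @export
print.cohort_result <- function(x, ...) {
  cat(report_text(x), sep = "\n")
  invisible(x)
}

#' Write machine- and human-readable reports
#'
#' Emits `report.json` (stable serialization of every statistic) and
#' `report.txt` (the [report_text()] rendering) into a directory.
#'
#' @param result a `cohort_result`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_report <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  strip <- function(x) {
    if (is.null(x)) return(NULL)
    x$participants <- NULL
    x$cousineau_se <- as.list(x$cousineau_se)
    x
  }
  payload <- list(ge = strip(result$ge), fv = strip(result$fv),
                  exclusions = list(
                    n_trials_excluded = result$exclusions$n_trials_excluded,
                    percent_trials_excluded = result$exclusions$percent_trials_excluded,
                    mean_trials_excluded_per_participant =
                      result$exclusions$mean_trials_excluded_per_participant,
                    n_participants_excluded = result$exclusions$n_participants_excluded,
                    counts = as.list(result$exclusions$counts)),
                  n_tests = result$n_tests)
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(report_text(result), file.path(dir, "report.txt"))
  invisible(dir)
}
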