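#' Write a raw cohort to a directory of sample files
#'
#' Serializes a cohort with raw streams into the package's on-disk dataset
#' layout: `participants.csv` (`participant,eq_score`), `manifest.csv`
#' (one row per trial: `participant,trial_id,task,scrambled,target_side,
#' social_position,social_side,file`) and one sample CSV per trial under
#' `samples/`.
#'
#' @param cohort a `gaze_cohort` with `raw_streams = TRUE`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!isTRUE(cohort$raw_streams))
    stop("write_cohort: only raw-stream cohorts can be serialized")
  dir.create(file.path(dir, "samples"), showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  parts <- list()
  for (p in cohort$participants) {
    parts[[length(parts) + 1]] <- data.frame(participant = p$id,
                                             eq_score = p$eq_score)
    for (task in c("ge", "fv")) {
      entries <- p[[paste0(task, "_trials")]]
      if (is.null(entries)) next
      for (k in seq_along(entries)) {
        e <- entries[[k]]
        id <- sprintf("%s_%s_%03d", p$id, task, k)
        file <- file.path("samples", paste0(id, ".csv"))
        write_gaze_csv(e$trial$stream, file.path(dir, file))
        manifest[[length(manifest) + 1]] <- data.frame(
          participant = p$id, trial_id = id, task = task,
          scrambled = as.integer(e$scrambled),
          target_side = if (task == "ge") e$trial$target_side else "",
          social_position = if (task == "ge") e$trial$social_position else "",
          social_side = if (task == "fv") e$trial$social_side else "",
          file = file)
      }
    }
  }
  utils::write.csv(do.call(rbind, parts), file.path(dir, "participants.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(do.call(rbind, manifest), file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Read a cohort from the on-disk dataset layout
#'
#' Inverse of [write_cohort()]: reads `participants.csv`, `manifest.csv`
#' and the per-trial sample CSVs, rebuilding the cohort structure that
#' [run_pipeline()] consumes.  Sample files must be degree-coded
#' (screen-centered); pass `geometry` together with `units = "px"` for
#' pixel-coded exports.
#'
#' @param dir dataset directory.
#' @param units,geometry forwarded to [read_gaze_csv()].
#' @param nominal_rate_hz nominal sampling rate of the recordings.
#' @return A `gaze_cohort` (without ground truth).
#' @export
read_cohort <- function(dir, units = "deg", geometry = NULL,
                        nominal_rate_hz = 500) {
  manifest <- utils::read.csv(file.path(dir, "manifest.csv"),
                              stringsAsFactors = FALSE)
  parts <- utils::read.csv(file.path(dir, "participants.csv"),
                           stringsAsFactors = FALSE)
  participants <- lapply(seq_len(nrow(parts)), function(i) {
    id <- parts$participant[i]
    rows <- manifest[manifest$participant == id, , drop = FALSE]
    load_entry <- function(j) {
      stream <- read_gaze_csv(file.path(dir, rows$file[j]), units = units,
                              geometry = geometry,
                              nominal_rate_hz = nominal_rate_hz)
      if (rows$task[j] == "ge")
        list(trial = ge_trial(stream, rows$target_side[j],
                              rows$social_position[j],
                              scrambled = rows$scrambled[j] == 1),
             scrambled = rows$scrambled[j] == 1)
      else
        list(trial = fv_trial(stream, rows$social_side[j],
                              scrambled = rows$scrambled[j] == 1),
             scrambled = rows$scrambled[j] == 1)
    }
    ge_idx <- which(rows$task == "ge")
    fv_idx <- which(rows$task == "fv")
    list(id = id,
         eq_score = if (is.na(parts$eq_score[i])) NA else parts$eq_score[i],
         ge_trials = if (length(ge_idx)) lapply(ge_idx, load_entry),
         fv_trials = if (length(fv_idx)) lapply(fv_idx, load_entry))
  })
  structure(list(participants = participants, truth = NULL,
                 raw_streams = TRUE, config = NULL),
            class = "gaze_cohort")
}
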