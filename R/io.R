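#' Write a synthetic study to plain-text files
#'
#' Emits `cohort.csv` (one row per patient), `tacs.csv` (long format:
#' `patient_id, lesion_id, timepoint, frame_start_s, frame_duration_s,
#' activity_kBq_ml`), `venous.csv` (`patient_id, timepoint, time_min,
#' activity_kBq_ml`), `idif.csv` (same long format as the TACs), one
#' whitespace-separated array file per static patch under `patches/` with a
#' JSON sidecar (`voxel_size_mm`, `dim`), and `config.json` holding the full
#' generator configuration and master seed.
#'
#' @param study a [StudyData-class]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
writeStudyData <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "patches"), showWarnings = FALSE)
  utils::write.csv(study@cohort, file.path(dir, "cohort.csv"), row.names = FALSE)

  tacRow <- function(scan, id, tac) {
    data.frame(patient_id = scan$patient_id, lesion_id = id,
               timepoint = scan$timepoint,
               frame_start_s = frameStarts(tac@schedule),
               frame_duration_s = frameDurations(tac@schedule),
               activity_kBq_ml = tac@activity, stringsAsFactors = FALSE)
  }
  tacs <- list(); ven <- list(); idifs <- list()
  for (scan in study@scans) {
    for (les in scan$lesions) {
      tacs[[length(tacs) + 1]] <- tacRow(scan, les$lesion_id, les$tac)
      pbase <- file.path(dir, "patches",
                         paste0(les$lesion_id, "_", scan$timepoint))
      vals <- les$patch@values
      utils::write.table(matrix(vals, nrow = dim(vals)[1]),
                         paste0(pbase, ".txt"),
                         row.names = FALSE, col.names = FALSE)
      writeLines(jsonlite::toJSON(list(voxel_size_mm = les$patch@voxelSize,
                                       dim = dim(vals)), auto_unbox = TRUE),
                 paste0(pbase, ".json"))
    }
    ven[[length(ven) + 1]] <- data.frame(
      patient_id = scan$patient_id, timepoint = scan$timepoint,
      time_min = scan$venous@time, activity_kBq_ml = scan$venous@activity,
      stringsAsFactors = FALSE)
    idifs[[length(idifs) + 1]] <- tacRow(scan, "aorta", scan$idif)
  }
  utils::write.csv(do.call(rbind, tacs), file.path(dir, "tacs.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, ven), file.path(dir, "venous.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, idifs), file.path(dir, "idif.csv"),
                   row.names = FALSE)
  cfg <- study@config
  cfg$seed <- study@seed
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA),
             file.path(dir, "config.json"))
  invisible(dir)
}

#' Read time-activity curves from a long-format CSV
#'
#' Counterpart of the TAC table written by [writeStudyData()]; returns one
#' [TimeActivityCurve-class] per (`patient_id`, `lesion_id`, `timepoint`).
#'
#' @param path CSV file with columns `patient_id, lesion_id, timepoint,
#'   frame_start_s, frame_duration_s, activity_kBq_ml`
#' @return named list of [TimeActivityCurve-class] objects, names
#'   `patientid.lesionid.timepoint`
#' @export
readTacCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  key <- interaction(df$patient_id, df$lesion_id, df$timepoint, drop = TRUE)
  out <- lapply(split(df, key), function(g) {
    g <- g[order(g$frame_start_s), ]
    timeActivityCurve(frameSchedule(g$frame_duration_s), g$activity_kBq_ml)
  })
  out
}
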