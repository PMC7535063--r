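#' Read regional time-activity curves
#'
#' CSV dialect: header `subject_id, session, region, frame_start_s,
#' frame_end_s, activity_kbq_per_ml`; RFC 4180, UTF-8, "." decimal. Frame
#' schedules are validated per (subject, session, region): contiguous,
#' non-overlapping, first frame at 0. Row order is irrelevant.
#'
#' @param path CSV file.
#' @return long data frame sorted by subject, session, region, frame
#'   start.
#' @export
read_tacs <- function(path) {
  df <- read_table_checked(path, c("subject_id", "session", "region",
                                   "frame_start_s", "frame_end_s",
                                   "activity_kbq_per_ml"))
  check_sessions(df$session, path)
  if (any(df$activity_kbq_per_ml < 0))
    stop_input(sprintf("%s: negative activity (row %d)", path,
                       which(df$activity_kbq_per_ml < 0)[1]))
  df$.row <- seq_len(nrow(df))
  key <- interaction(df$subject_id, df$session, df$region, drop = TRUE)
  for (g in levels(key)) {
    sub <- df[key == g, ]
    sub <- sub[order(sub$frame_start_s), ]
    ok <- tryCatch({ frame_schedule(sub$frame_start_s, sub$frame_end_s); TRUE },
                   error = function(e) e)
    if (!isTRUE(ok))
      stop_input(sprintf("%s: invalid frame schedule for %s (near row %d): %s",
                         path, g, sub$.row[1], conditionMessage(ok)))
  }
  df <- df[order(df$subject_id, df$session, df$region, df$frame_start_s), ]
  df$.row <- NULL
  rownames(df) <- NULL
  df
}

#' Read arterial plasma sample tables
#'
#' CSV dialect: header `subject_id, session, time_min, plasma_kbq_per_ml`.
#' Times must be non-negative and unique within a scan; rows are sorted by
#' time.
#'
#' @param path CSV file.
#' @return long data frame.
#' @export
read_blood <- function(path) {
  df <- read_table_checked(path, c("subject_id", "session", "time_min",
                                   "plasma_kbq_per_ml"))
  check_sessions(df$session, path)
  if (any(df$time_min < 0))
    stop_input(sprintf("%s: negative sample time", path))
  if (any(df$plasma_kbq_per_ml < 0))
    stop_input(sprintf("%s: negative plasma activity", path))
  key <- interaction(df$subject_id, df$session, drop = TRUE)
  for (g in levels(key)) {
    tt <- df$time_min[key == g]
    if (anyDuplicated(tt))
      stop_input(sprintf("%s: duplicate sample time %g for %s", path,
                         tt[duplicated(tt)][1], g))
  }
  df <- df[order(df$subject_id, df$session, df$time_min), ]
  rownames(df) <- NULL
  df
}

#' Read per-scan metadata
#'
#' CSV dialect: header `subject_id, session, injected_dose_mbq,
#' body_weight_kg, glycemia_arterial_mmol_l, glycemia_venous_mmol_l`
#' (venous may be blank).
#'
#' @param path CSV file.
#' @return data frame, one row per scan.
#' @export
read_meta <- function(path) {
  df <- read_table_checked(path, c("subject_id", "session", "injected_dose_mbq",
                                   "body_weight_kg", "glycemia_arterial_mmol_l",
                                   "glycemia_venous_mmol_l"))
  check_sessions(df$session, path)
  bad <- which(df$injected_dose_mbq <= 0 | df$body_weight_kg <= 0 |
               df$glycemia_arterial_mmol_l <= 0)
  if (length(bad))
    stop_input(sprintf("%s: non-positive dose, weight or glycemia (row %d)",
                       path, bad[1]))
  df
}

read_table_checked <- function(path, cols) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop_input(sprintf("%s: missing column(s): %s", path,
                       paste(missing, collapse = ", ")))
  if (nrow(df) == 0) stop_input(sprintf("%s: no rows", path))
  df[, cols]
}

check_sessions <- function(session, path) {
  bad <- setdiff(unique(session), c("test", "retest", "single"))
  if (length(bad))
    stop_input(sprintf("%s: unknown session label(s): %s", path,
                       paste(bad, collapse = ", ")))
}

#' Write the tables of a simulated study
#'
#' Writes `tacs.csv`, `blood.csv`, `meta.csv` (the dialects the readers
#' accept) and `truth.csv` with the ground-truth kinetics and effects.
#'
#' @param study an `fdg_study`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("tacs.csv", "blood.csv", "meta.csv", "truth.csv"))
  utils::write.csv(study$tacs, paths[1], row.names = FALSE)
  utils::write.csv(study$blood, paths[2], row.names = FALSE)
  utils::write.csv(study$meta, paths[3], row.names = FALSE)
  utils::write.csv(study$truth, paths[4], row.names = FALSE)
  invisible(paths)
}

#' Load a study bundle from CSV tables
#'
#' @param dir directory holding `tacs.csv`, `blood.csv`, `meta.csv` (and
#'   optionally `truth.csv`); alternatively give the three paths.
#' @param tacs,blood,meta explicit file paths (override `dir`).
#' @return a list with validated `tacs`, `blood`, `meta` (and `truth` when
#'   present), usable by [quantify_study()].
#' @export
read_study <- function(dir = NULL, tacs = NULL, blood = NULL, meta = NULL) {
  if (!is.null(dir)) {
    tacs <- tacs %||% file.path(dir, "tacs.csv")
    blood <- blood %||% file.path(dir, "blood.csv")
    meta <- meta %||% file.path(dir, "meta.csv")
  }
  out <- list(tacs = read_tacs(tacs), blood = read_blood(blood),
              meta = read_meta(meta))
  tkey <- unique(paste(out$tacs$subject_id, out$tacs$session))
  bkey <- unique(paste(out$blood$subject_id, out$blood$session))
  mkey <- unique(paste(out$meta$subject_id, out$meta$session))
  if (!all(tkey %in% bkey) || !all(tkey %in% mkey))
    stop_input("every (subject, session) in the TAC table needs blood and meta rows")
  if (!is.null(dir) && file.exists(file.path(dir, "truth.csv")))
    out$truth <- utils::read.csv(file.path(dir, "truth.csv"),
                                 stringsAsFactors = FALSE)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
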