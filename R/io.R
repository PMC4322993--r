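# Tabular cohort serialization. Four CSV files (header row, UTF-8,
# missing numerics as empty strings):
#   scans.csv    patient_id, scan_day, lesion_id, site, suv_max,
#                diameter_mm, is_target, resolved
#   psa.csv      patient_id, day, psa_ng_ml
#   ct.csv       patient_id, day, recist
#   outcomes.csv patient_id, pfs_months, pfs_event, os_months,
#                os_event, gleason_high, multi_chemo

.cohort_files <- c(scans = "scans.csv", psa = "psa.csv", ct = "ct.csv",
                   outcomes = "outcomes.csv")

.read_checked <- function(path, required) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("malformed file ", path, ": missing column(s) ",
         paste(missing_cols, collapse = ", "))
  df
}

#' Write a cohort to tabular files
#'
#' Serializes a list of [patient_course()]s into the four cohort CSV
#' files (`scans.csv`, `psa.csv`, `ct.csv`, `outcomes.csv`) in `dir`.
#' For a `synthetic_cohort` the latent truth is additionally written
#' to `truth.csv`.
#'
#' @param cohort A `synthetic_cohort` or list of [patient_course()]s.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_cohort <- function(cohort, dir) {
  truth <- NULL
  if (inherits(cohort, "synthetic_cohort")) {
    truth <- cohort$truth
    cohort <- cohort$courses
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  scan_rows <- function(course, scan) {
    df <- scan$lesions
    data.frame(patient_id = course$patient_id, scan_day = scan$scan_day,
               lesion_id = df$lesion_id, site = df$site,
               suv_max = df$suv_max, diameter_mm = df$diameter_mm,
               is_target = df$lesion_id %in% scan$target_ids,
               resolved = df$resolved, stringsAsFactors = FALSE)
  }
  scans <- do.call(rbind, lapply(cohort, function(course) {
    do.call(rbind, lapply(c(list(course$baseline_scan),
                            course$followup_scans),
                          scan_rows, course = course))
  }))
  psa <- do.call(rbind, lapply(cohort, function(course)
    data.frame(patient_id = course$patient_id, day = course$psa$day,
               psa_ng_ml = course$psa$value, stringsAsFactors = FALSE)))
  ct <- do.call(rbind, lapply(cohort, function(course)
    if (nrow(course$ct))
      data.frame(patient_id = course$patient_id, day = course$ct$day,
                 recist = course$ct$category, stringsAsFactors = FALSE)))
  outcomes <- do.call(rbind, lapply(cohort, function(course)
    data.frame(patient_id = course$patient_id,
               pfs_months = course$pfs_months, pfs_event = course$pfs_event,
               os_months = course$os_months, os_event = course$os_event,
               gleason_high = course$covariates$gleason_high,
               multi_chemo = course$covariates$multi_chemo,
               stringsAsFactors = FALSE)))

  paths <- file.path(dir, .cohort_files)
  names(paths) <- names(.cohort_files)
  utils::write.csv(scans, paths["scans"], row.names = FALSE, na = "")
  utils::write.csv(psa, paths["psa"], row.names = FALSE, na = "")
  utils::write.csv(ct, paths["ct"], row.names = FALSE, na = "")
  utils::write.csv(outcomes, paths["outcomes"], row.names = FALSE, na = "")
  if (!is.null(truth)) {
    truth_path <- file.path(dir, "truth.csv")
    utils::write.csv(truth, truth_path, row.names = FALSE, na = "")
    paths <- c(paths, truth = truth_path)
  }
  invisible(paths)
}

#' Read a cohort from tabular files
#'
#' Parses the four cohort CSV files written by [write_cohort()] (or
#' prepared externally in the same schema) back into a list of
#' [patient_course()]s. Parsing is strict about the schema but not
#' about content: run [validate_course()] on the result to check the
#' clinical invariants.
#'
#' @param dir Directory containing `scans.csv`, `psa.csv`, `ct.csv`,
#'   `outcomes.csv`.
#' @return Named list of [patient_course()]s (names = patient ids).
#' @export
read_cohort <- function(dir) {
  scans <- .read_checked(file.path(dir, "scans.csv"),
                         c("patient_id", "scan_day", "lesion_id", "site",
                           "suv_max", "diameter_mm", "is_target", "resolved"))
  psa <- .read_checked(file.path(dir, "psa.csv"),
                       c("patient_id", "day", "psa_ng_ml"))
  ct <- .read_checked(file.path(dir, "ct.csv"),
                      c("patient_id", "day", "recist"))
  outcomes <- .read_checked(file.path(dir, "outcomes.csv"),
                            c("patient_id", "pfs_months", "pfs_event",
                              "os_months", "os_event", "gleason_high",
                              "multi_chemo"))

  ids <- outcomes$patient_id
  courses <- lapply(ids, function(pid) {
    ps <- scans[scans$patient_id == pid, , drop = FALSE]
    if (!nrow(ps)) stop("read_cohort: no scans for patient ", pid)
    mk_scan <- function(day) {
      sl <- ps[ps$scan_day == day, , drop = FALSE]
      scan_record(
        scan_day = day,
        lesions = data.frame(lesion_id = as.character(sl$lesion_id),
                             site = sl$site, suv_max = sl$suv_max,
                             diameter_mm = as.numeric(sl$diameter_mm),
                             resolved = as.logical(sl$resolved),
                             stringsAsFactors = FALSE),
        target_ids = as.character(sl$lesion_id[as.logical(sl$is_target)]))
    }
    days <- sort(unique(ps$scan_day))
    base_days <- days[days <= 0]
    if (length(base_days) != 1)
      stop("read_cohort: patient ", pid, " must have exactly one baseline ",
           "(day <= 0) scan, found ", length(base_days))
    pp <- psa[psa$patient_id == pid, , drop = FALSE]
    pc <- ct[ct$patient_id == pid, , drop = FALSE]
    oc <- outcomes[outcomes$patient_id == pid, , drop = FALSE]
    patient_course(
      patient_id = pid,
      baseline_scan = mk_scan(base_days),
      followup_scans = lapply(days[days > 0], mk_scan),
      psa = data.frame(day = pp$day, value = pp$psa_ng_ml),
      ct = data.frame(day = pc$day, category = as.character(pc$recist),
                      stringsAsFactors = FALSE),
      pfs_months = oc$pfs_months, pfs_event = as.logical(oc$pfs_event),
      os_months = oc$os_months, os_event = as.logical(oc$os_event),
      covariates = list(gleason_high = as.logical(oc$gleason_high),
                        multi_chemo = as.logical(oc$multi_chemo)))
  })
  stats::setNames(courses, ids)
}
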