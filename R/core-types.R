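#' Lesion measurement
#'
#' A single lesion observed on one FCH-PET/CT scan. `suv_max` is the
#' maximum standardized uptake value (dimensionless, >= 0);
#' `diameter_mm` is the longest diameter on CT, absent (`NA`) for
#' non-measurable bone lesions; `resolved` marks uptake
#' indistinguishable from background, in which case the lesion
#' contributes an SUV of 0 to any percent change.
#'
#' @param lesion_id Opaque lesion identifier (character scalar).
#' @param site One of `"bone"`, `"node"`, `"lung"`, `"liver"`, `"other"`.
#' @param suv_max Non-negative SUVmax.
#' @param diameter_mm Longest diameter in mm, or `NA` if non-measurable.
#' @param resolved Logical; `TRUE` if uptake has disappeared.
#' @return A one-row data frame of class `lesion_measurement`.
#' @export
lesion_measurement <- function(lesion_id, site = "bone", suv_max = 0,
                               diameter_mm = NA_real_, resolved = FALSE) {
  df <- data.frame(
    lesion_id = as.character(lesion_id),
    site = as.character(site),
    suv_max = as.numeric(suv_max),
    diameter_mm = as.numeric(diameter_mm),
    resolved = as.logical(resolved),
    stringsAsFactors = FALSE
  )
  class(df) <- c("lesion_measurement", "data.frame")
  df
}

.lesion_sites <- c("bone", "node", "lung", "liver", "other")
.recist_levels <- c("CR", "PR", "SD", "PD")

#' Scan record
#'
#' One FCH-PET/CT scan: the day relative to treatment start (baseline
#' scans have `scan_day <= 0`), a lesion table, and the identifiers of
#' the designated target lesions (a baseline scan requires at least
#' two).
#'
#' @param scan_day Integer day since treatment start.
#' @param lesions Data frame with columns `lesion_id`, `site`,
#'   `suv_max`, `diameter_mm`, `resolved` (rows may be built with
#'   [lesion_measurement()] and `rbind`).
#' @param target_ids Character vector of target lesion ids (subset of
#'   `lesions$lesion_id`).
#' @return An object of class `scan_record`.
#' @export
scan_record <- function(scan_day, lesions, target_ids = lesions$lesion_id) {
  stopifnot(is.data.frame(lesions))
  lesions <- as.data.frame(lesions)
  class(lesions) <- "data.frame"
  structure(
    list(scan_day = as.integer(scan_day), lesions = lesions,
         target_ids = as.character(target_ids)),
    class = "scan_record"
  )
}

#' Patient course
#'
#' The full longitudinal record for one patient: baseline scan,
#' follow-up scans, PSA series, CT (RECIST) assessments, survival
#' outcomes and baseline covariates. Time within series is stored as
#' integer days from treatment start; survival endpoints are in
#' (fractional) months.
#'
#' @param patient_id Patient identifier.
#' @param baseline_scan A [scan_record()] with `scan_day <= 0`.
#' @param followup_scans List of [scan_record()]s, sorted by day.
#' @param psa Data frame with columns `day`, `value` (ng/mL); exactly
#'   one baseline (`day <= 0`) measurement.
#' @param ct Data frame with columns `day`, `category` (RECIST
#'   CR/PR/SD/PD).
#' @param pfs_months,pfs_event Progression-free survival time (months)
#'   and event indicator (`FALSE` = censored).
#' @param os_months,os_event Overall survival time and event indicator.
#' @param covariates List with logical elements `gleason_high`
#'   (Gleason 8-9 vs 6-7) and `multi_chemo` (>= 2 vs 1 prior
#'   chemotherapy regimens).
#' @return An object of class `patient_course`.
#' @seealso [validate_course()]
#' @export
patient_course <- function(patient_id, baseline_scan, followup_scans = list(),
                           psa = data.frame(day = integer(), value = numeric()),
                           ct = data.frame(day = integer(), category = character()),
                           pfs_months = NA_real_, pfs_event = NA,
                           os_months = NA_real_, os_event = NA,
                           covariates = list(gleason_high = NA, multi_chemo = NA)) {
  structure(
    list(patient_id = as.character(patient_id),
         baseline_scan = baseline_scan,
         followup_scans = followup_scans,
         psa = psa, ct = ct,
         pfs_months = as.numeric(pfs_months), pfs_event = as.logical(pfs_event),
         os_months = as.numeric(os_months), os_event = as.logical(os_event),
         covariates = covariates),
    class = "patient_course"
  )
}

#' @export
print.patient_course <- function(x, ...) {
  cat("<patient_course>", x$patient_id, "\n")
  cat("  baseline scan day", x$baseline_scan$scan_day, "with",
      nrow(x$baseline_scan$lesions), "lesion(s),",
      length(x$baseline_scan$target_ids), "target(s)\n")
  cat("  follow-up scans:",
      if (length(x$followup_scans)) paste(vapply(x$followup_scans, function(s)
        s$scan_day, integer(1)), collapse = ", ") else "none", "(days)\n")
  cat("  PSA measurements:", nrow(x$psa),
      " CT assessments:", nrow(x$ct), "\n")
  cat(sprintf("  PFS %.1f mo (event: %s)  OS %.1f mo (event: %s)\n",
              x$pfs_months, x$pfs_event, x$os_months, x$os_event))
  invisible(x)
}

.check_lesion_table <- function(lesions, where) {
  v <- character()
  req <- c("lesion_id", "site", "suv_max", "diameter_mm", "resolved")
  missing_cols <- setdiff(req, names(lesions))
  if (length(missing_cols)) {
    return(sprintf("%s: lesion table lacks column(s) %s", where,
                   paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(lesions$lesion_id))
    v <- c(v, sprintf("%s: lesion_ids not unique within scan", where))
  bad_suv <- !is.na(lesions$suv_max) & lesions$suv_max < 0
  if (any(bad_suv))
    v <- c(v, sprintf("%s: negative suv_max for lesion %s", where,
                      paste(lesions$lesion_id[bad_suv], collapse = ", ")))
  bad_site <- !lesions$site %in% .lesion_sites
  if (any(bad_site))
    v <- c(v, sprintf("%s: unknown site '%s'", where,
                      paste(unique(lesions$site[bad_site]), collapse = ", ")))
  bad_d <- !is.na(lesions$diameter_mm) & lesions$diameter_mm <= 0
  if (any(bad_d))
    v <- c(v, sprintf("%s: non-positive diameter for lesion %s", where,
                      paste(lesions$lesion_id[bad_d], collapse = ", ")))
  v
}

#' Validate a patient course
#'
#' Checks every structural invariant of a [patient_course()] and
#' returns the violations as a character vector (empty when the course
#' is well formed). The validator is total: it reports problems rather
#' than raising errors, so it can be run on arbitrary parsed input.
#'
#' Checked rules include: a unique baseline scan at day <= 0 with at
#' least 2 target lesions; unique lesion ids and non-negative SUVmax
#' within each scan; target ids referring to existing lesions;
#' follow-up scans strictly after baseline and sorted; a PSA series
#' with exactly one baseline value, non-negative values, sorted by
#' day; CT categories from CR/PR/SD/PD; non-negative survival times.
#'
#' @param course A [patient_course()] (or structurally similar list).
#' @return Character vector of human-readable violations; `character(0)`
#'   if the course is valid.
#' @export
validate_course <- function(course) {
  v <- character()
  add <- function(msg) v <<- c(v, msg)

  bs <- course$baseline_scan
  if (is.null(bs) || !is.list(bs) || is.null(bs$lesions)) {
    add("baseline_scan missing or malformed")
  } else {
    if (!is.na(bs$scan_day) && bs$scan_day > 0)
      add("baseline_scan: scan_day must be <= 0")
    v <- c(v, .check_lesion_table(bs$lesions, "baseline_scan"))
    if (length(bs$target_ids) < 2)
      add("baseline requires >=2 target lesions")
    orphan <- setdiff(bs$target_ids, bs$lesions$lesion_id)
    if (length(orphan))
      add(sprintf("baseline_scan: target_ids %s not in lesion table",
                  paste(orphan, collapse = ", ")))
  }

  fu <- course$followup_scans
  if (length(fu)) {
    days <- vapply(fu, function(s) as.numeric(s$scan_day), numeric(1))
    if (any(days <= 0)) add("followup_scans: scan_day must be > 0")
    if (is.unsorted(days, strictly = TRUE))
      add("followup_scans: not strictly sorted by day")
    for (i in seq_along(fu))
      v <- c(v, .check_lesion_table(fu[[i]]$lesions,
                                    sprintf("followup_scan[%d]", i)))
  }

  psa <- course$psa
  if (is.null(psa) || !all(c("day", "value") %in% names(psa))) {
    add("psa: series missing or lacks day/value columns")
  } else if (nrow(psa)) {
    bad <- !is.na(psa$value) & psa$value < 0
    if (any(bad))
      add(sprintf("psa: negative value at day %s",
                  paste(psa$day[bad], collapse = ", ")))
    if (is.unsorted(psa$day))
      add("psa: series not sorted by day")
    n_base <- sum(psa$day <= 0)
    if (n_base != 1)
      add(sprintf("psa: expected exactly one baseline (day <= 0) value, found %d",
                  n_base))
  }

  ct <- course$ct
  if (!is.null(ct) && nrow(ct)) {
    bad <- !ct$category %in% .recist_levels
    if (any(bad))
      add(sprintf("ct: category not in CR/PR/SD/PD at day %s",
                  paste(ct$day[bad], collapse = ", ")))
    if (is.unsorted(ct$day)) add("ct: assessments not sorted by day")
  }

  for (f in c("pfs_months", "os_months")) {
    val <- course[[f]]
    if (!is.null(val) && !is.na(val) && val < 0)
      add(sprintf("%s must be >= 0", f))
  }
  v
}
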