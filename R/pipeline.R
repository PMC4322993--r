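#' Classify every patient in a cohort
#'
#' Runs the full per-patient early-assessment pipeline: early PET
#' classification against baseline, PSA endpoints, the bone-flare
#' procedure, and the flare-adjusted progression label, and joins the
#' outcomes and covariates.
#'
#' @param courses List of [patient_course()]s, or a `synthetic_cohort`.
#' @param ... Passed to [classify_pet_response()] (e.g. `pr_rule`).
#' @return Data frame with one row per patient: `patient_id`,
#'   `pet_category`, `mean_delta_pct`, `new_lesion_count`,
#'   `size_progression`, `baseline_psa`, `nadir_psa`,
#'   `max_decline_pct`, `responder_50`, `psa_flare`, `flare_status`,
#'   `effective_nonprogression`, `ct_3mo`, `gleason_high`,
#'   `multi_chemo`, `pfs_months`, `pfs_event`, `os_months`,
#'   `os_event`.
#' @export
classify_cohort <- function(courses, ...) {
  if (inherits(courses, "synthetic_cohort")) courses <- courses$courses
  rows <- lapply(courses, function(course) {
    if (!length(course$followup_scans))
      stop("classify_cohort: patient ", course$patient_id,
           " has no follow-up scan")
    call <- classify_pet_response(course$baseline_scan,
                                  course$followup_scans[[1]], ...)
    flare <- assess_bone_flare(course, call)
    psa <- psa_endpoints(course)
    ct_3mo <- if (nrow(course$ct))
      course$ct$category[which.min(abs(course$ct$day - 90))] else NA_character_
    data.frame(
      patient_id = course$patient_id,
      pet_category = call$category,
      mean_delta_pct = call$mean_delta_pct,
      new_lesion_count = length(call$new_lesions),
      size_progression = call$size_progression,
      baseline_psa = psa$baseline_psa,
      nadir_psa = psa$nadir_psa,
      max_decline_pct = psa$max_decline_pct,
      responder_50 = psa$responder_50,
      psa_flare = psa$psa_flare,
      flare_status = flare$status,
      effective_nonprogression =
        effective_progression_label(course, call, flare),
      ct_3mo = ct_3mo,
      gleason_high = isTRUE(course$covariates$gleason_high),
      multi_chemo = isTRUE(course$covariates$multi_chemo),
      pfs_months = course$pfs_months, pfs_event = course$pfs_event,
      os_months = course$os_months, os_event = course$os_event,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Waterfall-style per-patient report
#'
#' The per-patient summary usually shown as a waterfall plot of
#' maximal PSA change with the corresponding mean SUVmax change,
#' 3-month CT category and flare flag, ordered from the largest PSA
#' rise to the deepest decline.
#'
#' @param labels Output of [classify_cohort()] (or a cohort/course
#'   list, which is classified first).
#' @return Data frame ordered for a waterfall display: `patient_id`,
#'   `psa_change_pct` (negative = decline), `mean_delta_suvmax_pct`,
#'   `pet_category`, `ct_3mo`, `flare` (flag: `*` confirmed or
#'   of-interest flare, `**` suspected unresolved).
#' @export
patient_report <- function(labels) {
  if (!is.data.frame(labels)) labels <- classify_cohort(labels)
  flag <- ifelse(labels$flare_status %in%
                   c("confirmed_flare", "flare_of_interest"), "*",
                 ifelse(labels$flare_status == "suspected_unresolved", "**", ""))
  out <- data.frame(
    patient_id = labels$patient_id,
    psa_change_pct = -labels$max_decline_pct,
    mean_delta_suvmax_pct = labels$mean_delta_pct,
    pet_category = labels$pet_category,
    ct_3mo = labels$ct_3mo,
    flare = flag,
    stringsAsFactors = FALSE
  )
  out[order(-out$psa_change_pct), , drop = FALSE]
}

#' Waterfall plot of maximal PSA change
#'
#' Barplot of per-patient maximal PSA change (negative = decline),
#' with reference lines at -30%, -50% and -90%, bars shaded by the
#' early PET category.
#'
#' @param report Output of [patient_report()].
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
plot_waterfall <- function(report, ...) {
  cols <- c(CR = "#1b9e77", PR = "#66c2a5", SD = "#fdbf6f", PD = "#d95f02")
  mid <- graphics::barplot(report$psa_change_pct,
                           col = cols[report$pet_category],
                           border = NA,
                           ylab = "Maximal PSA change (%)",
                           xlab = "Patients", ...)
  graphics::abline(h = c(-30, -50, -90),
                   col = c("darkgreen", "orange", "black"), lty = 2)
  graphics::legend("topright", legend = names(cols), fill = cols,
                   border = NA, bty = "n", title = "Early PET")
  invisible(mid)
}
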