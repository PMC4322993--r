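#' Multi-timepoint bone-flare assessment
#'
#' Early metabolic progression on FCH-PET/CT in bone can be a *flare*
#' (an osteoblastic healing reaction under effective therapy) rather
#' than true progression. This procedure re-reads an early PD call in
#' the light of the PSA trajectory, the ~3-month CT and a confirmatory
#' PET 2-3 months after the early scan, evaluating in order:
#'
#' 1. **Trigger** - the early scan shows a >25% uptake increase of at
#'    least one known (baseline) lesion;
#' 2. **PSA condition** - maximal PSA decline >= 50%, or the
#'    "of-interest" variant: a continued decline below baseline that
#'    stays short of the 50% threshold;
#' 3. **CT condition** - the CT assessment nearest day 90 is not PD
#'    (no CT at all fails the condition, conservatively);
#' 4. **Confirmation** - a second follow-up PET shows improvement or
#'    stability relative to the early scan (mean uptake change
#'    <= +25% over matched lesions, no new lesions).
#'
#' All four satisfied with PSA decline >= 50% gives `confirmed_flare`;
#' with the sub-50% variant, `flare_of_interest`. If (1)-(3) hold but
#' no confirmatory scan exists, `suspected_unresolved`. A failed PSA
#' or CT condition, a failed trigger, or a confirmatory scan showing
#' further progression gives `confirmed_progression`. Non-PD early
#' calls return `not_applicable`.
#'
#' Timing windows are soft: the early scan is expected within days
#' 19-69 of treatment start and the confirmatory scan 60-120 days
#' after the early one; deviations warn but do not stop the
#' assessment.
#'
#' @param course A [patient_course()].
#' @param early_call The [classify_pet_response()] call for the first
#'   follow-up scan; computed from `course` if omitted.
#' @param pd_uptake_threshold Percent uptake rise defining the flare
#'   trigger and confirmatory stability bound (default 25).
#' @param tol Floating-point tolerance on thresholds.
#' @return An object of class `flare_assessment`: `status` (one of
#'   `confirmed_flare`, `flare_of_interest`, `suspected_unresolved`,
#'   `confirmed_progression`, `not_applicable`) and `evidence`, a list
#'   recording each rule branch (early category, trigger, PSA decline
#'   and branch taken, CT category used, confirmatory verdict).
#' @export
assess_bone_flare <- function(course, early_call = NULL,
                              pd_uptake_threshold = 25, tol = 1e-9) {
  if (length(course$followup_scans) < 1)
    stop("assess_bone_flare: no early follow-up scan for patient ",
         course$patient_id)
  early <- course$followup_scans[[1]]
  if (is.null(early_call))
    early_call <- classify_pet_response(course$baseline_scan, early)

  ev <- list(early_category = early_call$category)
  mk <- function(status) structure(list(status = status, evidence = ev),
                                   class = "flare_assessment")

  if (early_call$category != "PD") return(mk("not_applicable"))

  if (early$scan_day < 19 || early$scan_day > 69)
    warning("early follow-up scan at day ", early$scan_day,
            " is outside the expected 19-69 day window")

  # (1) trigger: >25% uptake rise of >=1 known baseline lesion
  bl <- course$baseline_scan$lesions
  el <- early$lesions
  known <- intersect(bl$lesion_id, el$lesion_id)
  known <- known[bl$suv_max[match(known, bl$lesion_id)] > 0]
  rise <- if (length(known)) {
    d <- 100 * (el$suv_max[match(known, el$lesion_id)] -
                  bl$suv_max[match(known, bl$lesion_id)]) /
      bl$suv_max[match(known, bl$lesion_id)]
    d[el$resolved[match(known, el$lesion_id)]] <- -100
    any(d > pd_uptake_threshold + tol)
  } else FALSE
  ev$trigger_uptake_rise <- rise
  if (!rise) return(mk("confirmed_progression"))

  # (2) PSA condition
  decline <- psa_max_decline_pct(course$psa)
  ev$psa_max_decline_pct <- decline
  psa_50 <- decline >= 50 - tol
  s <- .psa_split(course$psa)
  below <- s$on$value < s$baseline
  psa_interest <- !psa_50 && any(below) && decline > 0 &&
    nrow(s$on) > 0 && s$on$value[nrow(s$on)] < s$baseline
  ev$psa_branch <- if (psa_50) "responder_50"
    else if (psa_interest) "continued_decline_below_50" else "failed"
  if (!psa_50 && !psa_interest) return(mk("confirmed_progression"))

  # (3) CT condition: assessment nearest day 90 not PD
  if (is.null(course$ct) || nrow(course$ct) == 0) {
    ev$ct_category <- NA_character_
    ev$ct_non_pd <- FALSE
    return(mk("confirmed_progression"))
  }
  ct_cat <- course$ct$category[which.min(abs(course$ct$day - 90))]
  ev$ct_category <- ct_cat
  ev$ct_non_pd <- ct_cat != "PD"
  if (!ev$ct_non_pd) return(mk("confirmed_progression"))

  # (4) confirmatory PET 2-3 months after the early scan
  if (length(course$followup_scans) < 2) {
    ev$confirmatory <- "absent"
    return(mk("suspected_unresolved"))
  }
  confirm <- course$followup_scans[[2]]
  gap <- confirm$scan_day - early$scan_day
  if (gap < 60 || gap > 120)
    warning("confirmatory scan ", gap,
            " days after the early scan (expected 60-120)")
  cl <- confirm$lesions
  matched <- intersect(el$lesion_id[el$suv_max > 0 & !el$resolved],
                       cl$lesion_id)
  change <- if (length(matched)) {
    dd <- 100 * (cl$suv_max[match(matched, cl$lesion_id)] -
                   el$suv_max[match(matched, el$lesion_id)]) /
      el$suv_max[match(matched, el$lesion_id)]
    dd[cl$resolved[match(matched, cl$lesion_id)]] <- -100
    mean(dd)
  } else -100  # all early-scan activity gone
  new_at_confirm <- setdiff(cl$lesion_id[cl$suv_max > 0 & !cl$resolved],
                            union(el$lesion_id, bl$lesion_id))
  ev$confirmatory_mean_change_pct <- change
  ev$confirmatory_new_lesions <- new_at_confirm
  stable <- change <= pd_uptake_threshold + tol && length(new_at_confirm) == 0
  ev$confirmatory <- if (!stable) "progression"
    else if (change <= -25 + tol) "improvement" else "stable"
  if (!stable) return(mk("confirmed_progression"))

  mk(if (psa_50) "confirmed_flare" else "flare_of_interest")
}

#' @export
print.flare_assessment <- function(x, ...) {
  cat("<flare_assessment>", x$status, "\n")
  for (nm in names(x$evidence)) {
    val <- x$evidence[[nm]]
    cat(sprintf("  %s: %s\n", nm,
                paste(format(val, digits = 4), collapse = ", ")))
  }
  invisible(x)
}

#' Effective progression label after flare adjudication
#'
#' Final non-progression indicator for a patient once the bone-flare
#' procedure has run: an early PD read is reclassified as
#' non-progression when the flare is confirmed (or of interest);
#' `suspected_unresolved` and `confirmed_progression` remain
#' progression; non-PD early calls pass through unchanged.
#'
#' @param course A [patient_course()] (unused except for interface
#'   symmetry; may be `NULL`).
#' @param early_call The early [classify_pet_response()] call.
#' @param flare The [assess_bone_flare()] result.
#' @return Logical: `TRUE` = non-progression (the favourable outcome),
#'   `FALSE` = progression.
#' @export
effective_progression_label <- function(course, early_call, flare) {
  if (early_call$category != "PD") return(TRUE)
  flare$status %in% c("confirmed_flare", "flare_of_interest")
}
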