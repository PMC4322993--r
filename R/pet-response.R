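#' Percent change in lesion SUVmax
#'
#' Relative change in maximum standardized uptake value between a
#' baseline and a follow-up measurement of the same lesion, in
#' percent: `100 * (SUV_fu - SUV_base) / SUV_base`. A follow-up
#' measurement flagged `resolved` (uptake indistinguishable from
#' background) counts as SUV 0 and therefore yields -100.
#'
#' @param baseline,followup [lesion_measurement()] rows (or one-row
#'   data frames with the same columns) for the same `lesion_id`.
#' @return Percent change (numeric scalar); negative = decrease.
#' @export
lesion_delta_pct <- function(baseline, followup) {
  if (!identical(as.character(baseline$lesion_id),
                 as.character(followup$lesion_id)))
    stop("lesion_delta_pct: baseline and follow-up refer to different lesions (",
         baseline$lesion_id, " vs ", followup$lesion_id, ")")
  if (is.na(baseline$suv_max) || baseline$suv_max <= 0)
    stop("lesion_delta_pct: degenerate input, baseline suv_max must be > 0 (lesion ",
         baseline$lesion_id, ")")
  if (isTRUE(followup$resolved)) return(-100)
  100 * (followup$suv_max - baseline$suv_max) / baseline$suv_max
}

# Vectorised delta over matched baseline targets: named percent vector.
# Targets whose baseline SUV is not > 0, or that are absent from the
# follow-up scan, are dropped.
.target_deltas <- function(baseline, followup) {
  bl <- baseline$lesions
  fl <- followup$lesions
  ids <- intersect(baseline$target_ids, bl$lesion_id)
  ids <- ids[bl$suv_max[match(ids, bl$lesion_id)] > 0]
  ids <- ids[ids %in% fl$lesion_id]
  if (!length(ids)) return(stats::setNames(numeric(0), character(0)))
  b <- bl$suv_max[match(ids, bl$lesion_id)]
  f <- fl$suv_max[match(ids, fl$lesion_id)]
  res <- fl$resolved[match(ids, fl$lesion_id)]
  d <- 100 * (f - b) / b
  d[res] <- -100
  stats::setNames(d, ids)
}

#' Mean SUVmax change over target lesions
#'
#' The per-patient summary of metabolic change: the arithmetic mean of
#' [lesion_delta_pct()] over baseline target lesions matched (by
#' `lesion_id`) in the follow-up scan. New lesions do not enter the
#' mean; resolved lesions contribute -100.
#'
#' @param baseline,followup [scan_record()]s.
#' @return Mean percent change across matched targets.
#' @export
mean_delta_suvmax <- function(baseline, followup) {
  d <- .target_deltas(baseline, followup)
  if (!length(d))
    stop("mean_delta_suvmax: no baseline target lesion with suv_max > 0 is ",
         "matched in the follow-up scan")
  mean(d)
}

#' Classify a follow-up PET against baseline
#'
#' Assigns the metabolic response category for one follow-up scan
#' relative to baseline, by applying, in order:
#'
#' 1. **CR** - every baseline target lesion is resolved at follow-up
#'    (complete disappearance of uptake) and there is no new lesion;
#' 2. **PD** - any new metabolically active lesion (a follow-up lesion
#'    id absent from baseline, with positive unresolved uptake), or a
#'    measurable target with increased uptake that also grew >= 20% in
#'    longest diameter, or a non-measurable (no-diameter) target whose
#'    uptake rose by more than `pd_uptake_threshold` percent;
#' 3. **PR** - mean target uptake decrease of at least 25%
#'    (`pr_rule = "mean"`, the default, matching the mean-change
#'    summary reported per patient), or every matched target down by
#'    at least 25% (`pr_rule = "per_lesion"`);
#' 4. **SD** otherwise (uptake substantially unchanged, no substantial
#'    size increase).
#'
#' The 25% boundaries are inclusive within a small floating-point
#' tolerance: a mean change of exactly -25% is PR.
#'
#' @param baseline,followup [scan_record()]s.
#' @param pr_rule `"mean"` or `"per_lesion"` (see above).
#' @param pd_uptake_threshold Percent uptake increase that alone marks
#'   progression of a non-measurable target (default 25).
#' @param tol Floating-point tolerance on the thresholds.
#' @return An object of class `pet_response_call` with elements
#'   `category` (CR/PR/SD/PD), `mean_delta_pct`, `per_lesion_delta_pct`
#'   (named vector), `new_lesions` (ids), `size_progression`.
#' @export
classify_pet_response <- function(baseline, followup,
                                  pr_rule = c("mean", "per_lesion"),
                                  pd_uptake_threshold = 25, tol = 1e-9) {
  pr_rule <- match.arg(pr_rule)
  bl <- baseline$lesions
  fl <- followup$lesions

  new_ids <- setdiff(fl$lesion_id, bl$lesion_id)
  new_active <- new_ids[!fl$resolved[match(new_ids, fl$lesion_id)] &
                          fl$suv_max[match(new_ids, fl$lesion_id)] > 0]

  deltas <- .target_deltas(baseline, followup)
  targets_matched <- names(deltas)

  # CR: every baseline target present and resolved at follow-up
  tids <- baseline$target_ids
  in_fu <- tids %in% fl$lesion_id
  all_resolved <- length(tids) > 0 && all(in_fu) &&
    all(fl$resolved[match(tids, fl$lesion_id)])

  # size progression: measurable matched target grew >= 20%
  meas <- targets_matched[
    !is.na(bl$diameter_mm[match(targets_matched, bl$lesion_id)]) &
      !is.na(fl$diameter_mm[match(targets_matched, fl$lesion_id)])]
  size_prog_ids <- character(0)
  if (length(meas)) {
    d0 <- bl$diameter_mm[match(meas, bl$lesion_id)]
    d1 <- fl$diameter_mm[match(meas, fl$lesion_id)]
    size_prog_ids <- meas[(d1 - d0) / d0 >= 0.20 - tol]
  }
  size_progression <- length(size_prog_ids) > 0

  mean_delta <- if (length(deltas)) mean(deltas)
    else if (all_resolved) -100
    else stop("classify_pet_response: no baseline target lesion with ",
              "suv_max > 0 is matched in the follow-up scan")

  nonmeas <- setdiff(targets_matched,
                     targets_matched[!is.na(bl$diameter_mm[match(targets_matched,
                                                                 bl$lesion_id)])])
  pd_uptake_only <- any(deltas[nonmeas] > pd_uptake_threshold + tol)
  pd_size_confirmed <- any(deltas[size_prog_ids] > tol)

  category <-
    if (all_resolved && length(new_active) == 0) "CR"
    else if (length(new_active) > 0 || pd_size_confirmed || pd_uptake_only) "PD"
    else if (pr_rule == "mean" && mean_delta <= -25 + tol) "PR"
    else if (pr_rule == "per_lesion" && length(deltas) &&
             all(deltas <= -25 + tol)) "PR"
    else "SD"

  structure(
    list(category = category,
         mean_delta_pct = mean_delta,
         per_lesion_delta_pct = deltas,
         new_lesions = new_active,
         size_progression = size_progression),
    class = "pet_response_call"
  )
}

#' @export
print.pet_response_call <- function(x, ...) {
  cat(sprintf("<pet_response_call> %s  (mean dSUVmax %+.1f%%, %d new lesion(s)%s)\n",
              x$category, x$mean_delta_pct, length(x$new_lesions),
              if (x$size_progression) ", size progression" else ""))
  invisible(x)
}

#' Dichotomize a PET response call
#'
#' The two binary readings used in the survival and agreement
#' analyses: responders (CR/PR) versus nonresponders (SD/PD), and
#' non-progressing (CR/PR/SD) versus progressing (PD). In both modes
#' the *favourable* outcome is `TRUE`: `mode = "response"` returns
#' `TRUE` for CR/PR; `mode = "progression"` returns `TRUE` for any
#' category other than PD (i.e. non-progression).
#'
#' @param call A `pet_response_call`, or a category string.
#' @param mode `"response"` or `"progression"`.
#' @return Logical scalar.
#' @export
dichotomize <- function(call, mode = c("response", "progression")) {
  mode <- match.arg(mode)
  category <- if (is.character(call)) call else call$category
  stopifnot(category %in% .recist_levels)
  if (mode == "response") category %in% c("CR", "PR") else category != "PD"
}
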