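#' @keywords internal
.psa_split <- function(psa) {
  if (is.list(psa) && inherits(psa, "patient_course")) psa <- psa$psa
  stopifnot(is.data.frame(psa), all(c("day", "value") %in% names(psa)))
  base <- psa[psa$day <= 0, , drop = FALSE]
  if (nrow(base) != 1)
    stop("PSA series must contain exactly one baseline (day <= 0) value, found ",
         nrow(base))
  on <- psa[psa$day > 0, , drop = FALSE]
  list(baseline = base$value, on = on)
}

#' Maximal on-treatment PSA decline
#'
#' Percent decline from the baseline PSA to the on-treatment nadir
#' over the whole follow-up:
#' `100 * (baseline - min(on-treatment)) / baseline`. Negative when
#' PSA only rose. Always <= 100, with equality exactly when the nadir
#' is 0.
#'
#' @param psa Data frame with columns `day` (integer days from
#'   treatment start, one baseline value at day <= 0) and `value`
#'   (ng/mL), or a [patient_course()].
#' @return Percent decline (numeric scalar).
#' @export
psa_max_decline_pct <- function(psa) {
  s <- .psa_split(psa)
  if (s$baseline <= 0)
    stop("psa_max_decline_pct: degenerate input, baseline PSA must be > 0")
  if (!nrow(s$on))
    stop("psa_max_decline_pct: no on-treatment PSA value")
  100 * (s$baseline - min(s$on$value)) / s$baseline
}

#' PSA responder status (>= 50% decline)
#'
#' `TRUE` iff the maximal PSA decline is at least 50% (boundary
#' inclusive).
#'
#' @inheritParams psa_max_decline_pct
#' @param tol Floating-point tolerance on the 50% boundary.
#' @return Logical scalar.
#' @export
classify_psa_responder <- function(psa, tol = 1e-9) {
  psa_max_decline_pct(psa) >= 50 - tol
}

#' Detect a PSA flare
#'
#' A PSA flare is an initial on-treatment PSA rise above baseline
#' followed by a later decline strictly below the baseline level. The
#' initial rise must occur within `window_days` of treatment start
#' (default 84 days = 12 weeks); the below-baseline crossing may occur
#' at any later time, and values appended after the crossing do not
#' change the verdict.
#'
#' @inheritParams psa_max_decline_pct
#' @param window_days Window (days) within which the initial rise must
#'   occur.
#' @return Logical scalar.
#' @export
detect_psa_flare <- function(psa, window_days = 84) {
  s <- .psa_split(psa)
  if (s$baseline <= 0)
    stop("detect_psa_flare: degenerate input, baseline PSA must be > 0")
  if (nrow(s$on) < 2) return(FALSE)
  rise_days <- s$on$day[s$on$value > s$baseline & s$on$day <= window_days]
  if (!length(rise_days)) return(FALSE)
  any(s$on$value < s$baseline & s$on$day > min(rise_days))
}

#' Per-patient PSA endpoint summary
#'
#' Convenience wrapper computing all PSA endpoints for one course.
#'
#' @param course A [patient_course()].
#' @return One-row data frame: `patient_id`, `baseline_psa`,
#'   `nadir_psa`, `max_decline_pct`, `responder_50`, `psa_flare`.
#' @export
psa_endpoints <- function(course) {
  s <- .psa_split(course$psa)
  data.frame(
    patient_id = course$patient_id,
    baseline_psa = s$baseline,
    nadir_psa = if (nrow(s$on)) min(s$on$value) else NA_real_,
    max_decline_pct = psa_max_decline_pct(course$psa),
    responder_50 = classify_psa_responder(course$psa),
    psa_flare = detect_psa_flare(course$psa),
    stringsAsFactors = FALSE
  )
}
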