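#' Kaplan-Meier fit with median survival
#'
#' Product-limit estimate of the survival function with the median
#' (smallest time at which the estimate drops to 0.5 or below) and its
#' 95% confidence interval obtained by inverting log-log confidence
#' bands (Brookmeyer-Crowley style). The median is `NA` when the curve
#' never reaches 0.5.
#'
#' @param times Event/censoring times in months (>= 0).
#' @param events Logical event indicators (`FALSE` = censored).
#' @param conf Confidence level (default 0.95).
#' @return An object of class `km_fit`: step-function vectors `time`,
#'   `surv`, `n_risk`, `n_event`, `n_censor`, plus `median`,
#'   `median_lo`, `median_hi`, `n`.
#' @export
km_fit <- function(times, events, conf = 0.95) {
  if (length(times) == 0) stop("km_fit: empty input")
  stopifnot(length(times) == length(events), all(times >= 0))
  sf <- survival::survfit(survival::Surv(times, events) ~ 1,
                          conf.type = "log-log", conf.int = conf)
  tab <- summary(sf)$table
  structure(
    list(time = sf$time, surv = sf$surv,
         n_risk = sf$n.risk, n_event = sf$n.event, n_censor = sf$n.censor,
         median = unname(tab["median"]),
         median_lo = unname(tab[grep("LCL", names(tab))]),
         median_hi = unname(tab[grep("UCL", names(tab))]),
         n = length(times), conf = conf),
    class = "km_fit"
  )
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("<km_fit> n = %d, events = %d\n", x$n, sum(x$n_event)))
  cat(sprintf("  median %s months (%.0f%% CI %s - %s)\n",
              format(x$median, digits = 3), 100 * x$conf,
              format(x$median_lo, digits = 3),
              format(x$median_hi, digits = 3)))
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard (unweighted) log-rank comparison of two survival curves,
#' 1 degree of freedom, two-sided p-value. If neither group has any
#' event the statistic is 0 and p = 1.
#'
#' @param times_a,events_a Times and event indicators, group A.
#' @param times_b,events_b Times and event indicators, group B.
#' @return List with `chi2` and `p`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (!length(times_a) || !length(times_b))
    stop("logrank_test: both groups must be non-empty")
  if (sum(events_a) + sum(events_b) == 0)
    return(list(chi2 = 0, p = 1))
  time <- c(times_a, times_b)
  event <- c(events_a, events_b)
  group <- rep(c("A", "B"), c(length(times_a), length(times_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(chi2 = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Maximum partial-likelihood fit (Newton-Raphson, as implemented in
#' `survival::coxph`) with per-covariate hazard ratios, Wald
#' confidence intervals and p-values. Tied event times are handled by
#' Efron's method by default; Breslow is available.
#'
#' @param covariates Numeric matrix or data frame (patients x k);
#'   logical columns are coerced to 0/1.
#' @param times Survival times (months).
#' @param events Logical event indicators.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param conf Confidence level for the Wald intervals.
#' @return An object of class `cox_result`: data frame with columns
#'   `term`, `beta`, `se`, `hazard_ratio`, `lo`, `hi`, `p`; the
#'   log partial likelihood at the optimum is in attribute `loglik`
#'   and the fitted `coxph` object in attribute `fit`.
#' @export
cox_fit <- function(covariates, times, events,
                    ties = c("efron", "breslow"), conf = 0.95) {
  ties <- match.arg(ties)
  x <- as.data.frame(covariates)
  if (!ncol(x)) stop("cox_fit: no covariate supplied")
  x[] <- lapply(x, function(col) as.numeric(col))
  if (sum(events) < 1) stop("cox_fit: at least one event is required")
  const <- vapply(x, function(col) length(unique(col)) < 2, logical(1))
  if (any(const))
    stop("cox_fit: covariate(s) ", paste(names(x)[const], collapse = ", "),
         " constant across patients (no information)")
  dat <- cbind(data.frame(.time = times, .event = as.numeric(events)), x)
  fit <- survival::coxph(
    stats::as.formula(paste("survival::Surv(.time, .event) ~",
                            paste(sprintf("`%s`", names(x)), collapse = " + "))),
    data = dat, ties = ties)
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  if (any(!is.finite(beta)) || any(!is.finite(se)) || any(abs(beta) > 15))
    stop("cox_fit: monotone partial likelihood (complete separation); ",
         "hazard ratio not estimable for ",
         paste(names(beta)[!is.finite(beta) | abs(beta) > 15], collapse = ", "))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  res <- data.frame(
    term = names(x),
    beta = unname(beta),
    se = unname(se),
    hazard_ratio = unname(exp(beta)),
    lo = unname(exp(beta - z * se)),
    hi = unname(exp(beta + z * se)),
    p = unname(2 * stats::pnorm(-abs(beta / se))),
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(res, class = c("cox_result", "data.frame"),
            loglik = unname(fit$loglik[2]), fit = fit)
}

#' @export
print.cox_result <- function(x, digits = 3, ...) {
  cat("<cox_result>  log partial likelihood:",
      format(attr(x, "loglik"), digits = 6), "\n")
  df <- as.data.frame(x)
  df$beta <- NULL; df$se <- NULL
  print(format(df, digits = digits), row.names = FALSE)
  invisible(x)
}

#' Univariate and multivariate Cox analyses of the standard predictors
#'
#' Mirrors the layout of the outcome-prediction table: univariate Cox
#' models for each of Gleason score (8-9 vs 6-7), number of prior
#' chemotherapy regimens (>= 2 vs 1), PSA decline (< 50% vs >= 50%),
#' PET response (SD/PD vs CR/PR) and PET progression (PD vs
#' CR/PR/SD), for the chosen endpoint, followed by a multivariate
#' model. In every predictor the *adverse* level is coded 1, so
#' hazard ratios > 1 indicate worse outcome.
#'
#' Because the two PET dichotomies are strongly collinear, the default
#' multivariate model enters Gleason, prior chemotherapy, PSA decline
#' and the PD-vs-non-PD PET dichotomy;
#' `multivariate = "univariate_significant"` instead enters the
#' predictors with univariate p < `alpha` (PET represented by
#' progression if both dichotomies qualify).
#'
#' @param labels Per-patient data frame as returned by
#'   [classify_cohort()]: needs logical columns `gleason_high`,
#'   `multi_chemo`, `responder_50`, plus `pet_category` and
#'   `effective_nonprogression`, and the endpoint columns
#'   `pfs_months`/`pfs_event` or `os_months`/`os_event`.
#' @param endpoint `"pfs"` or `"os"`.
#' @param multivariate `"all"` (default, see above) or
#'   `"univariate_significant"`.
#' @param alpha Univariate significance threshold for the selective
#'   mode.
#' @param use_flare_adjusted Use the flare-adjusted progression label
#'   (`effective_nonprogression`) for the PD-vs-non-PD dichotomy
#'   (default `TRUE`); otherwise the raw early PET category.
#' @param ties Passed to [cox_fit()].
#' @return List with elements `univariate` and `multivariate`, each a
#'   `cox_result` (multivariate may be `NULL` if no predictor
#'   qualifies).
#' @export
run_table4 <- function(labels, endpoint = c("pfs", "os"),
                       multivariate = c("all", "univariate_significant"),
                       alpha = 0.05, use_flare_adjusted = TRUE,
                       ties = "efron") {
  endpoint <- match.arg(endpoint)
  multivariate <- match.arg(multivariate)
  times <- labels[[paste0(endpoint, "_months")]]
  events <- labels[[paste0(endpoint, "_event")]]

  progression <- if (use_flare_adjusted) !labels$effective_nonprogression
    else labels$pet_category == "PD"
  preds <- data.frame(
    gleason_8_9 = as.numeric(labels$gleason_high),
    prior_chemo_2plus = as.numeric(labels$multi_chemo),
    psa_decline_lt50 = as.numeric(!labels$responder_50),
    pet_nonresponse = as.numeric(!labels$pet_category %in% c("CR", "PR")),
    pet_progression = as.numeric(progression)
  )

  uni <- do.call(rbind, lapply(names(preds), function(nm) {
    as.data.frame(cox_fit(preds[nm], times, events, ties = ties))
  }))
  class(uni) <- c("cox_result", "data.frame")

  mv_terms <- if (multivariate == "all") {
    c("gleason_8_9", "prior_chemo_2plus", "psa_decline_lt50",
      "pet_progression")
  } else {
    sig <- uni$term[uni$p < alpha]
    if (all(c("pet_nonresponse", "pet_progression") %in% sig))
      sig <- setdiff(sig, "pet_nonresponse")
    sig
  }
  mv <- if (length(mv_terms) >= 1)
    cox_fit(preds[mv_terms], times, events, ties = ties) else NULL
  list(univariate = uni, multivariate = mv, endpoint = endpoint)
}
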