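#' Synthetic cohort configuration
#'
#' Parameters of the cohort generator. Defaults emulate a ~42-patient
#' metastatic CRPC cohort starting abiraterone: latent early-response
#' classes in proportions 3:11:6:16:6 (CR, PR, SD, true progression,
#' bone flare), lesion SUVmax and baseline PSA drawn from lognormals
#' (PSA median 23.3 ng/mL with a wide 1.5-1083 range), class-specific
#' follow-up uptake factors straddling the +/-25% decision boundaries
#' (CR resolves, PR in U(0.3, 0.7), SD in U(0.8, 1.2), progression and
#' flare in U(1.3, 1.8)), PSA trajectories with >= 50% decline in
#' responders and occasional PSA flare, and exponential PFS/OS with a
#' PD-vs-non-PD hazard ratio of 6.8 (PFS) and 5.3 (OS). The baseline
#' hazards give an overall median PFS of about 7.0 months and OS of
#' about 18.7 months under the default class mix.
#'
#' @param n_patients Cohort size (default 42).
#' @param class_probs Named probabilities over
#'   `c("CR","PR","SD","PD","flare")`; must sum to 1. `"PD"` is true
#'   progression; `"flare"` patients read PD early but are not
#'   progressing.
#' @param baseline_suv_meanlog,baseline_suv_sdlog Lognormal parameters
#'   of baseline lesion SUVmax.
#' @param suv_noise_sd Multiplicative measurement noise on follow-up
#'   SUVs, as a lognormal sd in percent (0 = noiseless).
#' @param psa_meanlog,psa_sdlog Lognormal parameters of baseline PSA
#'   (ng/mL).
#' @param psa_noise_sd Multiplicative noise on on-treatment PSA values
#'   (percent).
#' @param psa_responder_prob Named per-class probability of a >= 50%
#'   PSA decline.
#' @param psa_flare_prob Probability that a PSA responder shows an
#'   initial PSA rise before declining.
#' @param hr_pd_pfs,hr_pd_os True hazard ratios of progressing vs
#'   non-progressing patients.
#' @param base_hazard_pfs,base_hazard_os Baseline (non-PD) exponential
#'   hazards, per month.
#' @param censor_max_months Upper bound of the independent uniform
#'   censoring time.
#' @param p_gleason_high,p_multi_chemo Covariate prevalences.
#' @param seed Optional integer seed stored in the config.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 42,
                          class_probs = c(CR = 3, PR = 11, SD = 6,
                                          PD = 16, flare = 6) / 42,
                          baseline_suv_meanlog = log(8),
                          baseline_suv_sdlog = 0.4,
                          suv_noise_sd = 5,
                          psa_meanlog = log(23.3),
                          psa_sdlog = 1.4,
                          psa_noise_sd = 2,
                          psa_responder_prob = c(CR = 1, PR = 0.9, SD = 0.4,
                                                 PD = 0.05, flare = 1),
                          psa_flare_prob = 0.05,
                          hr_pd_pfs = 6.8,
                          hr_pd_os = 5.3,
                          base_hazard_pfs = 0.0443,
                          base_hazard_os = 0.01845,
                          censor_max_months = 40,
                          p_gleason_high = 0.6,
                          p_multi_chemo = 0.37,
                          seed = NULL) {
  cfg <- as.list(environment())
  cls <- c("CR", "PR", "SD", "PD", "flare")
  if (!setequal(names(cfg$class_probs), cls))
    stop("cohort_config: class_probs must be named over ",
         paste(cls, collapse = ", "))
  cfg$class_probs <- cfg$class_probs[cls]
  if (abs(sum(cfg$class_probs) - 1) > 1e-8)
    stop("cohort_config: class_probs must sum to 1")
  if (!setequal(names(cfg$psa_responder_prob), cls))
    stop("cohort_config: psa_responder_prob must be named over ",
         paste(cls, collapse = ", "))
  for (f in c("n_patients", "baseline_suv_sdlog", "psa_sdlog",
              "hr_pd_pfs", "hr_pd_os", "base_hazard_pfs", "base_hazard_os",
              "censor_max_months"))
    if (cfg[[f]] <= 0) stop("cohort_config: ", f, " must be > 0")
  if (cfg$suv_noise_sd < 0 || cfg$psa_noise_sd < 0)
    stop("cohort_config: noise sds must be >= 0")
  structure(cfg, class = "cohort_config")
}

# data.frame() without the coercion/row-name machinery; columns must
# already be equal-length atomic vectors. Generator hot path only.
.quick_df <- function(...) {
  cols <- list(...)
  structure(cols, class = "data.frame",
            row.names = .set_row_names(length(cols[[1]])))
}

.sim_psa_series <- function(baseline, responder, riser, psa_flare, noise_sd) {
  days <- c(0L, 28L, 56L, 84L, 112L, 140L, 168L)
  k <- length(days) - 1
  frac <- if (responder) {
    nadir <- stats::runif(1, 0.02, 0.45)
    pmax(nadir, nadir + (1 - nadir) * exp(-(1:k)))
  } else if (riser) {
    stats::runif(1, 1.08, 1.2)^(1:k)
  } else {
    nadir <- stats::runif(1, 0.55, 0.95)
    pmax(nadir, nadir + (1 - nadir) * exp(-(1:k)))
  }
  if (psa_flare) frac[1] <- stats::runif(1, 1.1, 1.35)
  noise <- if (noise_sd > 0) exp(stats::rnorm(k, 0, noise_sd / 100)) else 1
  .quick_df(day = days, value = baseline * c(1, frac * noise))
}

#' Generate a synthetic cohort
#'
#' Draws a cohort of [patient_course()]s with known latent truth. Per
#' patient: a latent class; 2-5 baseline lesions (all targets) with
#' lognormal SUVmax — bone-only for progressing and flare patients,
#' mixed sites otherwise, with CT diameters for soft-tissue lesions;
#' an early follow-up scan (day 28-45) whose uptake is the baseline
#' scaled by the class factor with multiplicative noise; for
#' progressing and flare patients a confirmatory scan ~75 days later
#' (flare: back near baseline uptake; progression: a further >= 35%
#' rise); monthly PSA per class (flare patients always decline
#' >= 50%, progressing patients rise); a 3-month CT read (PD for
#' progressing patients, SD otherwise); and exponential PFS/OS with
#' the configured PD hazard ratios, censored by independent uniform
#' times.
#'
#' With `suv_noise_sd = 0` the early PET classification recovers the
#' latent class exactly and the flare procedure identifies exactly the
#' latent flare patients.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed (overrides `config$seed`); the generator
#'   is fully reproducible given a seed.
#' @return An object of class `synthetic_cohort`: list with `courses`
#'   (list of [patient_course()]), `truth` (data frame: `patient_id`,
#'   `class`, `is_flare`, `is_pd`), and `config`.
#' @export
generate_cohort <- function(config = cohort_config(), seed = config$seed) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_patients
  cls <- sample(names(config$class_probs), n, replace = TRUE,
                prob = config$class_probs)
  gleason <- stats::runif(n) < config$p_gleason_high
  chemo <- stats::runif(n) < config$p_multi_chemo

  is_pd <- cls == "PD"
  t_pfs <- stats::rexp(n, config$base_hazard_pfs *
                         ifelse(is_pd, config$hr_pd_pfs, 1))
  t_os <- stats::rexp(n, config$base_hazard_os *
                        ifelse(is_pd, config$hr_pd_os, 1))
  c_pfs <- stats::runif(n, 0, config$censor_max_months)
  c_os <- stats::runif(n, 0, config$censor_max_months)

  courses <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- sprintf("P%03d", i)
    k <- sample(2:5, 1)
    lesion_ids <- sprintf("%s_L%d", pid, seq_len(k))
    sites <- if (cls[i] %in% c("PD", "flare")) rep("bone", k)
      else sample(.lesion_sites[1:4], k, replace = TRUE,
                  prob = c(0.7, 0.2, 0.06, 0.04))
    suv0 <- stats::rlnorm(k, config$baseline_suv_meanlog,
                          config$baseline_suv_sdlog)
    diam0 <- ifelse(sites == "bone", NA_real_, stats::runif(k, 8, 30))
    baseline <- scan_record(
      scan_day = 0L,
      lesions = .quick_df(lesion_id = lesion_ids, site = sites,
                          suv_max = suv0, diameter_mm = diam0,
                          resolved = rep(FALSE, k)),
      target_ids = lesion_ids)

    factor_i <- switch(cls[i],
                       CR = 0,
                       PR = stats::runif(1, 0.3, 0.7),
                       SD = stats::runif(1, 0.8, 1.2),
                       stats::runif(1, 1.3, 1.8))  # PD and flare
    noise <- if (config$suv_noise_sd > 0)
      exp(stats::rnorm(k, 0, config$suv_noise_sd / 100)) else 1
    suv1 <- suv0 * factor_i * noise
    resolved1 <- cls[i] == "CR"
    diam1 <- diam0 * ifelse(rep(cls[i] == "PD", k), 1.3,
                            stats::runif(k, 0.92, 1.02))
    early_day <- sample(28:45, 1)
    early <- scan_record(
      scan_day = early_day,
      lesions = .quick_df(lesion_id = lesion_ids, site = sites,
                          suv_max = if (resolved1) rep(0, k) else suv1,
                          diameter_mm = diam1,
                          resolved = rep(resolved1, k)),
      target_ids = lesion_ids)

    followups <- list(early)
    if (cls[i] %in% c("PD", "flare")) {
      suv2 <- if (cls[i] == "flare") {
        suv0 * stats::runif(1, 0.85, 1.05)
      } else {
        suv1 * stats::runif(1, 1.35, 1.6)
      }
      noise2 <- if (config$suv_noise_sd > 0)
        exp(stats::rnorm(k, 0, config$suv_noise_sd / 100)) else 1
      confirm <- scan_record(
        scan_day = early_day + 75L,
        lesions = .quick_df(lesion_id = lesion_ids, site = sites,
                            suv_max = suv2 * noise2, diameter_mm = diam1,
                            resolved = rep(FALSE, k)),
        target_ids = lesion_ids)
      followups <- list(early, confirm)
    }

    psa0 <- stats::rlnorm(1, config$psa_meanlog, config$psa_sdlog)
    responder <- stats::runif(1) < config$psa_responder_prob[[cls[i]]]
    riser <- !responder && cls[i] == "PD"
    pflare <- responder && stats::runif(1) < config$psa_flare_prob
    psa <- .sim_psa_series(psa0, responder, riser, pflare,
                           config$psa_noise_sd)

    ct_cat <- if (cls[i] == "PD") "PD" else "SD"
    ct <- .quick_df(day = 90L, category = ct_cat)

    courses[[i]] <- patient_course(
      patient_id = pid, baseline_scan = baseline, followup_scans = followups,
      psa = psa, ct = ct,
      pfs_months = min(t_pfs[i], c_pfs[i]), pfs_event = t_pfs[i] <= c_pfs[i],
      os_months = min(t_os[i], c_os[i]), os_event = t_os[i] <= c_os[i],
      covariates = list(gleason_high = gleason[i], multi_chemo = chemo[i]))
  }

  truth <- data.frame(
    patient_id = vapply(courses, function(cc) cc$patient_id, character(1)),
    class = cls, is_flare = cls == "flare", is_pd = is_pd,
    stringsAsFactors = FALSE)
  structure(list(courses = courses, truth = truth, config = config),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", length(x$courses), "patients\n")
  print(table(latent_class = x$truth$class))
  invisible(x)
}
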