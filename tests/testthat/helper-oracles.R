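# Independent oracles and small fixture builders shared by the tests.
# These deliberately re-derive each quantity from first principles,
# never through the code paths they are used to check.

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- fixture builders -------------------------------------------------

make_lesions <- function(ids, suv, diameter = NA_real_, resolved = FALSE,
                         site = "bone") {
  data.frame(lesion_id = ids, site = rep_len(site, length(ids)),
             suv_max = suv, diameter_mm = rep_len(diameter, length(ids)),
             resolved = rep_len(resolved, length(ids)),
             stringsAsFactors = FALSE)
}

make_scan <- function(day, ids, suv, ...) {
  scan_record(day, make_lesions(ids, suv, ...), target_ids = ids)
}

make_psa <- function(values, days = seq(0, by = 28, length.out = length(values))) {
  data.frame(day = days, value = values)
}

# A minimal valid course around given scans/psa.
make_course <- function(id = "P1", baseline, followups = list(),
                        psa = make_psa(c(20, 10)),
                        ct = data.frame(day = 90L, category = "SD"),
                        pfs = 7, pfs_event = TRUE, os = 15, os_event = FALSE) {
  patient_course(id, baseline, followups, psa, ct,
                 pfs_months = pfs, pfs_event = pfs_event,
                 os_months = os, os_event = os_event,
                 covariates = list(gleason_high = TRUE, multi_chemo = FALSE))
}

# --- Kaplan-Meier product-limit, computed directly --------------------

km_oracle <- function(times, events) {
  ut <- sort(unique(times[events]))
  s <- 1
  surv <- numeric(length(ut))
  for (i in seq_along(ut)) {
    at_risk <- sum(times >= ut[i])
    d <- sum(times == ut[i] & events)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(time = ut, surv = surv,
       median = if (any(surv <= 0.5)) ut[which(surv <= 0.5)[1]] else NA_real_)
}

# --- Cox log partial likelihood (no tied event times) -----------------

cox_logpl <- function(beta, x, times, events) {
  ord <- order(times)
  x <- x[ord]; times <- times[ord]; events <- events[ord]
  ll <- numeric(length(beta))
  for (i in which(events)) {
    risk <- times >= times[i]
    ll <- ll + beta * x[i] - log(colSums(exp(outer(x[risk], beta))))
  }
  ll
}

# Exhaustive grid maximizer of the partial likelihood.
cox_grid_oracle <- function(x, times, events, lo = -5, hi = 5, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  ll <- cox_logpl(grid, x, times, events)
  grid[which.max(ll)]
}

# --- two-group log-rank statistic from the O-E tabulation -------------

logrank_oracle <- function(times_a, events_a, times_b, events_b) {
  time <- c(times_a, times_b)
  event <- c(events_a, events_b)
  grp_a <- rep(c(TRUE, FALSE), c(length(times_a), length(times_b)))
  ut <- sort(unique(time[event]))
  o_minus_e <- 0
  v <- 0
  for (t in ut) {
    n <- sum(time >= t)
    n_a <- sum(time >= t & grp_a)
    d <- sum(time == t & event)
    d_a <- sum(time == t & event & grp_a)
    o_minus_e <- o_minus_e + d_a - d * n_a / n
    if (n > 1)
      v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# Permutation p-value for the log-rank statistic.
logrank_perm_p <- function(times_a, events_a, times_b, events_b, reps = 500) {
  obs <- logrank_oracle(times_a, events_a, times_b, events_b)
  time <- c(times_a, times_b); event <- c(events_a, events_b)
  n_a <- length(times_a)
  hits <- 0
  for (r in seq_len(reps)) {
    idx <- sample(seq_along(time), n_a)
    stat <- logrank_oracle(time[idx], event[idx], time[-idx], event[-idx])
    if (stat >= obs - 1e-12) hits <- hits + 1
  }
  hits / reps
}

# Small Cox fixture datasets (n <= 8, binary covariate, no tied event
# times) for the grid-oracle comparisons.
# Event times interleave between the arms so the partial likelihood
# has an interior maximum (no separation).
cox_fixtures <- list(
  list(x = c(0, 1, 0, 1, 0, 1),
       times = c(1, 2, 3, 4, 5, 6),
       events = rep(TRUE, 6)),
  list(x = c(0, 1, 0, 1, 0, 1, 0, 1),
       times = c(2, 1, 4, 3, 6, 5, 8, 10),
       events = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE)),
  list(x = c(1, 0, 1, 0, 1),
       times = c(1.5, 2.5, 4.5, 3.5, 6.5),
       events = c(TRUE, TRUE, FALSE, TRUE, TRUE)),
  list(x = c(0, 0, 1, 1, 0, 1, 0),
       times = c(4, 9, 6, 7, 11, 2, 3),
       events = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE, FALSE))
)
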