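#' Build a 2x2 agreement table
#'
#' Cross-tabulates a per-patient PET dichotomy (test) against the PSA
#' dichotomy (reference): `a` = both positive, `b` = PET-positive /
#' PSA-negative, `c` = PET-negative / PSA-positive, `d` = both
#' negative. If both vectors are named, patients are aligned by name
#' and the sets must coincide.
#'
#' @param pet_flags,psa_flags Logical vectors (no `NA`), one entry per
#'   patient.
#' @return An object of class `two_by_two` with integer cells
#'   `a`, `b`, `c`, `d`.
#' @export
build_two_by_two <- function(pet_flags, psa_flags) {
  if (!is.null(names(pet_flags)) && !is.null(names(psa_flags))) {
    if (!setequal(names(pet_flags), names(psa_flags)))
      stop("build_two_by_two: patient sets differ between PET and PSA flags")
    psa_flags <- psa_flags[names(pet_flags)]
  }
  if (length(pet_flags) != length(psa_flags))
    stop("build_two_by_two: flag vectors have different lengths")
  if (length(pet_flags) == 0)
    stop("build_two_by_two: empty input")
  if (anyNA(pet_flags) || anyNA(psa_flags))
    stop("build_two_by_two: missing flags are not allowed")
  two_by_two(a = sum(pet_flags & psa_flags),
             b = sum(pet_flags & !psa_flags),
             c = sum(!pet_flags & psa_flags),
             d = sum(!pet_flags & !psa_flags))
}

#' @rdname build_two_by_two
#' @param a,b,c,d Non-negative integer cell counts (test-by-reference).
#' @export
two_by_two <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("two_by_two: cells must be non-negative integers")
  if (sum(cells) == 0) stop("two_by_two: table is empty (n = 0)")
  cells <- stats::setNames(as.integer(round(cells)), names(cells))
  structure(as.list(cells), class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(test = c("positive", "negative"),
                              reference = c("positive", "negative")))
  cat("<two_by_two> n =", x$a + x$b + x$c + x$d, "\n")
  print(m)
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Beta-quantile exact interval for a binomial proportion. For 0
#' successes the lower bound is 0; for `n` successes the upper bound
#' is 1.
#'
#' @param successes,n Counts with `0 <= successes <= n`, `n > 0`.
#' @param conf Confidence level (default 0.95).
#' @return Numeric vector `c(lo, hi)`.
#' @export
clopper_pearson_ci <- function(successes, n, conf = 0.95) {
  if (n <= 0 || successes < 0 || successes > n ||
      successes != round(successes) || n != round(n))
    stop("clopper_pearson_ci: invalid counts (successes = ", successes,
         ", n = ", n, ")")
  ci <- stats::binom.test(round(successes), round(n),
                          conf.level = conf)$conf.int
  c(lo = ci[1], hi = ci[2])
}

#' Woolf (logit) confidence interval for an odds ratio
#'
#' `OR = ad / bc` with CI
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. Any zero cell
#' triggers the Haldane-Anscombe correction (+0.5 to every cell),
#' flagged in the result.
#'
#' @param t A [two_by_two()] table.
#' @param conf Confidence level.
#' @return List with `estimate`, `lo`, `hi`, and logical `corrected`.
#' @export
woolf_or_ci <- function(t, conf = 0.95) {
  stopifnot(inherits(t, "two_by_two"))
  cells <- c(t$a, t$b, t$c, t$d)
  corrected <- any(cells == 0)
  if (corrected) cells <- cells + 0.5
  or <- cells[1] * cells[4] / (cells[2] * cells[3])
  z <- stats::qnorm(1 - (1 - conf) / 2)
  se <- sqrt(sum(1 / cells))
  list(estimate = or,
       lo = exp(log(or) - z * se),
       hi = exp(log(or) + z * se),
       corrected = corrected)
}

.proportion_stat <- function(num, den, conf, what) {
  if (den == 0)
    return(list(estimate = NA_real_, lo = NA_real_, hi = NA_real_,
                reason = paste0(what, " undefined: zero denominator")))
  ci <- clopper_pearson_ci(num, den, conf)
  list(estimate = num / den, lo = unname(ci[1]), hi = unname(ci[2]))
}

#' Agreement statistics for a 2x2 method comparison
#'
#' The six statistics comparing a test dichotomy against a reference
#' dichotomy: positive percent agreement `a/(a+c)`, negative percent
#' agreement `d/(b+d)`, positive predictive value `a/(a+b)`, negative
#' predictive value `d/(c+d)`, overall agreement `(a+d)/n` - each
#' with an exact Clopper-Pearson interval - and the odds ratio
#' `ad/bc` with a Woolf logit interval (see [woolf_or_ci()]).
#' A statistic with a zero denominator is reported as absent with a
#' reason rather than as `NaN`.
#'
#' @param t A [two_by_two()] table.
#' @param conf Confidence level (default 0.95).
#' @return An object of class `agreement_stats`: named list with
#'   elements `ppa`, `npa`, `ppv`, `npv`, `overall` (each a list
#'   `estimate`/`lo`/`hi` on the proportion scale) and `odds_ratio`.
#' @export
agreement_statistics <- function(t, conf = 0.95) {
  stopifnot(inherits(t, "two_by_two"))
  n <- t$a + t$b + t$c + t$d
  structure(
    list(ppa = .proportion_stat(t$a, t$a + t$c, conf, "PPA"),
         npa = .proportion_stat(t$d, t$b + t$d, conf, "NPA"),
         ppv = .proportion_stat(t$a, t$a + t$b, conf, "PPV"),
         npv = .proportion_stat(t$d, t$c + t$d, conf, "NPV"),
         overall = .proportion_stat(t$a + t$d, n, conf, "overall agreement"),
         odds_ratio = woolf_or_ci(t, conf),
         conf = conf, table = t),
    class = "agreement_stats"
  )
}

#' Round half away from zero
#'
#' Rounds 0.5 up (for positive numbers), matching how percentages are
#' conventionally rounded in clinical tables, unlike base R's
#' round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.agreement_stats <- function(x, ...) {
  labels <- c(ppa = "Positive % Agreement", npa = "Negative % Agreement",
              ppv = "Positive Predictive Value",
              npv = "Negative Predictive Value", overall = "Overall Agreement")
  cat(sprintf("%-28s %9s %10s %10s\n", "Measurement", "Estimate",
              sprintf("Lower %d%%", round(100 * x$conf)),
              sprintf("Upper %d%%", round(100 * x$conf))))
  for (nm in names(labels)) {
    s <- x[[nm]]
    if (is.na(s$estimate)) {
      cat(sprintf("%-28s %9s   (%s)\n", labels[[nm]], "-", s$reason))
    } else {
      cat(sprintf("%-28s %8d%% %9d%% %9d%%\n", labels[[nm]],
                  round_half_up(100 * s$estimate),
                  round_half_up(100 * s$lo), round_half_up(100 * s$hi)))
    }
  }
  or <- x$odds_ratio
  cat(sprintf("%-28s %9.2f %10.2f %10.2f%s\n", "Odds Ratio", or$estimate,
              or$lo, or$hi,
              if (isTRUE(or$corrected)) "  (Haldane-Anscombe corrected)" else ""))
  invisible(x)
}

#' Tabular form of agreement statistics
#'
#' @param x An `agreement_stats` object.
#' @param ... Unused.
#' @return Data frame with columns `statistic`, `estimate`, `lo`, `hi`
#'   (proportions; odds ratio on its own scale).
#' @export
as.data.frame.agreement_stats <- function(x, ...) {
  nms <- c("ppa", "npa", "ppv", "npv", "overall", "odds_ratio")
  data.frame(
    statistic = nms,
    estimate = vapply(nms, function(n) x[[n]]$estimate, numeric(1)),
    lo = vapply(nms, function(n) x[[n]]$lo, numeric(1)),
    hi = vapply(nms, function(n) x[[n]]$hi, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
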