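---
title: "Early FCH-PET/CT response assessment and bone-flare adjudication: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Early FCH-PET/CT response assessment and bone-flare adjudication: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petflare)
```

# The clinical problem

In metastatic castration-resistant prostate cancer (CRPC) treated with
abiraterone, the clinician wants to know *early* — within 3–6 weeks —
whether the drug is working, because treatment continues until
progression and ineffective cycles are costly and toxic. The two early
signals available are serum PSA and metabolic imaging
(18F-fluorocholine PET/CT, FCH-PET/CT), and both are imperfect: PSA
can show transient flares under androgen-biosynthesis inhibition, and
bone metastases responding to therapy can *increase* their tracer
uptake early on (an osteoblastic healing reaction — the bone flare)
and masquerade as progression.

`petflare` implements the analysis chain around these signals:
lesion-level metabolic response classification, PSA endpoints, a
multi-timepoint bone-flare adjudication, PET-vs-PSA agreement
statistics, and survival models linking the early classification to
progression-free (PFS) and overall survival (OS). A synthetic-cohort
generator provides data with known ground truth for every stage.

# Metabolic response classification

For a lesion with baseline SUVmax $s_0 > 0$ and follow-up SUVmax
$s_1$, the percent change is $\Delta = 100\,(s_1 - s_0)/s_0$; a lesion
whose uptake has become indistinguishable from background
(`resolved`) is treated as $s_1 = 0$, i.e. $\Delta = -100$. The
per-patient summary $\overline{\delta\mathrm{SUVmax}}$ is the
arithmetic mean of $\Delta$ over the baseline *target* lesions (at
least two are designated at baseline) that are matched by identifier
in the follow-up scan. New lesions never enter the mean.

Categories are assigned by the first matching rule:

1. **CR** — every baseline target resolved, no new metabolically
   active lesion.
2. **PD** — a new metabolically active lesion; or a measurable target
   with increased uptake *and* ≥ 20% growth in longest diameter; or a
   non-measurable (bone) target with uptake rise > 25%.
3. **PR** — mean change ≤ −25%.
4. **SD** — otherwise.

Design choices that were genuinely open:

- **PR on the mean, not per lesion.** The "decrease more than 25% of
  target lesions" criterion is applied to the mean δSUVmax, consistent
  with how per-patient metabolic change is conventionally summarised
  and reported; `pr_rule = "per_lesion"` provides the stricter
  every-target-down-25% variant for sensitivity analyses.
- **Size confirmation only where size exists.** For measurable
  (soft-tissue) targets, progression requires the uptake rise to be
  confirmed by ≥ 20% diameter growth; for non-measurable bone lesions
  — which have no RECIST diameter — an uptake rise > 25% alone
  suffices. This matches the flare definition's uptake-only trigger
  and the fact that early bone PD reads are made on uptake alone.
- **Boundary conventions.** The −25% boundary is inclusive toward PR
  (a mean change of exactly −25% is PR), implemented as
  $\Delta \le -25 + 10^{-9}$. The +25% progression boundary is
  strict ("more than 25%"): exactly +25% remains SD, implemented as
  $\Delta > 25 + 10^{-9}$. The asymmetry deliberately avoids calling
  progression at the printed threshold itself.
- **Matching is by lesion identifier**, not anatomy: a follow-up
  lesion id absent from baseline is a "new lesion"; a baseline target
  absent from follow-up simply drops out of the mean (and blocks CR,
  since its resolution is unverified). Image registration is out of
  scope.

Two dichotomies feed the downstream analyses: *response* (CR/PR vs
SD/PD) and *progression* (PD vs CR/PR/SD). Both return the favourable
level as `TRUE`.

# PSA endpoints

With baseline value $b > 0$ (the unique measurement at day ≤ 0) and
on-treatment nadir $m$, the maximal decline is $100\,(b - m)/b$; it is
≤ 100 with equality iff $m = 0$, and negative if PSA only rose.
Responders are declines ≥ 50% (boundary inclusive). A PSA flare is an
on-treatment value above baseline within the first 12 weeks (the
window is configurable; no magnitude threshold is imposed, since none
is established) followed by a later value strictly below baseline.

# Bone-flare adjudication

An early PD read enters a four-step procedure; every step's outcome is
recorded in an `evidence` list so the decision path is reproducible.

1. **Trigger** — the early scan shows > 25% uptake rise of at least
   one known (baseline) lesion. A PD read produced only by a new
   lesion is not a flare candidate and exits as
   `confirmed_progression`.
2. **PSA** — maximal decline ≥ 50%, or the *of-interest* variant: a
   continued decline below baseline that stays short of 50% (the last
   measurement must be below baseline).
3. **CT** — the CT assessment nearest day 90 is not PD. Absence of
   any CT fails the condition (conservative: a flare cannot be
   confirmed without it).
4. **Confirmation** — a second follow-up PET shows improvement or
   stability relative to the early scan. "Stability" is quantified as
   mean uptake change ≤ +25% over lesions matched between the two
   scans with no new lesion, reusing the only threshold the criteria
   define; "improvement" is ≤ −25%.

All four with PSA ≥ 50% → `confirmed_flare`; with the sub-50% variant
→ `flare_of_interest`; (1)–(3) but no confirmatory scan →
`suspected_unresolved`; any failure → `confirmed_progression`. The
flare-adjusted progression label reclassifies confirmed and
of-interest flares as non-progression; suspected-unresolved stays
progression (the evidence never arrived). Both counting conventions —
confirmed-only versus confirmed-plus-of-interest — are recoverable
from `flare_status`, since published flare counts have used either.

Timing windows are soft: the early scan is expected within days 19–69
from treatment start and the confirmatory scan 60–120 days after the
early one, reflecting observed rather than nominal practice; outside
these windows the assessment proceeds with a warning.

# Agreement statistics

For a 2×2 table (test = PET dichotomy, reference = PSA dichotomy) with
cells $a, b, c, d$: PPA $= a/(a+c)$, NPA $= d/(b+d)$, PPV $= a/(a+b)$,
NPV $= d/(c+d)$, overall agreement $= (a+d)/n$, each with an exact
Clopper–Pearson 95% interval, and OR $= ad/bc$ with the Woolf logit
interval $\exp(\ln \mathrm{OR} \pm z\sqrt{1/a+1/b+1/c+1/d})$; a zero
cell triggers the Haldane–Anscombe +0.5 correction, flagged in the
output. These two interval methods were chosen because they reproduce
published tables of this kind at their printed rounding. A statistic
with an empty denominator is reported as absent with a reason, never
as `NaN`. Displayed percentages are rounded half away from zero, the
convention of clinical tables.

# Survival analysis

Survival endpoints are in months (scan timing is in days; 1 month =
30.44 days where conversion is needed). Kaplan–Meier fits use the
product-limit estimator with the median defined as the smallest time
at which $\hat S(t) \le 0.5$ and its CI obtained by inverting log-log
confidence bands (Brookmeyer–Crowley style). Group comparisons use the
standard unweighted log-rank test. Cox proportional-hazards models are
fit by Newton–Raphson on the partial likelihood (via the `survival`
package) with Efron tie handling by default (less biased than Breslow
with ties; identical without), Wald intervals and p-values. Constant
covariates and monotone likelihoods (complete separation) raise
explicit diagnostic errors rather than returning absurd estimates.

The table-style analysis runs univariate models for five adverse-coded
predictors — Gleason 8–9, ≥ 2 prior chemotherapy regimens, PSA decline
< 50%, PET nonresponse (SD/PD), PET progression (PD) — and one
multivariate model. Because the two PET dichotomies are strongly
collinear, the default multivariate model enters Gleason, prior
chemotherapy, PSA decline and PET progression (the dichotomy with the
established prognostic signal); a `"univariate_significant"` mode
instead enters the univariately significant predictors, with PET
represented by progression if both dichotomies qualify. Patients
progression-free at last follow-up are censored at that date.

# The synthetic-cohort generator

The generator's defaults define the study conditions under which the
package is tested; they are not tuned per run.

| Parameter | Default | Why |
|---|---|---|
| `n_patients` | 42 | evaluable-cohort scale of the motivating setting |
| `class_probs` | 3:11:6:16:6 /42 (CR:PR:SD:PD:flare) | early-read mix with ~1/3 of PD reads being flares |
| baseline SUVmax | lognormal(log 8, 0.4) | typical bone-metastasis uptake scale |
| `suv_noise_sd` | 5% | multiplicative test–retest scale of SUV measurements |
| baseline PSA | lognormal(log 23.3, 1.4) | median 23.3 ng/mL with a 1.5–1083 spread |
| uptake factors | CR → 0; PR → U(0.3, 0.7); SD → U(0.8, 1.2); PD/flare → U(1.3, 1.8) | straddle the ±25% decision boundaries so classes are identifiable at zero noise yet confusable under noise |
| `hr_pd_pfs`, `hr_pd_os` | 6.8, 5.3 | PD-vs-non-PD hazard ratios of the magnitude reported for this setting |
| base hazards | 0.0443, 0.01845 /month | solved so the class mixture yields overall median PFS ≈ 7.0 and OS ≈ 18.7 months |
| censoring | U(0, 40) months, independent | administrative censoring over a ~2–3-year accrual window |

Flare patients are built to satisfy the flare definition: bone-only
lesions, an early uptake rise of 30–80%, PSA decline ≥ 50%, CT SD,
and a confirmatory scan back near baseline uptake. True-PD patients
get a further ≥ 35% uptake rise at confirmation, rising PSA (95% of
them) and a PD CT read. Consequently, at `suv_noise_sd = 0` the early
classification recovers the latent class exactly and the flare machine
returns `confirmed_flare` for exactly the latent-flare patients — a
designed identifiability property used by the tests, not an empirical
discovery about real data.

What the generator does *not* emulate: reader disagreement and
consensus effects, anatomically correlated lesion dynamics, PSA assay
noise structure beyond a lognormal 2%, non-proportional hazards,
informative censoring, and dropout linked to toxicity. Passing tests
therefore demonstrate the correctness of the analysis machinery under
the stated statistical model, not the clinical accuracy of the
criteria on real scans.

# Numerical and testing choices

- Thresholds carry a $10^{-9}$ relative tolerance; rule order is total
  and deterministic, so every scan pair maps to exactly one category.
- The Cox fit is checked against an exhaustive partial-likelihood grid
  (step $10^{-4}$ on $\beta \in [-5, 5]$) on fixtures of ≤ 8 patients
  with interleaved event times; KM against hand product-limit values;
  the log-rank p against a permutation reference.
- Statistical acceptance checks use 200 replicates of 400-patient
  cohorts for hazard-ratio CI coverage (expected ≥ 93% at the nominal
  95%) and for the type-I error of the null generator
  (expected within [0.02, 0.08] at α = 0.05), and a 200-patient
  zero-noise cohort for flare recall/precision. These sizes give
  stable Monte-Carlo estimates at desk-scale runtime and are the
  package's chosen problem sizes.
- Degenerate inputs (zero baseline SUV or PSA, empty series, constant
  covariates, separation) raise errors naming the offending quantity;
  the course validator, by contrast, is total and returns a list of
  violations.

# Limitations

Patient-level results of any specific published cohort (median
survival values, table hazard ratios, responder counts) are not
reproducible without that cohort's unpublished data; the package
reproduces the *analysis* — and the published 2×2 agreement tables,
which are fully determined by their printed counts — and validates the
statistical machinery by parameter recovery on synthetic cohorts.
PERCIST-style SUL normalisation, bone-scintigraphy flare criteria, the
two-new-lesion bone-scan progression rule, PSA kinetics beyond the
endpoints above, and proportional-hazards diagnostics are out of
scope.
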