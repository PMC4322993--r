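# Builders for the flare scenarios: bone-only disease, early scan at
# day 40 showing a +40% uptake rise (an early PD read), optional
# confirmatory scan ~75 days later.
flare_course <- function(psa, confirm_factor = NULL, ct_cat = "SD",
                         ct = data.frame(day = 90L, category = ct_cat)) {
  suv0 <- c(8, 6)
  bl <- make_scan(0L, c("B1", "B2"), suv0)
  early <- make_scan(40L, c("B1", "B2"), suv0 * 1.4)
  fus <- list(early)
  if (!is.null(confirm_factor))
    fus <- list(early, make_scan(115L, c("B1", "B2"), suv0 * confirm_factor))
  make_course(baseline = bl, followups = fus, psa = psa, ct = ct)
}

test_that("the four adjudication outcomes fire on their scenarios", {
  # early PD, 64% PSA decline, CT SD, stable confirmatory PET
  confirmed <- flare_course(make_psa(c(100, 80, 36, 40)), confirm_factor = 1.0)
  a <- assess_bone_flare(confirmed)
  expect_identical(a$status, "confirmed_flare")
  expect_identical(a$evidence$psa_branch, "responder_50")
  expect_identical(a$evidence$confirmatory, "improvement")

  # sub-50% but continued decline below baseline, stable third PET
  interest <- flare_course(make_psa(c(1.5, 1.2, 1.0, 0.9)),
                           confirm_factor = 1.35)
  b <- assess_bone_flare(interest)
  expect_identical(b$status, "flare_of_interest")
  expect_identical(b$evidence$psa_branch, "continued_decline_below_50")
  expect_identical(b$evidence$confirmatory, "stable")

  # 60% decline and CT SD, but the confirmatory scan rises further
  progressed <- flare_course(make_psa(c(100, 60, 40, 90)),
                             confirm_factor = 1.4 * 1.5)
  c_ <- assess_bone_flare(progressed)
  expect_identical(c_$status, "confirmed_progression")
  expect_identical(c_$evidence$confirmatory, "progression")

  # 48.8% decline, CT SD, confirmatory scan never done
  unresolved <- flare_course(make_psa(c(100, 70, 51.2, 51.5)))
  d <- assess_bone_flare(unresolved)
  expect_identical(d$status, "suspected_unresolved")
  expect_identical(d$evidence$confirmatory, "absent")
})

test_that("only early PD reads enter the flare machinery", {
  sd_course <- make_course(
    baseline = make_scan(0L, c("B1", "B2"), c(8, 6)),
    followups = list(make_scan(40L, c("B1", "B2"), c(8.2, 6.1))))
  a <- assess_bone_flare(sd_course)
  expect_identical(a$status, "not_applicable")
  call <- classify_pet_response(sd_course$baseline_scan,
                                sd_course$followup_scans[[1]])
  expect_true(effective_progression_label(sd_course, call, a))
  expect_error(assess_bone_flare(make_course(
    baseline = make_scan(0L, c("B1", "B2"), c(8, 6)))),
    "no early follow-up scan")
})

test_that("a patient whose PSA never falls below baseline is never a flare", {
  set.seed(5)
  for (rep in 1:20) {
    vals <- c(10, 10 + runif(4, 0, 15))  # never below baseline
    a <- assess_bone_flare(flare_course(make_psa(vals), confirm_factor = 1.0))
    expect_identical(a$status, "confirmed_progression")
  }
})

test_that("failed trigger, failed CT and absent CT all end in progression", {
  # PD driven by a new lesion while known lesions stay stable
  suv0 <- c(8, 6)
  bl <- make_scan(0L, c("B1", "B2"), suv0)
  early_new <- make_scan(40L, c("B1", "B2", "B3"), c(suv0 * 1.02, 5))
  nl <- make_course(baseline = bl, followups = list(early_new),
                    psa = make_psa(c(100, 40, 30)))
  a <- assess_bone_flare(nl)
  expect_identical(a$status, "confirmed_progression")
  expect_false(a$evidence$trigger_uptake_rise)

  ct_pd <- flare_course(make_psa(c(100, 45, 30)), confirm_factor = 1.0,
                        ct_cat = "PD")
  expect_identical(assess_bone_flare(ct_pd)$status, "confirmed_progression")

  no_ct <- flare_course(make_psa(c(100, 45, 30)), confirm_factor = 1.0,
                        ct = data.frame(day = integer(),
                                        category = character()))
  expect_identical(assess_bone_flare(no_ct)$status, "confirmed_progression")
})

test_that("timing deviations warn but do not change the verdict", {
  suv0 <- c(8, 6)
  late <- make_course(
    baseline = make_scan(0L, c("B1", "B2"), suv0),
    followups = list(make_scan(80L, c("B1", "B2"), suv0 * 1.4),
                     make_scan(100L, c("B1", "B2"), suv0)),
    psa = make_psa(c(100, 80, 36, 40)))
  expect_warning(expect_warning(a <- assess_bone_flare(late),
                                "19-69 day window"),
                 "expected 60-120")
  expect_identical(a$status, "confirmed_flare")
})

test_that("flare reclassification flips the effective progression label", {
  confirmed <- flare_course(make_psa(c(100, 80, 36, 40)), confirm_factor = 1.0)
  call <- classify_pet_response(confirmed$baseline_scan,
                                confirmed$followup_scans[[1]])
  expect_identical(call$category, "PD")
  a <- assess_bone_flare(confirmed, call)
  expect_true(effective_progression_label(confirmed, call, a))

  progressed <- flare_course(make_psa(c(100, 60, 40, 90)),
                             confirm_factor = 2.1)
  a2 <- assess_bone_flare(progressed)
  expect_false(effective_progression_label(progressed, call, a2))

  unresolved <- flare_course(make_psa(c(100, 70, 51.2, 51.5)))
  a3 <- assess_bone_flare(unresolved)
  expect_false(effective_progression_label(unresolved, call, a3))
})
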