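test_that("lesion-level percent change follows 100*(fu-base)/base", {
  base <- lesion_measurement("L1", suv_max = 10)
  expect_equal(lesion_delta_pct(base, lesion_measurement("L1", suv_max = 4.5)),
               -55)
  base8 <- lesion_measurement("L1", suv_max = 8)
  expect_equal(lesion_delta_pct(base8, lesion_measurement("L1", suv_max = 8)), 0)
  resolved <- lesion_measurement("L1", suv_max = 0.4, resolved = TRUE)
  expect_equal(lesion_delta_pct(lesion_measurement("L1", suv_max = 4), resolved),
               -100)
  expect_error(lesion_delta_pct(lesion_measurement("L1", suv_max = 0),
                                lesion_measurement("L1", suv_max = 3)),
               "degenerate")
  expect_error(lesion_delta_pct(base, lesion_measurement("L2", suv_max = 3)),
               "different lesions")
})

test_that("mean SUVmax change averages matched targets, excluding new lesions", {
  bl <- make_scan(0L, c("A", "B"), c(10, 10))
  expect_equal(mean_delta_suvmax(bl, make_scan(40L, c("A", "B"), c(4.5, 3.0))),
               -62.5)  # mean of -55 and -70
  expect_equal(mean_delta_suvmax(bl, make_scan(40L, c("A", "B"), c(10, 10))), 0)
  half <- scan_record(40L, make_lesions(c("A", "B"), c(0, 10),
                                        resolved = c(TRUE, FALSE)))
  expect_equal(mean_delta_suvmax(bl, half), -50)  # mean of -100 and 0
  # new lesion C must not enter the mean
  with_new <- make_scan(40L, c("A", "B", "C"), c(4.5, 3.0, 9))
  expect_equal(mean_delta_suvmax(bl, with_new), -62.5)
  expect_error(mean_delta_suvmax(bl, make_scan(40L, c("X", "Y"), c(1, 2))),
               "no baseline target")
})

test_that("classification applies CR, PD, PR, SD rules in order", {
  node_bl <- make_scan(0L, c("N1", "N2"), c(7, 5), site = "node",
                       diameter = c(15, 12))
  node_cr <- scan_record(
    40L, make_lesions(c("N1", "N2"), c(0, 0), resolved = TRUE,
                      site = "node", diameter = c(8, 6)))
  expect_identical(classify_pet_response(node_bl, node_cr)$category, "CR")
  expect_equal(classify_pet_response(node_bl, node_cr)$mean_delta_pct, -100)

  bone_bl <- make_scan(0L, c("B1", "B2"), c(8, 6))
  bone_pd <- make_scan(40L, c("B1", "B2"), c(8, 6) * 1.4)
  expect_identical(classify_pet_response(bone_bl, bone_pd)$category, "PD")

  pr <- make_scan(40L, c("B1", "B2"), c(8, 6) * 0.45)  # -55%
  expect_identical(classify_pet_response(bone_bl, pr)$category, "PR")

  sd <- make_scan(40L, c("B1", "B2"), c(8, 6) * 0.9)  # -10%
  expect_identical(classify_pet_response(bone_bl, sd)$category, "SD")
})

test_that("new active lesions and size-confirmed growth trigger PD", {
  bl <- make_scan(0L, c("B1", "B2"), c(8, 6))
  fu_new <- make_scan(40L, c("B1", "B2", "B3"), c(7, 5, 4))
  call <- classify_pet_response(bl, fu_new)
  expect_identical(call$category, "PD")
  expect_identical(call$new_lesions, "B3")

  # measurable lesion: uptake up but diameter stable -> not PD via size
  meas_bl <- make_scan(0L, c("N1", "N2"), c(7, 7), site = "node",
                       diameter = c(20, 20))
  up_stable <- scan_record(40L, make_lesions(c("N1", "N2"), c(8, 7.5),
                                             site = "node",
                                             diameter = c(21, 20)))
  expect_identical(classify_pet_response(meas_bl, up_stable)$category, "SD")
  # same uptake but >=20% diameter growth -> PD
  up_grown <- scan_record(40L, make_lesions(c("N1", "N2"), c(8, 7.5),
                                            site = "node",
                                            diameter = c(25, 20)))
  call2 <- classify_pet_response(meas_bl, up_grown)
  expect_identical(call2$category, "PD")
  expect_true(call2$size_progression)
})

test_that("the -25% boundary is PR and +25% bone rise is not yet PD", {
  bl <- make_scan(0L, c("B1", "B2"), c(8, 8))
  exact <- make_scan(40L, c("B1", "B2"), c(6, 6))      # exactly -25
  expect_identical(classify_pet_response(bl, exact)$category, "PR")
  plus25 <- make_scan(40L, c("B1", "B2"), c(10, 10))   # exactly +25
  expect_identical(classify_pet_response(bl, plus25)$category, "SD")
  over25 <- make_scan(40L, c("B1", "B2"), c(10.4, 10)) # +30/+25 mixed
  expect_identical(classify_pet_response(bl, over25)$category, "PD")
})

test_that("per-lesion PR rule is stricter than the mean rule", {
  bl <- make_scan(0L, c("B1", "B2"), c(10, 10))
  mixed <- make_scan(40L, c("B1", "B2"), c(2, 9))  # -80 and -10, mean -45
  expect_identical(classify_pet_response(bl, mixed)$category, "PR")
  expect_identical(
    classify_pet_response(bl, mixed, pr_rule = "per_lesion")$category, "SD")
  both <- make_scan(40L, c("B1", "B2"), c(2, 7))   # -80 and -30
  expect_identical(
    classify_pet_response(bl, both, pr_rule = "per_lesion")$category, "PR")
})

test_that("classification is invariant to lesion order and monotone in uptake", {
  set.seed(42)
  order_cats <- c(CR = 1, PR = 2, SD = 3, PD = 4)
  for (rep in 1:25) {
    k <- sample(2:5, 1)
    ids <- paste0("L", 1:k)
    suv0 <- runif(k, 2, 12)
    f <- runif(k, 0.2, 1.9)
    bl <- make_scan(0L, ids, suv0)
    fu <- make_scan(40L, ids, suv0 * f)
    call <- classify_pet_response(bl, fu)

    perm <- sample(k)
    fu_perm <- make_scan(40L, ids[perm], (suv0 * f)[perm])
    bl_perm <- make_scan(0L, ids[perm], suv0[perm])
    expect_identical(classify_pet_response(bl_perm, fu_perm)$category,
                     call$category)

    # uniformly lowering follow-up uptake never moves away from CR
    shrunk <- make_scan(40L, ids, suv0 * f * runif(1, 0.3, 0.95))
    expect_lte(order_cats[classify_pet_response(bl, shrunk)$category],
               order_cats[call$category])
  }
})

test_that("dichotomies code the favourable outcome as TRUE", {
  expect_true(dichotomize("PR", "response"))
  expect_false(dichotomize("SD", "response"))
  expect_true(dichotomize("SD", "progression"))
  expect_false(dichotomize("PD", "progression"))
  expect_true(dichotomize("CR", "progression"))
})
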