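test_that("change z divides by sqrt(2)*SEM and flips pathological increases", {
  expect_equal(change_z(-0.027, "FA_rostral"),
               c(FA_rostral = -0.027 / (sqrt(2) * 0.018)))
  expect_equal(unname(change_z(0, "CSA_mcl")), 0)
  # a T2* increase of exactly one null SD maps to z = -1
  expect_equal(unname(change_z(0.008 * sqrt(2), "T2sWMGM_rostral")), -1)
  expect_error(change_z(1, "CSA_caudal"), "no SEM")
})

test_that("change z is linear in delta with unit slope at sqrt(2)*SEM", {
  rel <- reliability_table()
  for (slot in names(rel$sem)) {
    dir <- if (grepl("T2sWMGM", slot)) -1 else 1
    for (k in c(-2, -0.5, 0, 1, 3)) {
      expect_equal(unname(change_z(k * sqrt(2) * rel$sem[[slot]], slot)),
                   dir * k)
    }
  }
})

test_that("composite is mean(z)*sqrt(m) with the t10 reference", {
  z10 <- rep(-3.30 / sqrt(10), 10)
  cs <- composite_score(z10)
  expect_equal(cs$composite_t, -3.30)
  expect_equal(cs$m, 10L)
  expect_equal(cs$df, 10)
  expect_equal(composite_score(rep(0, 10))$composite_t, 0)
  # seven available slots use SE = 1/sqrt(7)
  z7 <- c(rep(-1, 7), rep(NA, 3))
  expect_equal(composite_score(z7)$composite_t, -sqrt(7))
  expect_true(is.na(composite_score(rep(NA_real_, 10))$composite_t))
  expect_equal(detection_config()$composite_null_se, 1 / sqrt(10))
})

test_that("event classification uses strict thresholds and symmetric outliers", {
  nm <- paste(qmri_slots()$metric, qmri_slots()$region, sep = "_")
  z <- setNames(rep(0, 10), nm)

  # composite exactly at threshold is not flagged
  z_at <- setNames(rep(-3.30 / sqrt(10), 10), nm)
  expect_equal(classify_event(z_at)$qmri_cat, "stable")
  # just below the composite threshold is
  z_below <- setNames(rep(-3.31 / sqrt(10), 10), nm)
  res <- classify_event(z_below)
  expect_equal(res$qmri_cat, "declined")
  expect_length(res$progressed_slots, 0)

  # single-slot exceedance suffices
  z1 <- z; z1["FA_rostral"] <- -2.66
  expect_equal(classify_event(z1)$qmri_cat, "declined")
  z2 <- z; z2["FA_rostral"] <- -2.65
  expect_equal(classify_event(z2)$qmri_cat, "stable")

  # an isolated improvement is an outlier, not progression
  z3 <- z; z3["MTR_mcl"] <- 3.0
  res3 <- classify_event(z3)
  expect_equal(res3$qmri_cat, "stable")
  expect_equal(res3$improved_slots, "MTR_mcl")

  # all-missing events are unclassifiable
  expect_true(is.na(classify_event(setNames(rep(NA_real_, 10), nm))$qmri_cat))
})

test_that("flag logic is monotone: more negative z never rescues an event", {
  nm <- paste(qmri_slots()$metric, qmri_slots()$region, sep = "_")
  set.seed(11)
  for (i in 1:50) {
    z <- setNames(rnorm(10, 0, 1.5), nm)
    base <- classify_event(z)$qmri_cat
    j <- sample(10, 1)
    z[j] <- z[j] - runif(1, 0, 3)
    worse <- classify_event(z)$qmri_cat
    if (base == "declined") expect_equal(worse, "declined")
  }
})

test_that("per-test level equals the normal tail at the z threshold", {
  expect_equal(round(per_test_p_of_threshold(), 3), 0.004)
  expect_equal(per_test_p_of_threshold(detection_config(z_threshold = -1e-9)),
               0.5, tolerance = 1e-6)
  cfg <- detection_config(z_threshold = -1.6449)
  expect_equal(round(per_test_p_of_threshold(cfg), 3), 0.05)
})

test_that("profile differencing feeds detection with sign-correct z", {
  slots <- example_slots()
  base <- build_profile(make_panels(slots), 60, 60,
                        region = region_spec(mcl_level = "C4-C5"))
  rel <- reliability_table()
  # deteriorate FA rostral by 3 null SDs; raise T2* caudal by 3 null SDs
  fu_slots <- slots
  fu_slots["FA_rostral"] <- slots["FA_rostral"] - 3 * sqrt(2) * rel$sem[["FA_rostral"]]
  fu_slots["T2sWMGM_caudal"] <- slots["T2sWMGM_caudal"] +
    3 * sqrt(2) * rel$sem[["T2sWMGM_caudal"]]
  fu <- build_profile(make_panels(fu_slots, visit = "followup"), 60, 60,
                      region = region_spec(mcl_level = "C4-C5"))
  res <- qmri_change(base, fu, rel)
  expect_equal(res$qmri_cat, "declined")
  expect_setequal(res$progressed_slots, c("FA_rostral", "T2sWMGM_caudal"))
  expect_equal(unname(res$z[["FA_rostral"]]), -3)
  expect_equal(unname(res$z[["T2sWMGM_caudal"]]), -3)
})

test_that("reliability table rejects incomplete or non-positive SEMs", {
  expect_error(reliability_table(c(CSA_rostral = 0.95)), "SEM missing")
  sem <- reliability_table()$sem
  sem["FA_mcl"] <- 0
  expect_error(reliability_table(sem), "> 0")
})
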