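test_that("age correction applies the linear drift with the configured slope", {
  m <- age_correction_model()
  # at the reference age nothing changes
  expect_equal(age_correct(0.6, "FA", 55, m, reference_age = 55), 0.6)
  # FA slope is -0.00121/yr: ten years past reference adds back the decline
  expect_equal(age_correct(0.600, "FA", 65, m, reference_age = 55), 0.6121)
  # closed form: corrected visit difference = raw difference - beta * dt
  for (metric in c("CSA", "FA", "MTR", "T2sWMGM")) {
    raw0 <- 10; raw1 <- 10.3; dt <- 1.7
    d <- age_correct(raw1, metric, 60 + dt, m, 60) -
      age_correct(raw0, metric, 60, m, 60)
    expect_equal(d, (raw1 - raw0) - m$beta[[metric]] * dt)
  }
  expect_error(age_correct(1, "ADC", 60, m, 60), "no age-correction slope")
})

test_that("region aggregation averages eligible slices only", {
  p <- slice_panel("S01", "baseline", "FA",
                   level = c("C1", "C2", "C3", "C6", "C7"),
                   slice_index = 1:5,
                   value = c(0.62, 0.64, 0.66, 0.5, 0.52),
                   compressed = c(FALSE, FALSE, FALSE, FALSE, FALSE))
  rs <- region_spec(mcl_level = "C4-C5")
  expect_equal(aggregate_region(p, rs, "rostral"), 0.64)

  p2 <- slice_panel("S01", "baseline", "FA",
                    level = c("C1", "C2", "C3"), slice_index = 1:3,
                    value = c(0.62, 0.64, 0.66),
                    compressed = c(FALSE, TRUE, FALSE))
  expect_equal(aggregate_region(p2, rs, "rostral"), 0.64)

  p3 <- slice_panel("S01", "baseline", "FA",
                    level = c("C6", "C7"), slice_index = 1:2,
                    value = c(0.5, 0.52), excluded_artifact = TRUE)
  expect_true(is.na(aggregate_region(p3, rs, "caudal")))
})

test_that("aggregation is invariant to slice order and relabeling", {
  slots <- example_slots()
  p <- make_panels(slots)$FA
  rs <- region_spec(mcl_level = "C4-C5")
  ref <- sapply(c("rostral", "caudal", "mcl"), function(w)
    aggregate_region(p, rs, w))
  shuffled <- p[sample(nrow(p)), ]
  expect_equal(sapply(c("rostral", "caudal", "mcl"), function(w)
    aggregate_region(shuffled, rs, w)), ref)
  relabeled <- p
  relabeled$slice_index <- relabeled$slice_index * 10L
  expect_equal(sapply(c("rostral", "caudal", "mcl"), function(w)
    aggregate_region(relabeled, rs, w)), ref)
})

test_that("MCL extraction uses one slice for CSA and three otherwise", {
  slots <- example_slots()
  panels <- make_panels(slots)
  rs <- region_spec(mcl_level = "C4-C5")
  expect_equal(aggregate_region(panels$CSA, rs, "mcl"), slots[["CSA_mcl"]])
  expect_equal(aggregate_region(panels$FA, rs, "mcl"), slots[["FA_mcl"]])
  # MCL slices are compressed by definition and still used
  expect_true(all(panels$FA$compressed[7:9]))
  expect_error(aggregate_region(panels$FA, region_spec(), "mcl"),
               "mcl_level is unset")
})

test_that("profile has exactly 10 slots and never caudal CSA or MTR", {
  slots <- example_slots()
  prof <- build_profile(make_panels(slots), age_years = 60,
                        reference_age = 60,
                        region = region_spec(mcl_level = "C4-C5"))
  expect_length(prof, 10)
  expect_false(any(grepl("CSA_caudal|MTR_caudal", names(prof))))
  expect_equal(unclass(prof)[names(slots)], slots,
               ignore_attr = TRUE)

  # a metric panel lost to motion artifact gives missing slots only there
  panels <- make_panels(slots)
  panels$T2sWMGM <- NULL
  prof2 <- build_profile(panels, 60, 60,
                         region = region_spec(mcl_level = "C4-C5"))
  expect_equal(sum(is.na(prof2)), 3)
  expect_true(all(is.na(prof2[grepl("T2sWMGM", names(prof2))])))

  prof3 <- build_profile(list(), 60, 60,
                         region = region_spec(mcl_level = "C4-C5"))
  expect_equal(sum(is.na(prof3)), 10)
})

test_that("slice panels validate physical ranges and unique indices", {
  expect_error(slice_panel("S", "b", "FA", "C1", 1, 1.4), "out of physical")
  expect_error(slice_panel("S", "b", "CSA", c("C1", "C2"), c(1, 1),
                           c(70, 71)), "unique")
  expect_error(slice_panel("S", "b", "ADC", "C1", 1, 1), "unknown metric")
})
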