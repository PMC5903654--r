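test_that("simulation is reproducible and per-subject streams are stable", {
  cfg <- simulation_config(n_subjects = 6, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  # enlarging the cohort leaves earlier subjects untouched
  big <- simulate_cohort(simulation_config(n_subjects = 9, seed = 42))
  expect_identical(big$profiles[big$profiles$subject_id %in%
                                  a$profiles$subject_id, ],
                   a$profiles)
  expect_identical(big$truth$progressor[1:6], a$truth$progressor)
})

test_that("noiseless, effect-free cohorts give exactly zero z downstream", {
  cfg <- simulation_config(n_subjects = 4, seed = 7, noise_scale = 0,
                           progressor_fraction = 0)
  out <- run_pipeline(simulate_cohort(cfg))
  for (ch in out$changes) {
    expect_equal(unname(ch$z), rep(0, 10))
    expect_equal(ch$composite_t, 0)
    expect_equal(ch$qmri_cat, "stable")
  }
})

test_that("aging drift alone is exactly cancelled by age correction", {
  # noiseless, no progression, default (non-zero) aging slopes: the raw
  # values drift with age but corrected differences are zero
  cfg <- simulation_config(n_subjects = 3, seed = 13, noise_scale = 0,
                           progressor_fraction = 0)
  co <- simulate_cohort(cfg)
  drift <- co$profiles$followup - co$profiles$baseline
  expect_gt(max(abs(drift)), 0)   # raw drift is real
  out <- run_pipeline(co)
  for (ch in out$changes) expect_equal(unname(ch$z), rep(0, 10))
})

test_that("a strong noiseless effect is flagged in every progressor", {
  cfg <- simulation_config(n_subjects = 6, seed = 5, noise_scale = 0,
                           progressor_fraction = 1, effect_size = 3)
  out <- run_pipeline(simulate_cohort(cfg))
  for (ch in out$changes) {
    expect_equal(ch$qmri_cat, "declined")
    expect_equal(unname(ch$z), rep(-3, 10), tolerance = 1e-8)
  }
})

test_that("null calibration reproduces the nominal per-slot rate", {
  cal <- calibration_experiment(reps = 1e5, seed = 4)
  expect_equal(cal$expected_per_slot, pnorm(-2.65))
  expect_lt(abs(cal$per_slot_rate - cal$expected_per_slot),
            3 * cal$per_slot_mc_se)
  # composite flagging is conservative under the complete-data null
  expect_lte(cal$composite_rate, cal$per_slot_rate + 3 * cal$composite_mc_se)
  # determinism
  expect_identical(cal, calibration_experiment(reps = 1e5, seed = 4))
})

test_that("detection power follows the closed-form normal curve", {
  pw <- power_experiment(effect_sizes = c(0.5, 1, 2, 3), reps = 2e4, seed = 2)
  expect_true(all(abs(pw$detected_fraction - pw$expected) < 3 * pw$mc_se))
  # the k = 1 point: Phi(-1.65) ~ 0.0495
  expect_equal(pw$expected[pw$effect_size == 1], pnorm(-1.65))
})

test_that("slot-level detection on full synthetic cohorts recovers the power curve", {
  # end-to-end parameter recovery through per-slice generation, aggregation
  # and z-scoring (not just the closed-form shortcut)
  for (k in c(1, 2.5)) {
    cfg <- simulation_config(n_subjects = 60, seed = 31 + round(10 * k),
                             progressor_fraction = 1, effect_size = k)
    out <- run_pipeline(simulate_cohort(cfg))
    zmat <- do.call(rbind, lapply(out$changes, function(ch) ch$z))
    frac <- mean(zmat < -2.65)
    expected <- pnorm(-2.65 + k)
    mc_se <- sqrt(expected * (1 - expected) / length(zmat))
    expect_lt(abs(frac - expected), 4 * mc_se)
  }
})

test_that("the pipeline recovers strong progression with faithful reporting", {
  cfg <- simulation_config(n_subjects = 30, seed = 8, effect_size = 4,
                           progressor_fraction = 0.5,
                           p_worse_given_progression = 1,
                           p_worse_given_stable = 0)
  co <- simulate_cohort(cfg)
  out <- run_pipeline(co)
  truth <- co$truth$progressor[match(out$events$subject_id,
                                     co$truth$subject_id)]
  detected <- out$events$qmri_cat == "declined"
  expect_equal(sum(detected & truth), sum(truth))  # sensitivity 100%
  # decided statuses partition the cohort
  expect_equal(sum(out$counts), 30)
  # every true progressor reports worse and shows qMRI decline -> progression
  expect_equal(unname(out$counts["progression"]), sum(truth))
})

test_that("simulated tables obey the I/O contracts of the readers", {
  cfg <- simulation_config(n_subjects = 3, seed = 99)
  co <- simulate_cohort(cfg)
  dir <- withr::local_tempdir()
  write_cohort(co$visits, file.path(dir, "c.csv"), file.path(dir, "m.csv"))
  back <- read_cohort(file.path(dir, "c.csv"), file.path(dir, "m.csv"))
  expect_length(back$visits, 6)
  # panel rows validate as slice panels
  p <- co$panels[co$panels$subject_id == "S01" &
                   co$panels$visit == "baseline" & co$panels$metric == "FA", ]
  expect_silent(slice_panel("S01", "baseline", "FA", p$level, p$slice_index,
                            p$value, p$compressed, p$excluded_artifact))
})
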