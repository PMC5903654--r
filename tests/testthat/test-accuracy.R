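test_that("Wilson continuity-corrected interval matches known bounds", {
  w <- wilson_cc_interval(11, 26)
  expect_equal(round(c(w$lower, w$upper), 1), c(24.0, 62.8))
  w2 <- wilson_cc_interval(15, 22)
  expect_equal(round(c(w2$lower, w2$upper), 1), c(45.1, 85.3))
  expect_equal(wilson_cc_interval(0, 10)$lower, 0)
  expect_equal(wilson_cc_interval(10, 10)$upper, 100)
  expect_error(wilson_cc_interval(3, 0), "n = 0")
  expect_error(wilson_cc_interval(5, 4), "\\[0, n\\]")
})

test_that("Wilson CC interval agrees with the score interval of prop.test", {
  for (k in c(1, 5, 11, 20)) for (n in c(22, 26, 40)) {
    # prop.test caps its correction at |k - n/2|, vanishing at k = n/2;
    # restrict the cross-check to the regime where the two coincide
    if (k > n || abs(k - n / 2) < 0.5) next
    w <- wilson_cc_interval(k, n)
    ref <- prop.test(k, n, correct = TRUE)$conf.int * 100
    expect_equal(c(w$lower, w$upper), as.numeric(ref), tolerance = 1e-10)
  }
})

test_that("Wilson CC interval contains k/n and narrows with n", {
  for (n in c(5, 12, 26, 60)) for (k in 0:n) {
    w <- wilson_cc_interval(k, n)
    expect_lte(w$lower, w$point)
    expect_gte(w$upper, w$point)
    expect_gte(w$lower, 0); expect_lte(w$upper, 100)
  }
  # fixed k/n = 1/2, increasing n: width decreases
  widths <- sapply(c(10, 20, 40, 80), function(n) {
    w <- wilson_cc_interval(n / 2, n); w$upper - w$lower
  })
  expect_true(all(diff(widths) < 0))
})

test_that("one-tailed paired t matches the printed summary computation", {
  g <- paired_t_one_tailed(mean_diff = -3.5, sd_diff = 5.4, n = 22)
  expect_equal(round(g$one_tailed_p, 3), 0.003)
  expect_equal(paired_t_one_tailed(mean_diff = 0, sd_diff = 3,
                                   n = 10)$one_tailed_p, 0.5)
  expect_error(paired_t_one_tailed(rep(-1, 4)), "degenerate")
})

test_that("raw-difference and summary t paths agree with each other and t.test", {
  set.seed(9)
  d <- rnorm(15, -0.5, 1.2)
  a <- paired_t_one_tailed(d)
  b <- paired_t_one_tailed(mean_diff = mean(d), sd_diff = sd(d), n = 15)
  expect_equal(a$t_statistic, b$t_statistic)
  expect_equal(a$one_tailed_p, b$one_tailed_p)
  ref <- t.test(d, alternative = "less")
  expect_equal(a$t_statistic, unname(ref$statistic))
  expect_equal(a$one_tailed_p, ref$p.value)
})

test_that("accuracy reports percent sensitivity, specificity and exact Youden", {
  a <- accuracy(tp = 8, fp = 7, tn = 8, fn = 0)
  expect_equal(a$sensitivity, 100)
  expect_equal(round(a$specificity, 1), 53.3)
  a2 <- accuracy(10, 0, 10, 0)
  expect_equal(c(a2$sensitivity, a2$specificity, a2$youden), c(100, 100, 100))
  # Youden identity over arbitrary counts
  set.seed(21)
  for (i in 1:30) {
    cts <- rpois(4, 6) + c(1, 0, 1, 0)
    a3 <- accuracy(cts[1], cts[2], cts[3], cts[4])
    expect_equal(a3$youden, a3$sensitivity + a3$specificity - 100)
  }
  # undefined quantities are NA, not zero
  expect_true(is.na(accuracy(0, 3, 2, 0)$sensitivity))
})

test_that("two-sided Fisher p equals exhaustive hypergeometric enumeration", {
  set.seed(5)
  for (i in 1:200) {
    repeat {
      tab <- matrix(rpois(4, 4), 2)
      if (sum(tab) <= 40 && all(rowSums(tab) > 0) && all(colSums(tab) > 0))
        break
    }
    expect_equal(fisher_exact_2x2(tab), fisher_enumeration_p(tab),
                 tolerance = 1e-9)
  }
  expect_equal(fisher_exact_2x2(matrix(c(3, 5, 3, 5), 2, byrow = TRUE)), 1)
  expect_error(fisher_exact_2x2(matrix(c(0, 0, 2, 3), 2, byrow = TRUE)),
               "empty margin")
})

test_that("modality comparisons reproduce the reference cohort contrasts", {
  ev <- reference_events()
  expect_equal(round(compare_measures(ev, "qmri", "mjoa", "sensitivity")$p, 3),
               0.003)
  expect_lt(compare_measures(ev, "qmri", "mri", "sensitivity")$p, 0.001)
  expect_equal(round(compare_measures(ev, "clinical", "qmri", "sensitivity")$p, 2),
               0.47)
  expect_equal(round(compare_measures(ev, "mjoa", "qmri", "specificity")$p, 3),
               0.002)
  # a measure against itself carries no signal
  expect_equal(compare_measures(ev, "qmri", "qmri", "sensitivity")$p, 1)
})

test_that("confusion tables drop unavailable events instead of imputing", {
  ev <- reference_events()
  cf <- modality_confusion(ev, "qmri")
  expect_equal(cf$n_events, 23)
  expect_equal(cf$tp + cf$fn, 8)     # subjectively worse, qMRI available
  cf_mri <- modality_confusion(ev, "mri")
  expect_equal(cf_mri$n_events, 26)
  expect_equal(cf_mri$tp + cf_mri$fn, 11)
  # the mJOA narrative override lowers tp only
  with_override <- modality_confusion(ev, "mjoa")
  from_rows <- modality_confusion(ev, "mjoa", mjoa_detected = NULL)
  expect_equal(with_override$tp, 3)
  expect_equal(from_rows$tp, 4)
  expect_equal(with_override$tn, from_rows$tn)
})
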