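# Shared fixture builders; everything is generated in code at test time.

# A 13-slice panel with a constant value per region, in the canonical level
# layout (C1..C7 alternating body/disc), MCL at C4-C5.
make_panel <- function(metric, rostral, mcl, caudal, other = rostral,
                       subject = "S01", visit = "baseline",
                       compressed_at_mcl = TRUE) {
  lv <- c("C1", "C1-C2", "C2", "C2-C3", "C3", "C3-C4", "C4", "C4-C5", "C5",
          "C5-C6", "C6", "C6-C7", "C7")
  vals <- rep(other, 13)
  vals[1:5] <- rostral
  vals[7:9] <- mcl
  vals[11:13] <- caudal
  comp <- rep(FALSE, 13)
  if (compressed_at_mcl) comp[7:9] <- TRUE
  slice_panel(subject, visit, metric, lv, 1:13, vals, comp, FALSE)
}

# Complete set of four panels whose 10-slot profile equals `slots` (a named
# numeric over the canonical slot names).
make_panels <- function(slots, subject = "S01", visit = "baseline") {
  g <- function(nm) slots[[nm]]
  list(
    CSA = make_panel("CSA", g("CSA_rostral"), g("CSA_mcl"), g("CSA_mcl"),
                     subject = subject, visit = visit),
    FA = make_panel("FA", g("FA_rostral"), g("FA_mcl"), g("FA_caudal"),
                    subject = subject, visit = visit),
    MTR = make_panel("MTR", g("MTR_rostral"), g("MTR_mcl"), g("MTR_mcl"),
                     subject = subject, visit = visit),
    T2sWMGM = make_panel("T2sWMGM", g("T2sWMGM_rostral"), g("T2sWMGM_mcl"),
                         g("T2sWMGM_caudal"), subject = subject,
                         visit = visit)
  )
}

example_slots <- function() {
  c(CSA_rostral = 72, CSA_mcl = 60,
    FA_rostral = 0.65, FA_mcl = 0.58, FA_caudal = 0.62,
    T2sWMGM_rostral = 0.82, T2sWMGM_mcl = 0.88, T2sWMGM_caudal = 0.84,
    MTR_rostral = 51, MTR_mcl = 48)
}

# Tiny clinical cohort (2 subjects x 2 visits) written to CSVs in a tempdir;
# returns the two paths.
write_tiny_cohort <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  cohort <- data.frame(
    subject_id = rep(c("A", "A", "B", "B"), each = 2),
    visit = rep(c("baseline", "baseline", "followup", "followup"), 2),
    age = rep(c(55, 55, 62, 62), 2),
    measure = rep(c("mJOA", "grip_R"), 4),
    value = c(15, 30, 13, 26, 17, 41.5, 17, 42),
    stringsAsFactors = FALSE
  )
  mjoa <- data.frame(
    subject_id = c("A", "A", "B", "B"),
    visit = c("baseline", "followup", "baseline", "followup"),
    upper_motor = c(4, 3, 5, 5), lower = c(6, 5, 7, 7),
    upper_sensory = c(2, 2, 2, 2), urinary = c(3, 3, 3, 3),
    stringsAsFactors = FALSE
  )
  cohort_file <- file.path(dir, "cohort.csv")
  mjoa_file <- file.path(dir, "mjoa.csv")
  write.csv(cohort, cohort_file, row.names = FALSE)
  write.csv(mjoa, mjoa_file, row.names = FALSE)
  c(cohort = cohort_file, mjoa = mjoa_file)
}

# Exhaustive hypergeometric enumeration of the two-sided Fisher p-value:
# the sum of point probabilities of all tables with the observed margins
# whose probability does not exceed the observed one.
fisher_enumeration_p <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
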