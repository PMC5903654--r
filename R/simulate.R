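# Synthetic cohorts with the statistical structure the analysis assumes:
# per-subject true metric values, additive Gaussian measurement error with
# per-slot SEM, linear aging drift, injectable progression effects (in
# units of sqrt(2)*SEM, the null SD of a visit difference), and clinical
# measures with configurable worsening in progressors.

#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate the reference study conditions: 26 subjects, mean
#' baseline age 57.6 (SD 9.1) years, follow-up interval 13.5/12 years (SD
#' 4.9/12, truncated at 0.5 years), and the printed SEMs and aging slopes.
#' Between-subject baseline spread and the baseline metric means are
#' plausible values chosen for realism only — all downstream inference is on
#' within-subject differences, so they affect nothing.
#'
#' @param n_subjects Number of subjects.
#' @param seed Cohort seed; per-subject streams are derived from it so that
#'   enlarging the cohort leaves earlier subjects' data unchanged.
#' @param followup_mean_yr,followup_sd_yr,followup_min_yr Follow-up interval
#'   distribution (years, truncated normal).
#' @param age_mean,age_sd Baseline age distribution (years).
#' @param baseline_mean,baseline_sd Named numerics over the 10 slots:
#'   between-subject baseline distribution of the true metric values.
#' @param rel [reliability_table()] supplying the per-slot measurement-error
#'   SD per visit.
#' @param noise_scale Multiplier on the measurement-error SD (0 = noiseless
#'   visits, useful for exact-recovery checks).
#' @param model [age_correction_model()] supplying the aging slopes.
#' @param error_correlation Correlation of measurement errors across slots
#'   within a visit (0 = independent).
#' @param progressor_fraction Fraction of subjects with true progression.
#' @param effect_size Named numeric (or scalar) per-slot progression effect
#'   in units of sqrt(2)*SEM, applied in each slot's pathological direction.
#' @param clinical_worsen_measures Battery measures worsened in progressors.
#' @param clinical_worsen_percent Worsening-positive percent applied to each.
#' @param p_worse_given_progression Probability that a true progressor
#'   reports "worse" (adaptation/masking makes this < 1).
#' @param p_worse_given_stable False-alarm probability for non-progressors.
#' @param p_new_compression_progressor,p_new_compression_stable Probability
#'   of new/worsened cord compression at follow-up.
#' @param mcl_level MCL level label used for every subject.
#' @return `simulation_config` list.
#' @export
simulation_config <- function(
    n_subjects = 26,
    seed = 1L,
    followup_mean_yr = 13.5 / 12,
    followup_sd_yr = 4.9 / 12,
    followup_min_yr = 0.5,
    age_mean = 57.6,
    age_sd = 9.1,
    baseline_mean = c(CSA_rostral = 72, CSA_mcl = 60,
                      FA_rostral = 0.65, FA_mcl = 0.58, FA_caudal = 0.62,
                      T2sWMGM_rostral = 0.82, T2sWMGM_mcl = 0.88,
                      T2sWMGM_caudal = 0.84,
                      MTR_rostral = 51, MTR_mcl = 48),
    baseline_sd = c(CSA_rostral = 5, CSA_mcl = 7,
                    FA_rostral = 0.025, FA_mcl = 0.035, FA_caudal = 0.03,
                    T2sWMGM_rostral = 0.02, T2sWMGM_mcl = 0.04,
                    T2sWMGM_caudal = 0.03,
                    MTR_rostral = 1.5, MTR_mcl = 2.5),
    rel = reliability_table(),
    noise_scale = 1,
    model = age_correction_model(),
    error_correlation = 0,
    progressor_fraction = 11 / 26,
    effect_size = 1.5,
    clinical_worsen_measures = c("mJOA", "grip_R", "grip_L"),
    clinical_worsen_percent = 8,
    p_worse_given_progression = 8 / 15,
    p_worse_given_stable = 3 / 15,
    p_new_compression_progressor = 0.25,
    p_new_compression_stable = 0.05,
    mcl_level = "C4-C5") {
  sn <- .slot_names()
  if (length(effect_size) == 1L) effect_size <- stats::setNames(
    rep(effect_size, length(sn)), sn)
  stopifnot(all(sn %in% names(baseline_mean)), all(sn %in% names(baseline_sd)),
            all(baseline_sd >= 0),
            progressor_fraction >= 0, progressor_fraction <= 1,
            noise_scale >= 0,
            error_correlation >= 0, error_correlation < 1,
            p_worse_given_progression >= 0, p_worse_given_progression <= 1,
            p_worse_given_stable >= 0, p_worse_given_stable <= 1)
  structure(c(as.list(environment())), class = "simulation_config")
}

# deterministic per-subject sub-seed (kept below 2^31)
.subject_seed <- function(seed, i) {
  (as.integer(seed) %% 1000003L) * 2011L + 7919L * as.integer(i)
}

#' Simulate a two-visit cohort
#'
#' For each subject: true baseline slot values; at follow-up the truth moves
#' by the aging drift `beta * interval` plus, for progressors, the injected
#' effect `effect_size * sqrt(2) * SEM` in the slot's pathological
#' direction. Each visit adds fresh measurement error, drawn once per slot
#' and shared across the region's slices (with zero-sum within-region slice
#' scatter), so the aggregated region value carries exactly SD = SEM of
#' noise and aggregation followed by detection recovers the injected
#' effects. Clinical scores worsen by the configured percents in
#' progressors; the subjective response is a Bernoulli draw conditioned on
#' the true label.
#'
#' @param cfg [simulation_config()].
#' @return List understood by [run_pipeline()]: `panels`, `visits`,
#'   `subjective`, `anatomical`, `mcl`, `ages`, plus `truth` (ground-truth
#'   labels, never read by the pipeline) and `profiles` (true aggregated
#'   values per visit, for parameter-recovery checks).
#' @export
simulate_cohort <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  sn <- .slot_names()
  slots <- qmri_slots()
  dirs <- ifelse(slots$metric == "T2sWMGM", +1, -1)  # pathological sign
  names(dirs) <- sn
  sem <- cfg$rel$sem

  n <- cfg$n_subjects
  progressor <- logical(n)

  panels <- list(); visits <- list(); subjective <- list()
  anat <- list(); ages <- list(); profs <- list()
  for (i in seq_len(n)) {
    # per-subject stream: enlarging the cohort never reshuffles earlier
    # subjects' data
    set.seed(.subject_seed(cfg$seed, i))
    progressor[i] <- stats::runif(1) < cfg$progressor_fraction
    age0 <- stats::rnorm(1, cfg$age_mean, cfg$age_sd)
    dt <- max(cfg$followup_min_yr,
              stats::rnorm(1, cfg$followup_mean_yr, cfg$followup_sd_yr))
    sid <- sprintf("S%02d", i)
    ages[[i]] <- data.frame(subject_id = sid, baseline_age = age0,
                            followup_age = age0 + dt,
                            stringsAsFactors = FALSE)

    truth0 <- stats::rnorm(length(sn), cfg$baseline_mean[sn],
                           cfg$baseline_sd[sn])
    names(truth0) <- sn
    aging <- cfg$model$beta[slots$metric] * dt
    effect <- if (progressor[i])
      dirs * cfg$effect_size[sn] * sqrt(2) * sem[sn] else 0 * dirs
    truth1 <- truth0 + aging + effect

    err <- function() {
      if (cfg$noise_scale == 0) return(stats::setNames(numeric(length(sn)), sn))
      e <- stats::rnorm(length(sn), 0, cfg$noise_scale * sem[sn])
      if (cfg$error_correlation > 0) {
        shared <- stats::rnorm(1)
        e <- sqrt(1 - cfg$error_correlation) * e +
          sqrt(cfg$error_correlation) * shared * sem[sn]
      }
      e
    }
    obs0 <- truth0 + err()
    obs1 <- truth1 + err()
    profs[[i]] <- data.frame(subject_id = sid,
                             slot = sn, baseline = obs0, followup = obs1,
                             true_effect = effect, stringsAsFactors = FALSE)

    panels[[i]] <- rbind(
      .slices_for_visit(sid, "baseline", obs0, cfg$mcl_level),
      .slices_for_visit(sid, "followup", obs1, cfg$mcl_level))

    base_scores <- c(mJOA = 16, QuickDASH = 10, UEMS_R = 24, UEMS_L = 24,
                     grip_R = 32, grip_L = 30, dexterity_R = 8,
                     dexterity_L = 8, dexterity_time_R = 40,
                     dexterity_time_L = 42, sensation_R = 11,
                     sensation_L = 11, berg_balance = 52,
                     gait_stability_ratio = 0.9)
    fu_scores <- base_scores
    if (progressor[i]) {
      specs <- default_battery()
      for (m in cfg$clinical_worsen_measures) {
        sp <- specs[[m]]
        denom <- if (sp$scale_kind == "finite") sp$max_score
        else abs(base_scores[[m]])
        step <- cfg$clinical_worsen_percent / 100 * denom
        fu_scores[[m]] <- base_scores[[m]] +
          if (sp$polarity == "higher_is_better") -step else step
        if (sp$scale_kind == "finite")
          fu_scores[[m]] <- min(max(fu_scores[[m]], 0), sp$max_score)
        if (m == "mJOA") fu_scores[[m]] <- round(fu_scores[[m]])
      }
    }
    mk_visit <- function(visit, age, scores) {
      mj <- round(scores[["mJOA"]])
      # decompose total into subscores (motor absorbs the deficit first)
      lower <- min(7, mj); rest <- mj - lower
      upper <- min(5, rest); rest <- rest - upper
      sens <- min(3, rest); urin <- rest - sens
      list(subject_id = sid, visit = visit, age_years = age,
           scores = scores,
           mjoa = mjoa_score(upper, lower, sens, urin))
    }
    visits[[length(visits) + 1L]] <- mk_visit("baseline", age0, base_scores)
    visits[[length(visits) + 1L]] <- mk_visit("followup", age0 + dt, fu_scores)

    p_worse <- if (progressor[i]) cfg$p_worse_given_progression
    else cfg$p_worse_given_stable
    subjective[[i]] <- data.frame(
      subject_id = sid,
      response = if (stats::runif(1) < p_worse) "worse" else "same",
      stringsAsFactors = FALSE)

    p_comp <- if (progressor[i]) cfg$p_new_compression_progressor
    else cfg$p_new_compression_stable
    worsens <- stats::runif(1) < p_comp
    anat[[i]] <- data.frame(
      subject_id = sid,
      visit = rep(c("baseline", "followup"), each = 2),
      level = rep(c(cfg$mcl_level, "C5-C6"), 2),
      status = c("flattening", "indentation",
                 if (worsens) "torsion" else "flattening", "indentation"),
      stringsAsFactors = FALSE)
  }

  list(panels = do.call(rbind, panels),
       visits = structure(list(visits = visits, specs = default_battery()),
                          class = "clinical_cohort"),
       subjective = do.call(rbind, subjective),
       anatomical = do.call(rbind, anat),
       mcl = data.frame(subject_id = sprintf("S%02d", seq_len(n)),
                        mcl_level = cfg$mcl_level, stringsAsFactors = FALSE),
       ages = do.call(rbind, ages),
       truth = data.frame(subject_id = sprintf("S%02d", seq_len(n)),
                          progressor = progressor, stringsAsFactors = FALSE),
       profiles = do.call(rbind, profs))
}

# Lay out 13 axial slices (C1-C7, alternating body and disc) for all four
# metrics of one visit, consistent with the aggregation contract: region
# slices carry the slot value plus zero-sum scatter, so the region mean is
# exactly the slot value; MCL-adjacent slices are flagged compressed.
.slices_for_visit <- function(sid, visit, slot_values, mcl_level) {
  lv <- .level_labels
  rostral <- region_spec()$rostral_levels
  caudal <- region_spec()$caudal_levels
  mcl_pos <- match(mcl_level, lv)
  compressed <- abs(seq_along(lv) - mcl_pos) <= 1L
  out <- list()
  for (m in .qmri_metrics) {
    vals <- rep(NA_real_, length(lv))
    fill <- function(idx, centre) {
      if (!length(idx)) return()
      sc <- stats::rnorm(length(idx), 0, .slice_scatter[m])
      vals[idx] <<- centre + sc - mean(sc)
    }
    ros <- which(lv %in% rostral)
    cau <- which(lv %in% caudal)
    mcl_idx <- if (m == "CSA") mcl_pos else
      intersect(seq(mcl_pos - 1L, mcl_pos + 1L), seq_along(lv))
    has_caudal <- paste0(m, "_caudal") %in% names(slot_values)
    fill(ros, slot_values[[paste0(m, "_rostral")]])
    fill(mcl_idx, slot_values[[paste0(m, "_mcl")]])
    fill(cau, if (has_caudal) slot_values[[paste0(m, "_caudal")]]
         else slot_values[[paste0(m, "_mcl")]])
    rest <- which(is.na(vals))
    vals[rest] <- slot_values[[paste0(m, "_rostral")]]
    vals <- .clamp_metric(vals, m)
    out[[m]] <- data.frame(subject_id = sid, visit = visit, metric = m,
                           level = lv, slice_index = seq_along(lv),
                           value = vals, compressed = compressed,
                           excluded_artifact = FALSE,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# small within-region scatter (zero-sum, so it never biases the mean)
.slice_scatter <- c(CSA = 1.0, FA = 0.01, MTR = 0.5, T2sWMGM = 0.01)

.clamp_metric <- function(x, metric) {
  switch(metric,
         CSA = pmax(x, 1e-6),
         FA = pmin(pmax(x, 0), 1),
         MTR = pmin(pmax(x, 0), 100),
         T2sWMGM = pmax(x, 1e-6))
}

#' Null-calibration experiment for the change-detection rule
#'
#' Simulates visit differences under the measurement-error null
#' (`delta ~ Normal(0, 2*SEM^2)` per slot, complete data) and reports the
#' empirical per-slot and composite flag rates with Monte-Carlo standard
#' errors. With the default thresholds the per-slot rate converges to the
#' normal tail at -2.65 (0.004) and the composite rate stays below it (the
#' t10 threshold is wider than the standard-normal behaviour of
#' `mean(z)*sqrt(10)` under the null).
#'
#' @param reps Number of null replicates (>= 1e4 recommended).
#' @param seed RNG seed.
#' @param rel [reliability_table()].
#' @param cfg [detection_config()].
#' @param error_correlation Cross-slot error correlation (0 = independent).
#' @return List: `per_slot_rate`, `per_slot_mc_se`, `composite_rate`,
#'   `composite_mc_se`, `expected_per_slot`, `reps`.
#' @export
calibration_experiment <- function(reps = 1e5, seed = 1L,
                                   rel = reliability_table(),
                                   cfg = detection_config(),
                                   error_correlation = 0) {
  stopifnot(reps >= 1)
  set.seed(seed)
  k <- length(rel$sem)
  z <- matrix(stats::rnorm(reps * k), reps, k)
  if (error_correlation > 0) {
    shared <- stats::rnorm(reps)
    z <- sqrt(1 - error_correlation) * z + sqrt(error_correlation) * shared
  }
  # deltas ~ N(0, 2 SEM^2) give z = delta/(sqrt(2) SEM) standard normal;
  # polarity flips are symmetric under the null
  slot_flags <- z < cfg$z_threshold
  comp <- rowMeans(z) * sqrt(k)
  per_slot_rate <- mean(slot_flags)
  composite_rate <- mean(comp < cfg$composite_t_threshold)
  list(per_slot_rate = per_slot_rate,
       per_slot_mc_se = sqrt(per_slot_rate * (1 - per_slot_rate) / (reps * k)),
       composite_rate = composite_rate,
       composite_mc_se = sqrt(composite_rate * (1 - composite_rate) / reps),
       expected_per_slot = stats::pnorm(cfg$z_threshold),
       reps = reps)
}

#' Detection power against injected effect size
#'
#' Simulates progressors with a per-slot shift of `k * sqrt(2) * SEM` plus
#' measurement noise and reports the per-slot detection fraction, which
#' follows the closed-form normal power `pnorm(z_threshold + k)`.
#'
#' @param effect_sizes Numeric vector of shifts in units of sqrt(2)*SEM.
#' @param reps Replicates per effect size.
#' @param seed RNG seed.
#' @param cfg [detection_config()].
#' @return data.frame: `effect_size`, `detected_fraction`, `expected`,
#'   `mc_se`.
#' @export
power_experiment <- function(effect_sizes = c(0.5, 1, 2, 3), reps = 1e4,
                             seed = 1L, cfg = detection_config()) {
  set.seed(seed)
  rows <- lapply(effect_sizes, function(k) {
    z <- stats::rnorm(reps) - k   # pathological-negative convention
    frac <- mean(z < cfg$z_threshold)
    expected <- stats::pnorm(cfg$z_threshold + k)
    data.frame(effect_size = k, detected_fraction = frac,
               expected = expected,
               mc_se = sqrt(expected * (1 - expected) / reps))
  })
  do.call(rbind, rows)
}
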