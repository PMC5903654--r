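# Measurement-error change detection.
#
# Under the null hypothesis that a longitudinal change reflects only
# test-retest noise, the visit difference of a metric is Normal with mean 0
# and SD = sqrt(2) * SEM (two independent measurement errors). Each of the
# 10 region metrics yields z = delta / (sqrt(2) * SEM), sign-adjusted so
# pathological change is negative. The 10 z-scores are averaged into an
# unweighted composite referred to a t distribution with 10 d.f. and
# standard error 1/sqrt(10). Progression: any z < -2.65 or composite
# t10 < -3.30 (one-tailed p = 0.004, Bonferroni-corrected family alpha 0.05).

#' Test-retest reliability table (SEM per metric and region)
#'
#' Standard errors of measurement, in each metric's units: CSA (mm^2)
#' rostral 0.95, MCL 2.94; FA rostral 0.018, MCL 0.029, caudal 0.025;
#' T2*WI WM/GM rostral 0.008, MCL 0.034, caudal 0.022; MTR (%) rostral 1.26,
#' MCL 3.10. Rostral/caudal values pool healthy and DCM subjects; MCL values
#' come from DCM subjects only.
#'
#' @param sem Named numeric over the 10 slots (`metric_region` names).
#' @return `reliability_table` object.
#' @export
reliability_table <- function(sem = c(
  CSA_rostral = 0.95, CSA_mcl = 2.94,
  FA_rostral = 0.018, FA_mcl = 0.029, FA_caudal = 0.025,
  T2sWMGM_rostral = 0.008, T2sWMGM_mcl = 0.034, T2sWMGM_caudal = 0.022,
  MTR_rostral = 1.26, MTR_mcl = 3.10)) {
  missing_slots <- setdiff(.slot_names(), names(sem))
  if (length(missing_slots))
    stop("SEM missing for slots: ", paste(missing_slots, collapse = ", "),
         call. = FALSE)
  if (any(sem <= 0)) stop("all SEM values must be > 0", call. = FALSE)
  structure(list(sem = sem[.slot_names()]), class = "reliability_table")
}

#' Detection configuration
#'
#' Thresholds and polarity for the change-detection rule. The per-metric
#' threshold is z < -2.65 and the composite threshold t10 < -3.30, both
#' strict, one-tailed (per-test p = 0.004 after Bonferroni correction of a
#' family alpha of 0.05 across the 10 metrics and the composite). CSA, FA
#' and MTR decline pathologically; T2*WI WM/GM increases pathologically, so
#' its z is flipped to keep all pathological change negative.
#'
#' @param z_threshold Per-metric threshold (negative, strict `<`).
#' @param composite_t_threshold Composite threshold (negative, strict `<`).
#' @param composite_df Degrees of freedom of the composite null reference.
#' @param composite_reference `"t"` (default) or `"normal"` null reference
#'   for the composite.
#' @param alpha_overall Family alpha.
#' @param per_test_p Bonferroni per-test level.
#' @param pathological_direction Named character over slots, `"decrease"` or
#'   `"increase"`.
#' @return `detection_config` object.
#' @export
detection_config <- function(z_threshold = -2.65,
                             composite_t_threshold = -3.30,
                             composite_df = 10,
                             composite_reference = c("t", "normal"),
                             alpha_overall = 0.05,
                             per_test_p = 0.004,
                             pathological_direction = NULL) {
  composite_reference <- match.arg(composite_reference)
  if (z_threshold >= 0 || composite_t_threshold >= 0)
    stop("thresholds must be negative (pathological direction)", call. = FALSE)
  if (per_test_p <= 0 || per_test_p >= alpha_overall)
    stop("per_test_p must lie in (0, alpha_overall)", call. = FALSE)
  if (is.null(pathological_direction)) {
    slots <- qmri_slots()
    pathological_direction <- stats::setNames(
      ifelse(slots$metric == "T2sWMGM", "increase", "decrease"),
      .slot_names())
  }
  structure(list(z_threshold = z_threshold,
                 composite_t_threshold = composite_t_threshold,
                 composite_df = composite_df,
                 composite_reference = composite_reference,
                 composite_null_se = 1 / sqrt(composite_df),
                 alpha_overall = alpha_overall,
                 per_test_p = per_test_p,
                 pathological_direction = pathological_direction),
            class = "detection_config")
}

#' Measurement-error z-score of a longitudinal change
#'
#' `z = delta / (sqrt(2) * SEM)`, sign-adjusted so pathological change is
#' negative (a T2*WI WM/GM increase maps to negative z).
#'
#' @param delta Corrected follow-up minus baseline value (slot units); may
#'   be a vector over slots when `slot` is a matching vector.
#' @param slot Slot name(s), e.g. `"FA_rostral"`.
#' @param rel [reliability_table()].
#' @param cfg [detection_config()] (supplies polarity).
#' @return Signed z (NA where delta is missing).
#' @export
change_z <- function(delta, slot, rel = reliability_table(),
                     cfg = detection_config()) {
  stopifnot(inherits(rel, "reliability_table"))
  bad <- setdiff(slot, names(rel$sem))
  if (length(bad))
    stop("no SEM for slot(s): ", paste(bad, collapse = ", "), call. = FALSE)
  z <- delta / (sqrt(2) * rel$sem[slot])
  flip <- cfg$pathological_direction[slot] == "increase"
  z[flip] <- -z[flip]
  stats::setNames(z, slot)
}

#' Unweighted composite change score
#'
#' Mean of the available slot z-scores divided by its null standard error
#' `1/sqrt(m)` (`m` = number of available slots; 10 when complete). Under
#' the null the statistic is referred to a t distribution with
#' `composite_df` degrees of freedom.
#'
#' @param z Numeric vector of slot z-scores (NA = missing slot).
#' @param cfg [detection_config()].
#' @return List with `composite_t`, `m` (slots used), `reference` and `df`.
#' @export
composite_score <- function(z, cfg = detection_config()) {
  z <- z[!is.na(z)]
  if (!length(z))
    return(list(composite_t = NA_real_, m = 0L,
                reference = cfg$composite_reference, df = cfg$composite_df))
  list(composite_t = mean(z) * sqrt(length(z)), m = length(z),
       reference = cfg$composite_reference, df = cfg$composite_df)
}

#' Classify one follow-up event from its z-scores
#'
#' A slot is `progressed` when z < z_threshold, `improved_outlier` when
#' z > -z_threshold (symmetric bound), otherwise `stable`; missing slots are
#' `missing`. The event is `declined` when at least one slot progressed or
#' the composite falls below its threshold (strict inequalities), `NA` when
#' every slot is missing, and `stable` otherwise.
#'
#' @param z Named numeric of slot z-scores (NA = missing).
#' @param cfg [detection_config()].
#' @return `change_result`: list with `z`, `flags`, `composite_t`, `m`,
#'   `qmri_cat` and the flagged slot names.
#' @export
classify_event <- function(z, cfg = detection_config()) {
  flags <- rep("missing", length(z))
  names(flags) <- names(z)
  avail <- !is.na(z)
  flags[avail & z < cfg$z_threshold] <- "progressed"
  flags[avail & z > -cfg$z_threshold] <- "improved_outlier"
  flags[avail & flags == "missing"] <- "stable"
  comp <- composite_score(z, cfg)
  composite_flag <- !is.na(comp$composite_t) &&
    comp$composite_t < cfg$composite_t_threshold
  qmri_cat <- if (!any(avail)) NA_character_
  else if (any(flags == "progressed") || composite_flag) "declined"
  else "stable"
  structure(list(z = z, flags = flags, composite_t = comp$composite_t,
                 m = comp$m, composite_flag = composite_flag,
                 qmri_cat = qmri_cat,
                 progressed_slots = names(z)[flags == "progressed"],
                 improved_slots = names(z)[flags == "improved_outlier"]),
            class = "change_result")
}

#' @export
print.change_result <- function(x, ...) {
  cat("<change_result> category:", x$qmri_cat, "\n")
  cat("  composite t =", round(x$composite_t, 2),
      if (isTRUE(x$composite_flag)) "(flagged)", "\n")
  if (length(x$progressed_slots))
    cat("  progressed:", paste(x$progressed_slots, collapse = ", "), "\n")
  if (length(x$improved_slots))
    cat("  improved outliers:", paste(x$improved_slots, collapse = ", "), "\n")
  invisible(x)
}

#' One-tailed per-test level implied by the z threshold
#'
#' Standard normal lower-tail probability at `z_threshold`; at -2.65 this is
#' 0.004 to three decimals.
#'
#' @param cfg [detection_config()].
#' @return Tail probability.
#' @export
per_test_p_of_threshold <- function(cfg = detection_config()) {
  stats::pnorm(cfg$z_threshold)
}

#' Change detection between two visit profiles
#'
#' Differences two [build_profile()] outputs (follow-up minus baseline),
#' converts each slot to its measurement-error z and classifies the event.
#'
#' @param baseline,followup `qmri_profile` vectors.
#' @param rel [reliability_table()].
#' @param cfg [detection_config()].
#' @return `change_result` (see [classify_event()]).
#' @export
qmri_change <- function(baseline, followup, rel = reliability_table(),
                        cfg = detection_config()) {
  stopifnot(identical(names(baseline), .slot_names()),
            identical(names(followup), .slot_names()))
  delta <- unclass(followup) - unclass(baseline)
  z <- change_z(as.numeric(delta), names(delta), rel, cfg)
  classify_event(z, cfg)
}
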