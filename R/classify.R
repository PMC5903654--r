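# Rule-based progression classifiers for the non-qMRI modalities.

#' Progression rules for the clinical modalities
#'
#' mJOA: a decrease of >= 2 points is progression, a 1-point decline is
#' borderline. Comprehensive battery: >= 3 measures worsening by >= 5% is
#' progression, 1-2 worsening measures is borderline.
#'
#' @param mjoa_decline_progression,mjoa_decline_borderline Point declines.
#' @param battery_worsen_threshold Percent worsening counting a measure as
#'   worsened (inclusive).
#' @param battery_count_progression Worsened-measure count defining
#'   progression.
#' @param battery_count_borderline Range (length-2) defining borderline.
#' @return `classification_rules` object.
#' @export
classification_rules <- function(mjoa_decline_progression = 2,
                                 mjoa_decline_borderline = 1,
                                 battery_worsen_threshold = 5,
                                 battery_count_progression = 3,
                                 battery_count_borderline = c(1, 2)) {
  stopifnot(mjoa_decline_progression > mjoa_decline_borderline,
            mjoa_decline_borderline > 0,
            battery_worsen_threshold > 0,
            max(battery_count_borderline) < battery_count_progression)
  structure(as.list(environment()), class = "classification_rules")
}

#' Classify the patient's subjective impression
#'
#' "Worse" defines progression, "maybe worse" borderline progression,
#' "same" or "better" stability.
#'
#' @param response One of `"better"`, `"same"`, `"maybe_worse"`, `"worse"`.
#' @return `"progression"`, `"borderline"` or `"stable"`.
#' @export
classify_subjective <- function(response) {
  response <- match.arg(response, .subjective_levels)
  switch(response,
         worse = "progression",
         maybe_worse = "borderline",
         "stable")
}

#' Classify mJOA change
#'
#' @param baseline_total,followup_total mJOA totals (0-18).
#' @param rules [classification_rules()].
#' @return `"declined"`, `"borderline"`, `"stable"` or `"improved"`.
#' @export
classify_mjoa <- function(baseline_total, followup_total,
                          rules = classification_rules()) {
  tot <- c(baseline_total, followup_total)
  if (any(tot < 0 | tot > 18))
    stop("mJOA totals must lie in [0, 18]", call. = FALSE)
  delta <- followup_total - baseline_total
  if (delta <= -rules$mjoa_decline_progression) "declined"
  else if (delta <= -rules$mjoa_decline_borderline) "borderline"
  else if (delta == 0) "stable"
  else "improved"
}

#' Classify the comprehensive battery
#'
#' Counts measures whose worsening-positive percent change (see
#' [percent_change()]) meets the threshold. Bilateral instruments enter as
#' separate measures per side.
#'
#' @param changes Named numeric of signed percent changes (positive =
#'   worsening), one entry per measure.
#' @param rules [classification_rules()].
#' @return List with `category` (`"stable"`, `"borderline"`, `"declined"`)
#'   and `worsened` (names of worsened measures).
#' @export
classify_battery <- function(changes, rules = classification_rules()) {
  stopifnot(is.numeric(changes))
  if (anyDuplicated(names(changes)))
    stop("each measure may appear only once", call. = FALSE)
  changes <- changes[!is.na(changes)]
  worsened <- names(changes)[changes >= rules$battery_worsen_threshold]
  n <- length(worsened)
  category <- if (n >= rules$battery_count_progression) "declined"
  else if (n >= min(rules$battery_count_borderline)) "borderline"
  else "stable"
  list(category = category, worsened = worsened)
}

# ordinal severity used to detect worsened compression; the qualitative
# types are ordered by increasing cord deformation
.compression_levels <- c("none", "indentation", "flattening", "torsion",
                         "circumferential")

#' Classify anatomical MRI change
#'
#' Declined if any intervertebral level gains new cord compression or its
#' compression type worsens along the ordinal chain none < indentation <
#' flattening < torsion < circumferential. Resolution at one level never
#' offsets worsening at another.
#'
#' @param baseline,followup Named character vectors of per-level compression
#'   status (same level set at both visits).
#' @param severity Character vector giving the ordinal chain.
#' @return `"declined"` or `"stable"`.
#' @export
classify_anatomical <- function(baseline, followup,
                                severity = .compression_levels) {
  if (!setequal(names(baseline), names(followup)) ||
      is.null(names(baseline)))
    stop("baseline and follow-up must cover the same named levels",
         call. = FALSE)
  followup <- followup[names(baseline)]
  bad <- !(baseline %in% severity) | !(followup %in% severity)
  if (any(bad))
    stop("unknown compression status: ",
         paste(unique(c(baseline[bad], followup[bad])), collapse = ", "),
         call. = FALSE)
  b <- match(baseline, severity)
  f <- match(followup, severity)
  if (any(f > b)) "declined" else "stable"
}

#' Classify one subject's clinical data end to end
#'
#' Convenience wrapper: computes battery percent changes from two
#' [read_cohort()] visits and applies the battery and mJOA rules.
#'
#' @param baseline,followup Visit records (elements of a
#'   `clinical_cohort$visits`).
#' @param specs Measure specifications.
#' @param rules [classification_rules()].
#' @return List with `mjoa_cat`, `clinical_cat`, `worsened`, `changes`.
#' @export
classify_visit_pair <- function(baseline, followup,
                                specs = default_battery(),
                                rules = classification_rules()) {
  shared <- intersect(names(baseline$scores), names(followup$scores))
  changes <- vapply(shared, function(m)
    percent_change(specs[[m]], baseline$scores[[m]], followup$scores[[m]]),
    numeric(1))
  bat <- classify_battery(changes, rules)
  mj <- if (!is.null(baseline$mjoa) && !is.null(followup$mjoa))
    classify_mjoa(baseline$mjoa$total, followup$mjoa$total, rules)
  else NA_character_
  list(mjoa_cat = mj, clinical_cat = bat$category,
       worsened = bat$worsened, changes = changes)
}
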