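# Surgical decision algorithm: combine the patient's subjective impression
# with the objective modalities into a progression status and a management
# recommendation.
#
#   progression          = subjective worsening AND any objective sign
#   possible progression = exactly one of the two
#   stable               = neither
#
# Objective sign = any available objective modality (mJOA, comprehensive
# battery, anatomical MRI, qMRI) classified declined, unless the clinician
# attributed the deterioration to another cause. Borderline categories do
# not count as objective progression; they are surfaced for clinician
# review.

#' Decide progression status and recommendation for one event
#'
#' @param subjective `"better"`, `"same"`, `"maybe_worse"` or `"worse"`.
#' @param mjoa_cat,clinical_cat,mri_cat,qmri_cat Per-modality categories
#'   (NA = modality not acquired).
#' @param attributed_to_other_cause Clinician annotation that the objective
#'   deterioration stems from a condition other than myelopathy.
#' @param attribution_scope Which modalities an attribution discounts:
#'   `"all"` (default; the annotation voids every objective finding of the
#'   event) or `"clinical"` (only the battery finding).
#' @return List: `subjective_prog`, `objective_prog`, `status`
#'   (`"progression"`, `"possible_progression"`, `"stable"`),
#'   `recommendation` (`"discuss_surgery"`, `"clinic_reassessment"`,
#'   `"continue_monitoring"`), `borderline_findings`.
#' @export
decide <- function(subjective, mjoa_cat = NA, clinical_cat = NA,
                   mri_cat = NA, qmri_cat = NA,
                   attributed_to_other_cause = FALSE,
                   attribution_scope = c("all", "clinical")) {
  attribution_scope <- match.arg(attribution_scope)
  cats <- c(mjoa = mjoa_cat, clinical = clinical_cat, mri = mri_cat,
            qmri = qmri_cat)
  if (is.na(subjective) && all(is.na(cats)))
    stop("undecidable event: no subjective response and no objective modality",
         call. = FALSE)
  subjective_prog <- !is.na(subjective) && subjective == "worse"
  declined <- !is.na(cats) & cats == "declined"
  if (isTRUE(attributed_to_other_cause)) {
    declined[if (attribution_scope == "all") names(cats) else "clinical"] <- FALSE
  }
  objective_prog <- any(declined)
  status <- if (subjective_prog && objective_prog) "progression"
  else if (subjective_prog || objective_prog) "possible_progression"
  else "stable"
  recommendation <- switch(status,
                           progression = "discuss_surgery",
                           possible_progression = "clinic_reassessment",
                           stable = "continue_monitoring")
  borderline <- names(cats)[!is.na(cats) & cats == "borderline"]
  if (!is.na(subjective) && subjective == "maybe_worse")
    borderline <- c("subjective", borderline)
  list(subjective_prog = subjective_prog, objective_prog = objective_prog,
       status = status, recommendation = recommendation,
       borderline_findings = borderline)
}

#' Decide every subject of a cohort at latest follow-up
#'
#' @param events Event data.frame (see [reference_events()]).
#' @param attribution_scope See [decide()].
#' @return List: `decisions` (data.frame, one row per subject) and `counts`
#'   (named integer: progression / possible_progression / stable).
#' @export
decide_cohort <- function(events, attribution_scope = "all") {
  latest <- latest_events(events)
  rows <- lapply(seq_len(nrow(latest)), function(i) {
    e <- latest[i, ]
    d <- decide(e$subjective, e$mjoa_cat, e$clinical_cat, e$mri_cat,
                e$qmri_cat, e$attributed_to_other_cause, attribution_scope)
    data.frame(subject_id = e$subject_id, status = d$status,
               recommendation = d$recommendation,
               subjective_prog = d$subjective_prog,
               objective_prog = d$objective_prog,
               borderline = paste(d$borderline_findings, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  decisions <- do.call(rbind, rows)
  counts <- vapply(c("progression", "possible_progression", "stable"),
                   function(s) sum(decisions$status == s), integer(1))
  list(decisions = decisions, counts = counts)
}

#' Run the full monitoring pipeline on a cohort
#'
#' Executes qMRI aggregation and change detection, clinical and anatomical
#' classification, the decision algorithm, and the accuracy stage, from the
#' in-memory cohort structure produced by [simulate_cohort()] (or assembled
#' from the readers). Deterministic given its input.
#'
#' @param cohort List with `panels` (per-slice qMRI data.frame), `visits`
#'   (clinical cohort), `subjective` (data.frame subject_id, response),
#'   `anatomical` (per-level readings, long format), `mcl` (data.frame
#'   subject_id, mcl_level), `ages` (subject_id, baseline_age,
#'   followup_age), and optional `attributed` (subject_id, flag).
#' @param rel [reliability_table()].
#' @param cfg [detection_config()].
#' @param rules [classification_rules()].
#' @param specs Measure specifications for the battery.
#' @param model [age_correction_model()].
#' @param attribution_scope See [decide()].
#' @return List: `events` (per-event classification table), `changes`
#'   (per-subject `change_result`s), `decisions`, `counts`, `accuracy`.
#' @export
run_pipeline <- function(cohort, rel = reliability_table(),
                         cfg = detection_config(),
                         rules = classification_rules(),
                         specs = default_battery(),
                         model = age_correction_model(),
                         attribution_scope = "all") {
  subjects <- unique(cohort$ages$subject_id)
  if (!length(subjects)) stop("empty cohort", call. = FALSE)
  changes <- list()
  rows <- lapply(subjects, function(s) {
    ages <- cohort$ages[cohort$ages$subject_id == s, ]
    mcl <- cohort$mcl$mcl_level[cohort$mcl$subject_id == s][1]
    region <- region_spec(mcl_level = mcl)

    get_panels <- function(visit) {
      p <- cohort$panels[cohort$panels$subject_id == s &
                           cohort$panels$visit == visit, ]
      out <- lapply(.qmri_metrics, function(m) {
        d <- p[p$metric == m, ]
        if (!nrow(d)) return(NULL)
        slice_panel(s, visit, m, d$level, d$slice_index, d$value,
                    d$compressed, d$excluded_artifact)
      })
      stats::setNames(out, .qmri_metrics)
    }
    has_qmri <- any(cohort$panels$subject_id == s)
    qmri_cat <- NA_character_
    if (has_qmri) {
      base_prof <- build_profile(get_panels("baseline"), ages$baseline_age,
                                 ages$baseline_age, model, region)
      fu_prof <- build_profile(get_panels("followup"), ages$followup_age,
                               ages$baseline_age, model, region)
      ch <- qmri_change(base_prof, fu_prof, rel, cfg)
      changes[[s]] <<- ch
      qmri_cat <- ch$qmri_cat
    }

    vis <- cohort$visits$visits
    vb <- Filter(function(v) v$subject_id == s && v$visit == "baseline", vis)
    vf <- Filter(function(v) v$subject_id == s && v$visit == "followup", vis)
    mjoa_cat <- clinical_cat <- NA_character_
    if (length(vb) && length(vf)) {
      cl <- classify_visit_pair(vb[[1]], vf[[1]], specs, rules)
      mjoa_cat <- cl$mjoa_cat
      clinical_cat <- cl$clinical_cat
    }

    mri_cat <- NA_character_
    an <- cohort$anatomical[cohort$anatomical$subject_id == s, ]
    if (nrow(an)) {
      b <- stats::setNames(an$status[an$visit == "baseline"],
                           an$level[an$visit == "baseline"])
      f <- stats::setNames(an$status[an$visit == "followup"],
                           an$level[an$visit == "followup"])
      mri_cat <- classify_anatomical(b, f)
    }

    subj <- cohort$subjective$response[cohort$subjective$subject_id == s][1]
    attributed <- FALSE
    if (!is.null(cohort$attributed))
      attributed <- isTRUE(cohort$attributed$flag[
        cohort$attributed$subject_id == s][1])
    event_record(s, "followup_1", subj, mjoa_cat, clinical_cat, mri_cat,
                 qmri_cat, attributed)
  })
  events <- do.call(rbind, rows)
  dec <- decide_cohort(events, attribution_scope)
  acc <- accuracy_report(events, mjoa_detected = NULL)
  list(events = events, changes = changes, decisions = dec$decisions,
       counts = dec$counts, accuracy = acc)
}
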