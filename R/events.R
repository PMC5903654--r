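# Per-event classification records: one baseline->follow-up comparison per
# row, one category per monitoring modality, NA where a modality was not
# acquired. This is the shape the accuracy and decision stages consume.

.subjective_levels <- c("better", "same", "maybe_worse", "worse")
.mjoa_cat_levels <- c("improved", "stable", "borderline", "declined")
.clinical_cat_levels <- c("stable", "borderline", "declined")
.binary_cat_levels <- c("stable", "declined")

#' Construct a per-event classification record
#'
#' @param subject_id Subject identifier.
#' @param event_label Label of the follow-up event (`"followup_1"`, ...).
#' @param subjective Patient's own rating: better / same / maybe_worse /
#'   worse, or NA.
#' @param mjoa_cat improved / stable / borderline / declined, or NA.
#' @param clinical_cat stable / borderline / declined, or NA (comprehensive
#'   battery).
#' @param mri_cat stable / declined, or NA (anatomical MRI).
#' @param qmri_cat stable / declined, or NA (quantitative MRI).
#' @param attributed_to_other_cause Clinician annotation: the objective
#'   deterioration on this event was judged to stem from a condition other
#'   than myelopathy (e.g. arthritis, an interval injury).
#' @param confounders Free-text annotation of confounding conditions.
#' @param latest Is this the subject's latest follow-up event?
#' @return One-row data.frame.
#' @export
event_record <- function(subject_id, event_label = "followup_1",
                         subjective = NA, mjoa_cat = NA, clinical_cat = NA,
                         mri_cat = NA, qmri_cat = NA,
                         attributed_to_other_cause = FALSE,
                         confounders = NA_character_, latest = TRUE) {
  chk <- function(x, levels, what) {
    if (length(x) != 1L) stop(what, " must be length 1", call. = FALSE)
    if (!is.na(x) && !x %in% levels)
      stop("invalid ", what, ": '", x, "' (allowed: ",
           paste(levels, collapse = ", "), ")", call. = FALSE)
    as.character(x)
  }
  data.frame(
    subject_id = as.character(subject_id),
    event_label = as.character(event_label),
    subjective = chk(subjective, .subjective_levels, "subjective"),
    mjoa_cat = chk(mjoa_cat, .mjoa_cat_levels, "mjoa_cat"),
    clinical_cat = chk(clinical_cat, .clinical_cat_levels, "clinical_cat"),
    mri_cat = chk(mri_cat, .binary_cat_levels, "mri_cat"),
    qmri_cat = chk(qmri_cat, .binary_cat_levels, "qmri_cat"),
    attributed_to_other_cause = isTRUE(attributed_to_other_cause),
    confounders = as.character(confounders),
    latest = isTRUE(latest),
    stringsAsFactors = FALSE
  )
}

#' Reference cohort of per-event classifications
#'
#' The packaged 26-subject reference cohort of non-operatively managed DCM
#' patients: 27 follow-up events (subject 12 was reassessed twice after
#' interim subjective deterioration), each carrying the per-modality
#' progression categories. Subjects 1-3 deteriorated rapidly and went to
#' urgent surgery before comprehensive/qMRI follow-up (those modalities are
#' NA); subject 26 declined everything beyond the interview and mJOA.
#' Clinician attribution annotations mark events whose objective decline was
#' judged to stem from a confounding condition rather than myelopathy.
#'
#' @return data.frame of 27 event records.
#' @export
reference_events <- function() {
  r <- function(...) event_record(...)
  out <- rbind(
    r(1, subjective = "worse", mjoa_cat = "declined", mri_cat = "stable"),
    r(2, subjective = "worse", mjoa_cat = "declined", mri_cat = "stable"),
    r(3, subjective = "worse", mjoa_cat = "declined", mri_cat = "stable"),
    r(4, subjective = "worse", mjoa_cat = "declined",
      clinical_cat = "declined", mri_cat = "declined", qmri_cat = "declined"),
    r(5, subjective = "better", mjoa_cat = "stable",
      clinical_cat = "borderline", mri_cat = "stable", qmri_cat = "declined",
      confounders = "L elbow injury"),
    r(6, subjective = "same", mjoa_cat = "stable",
      clinical_cat = "declined", mri_cat = "declined", qmri_cat = "declined"),
    r(7, subjective = "same", mjoa_cat = "stable",
      clinical_cat = "stable", mri_cat = "stable", qmri_cat = "stable"),
    r(8, subjective = "same", mjoa_cat = "stable",
      clinical_cat = "declined", mri_cat = "stable", qmri_cat = "stable",
      attributed_to_other_cause = TRUE,
      confounders = "lumbar radiculopathy; psoriatic arthritis (hands); knee replacement"),
    r(9, subjective = "same", mjoa_cat = "stable",
      clinical_cat = "declined", mri_cat = "stable", qmri_cat = "declined"),
    r(10, subjective = "worse", mjoa_cat = "stable",
      clinical_cat = "declined", mri_cat = "declined", qmri_cat = "declined",
      confounders = "rheumatoid arthritis"),
    r(11, subjective = "same", mjoa_cat = "stable",
      clinical_cat = "borderline", mri_cat = "stable", qmri_cat = "stable"),
    r(12, event_label = "followup_1", subjective = "same", mjoa_cat = "stable",
      clinical_cat = "borderline", mri_cat = "stable", qmri_cat = "stable",
      latest = FALSE),
    r(12, event_label = "followup_2", subjective = "worse",
      mjoa_cat = "stable", clinical_cat = "declined", mri_cat = "stable",
      qmri_cat = "declined"),
    r(13, subjective = "worse", mjoa_cat = "stable",
      clinical_cat = "declined", mri_cat = "stable", qmri_cat = "declined"),
    r(14, subjective = "same", mjoa_cat = "stable",
      clinical_cat = "declined", mri_cat = "declined", qmri_cat = "declined"),
    r(15, subjective = "worse", mjoa_cat = "stable",
      clinical_cat = "borderline", mri_cat = "stable", qmri_cat = "declined"),
    r(16, subjective = "same", mjoa_cat = "stable",
      clinical_cat = "declined", mri_cat = "stable", qmri_cat = "stable",
      attributed_to_other_cause = TRUE, confounders = "L hand fasciitis"),
    r(17, subjective = "worse", mjoa_cat = "stable",
      clinical_cat = "borderline", mri_cat = "stable", qmri_cat = "declined"),
    r(18, subjective = "same", mjoa_cat = "stable",
      clinical_cat = "declined", mri_cat = "stable", qmri_cat = "stable",
      attributed_to_other_cause = TRUE, confounders = "severe back pain"),
    r(19, subjective = "worse", mjoa_cat = "stable",
      clinical_cat = "declined", mri_cat = "stable", qmri_cat = "declined"),
    r(20, subjective = "same", mjoa_cat = "stable",
      clinical_cat = "borderline", mri_cat = "stable", qmri_cat = "declined"),
    r(21, subjective = "same", mjoa_cat = "stable",
      clinical_cat = "stable", mri_cat = "stable", qmri_cat = "declined",
      attributed_to_other_cause = TRUE,
      confounders = "mild TBI with post-concussion symptoms"),
    r(22, subjective = "worse", mjoa_cat = "stable",
      clinical_cat = "declined", mri_cat = "stable", qmri_cat = "declined"),
    r(23, subjective = "same", mjoa_cat = "stable",
      clinical_cat = "borderline", mri_cat = "stable", qmri_cat = "declined"),
    r(24, subjective = "better", mjoa_cat = "improved",
      clinical_cat = "borderline", mri_cat = "stable", qmri_cat = "stable",
      confounders = "shoulder and neck injury"),
    r(25, subjective = "better", mjoa_cat = "stable",
      clinical_cat = "stable", mri_cat = "declined", qmri_cat = "stable"),
    r(26, subjective = "same", mjoa_cat = "stable")
  )
  rownames(out) <- NULL
  out
}

#' Write / read per-event classification tables
#'
#' CSV dialect: one row per follow-up event with the per-modality category
#' columns; NA cells denote modalities not acquired for that event.
#'
#' @param events data.frame as returned by [reference_events()].
#' @param file Path to CSV.
#' @return `read_events` returns the validated data.frame.
#' @export
write_events <- function(events, file) {
  utils::write.csv(events, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_events
#' @export
read_events <- function(file) {
  d <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("subject_id", "event_label", "subjective", "mjoa_cat",
            "clinical_cat", "mri_cat", "qmri_cat",
            "attributed_to_other_cause", "latest")
  if (!all(need %in% names(d)))
    stop("event file lacks columns: ",
         paste(setdiff(need, names(d)), collapse = ", "), call. = FALSE)
  if (!"confounders" %in% names(d)) d$confounders <- NA_character_
  d$subject_id <- as.character(d$subject_id)
  out <- do.call(rbind, lapply(seq_len(nrow(d)), function(i)
    event_record(d$subject_id[i], d$event_label[i], d$subjective[i],
                 d$mjoa_cat[i], d$clinical_cat[i], d$mri_cat[i],
                 d$qmri_cat[i], d$attributed_to_other_cause[i],
                 d$confounders[i], d$latest[i])))
  rownames(out) <- NULL
  out
}

#' Keep each subject's latest follow-up event
#'
#' Subject-level rates use the latest event; event-level accuracy uses all
#' events.
#'
#' @param events Event data.frame.
#' @return Subset with one row per subject.
#' @export
latest_events <- function(events) {
  events[events$latest, , drop = FALSE]
}
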