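#' Define a clinical outcome measure
#'
#' A measure specification carries everything the change rules need to turn a
#' pair of raw scores into a signed, worsening-positive percent change: the
#' kind of scale (finite scales have a fixed maximum used as the denominator,
#' infinite scales such as grip strength use the baseline value) and the
#' polarity (whether larger values mean better or worse function).
#'
#' @param name Measure identifier, e.g. `"mJOA"` or `"grip_R"`.
#' @param scale_kind `"finite"` (bounded score) or `"infinite"` (unbounded
#'   physical quantity).
#' @param max_score Maximum attainable score; required for finite scales,
#'   ignored otherwise.
#' @param polarity `"higher_is_better"` or `"lower_is_better"`.
#' @return A `measure_spec` object (a named list).
#' @examples
#' measure_spec("mJOA", "finite", max_score = 18)
#' measure_spec("grip_R", "infinite")
#' @export
measure_spec <- function(name,
                         scale_kind = c("finite", "infinite"),
                         max_score = NULL,
                         polarity = c("higher_is_better", "lower_is_better")) {
  scale_kind <- match.arg(scale_kind)
  polarity <- match.arg(polarity)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (scale_kind == "finite") {
    if (is.null(max_score) || !is.numeric(max_score) || max_score <= 0)
      stop("finite measure '", name, "' requires max_score > 0", call. = FALSE)
  } else {
    max_score <- NA_real_
  }
  structure(
    list(name = name, scale_kind = scale_kind,
         max_score = as.numeric(max_score), polarity = polarity),
    class = "measure_spec"
  )
}

#' @export
print.measure_spec <- function(x, ...) {
  cat("<measure_spec> ", x$name, ": ", x$scale_kind,
      if (x$scale_kind == "finite") paste0(" (max ", x$max_score, ")"),
      ", ", x$polarity, "\n", sep = "")
  invisible(x)
}

#' Default clinical assessment battery
#'
#' The battery used for comprehensive monitoring of cervical myelopathy:
#' mJOA (18 points), QuickDASH (44 points, lower is better), ISNCSCI upper
#' extremity motor score per arm (25 points per side), grip dynamometry per
#' hand (kg, unbounded), GRASSP dexterity precision per hand (9 points) and
#' time to completion per hand (seconds, lower is better), monofilament
#' sensory score per hand, Berg Balance Scale (56 points) and the GAITRite
#' gait stability ratio (single/double stance time, unbounded, lower is
#' better as imbalance inflates double-support time and myelopathic gait
#' lowers the ratio). Bilateral instruments enter as separate measures per
#' side so each side counts toward the worsening-measure tally.
#'
#' @return Named list of [measure_spec()] objects.
#' @export
default_battery <- function() {
  specs <- list(
    measure_spec("mJOA", "finite", 18),
    measure_spec("QuickDASH", "finite", 44, polarity = "lower_is_better"),
    measure_spec("UEMS_R", "finite", 25),
    measure_spec("UEMS_L", "finite", 25),
    measure_spec("grip_R", "infinite"),
    measure_spec("grip_L", "infinite"),
    measure_spec("dexterity_R", "finite", 9),
    measure_spec("dexterity_L", "finite", 9),
    measure_spec("dexterity_time_R", "infinite", polarity = "lower_is_better"),
    measure_spec("dexterity_time_L", "infinite", polarity = "lower_is_better"),
    measure_spec("sensation_R", "finite", 12),
    measure_spec("sensation_L", "finite", 12),
    measure_spec("berg_balance", "finite", 56),
    measure_spec("gait_stability_ratio", "infinite")
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Signed percent change of a clinical measure
#'
#' Computes the change between baseline and follow-up on the percent scale
#' the progression rules operate on. Finite scales use the maximum score as
#' the denominator (e.g. 18 for mJOA); infinite scales use the baseline
#' value. The result is polarity-adjusted so that a positive value always
#' means worsening, which makes the ">= 5% worsened" rule a single
#' comparison.
#'
#' @param spec A [measure_spec()].
#' @param baseline,followup Raw scores at the two visits.
#' @return Signed percent change, positive = worsening.
#' @examples
#' percent_change(measure_spec("mJOA", "finite", 18), 15, 13)  # +11.1
#' @export
percent_change <- function(spec, baseline, followup) {
  stopifnot(inherits(spec, "measure_spec"),
            is.numeric(baseline), is.numeric(followup))
  if (spec$scale_kind == "finite") {
    if (any(c(baseline, followup) < 0) || any(c(baseline, followup) > spec$max_score))
      stop("score out of [0, ", spec$max_score, "] for measure '",
           spec$name, "'", call. = FALSE)
    denom <- spec$max_score
  } else {
    if (baseline == 0)
      stop("percent change undefined: infinite-scale measure '", spec$name,
           "' has baseline 0", call. = FALSE)
    denom <- abs(baseline)
  }
  raw <- 100 * (followup - baseline) / denom
  if (spec$polarity == "higher_is_better") -raw else raw
}

#' mJOA score with subscore validation
#'
#' The modified Japanese Orthopedic Association score is an 18-point
#' myelopathy disability scale: upper extremity motor (0-5), lower extremity
#' (0-7), upper extremity sensory (0-3) and urinary function (0-3). The
#' total must equal the subscore sum.
#'
#' @param upper_motor,lower,upper_sensory,urinary Integer subscores.
#' @return An `mjoa_score` list with a `total` field.
#' @export
mjoa_score <- function(upper_motor, lower, upper_sensory, urinary) {
  subs <- c(upper_motor = upper_motor, lower = lower,
            upper_sensory = upper_sensory, urinary = urinary)
  maxes <- c(upper_motor = 5, lower = 7, upper_sensory = 3, urinary = 3)
  if (any(subs != round(subs)))
    stop("mJOA subscores must be integers", call. = FALSE)
  bad <- subs < 0 | subs > maxes
  if (any(bad))
    stop("mJOA subscore out of range: ",
         paste0(names(subs)[bad], "=", subs[bad], " (max ",
                maxes[bad], ")", collapse = ", "), call. = FALSE)
  subs <- stats::setNames(as.integer(subs), names(subs))
  structure(c(as.list(subs), list(total = sum(subs))),
            class = "mjoa_score")
}

# internal: level ordering used for vertebral labels (mid-body and disc)
.level_labels <- c("C1", "C1-C2", "C2", "C2-C3", "C3", "C3-C4", "C4",
                   "C4-C5", "C5", "C5-C6", "C6", "C6-C7", "C7")

#' Read a cohort of clinical visits
#'
#' Reads the long-format cohort table (one row per subject, visit and
#' measure) and the mJOA subscore table, validating every score against its
#' measure specification. Unknown measure names and out-of-range scores are
#' rejected with the offending subject/visit named.
#'
#' @param cohort_file CSV with columns `subject_id, visit, age, measure,
#'   value`.
#' @param mjoa_file CSV with columns `subject_id, visit, upper_motor, lower,
#'   upper_sensory, urinary`.
#' @param specs Named list of [measure_spec()]s, e.g. [default_battery()].
#' @return A `clinical_cohort`: list of visits, each with `subject_id`,
#'   `visit`, `age_years`, `scores` (named numeric) and `mjoa`.
#' @export
read_cohort <- function(cohort_file, mjoa_file, specs = default_battery()) {
  scores <- utils::read.csv(cohort_file, stringsAsFactors = FALSE)
  need <- c("subject_id", "visit", "age", "measure", "value")
  if (!all(need %in% names(scores)))
    stop("cohort file lacks columns: ",
         paste(setdiff(need, names(scores)), collapse = ", "), call. = FALSE)
  mj <- utils::read.csv(mjoa_file, stringsAsFactors = FALSE)
  unknown <- setdiff(unique(scores$measure), names(specs))
  if (length(unknown))
    stop("no measure_spec configured for: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  key <- interaction(scores$subject_id, scores$visit, drop = TRUE)
  visits <- lapply(split(scores, key), function(d) {
    if (anyDuplicated(d$measure))
      stop("duplicate measure rows for subject ", d$subject_id[1],
           " visit ", d$visit[1], call. = FALSE)
    for (i in seq_len(nrow(d))) {
      sp <- specs[[d$measure[i]]]
      if (sp$scale_kind == "finite" &&
          (d$value[i] < 0 || d$value[i] > sp$max_score))
        stop("score out of range for '", d$measure[i], "' (subject ",
             d$subject_id[1], ", visit ", d$visit[1], "): ", d$value[i],
             call. = FALSE)
    }
    row <- mj[mj$subject_id == d$subject_id[1] & mj$visit == d$visit[1], ]
    mjoa <- if (nrow(row) == 1L)
      mjoa_score(row$upper_motor, row$lower, row$upper_sensory, row$urinary)
    else NULL
    age <- d$age[1]
    if (!is.finite(age) || age <= 0)
      stop("age_years must be > 0 (subject ", d$subject_id[1], ")",
           call. = FALSE)
    list(subject_id = d$subject_id[1], visit = d$visit[1], age_years = age,
         scores = stats::setNames(d$value, d$measure), mjoa = mjoa)
  })
  names(visits) <- NULL
  structure(list(visits = visits, specs = specs), class = "clinical_cohort")
}

#' Write a cohort back to its CSV dialect
#'
#' Inverse of [read_cohort()]; the round trip is lossless for score values.
#'
#' @param cohort A `clinical_cohort`.
#' @param cohort_file,mjoa_file Output paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(cohort, cohort_file, mjoa_file) {
  stopifnot(inherits(cohort, "clinical_cohort"))
  rows <- do.call(rbind, lapply(cohort$visits, function(v) {
    data.frame(subject_id = v$subject_id, visit = v$visit, age = v$age_years,
               measure = names(v$scores), value = unname(v$scores),
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(rows, cohort_file, row.names = FALSE, quote = FALSE)
  mj <- do.call(rbind, lapply(cohort$visits, function(v) {
    if (is.null(v$mjoa)) return(NULL)
    data.frame(subject_id = v$subject_id, visit = v$visit,
               upper_motor = v$mjoa$upper_motor, lower = v$mjoa$lower,
               upper_sensory = v$mjoa$upper_sensory, urinary = v$mjoa$urinary,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(mj, mjoa_file, row.names = FALSE, quote = FALSE)
  invisible(c(cohort_file, mjoa_file))
}
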