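# From per-slice qMRI values to the 10 age-corrected region metrics.
#
# Axial slices cover C1-C7 (13 slices alternating mid-vertebral body and
# disc). Metrics are averaged over the rostral (C1-C3) and caudal (C6-C7)
# levels, excluding compressed or artifact-degraded slices, and extracted at
# the maximally compressed level (MCL): the single MCL slice for CSA, the
# MCL slice plus its two neighbours for FA, MTR and T2*WI WM/GM. Caudal CSA
# and caudal MTR are structurally absent (no reliable test-retest basis), so
# the profile has exactly 10 (metric, region) slots.

.qmri_metrics <- c("CSA", "FA", "MTR", "T2sWMGM")

#' The 10 retained (metric, region) slots
#'
#' @return data.frame with columns `metric` and `region` in canonical order.
#' @export
qmri_slots <- function() {
  data.frame(
    metric = c("CSA", "CSA", "FA", "FA", "FA", "T2sWMGM", "T2sWMGM",
               "T2sWMGM", "MTR", "MTR"),
    region = c("rostral", "mcl", "rostral", "mcl", "caudal", "rostral",
               "mcl", "caudal", "rostral", "mcl"),
    stringsAsFactors = FALSE
  )
}

.slot_names <- function() {
  s <- qmri_slots()
  paste(s$metric, s$region, sep = "_")
}

#' Linear age-correction model for qMRI metrics
#'
#' Slopes from linear regression of each metric on age in 40 healthy
#' subjects: CSA -0.0867 mm^2/yr, FA -0.00121/yr, MTR -0.0815 %/yr,
#' T2*WI WM/GM +0.000740/yr.
#'
#' @param beta Named numeric of per-metric slopes (units per year of age).
#' @return `age_model` object.
#' @export
age_correction_model <- function(beta = c(CSA = -0.0867, FA = -0.00121,
                                          MTR = -0.0815, T2sWMGM = 0.000740)) {
  stopifnot(is.numeric(beta), !is.null(names(beta)))
  structure(list(beta = beta), class = "age_model")
}

#' Age-correct a metric value
#'
#' Removes the expected aging drift: `value - beta * (age - reference_age)`.
#' With `reference_age` set to the subject's baseline age the baseline value
#' is untouched and the follow-up correction subtracts exactly the expected
#' aging over the scan interval, so corrected visit differences are aging-free.
#'
#' @param value Raw metric value.
#' @param metric One of `"CSA"`, `"FA"`, `"MTR"`, `"T2sWMGM"`.
#' @param age_years Age at acquisition.
#' @param model [age_correction_model()].
#' @param reference_age Age at which no correction is applied.
#' @return Corrected value (same units).
#' @export
age_correct <- function(value, metric, age_years, model = age_correction_model(),
                        reference_age) {
  stopifnot(inherits(model, "age_model"))
  if (!metric %in% names(model$beta))
    stop("no age-correction slope configured for metric '", metric, "'",
         call. = FALSE)
  value - model$beta[[metric]] * (age_years - reference_age)
}

#' Region definition for slice aggregation
#'
#' @param mcl_level Vertebral level label of the maximally compressed level,
#'   e.g. `"C4-C5"`. When the MCL shifts between visits, pass the follow-up
#'   MCL for both visits' extraction.
#' @param rostral_levels,caudal_levels Level labels pooled into the rostral
#'   and caudal regions.
#' @return `region_spec` object.
#' @export
region_spec <- function(mcl_level = NULL,
                        rostral_levels = c("C1", "C1-C2", "C2", "C2-C3", "C3"),
                        caudal_levels = c("C6", "C6-C7", "C7")) {
  if (!is.null(mcl_level) && !mcl_level %in% .level_labels)
    stop("mcl_level '", mcl_level, "' is not a C1-C7 level label",
         call. = FALSE)
  structure(list(mcl_level = mcl_level, rostral_levels = rostral_levels,
                 caudal_levels = caudal_levels), class = "region_spec")
}

#' Build a per-slice metric panel
#'
#' One metric, one visit: values per axial slice with level labels and
#' exclusion flags.
#'
#' @param subject_id,visit Identifiers.
#' @param metric Metric name.
#' @param level Vertebral level label per slice.
#' @param slice_index Unique slice index per slice.
#' @param value Metric value per slice.
#' @param compressed Slice lies at a compressed level.
#' @param excluded_artifact Slice excluded for artifact.
#' @return `slice_panel` data.frame.
#' @export
slice_panel <- function(subject_id, visit, metric, level, slice_index, value,
                        compressed = FALSE, excluded_artifact = FALSE) {
  if (!metric %in% .qmri_metrics)
    stop("unknown metric '", metric, "'", call. = FALSE)
  n <- length(value)
  d <- data.frame(subject_id = as.character(subject_id), visit = visit,
                  metric = metric, level = level,
                  slice_index = as.integer(slice_index), value = value,
                  compressed = rep_len(compressed, n),
                  excluded_artifact = rep_len(excluded_artifact, n),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(d$slice_index))
    stop("slice indices must be unique within a panel", call. = FALSE)
  ok <- is.na(d$value) |
    switch(metric,
           CSA = d$value > 0,
           FA = d$value >= 0 & d$value <= 1,
           MTR = d$value >= 0 & d$value <= 100,
           T2sWMGM = d$value > 0)
  if (!all(ok))
    stop(metric, " values out of physical range in panel (subject ",
         subject_id, ")", call. = FALSE)
  class(d) <- c("slice_panel", "data.frame")
  d
}

#' Aggregate a slice panel over a region
#'
#' Rostral and caudal values are unweighted means over the region's slices
#' with compressed and artifact slices excluded. The MCL value is the single
#' MCL slice for CSA, or the mean of the MCL slice and its two nearest
#' neighbours in slice order for the other metrics; MCL slices are compressed
#' by definition, so the compression flag is not an exclusion there (artifact
#' slices are still dropped). A region with no eligible slice is missing
#' (`NA`), never zero.
#'
#' @param panel [slice_panel()].
#' @param region [region_spec()].
#' @param which `"rostral"`, `"caudal"` or `"mcl"`.
#' @return Numeric scalar or `NA_real_`.
#' @export
aggregate_region <- function(panel, region, which = c("rostral", "caudal", "mcl")) {
  which <- match.arg(which)
  stopifnot(inherits(region, "region_spec"))
  panel <- panel[order(panel$slice_index), , drop = FALSE]
  if (which %in% c("rostral", "caudal")) {
    lv <- if (which == "rostral") region$rostral_levels else region$caudal_levels
    keep <- panel$level %in% lv & !panel$compressed & !panel$excluded_artifact &
      !is.na(panel$value)
    if (!any(keep)) return(NA_real_)
    return(mean(panel$value[keep]))
  }
  if (is.null(region$mcl_level))
    stop("MCL aggregation requested but mcl_level is unset", call. = FALSE)
  at_mcl <- which(panel$level == region$mcl_level)
  if (!length(at_mcl)) return(NA_real_)
  centre <- at_mcl[ceiling(length(at_mcl) / 2)]
  idx <- if (panel$metric[1] == "CSA") centre else
    intersect(seq(centre - 1L, centre + 1L), seq_len(nrow(panel)))
  keep <- idx[!panel$excluded_artifact[idx] & !is.na(panel$value[idx])]
  if (!length(keep)) return(NA_real_)
  mean(panel$value[keep])
}

#' Build the 10-slot age-corrected region profile for one visit
#'
#' Applies [age_correct()] to every slice and [aggregate_region()] for each
#' of the 10 retained (metric, region) slots. Panels missing for a metric
#' (e.g. a T2*WI acquisition excluded for motion) yield missing slots.
#'
#' @param panels Named list of [slice_panel()]s keyed by metric name; missing
#'   or NULL entries give missing slots.
#' @param age_years Subject age at this visit.
#' @param reference_age Age at which no correction applies (conventionally
#'   the subject's baseline age).
#' @param model [age_correction_model()].
#' @param region [region_spec()] (use the follow-up MCL for both visits when
#'   the MCL shifted).
#' @return `qmri_profile`: named numeric of length 10 (NA = missing) with the
#'   subject/visit as attributes.
#' @export
build_profile <- function(panels, age_years, reference_age,
                          model = age_correction_model(), region) {
  slots <- qmri_slots()
  vals <- rep(NA_real_, nrow(slots))
  names(vals) <- .slot_names()
  for (i in seq_len(nrow(slots))) {
    m <- slots$metric[i]
    p <- panels[[m]]
    if (is.null(p)) next
    p$value <- age_correct(p$value, m, age_years, model, reference_age)
    vals[i] <- aggregate_region(p, region, slots$region[i])
  }
  nonnull <- which(!vapply(panels, is.null, TRUE))
  meta <- if (length(nonnull)) panels[[nonnull[1]]] else NULL
  structure(vals, class = "qmri_profile",
            subject_id = if (!is.null(meta)) meta$subject_id[1] else NA,
            visit = if (!is.null(meta)) meta$visit[1] else NA)
}
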