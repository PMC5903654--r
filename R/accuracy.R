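# Diagnostic accuracy and group statistics: Wilson continuity-corrected
# intervals for proportions, one-tailed paired t tests for group
# deterioration, sensitivity/specificity/Youden against the subjective case
# definition, and pairwise Fisher exact comparisons between monitoring
# methods.

#' Wilson continuity-corrected confidence interval for a proportion
#'
#' Closed-form score interval with continuity correction (Newcombe's
#' formulation). Bounds are clipped to \[0, 100\]%; k = 0 forces the lower
#' bound to 0 and k = n forces the upper bound to 100.
#'
#' @param k Successes.
#' @param n Trials (>= 1).
#' @param confidence Coverage, default 0.95.
#' @return List: `k`, `n`, `point`, `lower`, `upper` (percent),
#'   `confidence`.
#' @export
wilson_cc_interval <- function(k, n, confidence = 0.95) {
  stopifnot(length(k) == 1L, length(n) == 1L)
  if (n < 1) stop("interval undefined for n = 0", call. = FALSE)
  if (k < 0 || k > n) stop("k must lie in [0, n]", call. = FALSE)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  p <- k / n
  lower <- if (k == 0) 0 else
    (2 * n * p + z^2 - 1 -
       z * sqrt(z^2 - 2 - 1 / n + 4 * p * (n * (1 - p) + 1))) /
    (2 * (n + z^2))
  upper <- if (k == n) 1 else
    (2 * n * p + z^2 + 1 +
       z * sqrt(z^2 + 2 - 1 / n + 4 * p * (n * (1 - p) - 1))) /
    (2 * (n + z^2))
  list(k = k, n = n, point = 100 * p,
       lower = 100 * max(0, lower), upper = 100 * min(1, upper),
       confidence = confidence)
}

#' One-tailed paired t test for group deterioration
#'
#' Accepts either the per-subject differences (oriented so deterioration is
#' negative) or the summary triple (mean, sd, n), as printed group rows give
#' only the summary. `t = mean / (sd / sqrt(n))`; p is the lower Student-t
#' tail with n - 1 degrees of freedom.
#'
#' @param diffs Per-subject differences; or NULL when using the summary.
#' @param mean_diff,sd_diff,n Summary statistics (used when `diffs` is NULL).
#' @return List: `n`, `mean_diff`, `sd_diff`, `t_statistic`, `one_tailed_p`.
#' @export
paired_t_one_tailed <- function(diffs = NULL, mean_diff = NULL,
                                sd_diff = NULL, n = NULL) {
  if (!is.null(diffs)) {
    diffs <- diffs[!is.na(diffs)]
    n <- length(diffs)
    mean_diff <- mean(diffs)
    sd_diff <- stats::sd(diffs)
  }
  if (is.null(n) || n < 2) stop("need n >= 2", call. = FALSE)
  if (!is.finite(sd_diff) || sd_diff <= 0)
    stop("degenerate input: sd of differences must be > 0", call. = FALSE)
  t <- mean_diff / (sd_diff / sqrt(n))
  list(n = n, mean_diff = mean_diff, sd_diff = sd_diff, t_statistic = t,
       one_tailed_p = stats::pt(t, df = n - 1))
}

#' Sensitivity, specificity and Youden's index
#'
#' Percent scale. A quantity whose denominator is zero is returned as NA
#' (undefined), never as 0.
#'
#' @param tp,fp,tn,fn Confusion counts.
#' @return List: `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`,
#'   `youden` (all percent).
#' @export
accuracy <- function(tp, fp, tn, fn) {
  counts <- c(tp, fp, tn, fn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = sens, specificity = spec,
       youden = sens + spec - 100)
}

#' Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric test; the two-sided p sums every table (at fixed
#' margins) whose point probability does not exceed the observed one, and
#' the one-sided p is the lower tail of the (1,1) cell.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @param sided `"two"` or `"one"`.
#' @return p-value.
#' @export
fisher_exact_2x2 <- function(tab, sided = c("two", "one")) {
  sided <- match.arg(sided)
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0),
            all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("Fisher test undefined: empty margin", call. = FALSE)
  alt <- if (sided == "two") "two.sided"
  else if (tab[1, 1] * tab[2, 2] >= tab[1, 2] * tab[2, 1]) "greater"
  else "less"  # one-sided: tail in the observed direction
  stats::fisher.test(tab, alternative = alt)$p.value
}

#' Confusion table of one monitoring modality against the case definition
#'
#' Positives are events the patient rated subjectively "worse" (the clinical
#' case definition); "maybe worse" counts as negative. A modality's table is
#' built over its available events only: events with a missing category are
#' dropped, not imputed. For mJOA, an explicit detected-count override is
#' supported because the source cohort's narrative count of mJOA-detected
#' worsened events (3) differs from the per-row table (4); the narrative
#' count is the default for accuracy arithmetic.
#'
#' @param events Event data.frame (see [reference_events()]).
#' @param modality `"mjoa"`, `"clinical"`, `"mri"` or `"qmri"`.
#' @param mjoa_detected Optional integer override of mJOA true positives;
#'   `NULL` uses the per-row categories.
#' @return List: confusion counts plus `n_events`.
#' @export
modality_confusion <- function(events,
                               modality = c("mjoa", "clinical", "mri", "qmri"),
                               mjoa_detected = if (modality == "mjoa") 3L else NULL) {
  modality <- match.arg(modality)
  col <- paste0(modality, "_cat")
  cat <- events[[col]]
  keep <- !is.na(cat) & !is.na(events$subjective)
  cat <- cat[keep]
  pos <- events$subjective[keep] == "worse"
  det <- cat == "declined"
  tp <- sum(det & pos); fn <- sum(!det & pos)
  fp <- sum(det & !pos); tn <- sum(!det & !pos)
  if (!is.null(mjoa_detected)) {
    if (modality != "mjoa")
      stop("detected-count override applies to mJOA only", call. = FALSE)
    mjoa_detected <- as.integer(mjoa_detected)
    stopifnot(mjoa_detected >= 0, mjoa_detected <= tp + fn)
    tp <- mjoa_detected
    fn <- sum(pos) - tp
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn, n_events = sum(keep))
}

#' Pairwise Fisher comparison of two monitoring methods
#'
#' Builds the detected/missed (sensitivity: among subjectively worse events;
#' specificity: stable-called/declined-called among subjectively non-worse
#' events) or agree/disagree (concordance with the case definition) 2x2 over
#' each modality's own available events — denominators legitimately differ
#' between modalities — and applies the Fisher exact test.
#'
#' @param events Event data.frame.
#' @param measure_a,measure_b Modalities as in [modality_confusion()].
#' @param aspect `"sensitivity"`, `"specificity"` or `"concordance"`.
#' @param sided Passed to [fisher_exact_2x2()].
#' @param ... Passed to [modality_confusion()] (e.g. `mjoa_detected`).
#' @return List: `p`, `table`, `aspect`.
#' @export
compare_measures <- function(events, measure_a, measure_b,
                             aspect = c("sensitivity", "specificity",
                                        "concordance"),
                             sided = "two", ...) {
  aspect <- match.arg(aspect)
  pair <- function(m) {
    cf <- modality_confusion(events, m, ...)
    switch(aspect,
           sensitivity = c(cf$tp, cf$fn),
           specificity = c(cf$tn, cf$fp),
           concordance = c(cf$tp + cf$tn, cf$fp + cf$fn))
  }
  tab <- rbind(pair(measure_a), pair(measure_b))
  dimnames(tab) <- list(c(measure_a, measure_b), c("hit", "miss"))
  if (sum(tab[1, ]) == 0 || sum(tab[2, ]) == 0)
    stop("no applicable events for one of the measures", call. = FALSE)
  # a zero column margin (e.g. a measure against itself with perfect hits)
  # admits a single table at fixed margins: no evidence of a difference
  p <- if (any(colSums(tab) == 0)) 1 else fisher_exact_2x2(tab, sided)
  list(p = p, table = tab, aspect = aspect)
}

#' Accuracy report over all monitoring modalities
#'
#' Per-modality subject-level progression rates (latest events, Wilson CC
#' intervals) and event-level diagnostic accuracy against the subjective
#' case definition.
#'
#' @param events Event data.frame.
#' @param mjoa_detected mJOA detected-count override (see
#'   [modality_confusion()]).
#' @return data.frame, one row per modality: `rate_k`, `rate_n`, `rate`,
#'   `rate_lower`, `rate_upper`, `sensitivity`, `specificity`, `youden`,
#'   `n_events`.
#' @export
accuracy_report <- function(events, mjoa_detected = 3L) {
  latest <- latest_events(events)
  rows <- lapply(c("mjoa", "clinical", "mri", "qmri"), function(m) {
    col <- paste0(m, "_cat")
    avail <- !is.na(latest[[col]])
    k <- sum(latest[[col]][avail] == "declined")
    n <- sum(avail)
    ci <- wilson_cc_interval(k, n)
    cf <- modality_confusion(events, m,
                             mjoa_detected = if (m == "mjoa") mjoa_detected)
    acc <- accuracy(cf$tp, cf$fp, cf$tn, cf$fn)
    data.frame(modality = m, rate_k = k, rate_n = n, rate = ci$point,
               rate_lower = ci$lower, rate_upper = ci$upper,
               sensitivity = acc$sensitivity, specificity = acc$specificity,
               youden = acc$youden, n_events = cf$n_events,
               stringsAsFactors = FALSE)
  })
  subj <- latest$subjective
  k <- sum(subj == "worse", na.rm = TRUE)
  n <- sum(!is.na(subj))
  ci <- wilson_cc_interval(k, n)
  out <- rbind(
    data.frame(modality = "subjective", rate_k = k, rate_n = n,
               rate = ci$point, rate_lower = ci$lower, rate_upper = ci$upper,
               sensitivity = NA_real_, specificity = NA_real_,
               youden = NA_real_, n_events = n, stringsAsFactors = FALSE),
    do.call(rbind, rows))
  rownames(out) <- NULL
  out
}
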