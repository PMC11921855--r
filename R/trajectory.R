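#' Trajectory labels in reporting order
#' @return `c("chronic", "delayed", "recovery", "resistance")`.
#' @export
trajectory_labels <- function() c("chronic", "delayed", "recovery", "resistance")

#' Total PHQ-9 score per subject at a wave
#'
#' @param panel A [symptom_panel()].
#' @param wave `"t1"` or `"t2"`.
#' @param subject Optional subject identifier(s); defaults to all subjects.
#' @return Integer vector of item-sum totals (0-27 for 9 items).
#' @export
phq_total <- function(panel, wave = c("t1", "t2"), subject = NULL) {
  stopifnot(inherits(panel, "symptom_panel"))
  wave <- match.arg(wave)
  totals <- rowSums(panel[[wave]])
  names(totals) <- panel$subject_id
  if (!is.null(subject)) {
    pos <- match(subject, panel$subject_id)
    if (anyNA(pos)) stop("unknown subject: ",
                         paste(subject[is.na(pos)], collapse = ", "),
                         call. = FALSE)
    totals <- totals[pos]
  }
  as.integer(totals)
}

#' Classify a depressive-symptom trajectory from two total scores
#'
#' A subject is counted as having probable depressive symptoms at a wave when
#' the total score is at or above the cutoff (default 7: "7 or more" is
#' depressed, so a score of exactly 7 is above threshold). The 2x2
#' depressed-at-T1 x depressed-at-T2 pattern maps to four trajectories:
#' both waves = chronic, T2 only = delayed, T1 only = recovery,
#' neither = resistance.
#'
#' @param t1_total,t2_total Integer totals in 0-27 (vectorized).
#' @param cutoff Dichotomization threshold, in 1-27; default 7.
#' @return Factor with levels [trajectory_labels()].
#' @export
classify_trajectory <- function(t1_total, t2_total, cutoff = 7) {
  if (length(cutoff) != 1 || !is.finite(cutoff) || cutoff < 1 || cutoff > 27)
    stop("cutoff must be a single value in [1, 27]", call. = FALSE)
  stopifnot(all(t1_total >= 0 & t1_total <= 27),
            all(t2_total >= 0 & t2_total <= 27))
  d1 <- t1_total >= cutoff
  d2 <- t2_total >= cutoff
  lab <- ifelse(d1 & d2, "chronic",
         ifelse(!d1 & d2, "delayed",
         ifelse(d1 & !d2, "recovery", "resistance")))
  factor(lab, levels = trajectory_labels())
}

# Round half up to `digits` decimals (round() rounds half to even).
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  floor(x * f + 0.5) / f
}

#' Percentage of a count out of a total, reported to one decimal
#'
#' The reporting convention used for all cohort-composition figures:
#' `100 * count / total`, rounded half-up to one decimal place.
#'
#' @param count,total Non-negative numbers, `total > 0`.
#' @return Percentage rounded to one decimal.
#' @export
percent_of <- function(count, total) {
  stopifnot(total > 0)
  round_half_up(100 * count / total, 1)
}

#' Stratify a cohort into the four depressive trajectories
#'
#' Scores both waves, dichotomizes at the cutoff, labels every subject with
#' exactly one trajectory, and summarizes cohort composition.
#'
#' @param panel A [symptom_panel()].
#' @param cutoff Dichotomization threshold (default 7).
#' @return An object of class `cohort_stratification`: list with
#'   `assignments` (data frame: subject_id, t1_total, t2_total, depressed_t1,
#'   depressed_t2, label), `counts` and `percentages` (named by trajectory,
#'   percentages rounded to one decimal), `proportions` (unrounded),
#'   `total_n`, `cutoff`.
#' @export
stratify_cohort <- function(panel, cutoff = 7) {
  stopifnot(inherits(panel, "symptom_panel"))
  if (n_subjects(panel) == 0) stop("empty panel", call. = FALSE)
  t1 <- phq_total(panel, "t1")
  t2 <- phq_total(panel, "t2")
  label <- classify_trajectory(t1, t2, cutoff)
  assignments <- data.frame(
    subject_id = panel$subject_id,
    t1_total = t1, t2_total = t2,
    depressed_t1 = t1 >= cutoff, depressed_t2 = t2 >= cutoff,
    label = label)
  counts <- table(label)
  counts <- stats::setNames(as.integer(counts), names(counts))
  total_n <- n_subjects(panel)
  structure(
    list(assignments = assignments,
         counts = counts,
         proportions = counts / total_n,
         percentages = percent_of(counts, total_n),
         total_n = total_n,
         cutoff = cutoff),
    class = "cohort_stratification")
}

#' @export
print.cohort_stratification <- function(x, ...) {
  cat(sprintf("Cohort stratification (n = %d, cutoff >= %s):\n",
              x$total_n, format(x$cutoff)))
  tab <- data.frame(trajectory = names(x$counts), n = x$counts,
                    percent = sprintf("%.1f", x$percentages),
                    row.names = NULL)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Split a panel by trajectory group
#'
#' @param panel A [symptom_panel()].
#' @param stratification Optional result of [stratify_cohort()]; computed from
#'   `panel` if omitted.
#' @param cutoff Used when `stratification` is omitted.
#' @return Named list of `symptom_panel` objects, one per non-empty
#'   trajectory, in the fixed reporting order.
#' @export
split_by_trajectory <- function(panel, stratification = NULL, cutoff = 7) {
  if (is.null(stratification)) stratification <- stratify_cohort(panel, cutoff)
  lab <- stratification$assignments$label
  out <- list()
  for (g in trajectory_labels()) {
    keep <- which(lab == g)
    if (!length(keep)) next
    out[[g]] <- symptom_panel(
      panel$t1[keep, , drop = FALSE], panel$t2[keep, , drop = FALSE],
      covariates = if (!is.null(panel$covariates))
        panel$covariates[keep, , drop = FALSE] else NULL,
      subject_id = panel$subject_id[keep],
      item_labels = panel$item_labels)
  }
  out
}
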