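#' Cumulative frequency curves for patients and controls
#'
#' For every integer score `s` in 0-30, `sens_by_score(s)` is the cumulative
#' fraction of patients scoring at or below `s`, and `spec_by_score(s)` is the
#' complementary cumulative fraction of controls — the fraction scoring above
#' `s`. Reading the two curves at one score gives the sensitivity and
#' specificity of the cut-off `s/(s+1)`, so these curves agree with
#' [roc_curve()] at identical thresholds; they are kept as their own object
#' because the dual-cut-off procedure reads the two curves at *different*
#' scores.
#'
#' @param patient_scores integer scores of the patient group.
#' @param control_scores integer scores of the control group.
#' @return object of class `cumulative_curves`: data.frame with columns
#'   `score` (0-30), `sens_by_score`, `spec_by_score`.
#' @export
cumulative_curves <- function(patient_scores, control_scores) {
  if (length(patient_scores) == 0 || length(control_scores) == 0) {
    stop("empty group", call. = FALSE)
  }
  s <- seq(0L, SCORE_MAX)
  structure(
    data.frame(
      score = s,
      sens_by_score = vapply(s, function(x) mean(patient_scores <= x),
                             numeric(1)),
      spec_by_score = vapply(s, function(x) mean(control_scores > x),
                             numeric(1))
    ),
    class = c("cumulative_curves", "data.frame")
  )
}

#' Two cut-offs separated by an indecisive area
#'
#' Instead of forcing one threshold to trade sensitivity against specificity,
#' the procedure fixes two: a *not-healthy* cut-off `lower_t` — the largest
#' score at which specificity still meets its target, so scores `<= lower_t`
#' are rare among healthy controls — and a *not-pathological* cut-off
#' `upper_t` — the smallest score at which sensitivity meets its target, so
#' scores `> upper_t` are rare among patients. Scores in between
#' (`lower_t + 1 .. upper_t`) form the indecisive area where classification
#' is deferred to further examination.
#'
#' The default selection rule is the strict one stated above (achieved value
#' `>=` target on each side). Because published analyses sometimes accept the
#' score *closest* to an approximate target instead, `rule = "nearest"` picks
#' the score whose achieved value minimises the absolute distance to the
#' target (ties toward the stricter side).
#'
#' When the groups separate so well that `lower_t > upper_t`, the indecisive
#' set is empty and every score is decided; [classify_score()] then gives
#' precedence to *not pathological* for scores above `upper_t`.
#'
#' @param curves a [cumulative_curves()].
#' @param target_sens,target_spec targets in (0, 1); default 0.90 each.
#' @param rule `"strict"` (achieved >= target) or `"nearest"`.
#' @return object of class `dual_cutoff_result`: list with `lower_t`,
#'   `upper_t`, `target_sens`, `target_spec`, `achieved_sens`,
#'   `achieved_spec`, `indecisive_scores`, `rule`.
#' @export
find_dual_cutoffs <- function(curves, target_sens = 0.90, target_spec = 0.90,
                              rule = c("strict", "nearest")) {
  stopifnot(inherits(curves, "cumulative_curves"),
            target_sens > 0, target_sens < 1,
            target_spec > 0, target_spec < 1)
  rule <- match.arg(rule)
  s <- curves$score
  if (rule == "strict") {
    ok_spec <- which(curves$spec_by_score >= target_spec)
    if (length(ok_spec) == 0) {
      stop("target specificity ", target_spec,
           " unattainable on the control curve", call. = FALSE)
    }
    lower_t <- s[max(ok_spec)]
    ok_sens <- which(curves$sens_by_score >= target_sens)
    if (length(ok_sens) == 0) {
      stop("target sensitivity ", target_sens,
           " unattainable on the patient curve", call. = FALSE)
    }
    upper_t <- s[min(ok_sens)]
  } else {
    # nearest achieved value; ties toward the stricter side (lower score for
    # specificity, higher score for sensitivity)
    dspec <- abs(curves$spec_by_score - target_spec)
    lower_t <- s[which.min(dspec)]
    dsens <- abs(curves$sens_by_score - target_sens)
    upper_t <- s[length(s) + 1 - which.min(rev(dsens))]
  }
  structure(list(
    lower_t = lower_t, upper_t = upper_t,
    target_sens = target_sens, target_spec = target_spec,
    achieved_sens = curves$sens_by_score[s == upper_t],
    achieved_spec = curves$spec_by_score[s == lower_t],
    indecisive_scores = if (lower_t < upper_t) {
      seq(lower_t + 1L, upper_t)
    } else integer(0),
    rule = rule
  ), class = "dual_cutoff_result")
}

#' @export
print.dual_cutoff_result <- function(x, ...) {
  cat(sprintf("dual cut-offs: not healthy <= %d (%s; spec %s), ",
              x$lower_t, cutoff_label(x$lower_t),
              format_percent(x$achieved_spec)))
  cat(sprintf("not pathological > %d (%s; sens %s)\n",
              x$upper_t, cutoff_label(x$upper_t),
              format_percent(x$achieved_sens)))
  if (length(x$indecisive_scores)) {
    cat("  indecisive scores:", paste(range(x$indecisive_scores),
                                      collapse = "-"), "\n")
  } else {
    cat("  indecisive area empty (groups fully separated)\n")
  }
  invisible(x)
}

#' Classify a score into the three decision zones
#'
#' `not_healthy` for scores at or below the lower cut-off, `not_pathological`
#' for scores above the upper cut-off, `indecisive` in between. The zones
#' partition 0-30 for every valid result; when the cut-offs cross (empty
#' indecisive set), *not pathological* takes precedence above `upper_t`.
#' Vectorised over `score`.
#'
#' @param score integer score(s) in 0-30.
#' @param result a [find_dual_cutoffs()] result.
#' @return factor with levels `not_healthy`, `indecisive`, `not_pathological`.
#' @export
classify_score <- function(score, result) {
  stopifnot(inherits(result, "dual_cutoff_result"))
  if (any(score < 0 | score > SCORE_MAX)) {
    stop("score outside [0,", SCORE_MAX, "]", call. = FALSE)
  }
  zone <- ifelse(score > result$upper_t, "not_pathological",
                 ifelse(score <= result$lower_t, "not_healthy", "indecisive"))
  factor(zone, levels = c("not_healthy", "indecisive", "not_pathological"))
}

#' Per-group counts of the three decision zones
#'
#' @param ds a [study_cohort()].
#' @param result a [find_dual_cutoffs()] result.
#' @param score_field score column used for classification.
#' @return data.frame: one row per group present in the factor levels, columns
#'   `group`, `not_healthy`, `indecisive`, `not_pathological`, `n`; rows sum
#'   to the group sizes.
#' @export
zone_summary <- function(ds, result,
                         score_field = c("moca_adj", "moca_raw", "mmse")) {
  score_field <- match.arg(score_field)
  stopifnot(inherits(ds, "study_cohort"))
  zones <- classify_score(ds[[score_field]], result)
  tab <- table(factor(ds$group, levels = GROUP_LEVELS), zones)
  out <- as.data.frame.matrix(tab)
  out <- cbind(group = rownames(out), out, n = rowSums(out),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
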