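#' Confusion-table metrics at one integer threshold
#'
#' A threshold `t` (reported with the label `"t/(t+1)"`) classifies scores
#' `<= t` as positive. Derived measures follow the screening-literature
#' definitions: `ccr = (sensitivity + specificity)/2` (the correct
#' classification rate for balanced group weighting) and Youden's
#' `J = sensitivity + specificity - 1`, so `ccr = (J + 1)/2` identically.
#' Proportions are kept at full precision; rounding happens only at display
#' time (see [format_percent()]).
#'
#' @param pos_scores scores of the positive (impaired) class.
#' @param neg_scores scores of the negative class.
#' @param t integer threshold.
#' @param ci_level if non-`NULL`, attach Clopper-Pearson intervals for
#'   sensitivity and specificity at this level.
#' @return one-row data.frame of class `threshold_metrics`: `threshold`,
#'   `label`, `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`, `ccr`,
#'   `youden_j` (and CI columns when requested).
#' @examples
#' evaluate_cutoff(c(20, 25), c(27, 28), 23)
#' @export
evaluate_cutoff <- function(pos_scores, neg_scores, t, ci_level = NULL) {
  check_two_class(pos_scores, neg_scores)
  tp <- sum(pos_scores <= t)
  fn <- sum(pos_scores > t)
  tn <- sum(neg_scores > t)
  fp <- sum(neg_scores <= t)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  out <- data.frame(
    threshold = t, label = cutoff_label(t),
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = sens, specificity = spec,
    ccr = (sens + spec) / 2, youden_j = sens + spec - 1,
    stringsAsFactors = FALSE
  )
  if (!is.null(ci_level)) {
    cs <- clopper_pearson(tp, tp + fn, ci_level)
    cp <- clopper_pearson(tn, tn + fp, ci_level)
    out$sens_lower <- cs$lower
    out$sens_upper <- cs$upper
    out$spec_lower <- cp$lower
    out$spec_upper <- cp$upper
  }
  class(out) <- c("threshold_metrics", "data.frame")
  out
}

# "t/(t+1)" cut-off label, e.g. threshold 23 -> "23/24"; continuous
# thresholds (z-scores) are labelled "<= t" instead
cutoff_label <- function(t) {
  if (all(t == floor(t))) sprintf("%d/%d", as.integer(t), as.integer(t) + 1L)
  else sprintf("<= %.2f", t)
}

#' Metrics at every threshold of the grid
#'
#' One row per grid threshold, ascending; for bounded 0-30 integer scores the
#' grid is `-1..30` (32 rows), so the sensitivity column runs from 0 to 1 and
#' the specificity column from 1 to 0.
#'
#' @inheritParams evaluate_cutoff
#' @param grid optional explicit integer threshold grid.
#' @return data.frame of stacked [evaluate_cutoff()] rows.
#' @export
metrics_at_all_thresholds <- function(pos_scores, neg_scores, grid = NULL,
                                      ci_level = NULL) {
  check_two_class(pos_scores, neg_scores)
  if (is.null(grid)) grid <- seq(-1L, SCORE_MAX)
  rows <- lapply(grid, function(t) {
    evaluate_cutoff(pos_scores, neg_scores, t, ci_level = ci_level)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("threshold_metrics", "data.frame")
  out
}

#' Balanced cut-off: sensitivity and specificity as equal as possible
#'
#' Picks the grid threshold minimising `|sensitivity - specificity|`; ties go
#' to the lower threshold (the higher-specificity side), reflecting the
#' screening priority of avoiding false positives.
#'
#' @param metrics a data.frame from [metrics_at_all_thresholds()].
#' @return object of class `cutoff_choice`: list with `strategy`, `threshold`,
#'   `label`, `metrics` (the selected row), `strategy_params`.
#' @export
balanced_cutoff <- function(metrics) {
  stopifnot(nrow(metrics) > 0)
  gap <- abs(metrics$sensitivity - metrics$specificity)
  i <- which.min(gap)  # which.min takes the first (lowest threshold) on ties
  cutoff_choice("balanced", metrics[i, , drop = FALSE])
}

#' Youden-index cut-off
#'
#' Picks the grid threshold maximising `J = sensitivity + specificity - 1`;
#' ties go to the lower threshold (higher specificity).
#'
#' @inheritParams balanced_cutoff
#' @return a `cutoff_choice`.
#' @export
youden_cutoff <- function(metrics) {
  stopifnot(nrow(metrics) > 0)
  i <- which.max(metrics$youden_j)
  cutoff_choice("youden", metrics[i, , drop = FALSE])
}

#' Fixed (pre-specified) cut-off
#'
#' Wraps a literature cut-off — for the MoCA the originally proposed 25/26 —
#' as a `cutoff_choice` so all strategies share one result shape.
#'
#' @inheritParams balanced_cutoff
#' @param t the fixed integer threshold.
#' @return a `cutoff_choice`.
#' @export
fixed_cutoff <- function(metrics, t = 25L) {
  i <- which(metrics$threshold == t)
  if (length(i) != 1) stop("threshold ", t, " not on the metric grid")
  cutoff_choice("fixed", metrics[i, , drop = FALSE], list(t = t))
}

#' Percentile-in-controls cut-off
#'
#' Derives a cut-off from the control group alone: the score splitting the
#' controls at the lower `q`-quantile is taken as the boundary of normality,
#' targeting specificity of about `1 - q`. The empirical quantile uses the
#' linear-interpolation convention (`stats::quantile` type 7); for discrete
#' scores the threshold is its floor, so scores at or below the threshold
#' fall below the percentile and are called pathological.
#'
#' @param neg_scores control-group scores (non-empty).
#' @param q lower tail probability in (0, 1); default 0.10.
#' @param discrete floor the quantile to an integer threshold (`TRUE`, for
#'   0-30 scores) or return it as-is (`FALSE`, for continuous z-scores).
#' @return a `cutoff_choice` with `strategy_params = list(q = q, quantile =
#'   <raw quantile>)`; `metrics` is `NULL` until evaluated against a patient
#'   group (see [evaluate_cutoff()]).
#' @examples
#' percentile_cutoff(20:29, q = 0.10)  # quantile 20.9 -> threshold 20
#' @export
percentile_cutoff <- function(neg_scores, q = 0.10, discrete = TRUE) {
  if (length(neg_scores) == 0) stop("empty controls", call. = FALSE)
  stopifnot(q > 0, q < 1)
  qq <- quantile(neg_scores, q, names = FALSE, type = 7)
  t <- if (discrete) floor(qq) else qq
  structure(list(strategy = "percentile",
                 threshold = if (discrete) as.integer(t) else t,
                 label = if (discrete) cutoff_label(as.integer(t)) else
                   sprintf("<= %.2f", t),
                 metrics = NULL,
                 strategy_params = list(q = q, quantile = qq)),
            class = "cutoff_choice")
}

cutoff_choice <- function(strategy, row, params = list()) {
  structure(list(strategy = strategy, threshold = row$threshold,
                 label = row$label, metrics = row, strategy_params = params),
            class = "cutoff_choice")
}

#' @export
print.cutoff_choice <- function(x, ...) {
  cat(sprintf("cutoff_choice [%s]: %s", x$strategy, x$label))
  if (!is.null(x$metrics)) {
    cat(sprintf("  sens %s, spec %s, CCR %s",
                format_percent(x$metrics$sensitivity),
                format_percent(x$metrics$specificity),
                format_percent(x$metrics$ccr)))
  }
  cat("\n")
  invisible(x)
}

#' Positive and negative predictive values at a given prevalence
#'
#' Bayes' rule on sensitivity/specificity: `ppv = sens * prev / (sens * prev
#' + (1 - spec) * (1 - prev))` and `npv = spec * (1 - prev) / (spec *
#' (1 - prev) + (1 - sens) * prev)`. The 0/0 corners are fixed by convention
#' for stable reports: at prevalence 0 the PPV is 0 (no positives exist) and
#' at prevalence 1 the NPV is 0. Vectorised over `prevalence`.
#'
#' @param sensitivity,specificity proportions in `[0, 1]`.
#' @param prevalence proportion(s) in `[0, 1]`.
#' @return data.frame with columns `prevalence`, `ppv`, `npv`.
#' @export
ppv_npv <- function(sensitivity, specificity, prevalence) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1,
            all(prevalence >= 0), all(prevalence <= 1))
  num_p <- sensitivity * prevalence
  den_p <- num_p + (1 - specificity) * (1 - prevalence)
  ppv <- ifelse(den_p == 0, 0, num_p / den_p)
  num_n <- specificity * (1 - prevalence)
  den_n <- num_n + (1 - sensitivity) * prevalence
  npv <- ifelse(den_n == 0, 0, num_n / den_n)
  # conventions for the degenerate prevalences
  ppv[prevalence == 0] <- 0
  npv[prevalence == 0] <- 1
  ppv[prevalence == 1] <- 1
  npv[prevalence == 1] <- 0
  data.frame(prevalence = prevalence, ppv = ppv, npv = npv)
}

#' Prevalence of disease in a clinic sample
#'
#' @param n_patients number of diseased subjects.
#' @param n_controls_in_clinic number of clinic subjects without the disease.
#' @return proportion `n_patients / (n_patients + n_controls_in_clinic)`.
#' @examples
#' prevalence(447, 49)  # 0.9012
#' @export
prevalence <- function(n_patients, n_controls_in_clinic) {
  total <- n_patients + n_controls_in_clinic
  if (total <= 0) stop("total must be positive", call. = FALSE)
  n_patients / total
}

#' Display rounding for report tables
#'
#' Proportions are reported as integer percentages, rounded half away from
#' zero — e.g. a CCR of 0.785 prints as `"79%"` — matching the convention of
#' published screening-accuracy tables. Full precision is retained in all
#' computation; this is display-only.
#'
#' @param p proportion(s) in `[0, 1]`.
#' @param digits decimal places of the percentage (default 0).
#' @return character vector like `"79%"`.
#' @export
format_percent <- function(p, digits = 0) {
  # snap to 9 decimals first so float noise (0.94 + 0.63 gives 1.5699...98)
  # cannot pull an exact half below the rounding boundary
  scaled <- round(p * 100 * 10^digits, 9)
  rounded <- round_half_away(scaled) / 10^digits
  paste0(formatC(rounded, format = "f", digits = digits), "%")
}
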