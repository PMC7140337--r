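#' One-call accuracy analysis of a cohort
#'
#' Orchestrates the pipeline for one score field and one patient/control
#' contrast: per-threshold metrics, the requested single-cut-off strategies,
#' AUC with a percentile-bootstrap CI, and the dual-cut-off procedure. The
#' headline contrast of the memory-clinic design evaluates cut-offs against
#' the clinic patients with normal findings (`NF`) — the group a screen must
#' separate from patients in practice — while the dual cut-offs are defined
#' against the community normal controls (`NC`) and the mild patients.
#'
#' @param ds a [study_cohort()].
#' @param score_field score column to analyse (education-adjusted MoCA by
#'   default).
#' @param patient_groups groups forming the positive class.
#' @param control_group single group forming the negative class.
#' @param strategies subset of `c("fixed", "balanced", "youden",
#'   "percentile")`.
#' @param fixed_t threshold for the `fixed` strategy (25, i.e. the original
#'   25/26 MoCA cut-off).
#' @param percentile_q lower-tail probability for the `percentile` strategy;
#'   the percentile is always computed in the `NC` group per that strategy's
#'   definition.
#' @param dual_targets `c(sensitivity, specificity)` targets for
#'   [find_dual_cutoffs()]; the dual analysis contrasts `dual_patient_group`
#'   vs `dual_control_group`.
#' @param dual_patient_group,dual_control_group groups for the dual-cut-off
#'   curves (defaults `MILD` vs `NC`).
#' @param ci_level confidence level for all intervals.
#' @param n_boot bootstrap replicates for the AUC interval.
#' @param seed integer seed for all resampling.
#' @return object of class `accuracy_report`: list with `metrics` (full
#'   per-threshold table with Clopper-Pearson CIs), `summary` (one row per
#'   strategy: label, sensitivity, specificity, CCR and their display
#'   rounding), `auc` (an [interval_estimate()]), `dual` (a
#'   [find_dual_cutoffs()] result or `NULL` when the dual groups are absent),
#'   `config` (the echoed settings).
#' @export
run_analysis <- function(ds,
                         score_field = c("moca_adj", "moca_raw", "moca_z",
                                         "mmse"),
                         patient_groups = c("MILD", "MAJOR"),
                         control_group = "NF",
                         strategies = c("fixed", "balanced", "youden",
                                        "percentile"),
                         fixed_t = 25L,
                         percentile_q = 0.10,
                         dual_targets = c(sens = 0.90, spec = 0.90),
                         dual_patient_group = "MILD",
                         dual_control_group = "NC",
                         ci_level = 0.95,
                         n_boot = 2000,
                         seed = 1L) {
  score_field <- match.arg(score_field)
  strategies <- match.arg(strategies, several.ok = TRUE)
  patient_groups <- toupper(patient_groups)
  control_group <- toupper(control_group)
  if (length(intersect(patient_groups, control_group)) > 0) {
    stop("patient and control groups must be disjoint", call. = FALSE)
  }
  pos <- group_scores(ds, patient_groups, score_field)
  neg <- group_scores(ds, control_group, score_field)
  check_two_class(pos, neg)

  discrete <- score_field != "moca_z"
  grid <- if (discrete) seq(-1L, SCORE_MAX) else {
    u <- sort(unique(c(pos, neg)))
    c(u[1] - 1, u)
  }
  metrics <- metrics_at_all_thresholds(pos, neg, grid = grid,
                                       ci_level = ci_level)

  choices <- list()
  for (st in strategies) {
    choices[[st]] <- switch(
      st,
      fixed = fixed_cutoff(metrics, fixed_t),
      balanced = balanced_cutoff(metrics),
      youden = youden_cutoff(metrics),
      percentile = {
        pc <- percentile_cutoff(group_scores(ds, "NC", score_field),
                                q = percentile_q, discrete = discrete)
        # validate the NC-derived threshold in the clinic contrast
        row <- evaluate_cutoff(pos, neg, pc$threshold, ci_level = ci_level)
        pc$metrics <- row
        pc
      }
    )
  }

  summary_df <- do.call(rbind, lapply(names(choices), function(st) {
    ch <- choices[[st]]
    m <- ch$metrics
    data.frame(strategy = st, cutoff = ch$label, threshold = ch$threshold,
               sensitivity = m$sensitivity, specificity = m$specificity,
               ccr = m$ccr,
               sens_ci = sprintf("%s-%s", format_percent(m$sens_lower),
                                 format_percent(m$sens_upper)),
               spec_ci = sprintf("%s-%s", format_percent(m$spec_lower),
                                 format_percent(m$spec_upper)),
               display = sprintf("CCR %s, sens %s, spec %s",
                                 format_percent(m$ccr),
                                 format_percent(m$sensitivity),
                                 format_percent(m$specificity)),
               stringsAsFactors = FALSE)
  }))

  dual <- NULL
  dp <- toupper(dual_patient_group)
  dc <- toupper(dual_control_group)
  if (discrete && all(c(dp, dc) %in% ds$group)) {
    curves <- cumulative_curves(group_scores(ds, dp, score_field),
                                group_scores(ds, dc, score_field))
    dual <- find_dual_cutoffs(curves, target_sens = dual_targets[[1]],
                              target_spec = dual_targets[[2]])
  }

  structure(list(
    metrics = metrics,
    summary = summary_df,
    auc = auc_ci(pos, neg, n_boot = n_boot, level = ci_level, seed = seed),
    dual = dual,
    config = list(score_field = score_field,
                  patient_groups = patient_groups,
                  control_group = control_group,
                  dual_patient_group = dp, dual_control_group = dc,
                  fixed_t = fixed_t, percentile_q = percentile_q,
                  dual_targets = dual_targets, ci_level = ci_level,
                  n_boot = n_boot, seed = seed,
                  provenance = attr(ds, "provenance"))
  ), class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("accuracy_report: %s, %s vs %s\n", cfg$score_field,
              paste(cfg$patient_groups, collapse = "+"), cfg$control_group))
  cat(sprintf("  AUC %.3f (%.0f%% CI %.3f-%.3f)\n", x$auc$point,
              cfg$ci_level * 100, x$auc$lower, x$auc$upper))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  %-10s %-8s %s\n", x$summary$strategy[i],
                x$summary$cutoff[i], x$summary$display[i]))
  }
  if (!is.null(x$dual)) print(x$dual)
  invisible(x)
}

#' Write the report bundle to disk
#'
#' Emits deterministic, machine-readable files: `metrics.tsv` (full
#' per-threshold table), `summary.tsv` (one row per strategy), `curves.tsv`
#' (score, sensitivity, specificity for the dual-cut-off plot), and
#' `dual_cutoffs.json`. Identical report objects produce byte-identical
#' files.
#'
#' @param report an [run_analysis()] result.
#' @param dir output directory (created if missing).
#' @param ds the cohort, needed to re-derive the dual-cut-off curves; omit to
#'   skip `curves.tsv`.
#' @return character vector of the files written, invisibly.
#' @export
write_report <- function(report, dir, ds = NULL) {
  stopifnot(inherits(report, "accuracy_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  tsv <- function(df, name) {
    path <- file.path(dir, name)
    write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    path
  }
  written <- c(written, tsv(as.data.frame(report$metrics), "metrics.tsv"))
  written <- c(written, tsv(report$summary, "summary.tsv"))
  if (!is.null(report$dual)) {
    path <- file.path(dir, "dual_cutoffs.json")
    jsonlite::write_json(
      report$dual[c("lower_t", "upper_t", "target_sens", "target_spec",
                    "achieved_sens", "achieved_spec", "indecisive_scores",
                    "rule")],
      path, auto_unbox = TRUE, digits = NA)
    written <- c(written, path)
    if (!is.null(ds)) {
      cfg <- report$config
      curves <- cumulative_curves(
        group_scores(ds, cfg$dual_patient_group, cfg$score_field),
        group_scores(ds, cfg$dual_control_group, cfg$score_field))
      written <- c(written, tsv(as.data.frame(curves), "curves.tsv"))
    }
  }
  invisible(written)
}

#' Three-zone triage text for one score
#'
#' Renders the decision logic of the dual-cut-off rule as structured text for
#' a clinical report: which zone the score falls in and the deferral advice
#' for the indecisive band.
#'
#' @param score integer score.
#' @param result a [find_dual_cutoffs()] result.
#' @return character string.
#' @export
triage_text <- function(score, result) {
  zone <- as.character(classify_score(score, result))
  switch(zone,
    not_healthy = sprintf(
      "Score %d <= %d (%s): below the not-healthy cut-off; result pathological.",
      score, result$lower_t, cutoff_label(result$lower_t)),
    not_pathological = sprintf(
      "Score %d > %d (%s): above the not-pathological cut-off; result within the normal range.",
      score, result$upper_t, cutoff_label(result$upper_t)),
    indecisive = sprintf(
      "Score %d lies in the indecisive area (%d-%d): classification deferred; further examination required.",
      score, min(result$indecisive_scores), max(result$indecisive_scores))
  )
}
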