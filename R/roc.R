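#' Empirical ROC curve for a lower-is-impaired score
#'
#' Orientation is fixed: lower scores indicate impairment, and a threshold `t`
#' classifies scores `<= t` as positive, so `sens(t)` is the fraction of
#' positives at or below `t` and `spec(t)` the fraction of negatives above
#' `t`. For bounded integer scores the threshold grid is `-1..30` (the anchors
#' where sensitivity is 0 and 1); continuous scores use the sorted unique
#' observed values with a left anchor below the minimum.
#'
#' @param pos_scores scores of the positive (impaired) class; non-empty.
#' @param neg_scores scores of the negative class; non-empty.
#' @param grid optional explicit threshold vector; by default the integer grid
#'   when all scores are integers in 0-30, otherwise the observed-value grid.
#' @return object of class `roc_curve`: data.frame columns `threshold`,
#'   `sens`, `spec`, plus attributes `auc` and `orientation`.
#' @examples
#' r <- roc_curve(c(18, 20, 22), c(26, 27, 29))
#' attr(r, "auc")
#' @export
roc_curve <- function(pos_scores, neg_scores, grid = NULL) {
  check_two_class(pos_scores, neg_scores)
  if (is.null(grid)) {
    allv <- c(pos_scores, neg_scores)
    if (all(allv == floor(allv)) && all(allv >= 0) && all(allv <= SCORE_MAX)) {
      grid <- seq(-1L, SCORE_MAX)
    } else {
      u <- sort(unique(allv))
      grid <- c(u[1] - 1, u)
    }
  }
  sens <- vapply(grid, function(t) mean(pos_scores <= t), numeric(1))
  spec <- vapply(grid, function(t) mean(neg_scores > t), numeric(1))
  structure(
    data.frame(threshold = grid, sens = sens, spec = spec),
    auc = auc(pos_scores, neg_scores),
    orientation = "lower score = positive (impaired)",
    class = c("roc_curve", "data.frame")
  )
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("roc_curve:", nrow(x), "thresholds; AUC =",
      format(attr(x, "auc"), digits = 4), "\n")
  cat("  orientation:", attr(x, "orientation"), "\n")
  invisible(x)
}

#' Mann-Whitney AUC
#'
#' Probability that a random positive subject scores below a random negative
#' subject, ties counted one half — computed via midranks, which is exactly
#' the mean over all (positive, negative) pairs of
#' `1[p < n] + 0.5 * 1[p == n]`, and equals the trapezoidal area under the
#' empirical ROC curve.
#'
#' @inheritParams roc_curve
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(20, 25), c(24, 26))  # 0.75
#' @export
auc <- function(pos_scores, neg_scores) {
  check_two_class(pos_scores, neg_scores)
  np <- length(pos_scores)
  nn <- length(neg_scores)
  r <- rank(c(pos_scores, neg_scores))  # midranks for ties
  (sum(r[(np + 1):(np + nn)]) - nn * (nn + 1) / 2) / (np * nn)
}

check_two_class <- function(pos_scores, neg_scores) {
  if (length(pos_scores) == 0 || length(neg_scores) == 0) {
    stop("single-class input: both score sets must be non-empty",
         call. = FALSE)
  }
  if (anyNA(pos_scores) || anyNA(neg_scores)) {
    stop("scores contain missing values", call. = FALSE)
  }
  invisible(TRUE)
}

#' Paired stratified-bootstrap comparison of two correlated AUCs
#'
#' Both markers are measured on the same subjects, so their AUCs are
#' correlated; subjects are resampled with replacement stratified by class
#' (per-class sample sizes preserved in every replicate), both AUCs are
#' recomputed on each replicate, and the observed AUC difference is
#' standardised by the bootstrap standard deviation of the difference:
#' `D = (auc_a - auc_b) / sd_boot`, with a two-sided normal p-value
#' `2 * (1 - pnorm(|D|))`.
#'
#' If the bootstrap SD is exactly zero the p-value is 1 when the observed
#' difference is zero (identical markers) and an error otherwise.
#'
#' @param score_a,score_b per-subject scores of the two markers (same
#'   subjects, same order).
#' @param labels per-subject class: `TRUE`/1 for positive (impaired).
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed integer seed; results are deterministic given it.
#' @return object of class `auc_comparison`: list with `auc_a`, `auc_b`,
#'   `d_stat`, `p_two_sided`, `n_boot`, `seed`.
#' @export
compare_auc_paired_bootstrap <- function(score_a, score_b, labels,
                                         n_boot = 2000, seed = 1L) {
  stopifnot(length(score_a) == length(score_b),
            length(score_a) == length(labels))
  lab <- as.logical(labels)
  ip <- which(lab)
  ineg <- which(!lab)
  if (length(ip) == 0 || length(ineg) == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  auc_a <- auc(score_a[ip], score_a[ineg])
  auc_b <- auc(score_b[ip], score_b[ineg])
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  diffs <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    rp <- ip[sample.int(length(ip), replace = TRUE)]
    rn <- ineg[sample.int(length(ineg), replace = TRUE)]
    diffs[b] <- auc(score_a[rp], score_a[rn]) - auc(score_b[rp], score_b[rn])
  }
  sd_boot <- sd(diffs)
  obs <- auc_a - auc_b
  if (sd_boot == 0) {
    if (obs == 0) {
      d <- 0
      p <- 1
    } else {
      stop("degenerate bootstrap: SD of AUC difference is zero but the ",
           "observed difference is not", call. = FALSE)
    }
  } else {
    d <- obs / sd_boot
    p <- 2 * (1 - pnorm(abs(d)))
  }
  structure(list(auc_a = auc_a, auc_b = auc_b, d_stat = d, p_two_sided = p,
                 n_boot = n_boot, seed = seed),
            class = "auc_comparison")
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf(
    "auc_comparison: AUC_a = %.4f, AUC_b = %.4f, D = %.3f, p = %.4g (B = %d)\n",
    x$auc_a, x$auc_b, x$d_stat, x$p_two_sided, x$n_boot))
  invisible(x)
}

#' Percentile-bootstrap confidence interval for an AUC
#'
#' Stratified resampling within each class; the interval method is recorded in
#' the result because the choice of CI method matters for reporting.
#'
#' @inheritParams roc_curve
#' @param n_boot bootstrap replicates.
#' @param level confidence level.
#' @param seed integer seed.
#' @return an `interval_estimate` (see [clopper_pearson()]).
#' @export
auc_ci <- function(pos_scores, neg_scores, n_boot = 2000, level = 0.95,
                   seed = 1L) {
  check_two_class(pos_scores, neg_scores)
  point <- auc(pos_scores, neg_scores)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  reps <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    reps[b] <- auc(pos_scores[sample.int(length(pos_scores), replace = TRUE)],
                   neg_scores[sample.int(length(neg_scores), replace = TRUE)])
  }
  alpha <- 1 - level
  q <- quantile(reps, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 7)
  interval_estimate(point, q[1], q[2], level, "bootstrap_percentile")
}
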