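#' Interval estimate container
#'
#' @param point,lower,upper proportions in `[0, 1]` with
#'   `lower <= point <= upper`.
#' @param level confidence level.
#' @param method `"clopper_pearson"` or `"bootstrap_percentile"`.
#' @return object of class `interval_estimate`.
#' @export
interval_estimate <- function(point, lower, upper, level, method) {
  stopifnot(method %in% c("clopper_pearson", "bootstrap_percentile"))
  # percentile intervals can, in extreme skew, miss the plug-in point; widen
  lower <- min(lower, point)
  upper <- max(upper, point)
  structure(list(point = point, lower = lower, upper = upper, level = level,
                 method = method),
            class = "interval_estimate")
}

#' @export
print.interval_estimate <- function(x, ...) {
  cat(sprintf("%.4f (%.0f%% CI %.4f-%.4f, %s)\n", x$point, x$level * 100,
              x$lower, x$upper, x$method))
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Beta-quantile form of the exact interval; the boundary conventions are the
#' usual ones — lower limit 0 when there are no successes, upper limit 1 when
#' every trial succeeded.
#'
#' @param successes,trials counts with `0 <= successes <= trials`,
#'   `trials > 0`.
#' @param level confidence level (default 0.95).
#' @return an [interval_estimate()].
#' @examples
#' clopper_pearson(8, 10)
#' @export
clopper_pearson <- function(successes, trials, level = 0.95) {
  if (trials <= 0 || successes < 0 || successes > trials) {
    stop("need 0 <= successes <= trials with trials > 0", call. = FALSE)
  }
  alpha <- 1 - level
  lower <- if (successes == 0) 0 else qbeta(alpha / 2, successes,
                                            trials - successes + 1)
  upper <- if (successes == trials) 1 else qbeta(1 - alpha / 2, successes + 1,
                                                 trials - successes)
  interval_estimate(successes / trials, lower, upper, level,
                    "clopper_pearson")
}

#' McNemar comparison of two paired classifiers
#'
#' Compares the per-subject correctness of two classification rules applied
#' to the same subjects. Only the discordant pairs are informative: `b`
#' subjects classified correctly by rule A but not B, and `c` the reverse.
#' Small discordant totals (`b + c < 25`) use the exact two-sided binomial
#' test on `b` out of `b + c` with null probability 1/2; larger totals use
#' the chi-squared statistic with continuity correction
#' `max(0, |b - c| - 1)^2 / (b + c)` on 1 df — the correction is capped at
#' zero so a perfectly balanced discordance cannot be overcorrected into a
#' spurious discrepancy (the exact p is 1 there, and so is the capped
#' approximation's). No discordant pairs at all gives p = 1 by convention.
#'
#' @param correct_a,correct_b logical vectors, same subjects in the same
#'   order: was the subject classified correctly by each rule?
#' @return object of class `paired_test_result`: list with `statistic`,
#'   `p_raw`, `method` (`"mcnemar_exact"` or `"mcnemar_cc"`),
#'   `discordant_b`, `discordant_c`.
#' @export
mcnemar_paired <- function(correct_a, correct_b) {
  stopifnot(length(correct_a) == length(correct_b))
  if (length(correct_a) == 0) stop("zero-length input", call. = FALSE)
  a <- as.logical(correct_a)
  b_ <- as.logical(correct_b)
  b <- sum(a & !b_)
  cc <- sum(!a & b_)
  n_disc <- b + cc
  if (n_disc == 0) {
    res <- list(statistic = 0, p_raw = 1, method = "mcnemar_exact",
                discordant_b = b, discordant_c = cc)
  } else if (n_disc < 25) {
    p <- binom.test(b, n_disc, p = 0.5)$p.value
    res <- list(statistic = as.numeric(b), p_raw = p,
                method = "mcnemar_exact", discordant_b = b,
                discordant_c = cc)
  } else {
    stat <- max(0, abs(b - cc) - 1)^2 / n_disc
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    res <- list(statistic = stat, p_raw = p, method = "mcnemar_cc",
                discordant_b = b, discordant_c = cc)
  }
  structure(res, class = "paired_test_result")
}

#' @export
print.paired_test_result <- function(x, ...) {
  cat(sprintf("%s: b = %d, c = %d, statistic = %.3f, p = %.4g\n",
              x$method, x$discordant_b, x$discordant_c, x$statistic, x$p_raw))
  invisible(x)
}

#' Holm (step-down Bonferroni) adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "holm")`: order-preserving,
#' clipped at 1, monotone along the sorted raw ordering.
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @examples
#' holm_adjust(c(0.01, 0.04, 0.03))  # 0.03 0.06 0.06
#' @export
holm_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "holm")
}

#' Percentile-bootstrap confidence interval for an arbitrary statistic
#'
#' Resamples rows of `data` with replacement — stratified by `strata` when
#' given, so per-stratum sizes are preserved — and takes the percentile
#' interval of the replicated statistic. Deterministic given `seed`. A
#' constant statistic yields a zero-width interval with a warning.
#'
#' @param statistic function `data -> scalar`.
#' @param data data.frame or vector passed to `statistic`.
#' @param n_boot replicates.
#' @param level confidence level.
#' @param seed integer seed.
#' @param strata optional stratification vector (one entry per row/element).
#' @return an [interval_estimate()] with method `"bootstrap_percentile"`.
#' @export
bootstrap_ci <- function(statistic, data, n_boot = 2000, level = 0.95,
                         seed = 1L, strata = NULL) {
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  stopifnot(n > 0)
  take <- function(d, idx) if (is.data.frame(d)) d[idx, , drop = FALSE] else
    d[idx]
  point <- statistic(data)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  reps <- numeric(n_boot)
  for (i in seq_len(n_boot)) {
    idx <- if (is.null(strata)) {
      sample.int(n, replace = TRUE)
    } else {
      unlist(lapply(split(seq_len(n), strata), function(ix) {
        ix[sample.int(length(ix), replace = TRUE)]
      }), use.names = FALSE)
    }
    reps[i] <- statistic(take(data, idx))
  }
  if (length(unique(reps)) == 1 && reps[1] == point) {
    warning("statistic constant across resamples: zero-width interval")
  }
  alpha <- 1 - level
  q <- quantile(reps, c(alpha / 2, 1 - alpha / 2), names = FALSE, type = 7)
  interval_estimate(point, q[1], q[2], level, "bootstrap_percentile")
}
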