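# Independent brute-force oracles used to verify the fast implementations.

# Mann-Whitney AUC by explicit enumeration of all (positive, negative) pairs
auc_pair_enumeration <- function(pos, neg) {
  cmp <- outer(pos, neg, function(p, n) (p < n) + 0.5 * (p == n))
  mean(cmp)
}

# trapezoidal area under the empirical ROC polygon in (1 - spec, sens) space
auc_trapezoid <- function(curve) {
  fpr <- 1 - curve$spec
  o <- order(fpr, curve$sens)
  x <- c(0, fpr[o], 1)
  y <- c(0, curve$sens[o], 1)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# exhaustive-search cut-off oracles over a metric grid
balanced_oracle <- function(metrics) {
  metrics$threshold[which.min(abs(metrics$sensitivity - metrics$specificity))]
}
youden_oracle <- function(metrics) {
  metrics$threshold[which.max(metrics$sensitivity + metrics$specificity - 1)]
}

# small random two-class integer-score instance
random_instance <- function(max_n = 12) {
  list(pos = sample(0:30, sample(1:max_n, 1), replace = TRUE),
       neg = sample(0:30, sample(1:max_n, 1), replace = TRUE))
}

# minimal valid cohort for I/O and report tests
tiny_cohort <- function() {
  study_cohort(data.frame(
    id = sprintf("s%02d", 1:8),
    group = c("NC", "NC", "NF", "NF", "MILD", "MILD", "MAJOR", "MAJOR"),
    age = c(70, 75, 68, 81, 77, 74, 83, 79),
    education = c(13, 9, 15, 11, 8, 14, 10, 12),
    sex = c("F", "M", "F", "F", "M", "F", "M", "M"),
    moca_raw = c(28, 26, 27, 25, 21, 23, 15, 18),
    mmse = c(30, 29, 29, 28, 27, 28, 22, 24),
    moca_z = c(0.5, -0.2, 0.1, -0.6, -1.8, -1.2, -2.9, -2.4)
  ), provenance = "test fixture")
}
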