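test_that("evaluate_cutoff counts the confusion table for score <= t positive", {
  m <- evaluate_cutoff(c(20, 25), c(27, 28), 23)
  expect_equal(m[, c("tp", "fn", "tn", "fp")],
               data.frame(tp = 1L, fn = 1L, tn = 2L, fp = 0L),
               ignore_attr = TRUE)
  expect_equal(m$sensitivity, 0.5)
  expect_equal(m$specificity, 1.0)
  expect_equal(m$label, "23/24")

  perfect <- evaluate_cutoff(c(10, 12), c(28, 29), 20)
  expect_equal(perfect$ccr, 1)
  expect_equal(perfect$youden_j, 1)
})

test_that("ccr and Youden J satisfy their algebraic identity on random tables", {
  set.seed(3)
  for (i in 1:50) {
    inst <- random_instance(25)
    t <- sample(-1:30, 1)
    m <- evaluate_cutoff(inst$pos, inst$neg, t)
    expect_equal(m$ccr, (m$sensitivity + m$specificity) / 2)
    expect_equal(m$youden_j, m$sensitivity + m$specificity - 1)
    expect_equal(m$ccr, (m$youden_j + 1) / 2)
    expect_equal(m$tp + m$fn, length(inst$pos))
    expect_equal(m$tn + m$fp, length(inst$neg))
  }
})

test_that("display rounding is half away from zero (0.785 -> 79%)", {
  expect_equal(format_percent((0.94 + 0.63) / 2), "79%")  # 78.5 rounds up
  expect_equal(format_percent(0.625), "63%")
  expect_equal(format_percent(0.5), "50%")
  expect_equal(format_percent(0.9012, digits = 1), "90.1%")
})

test_that("the full-threshold table matches per-threshold evaluation", {
  set.seed(8)
  inst <- random_instance(30)
  tab <- metrics_at_all_thresholds(inst$pos, inst$neg)
  expect_equal(nrow(tab), 32)
  expect_true(all(diff(tab$sensitivity) >= 0))
  expect_true(all(diff(tab$specificity) <= 0))
  for (t in c(-1L, 0L, 15L, 23L, 30L)) {
    expect_equal(tab[tab$threshold == t, ],
                 evaluate_cutoff(inst$pos, inst$neg, t), ignore_attr = TRUE)
  }
})

test_that("balanced and Youden selections equal exhaustive search, ties to lower t", {
  set.seed(17)
  for (i in 1:200) {
    inst <- random_instance(20)
    tab <- metrics_at_all_thresholds(inst$pos, inst$neg)
    expect_equal(balanced_cutoff(tab)$threshold, balanced_oracle(tab))
    expect_equal(youden_cutoff(tab)$threshold, youden_oracle(tab))
  }
  # a perfectly separating gap: J = 1 on every threshold in [20, 24];
  # the lowest (highest-specificity) threshold wins
  tab <- metrics_at_all_thresholds(c(15, 18, 20), c(25, 27, 30))
  expect_equal(youden_cutoff(tab)$threshold, 20L)
  expect_equal(balanced_cutoff(tab)$threshold, 20L)
})

test_that("balanced cut-off lands where sens and spec are closest", {
  # grid engineered so t = 24 gives exactly (0.74, 0.74) and no lower
  # threshold ties it
  pos <- c(rep(24, 74), rep(27, 26))   # sens(24) = 0.74, sens(23) = 0
  neg <- c(rep(28, 74), rep(24, 26))   # spec(24) = 0.74, spec(23) = 1
  tab <- metrics_at_all_thresholds(pos, neg)
  ch <- balanced_cutoff(tab)
  expect_equal(ch$threshold, 24L)
  expect_equal(ch$metrics$sensitivity, 0.74)
  expect_equal(ch$metrics$specificity, 0.74)
})

test_that("percentile cut-off floors the type-7 empirical quantile", {
  ch <- percentile_cutoff(20:29, q = 0.10)
  expect_equal(ch$strategy_params$quantile, 20.9)
  expect_equal(ch$threshold, 20L)
  expect_equal(ch$label, "20/21")

  # q -> 0 limit: threshold at or below every control score
  lo <- percentile_cutoff(c(18, 22, 25), q = 1e-9)
  expect_lte(lo$threshold, 18)

  # threshold never exceeds the control maximum
  set.seed(29)
  for (i in 1:30) {
    neg <- sample(0:30, sample(3:40, 1), replace = TRUE)
    q <- runif(1, 0.01, 0.99)
    expect_lte(percentile_cutoff(neg, q)$threshold, max(neg))
  }

  cont <- percentile_cutoff(rnorm(100), q = 0.10, discrete = FALSE)
  expect_false(cont$threshold == floor(cont$threshold) &&
                 grepl("/", cont$label))
  expect_error(percentile_cutoff(numeric(0)), "empty")
})

test_that("predictive values follow Bayes' rule and the confusion-table identity", {
  r <- ppv_npv(0.84, 0.92, 0.901)
  expect_equal(r$ppv, 0.84 * 0.901 / (0.84 * 0.901 + 0.08 * 0.099))
  expect_equal(r$ppv, 0.9896, tolerance = 1e-4)

  expect_equal(ppv_npv(1, 1, 0.5), data.frame(prevalence = 0.5, ppv = 1,
                                              npv = 1))
  edge <- ppv_npv(0.8, 0.9, c(0, 1))
  expect_equal(edge$ppv, c(0, 1))
  expect_equal(edge$npv, c(1, 0))

  # conservation: at the sample prevalence, ppv/npv equal the column ratios
  set.seed(31)
  inst <- random_instance(40)
  m <- evaluate_cutoff(inst$pos, inst$neg, 22)
  prev <- (m$tp + m$fn) / (m$tp + m$fn + m$tn + m$fp)
  r2 <- ppv_npv(m$sensitivity, m$specificity, prev)
  if (m$tp + m$fp > 0) expect_equal(r2$ppv, m$tp / (m$tp + m$fp))
  if (m$tn + m$fn > 0) expect_equal(r2$npv, m$tn / (m$tn + m$fn))
})

test_that("prevalence is the patient fraction of the clinic sample", {
  expect_equal(prevalence(447, 49), 447 / 496)
  expect_equal(format_percent(prevalence(447, 49), 1), "90.1%")
  expect_equal(format_percent(prevalence(159, 337), 1), "32.1%")
  expect_equal(prevalence(0, 49), 0)
  expect_error(prevalence(0, 0), "positive")
})

test_that("fixed cut-off wraps a pre-specified threshold", {
  inst <- list(pos = c(18, 22, 26), neg = c(24, 27, 29))
  tab <- metrics_at_all_thresholds(inst$pos, inst$neg)
  ch <- fixed_cutoff(tab, 25L)
  expect_equal(ch$label, "25/26")
  expect_equal(ch$metrics, evaluate_cutoff(inst$pos, inst$neg, 25),
               ignore_attr = TRUE)
  expect_error(fixed_cutoff(tab, 99L), "not on the metric grid")
})
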