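test_that("cumulative curves are exact empirical fractions", {
  cc <- cumulative_curves(c(20, 20, 25), c(27, 29))
  expect_equal(cc$sens_by_score[cc$score == 20], 2 / 3)
  expect_equal(cc$sens_by_score[cc$score == 25], 1)
  expect_equal(cc$spec_by_score[cc$score == 26], 1)
  expect_equal(cc$spec_by_score[cc$score == 27], 1 / 2)

  single <- cumulative_curves(c(10), c(30))
  expect_true(all(single$spec_by_score[single$score < 30] == 1))
  expect_equal(single$spec_by_score[single$score == 30], 0)
  expect_error(cumulative_curves(numeric(0), 1:3), "empty")
})

test_that("cumulative curves agree with the ROC module at every threshold", {
  set.seed(43)
  for (i in 1:10) {
    inst <- random_instance(30)
    cc <- cumulative_curves(inst$pos, inst$neg)
    r <- roc_curve(inst$pos, inst$neg)
    shared <- intersect(cc$score, r$threshold)
    expect_equal(cc$sens_by_score[match(shared, cc$score)],
                 r$sens[match(shared, r$threshold)])
    expect_equal(cc$spec_by_score[match(shared, cc$score)],
                 r$spec[match(shared, r$threshold)])
  }
})

test_that("dual cut-offs follow the strict >=-target selection rule", {
  # hand-enumerable staircase: patients 20..29, controls 21..30
  cc <- cumulative_curves(20:29, 21:30)
  res <- find_dual_cutoffs(cc, target_sens = 0.90, target_spec = 0.90)
  expect_equal(res$lower_t, 21L)     # spec_by_score(21) = 0.9
  expect_equal(res$upper_t, 28L)     # sens_by_score(28) = 0.9
  expect_equal(res$achieved_spec, 0.9)
  expect_equal(res$achieved_sens, 0.9)
  expect_equal(res$indecisive_scores, 22:28)

  # a control scoring 0 caps attainable specificity below 1
  cc2 <- cumulative_curves(20:29, c(0, 21:30))
  expect_error(find_dual_cutoffs(cc2, target_spec = 0.999), "specificity")
  # a patient scoring 31 is impossible, so sensitivity 1 is always reachable,
  # but an above-max target is rejected outright
  expect_error(find_dual_cutoffs(cc, target_sens = 1.2))
})

test_that("non-overlapping groups give an empty indecisive set, fully decided", {
  cc <- cumulative_curves(patient_scores = c(10, 12, 15),
                          control_scores = c(25, 27, 30))
  res <- find_dual_cutoffs(cc, 0.90, 0.90)
  expect_equal(res$lower_t, 24L)  # spec = 1 up to 24
  expect_equal(res$upper_t, 15L)  # sens = 1 from 15
  expect_length(res$indecisive_scores, 0)
  z <- classify_score(0:30, res)
  expect_false(any(z == "indecisive"))
  # precedence above upper_t is not-pathological
  expect_equal(as.character(z[0:30 > res$upper_t][1]), "not_pathological")
})

test_that("the three zones partition the score range", {
  set.seed(47)
  for (i in 1:20) {
    pats <- sample(0:30, 40, replace = TRUE, prob = dnorm(0:30, 20, 5))
    ctrls <- sample(0:30, 40, replace = TRUE, prob = dnorm(0:30, 27, 2))
    cc <- cumulative_curves(pats, ctrls)
    res <- try(find_dual_cutoffs(cc, 0.9, 0.9), silent = TRUE)
    if (inherits(res, "try-error")) next
    z <- classify_score(0:30, res)
    expect_false(anyNA(z))
    expect_equal(sum(z == "not_healthy"), res$lower_t + 1)
    expect_equal(sum(z == "not_pathological"), 30 - res$upper_t)
    expect_equal(sum(z == "indecisive"), length(res$indecisive_scores))
  }
  expect_error(classify_score(31, find_dual_cutoffs(
    cumulative_curves(20:29, 21:30), 0.9, 0.9)), "\\[0,30\\]")
})

test_that("raising both targets never shrinks the indecisive area", {
  set.seed(53)
  pats <- pmin(30, pmax(0, round(rnorm(300, 22, 3.6))))
  ctrls <- pmin(30, pmax(0, round(rnorm(300, 26.5, 2.4))))
  cc <- cumulative_curves(pats, ctrls)
  prev <- NULL
  for (tg in c(0.80, 0.85, 0.90, 0.95)) {
    res <- find_dual_cutoffs(cc, tg, tg)
    if (!is.null(prev)) {
      expect_true(all(prev$indecisive_scores %in% res$indecisive_scores))
    }
    prev <- res
  }
})

test_that("achieved accuracies are self-consistent when re-applied to the samples", {
  set.seed(59)
  pats <- pmin(30, pmax(0, round(rnorm(500, 22, 3.6))))
  ctrls <- pmin(30, pmax(0, round(rnorm(500, 26.5, 2.4))))
  cc <- cumulative_curves(pats, ctrls)
  res <- find_dual_cutoffs(cc, 0.9, 0.9)
  expect_equal(mean(ctrls > res$lower_t), res$achieved_spec)
  expect_equal(mean(pats <= res$upper_t), res$achieved_sens)
})

test_that("the nearest rule picks the closest achieved value to the target", {
  cc <- cumulative_curves(20:29, 21:30)
  # targets between grid steps: 0.87 sens is closer to 0.9 (s=28) than 0.8
  res <- find_dual_cutoffs(cc, 0.87, 0.87, rule = "nearest")
  expect_equal(res$upper_t, 28L)  # sens(28) = 0.9, |0.9 - 0.87| < |0.8 - 0.87|
  expect_equal(res$lower_t, 21L)  # spec(21) = 0.9, likewise

  # targets nearer the lower step flip both choices by one score
  res2 <- find_dual_cutoffs(cc, 0.82, 0.82, rule = "nearest")
  expect_equal(res2$upper_t, 27L)  # sens(27) = 0.8
  expect_equal(res2$lower_t, 22L)  # spec(22) = 0.8
})

test_that("zone_summary counts sum to group sizes", {
  ds <- tiny_cohort()
  cc <- cumulative_curves(group_scores(ds, "MILD", "moca_raw"),
                          group_scores(ds, "NC", "moca_raw"))
  res <- find_dual_cutoffs(cc, 0.5, 0.5)
  zs <- zone_summary(ds, res, "moca_raw")
  expect_equal(zs$n, as.vector(table(factor(ds$group,
                                            c("NC", "NF", "MILD", "MAJOR")))))
  expect_equal(zs$not_healthy + zs$indecisive + zs$not_pathological, zs$n)

  empty <- study_cohort(as.data.frame(ds)[0, ])
  zs0 <- zone_summary(empty, res, "moca_raw")
  expect_true(all(zs0$n == 0))
})

test_that("large simulated NC misclassification matches 1 - achieved specificity", {
  set.seed(61)
  ctrls <- pmin(30, pmax(0, round(rnorm(20000, 26.5, 2.4))))
  pats <- pmin(30, pmax(0, round(rnorm(20000, 22, 3.6))))
  cc <- cumulative_curves(pats, ctrls)
  res <- find_dual_cutoffs(cc, 0.9, 0.9)
  frac_nc_not_healthy <- mean(ctrls <= res$lower_t)
  expect_equal(frac_nc_not_healthy, 1 - res$achieved_spec, tolerance = 1e-12)
})
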