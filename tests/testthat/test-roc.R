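test_that("empirical ROC handles the canonical toy cases", {
  # perfect separation
  cv <- empiricalROC(c(3, 4, 1, 2), c(1, 1, 0, 0), "high")
  expect_equal(aucPValue(cv)$auc, 1)
  cut <- selectCutoff(cv)
  expect_equal(cut$cutoff, 2.5)
  expect_equal(cut$sensitivity, 1)
  expect_equal(cut$specificity, 1)

  # total ties
  cv <- empiricalROC(rep(5, 10), rep(c(1, 0), 5), "high")
  expect_equal(aucPValue(cv)$auc, 0.5)

  # direction: low tail abnormal
  cv <- empiricalROC(c(1, 2, 3, 4), c(1, 1, 0, 0), "low")
  expect_equal(aucPValue(cv)$auc, 1)
  expect_equal(selectCutoff(cv)$cutoff, 2.5) # rule: value < 2.5

  # degenerate inputs
  expect_error(empiricalROC(1:4, c(1, 1, 1, 1), "high"), "degenerate")
  expect_error(empiricalROC(c(1, NA), c(1, 0), "high"), "degenerate")
})

test_that("curve invariants hold: monotone sens/spec with both endpoints", {
  set.seed(101)
  for (i in 1:20) {
    co <- randomCohort(7, 9, 1, shift = runif(1, 0, 2), ties = i %% 2 == 0)
    cv <- empiricalROC(co$values[1, ], co$case, "high")
    expect_true(all(diff(cv@sensitivity) <= 0))
    expect_true(all(diff(cv@specificity) >= 0))
    expect_equal(cv@sensitivity[1], 1)
    expect_equal(cv@specificity[1], 0)
    expect_equal(cv@sensitivity[length(cv@sensitivity)], 0)
    expect_equal(cv@specificity[length(cv@specificity)], 1)
  }
})

test_that("AUC equals exhaustive pair counting exactly, all n <= 50", {
  set.seed(7)
  for (i in 1:40) {
    n1 <- sample(2:25, 1); n2 <- sample(2:25, 1)
    v <- round(rnorm(n1 + n2, sd = 2), sample(0:1, 1)) # force ties often
    case <- rep(c(TRUE, FALSE), c(n1, n2))
    auc <- aucPValue(empiricalROC(v, case, "high"))$auc
    expect_identical(auc, bruteForceAUC(v[case], v[!case]))
  }
})

test_that("AUC agrees with the rank-sum statistic from wilcox.test", {
  set.seed(8)
  v <- round(rnorm(60), 1)
  case <- rep(c(TRUE, FALSE), 30)
  w <- suppressWarnings(wilcox.test(v[case], v[!case]))
  expect_equal(aucPValue(empiricalROC(v, case, "high"))$auc,
               unname(w$statistic) / (30 * 30))
})

test_that("flipping direction maps AUC to 1 - AUC", {
  set.seed(9)
  for (i in 1:10) {
    v <- round(rnorm(40), 1)
    case <- rep(c(TRUE, FALSE), 20)
    hi <- aucPValue(empiricalROC(v, case, "high"))$auc
    lo <- aucPValue(empiricalROC(v, case, "low"))$auc
    expect_equal(hi + lo, 1)
  }
})

test_that("AUC p-value behaves at the extremes and holds its size", {
  v <- rep(c(1, 2), each = 20)
  expect_lt(aucPValue(empiricalROC(v, rep(c(1, 0), each = 20), "high"))$pValue,
            1e-4)
  # AUC exactly 0.5 -> p = 1
  expect_equal(aucPValue(empiricalROC(c(1, 2, 1, 2),
                                      c(1, 1, 0, 0), "high"))$pValue, 1)
  # type-I error of the Hanley-McNeil normal test at study scale
  set.seed(42)
  hits <- mean(replicate(2000, {
    x <- rnorm(134)
    aucPValue(empiricalROC(x, rep(c(1, 0), each = 67), "high"))$pValue < 0.05
  }))
  expect_gt(hits, 0.035)
  expect_lt(hits, 0.065)
})

test_that("selected cutoff maximizes Youden J (exhaustive-scan oracle)", {
  set.seed(11)
  for (i in 1:20) {
    co <- randomCohort(30, 30, 1, shift = runif(1, 0, 1.5), ties = TRUE)
    v <- co$values[1, ]
    cv <- empiricalROC(v, co$case, "high")
    cut <- selectCutoff(cv)
    expect_equal(cut$sensitivity + cut$specificity - 1,
                 bruteForceBestJ(v[co$case], v[!co$case]))
  }
  # fully overlapping distributions: J near zero
  cv <- empiricalROC(rep(1:5, 4), rep(c(1, 0), 10), "high")
  cut <- selectCutoff(cv)
  expect_lt(cut$sensitivity + cut$specificity - 1, 0.2)
})

test_that("accuracy sits between sens and spec for equal groups", {
  set.seed(12)
  for (i in 1:10) {
    co <- randomCohort(20, 20, 1, shift = 1)
    r <- rocAnalysis(co$values[1, ], co$case, "high")
    expect_gte(r@accuracy, min(r@sensitivity, r@specificity))
    expect_lte(r@accuracy, max(r@sensitivity, r@specificity))
  }
})

test_that("diagnostic odds ratio: closed form, boundaries, Haldane", {
  expect_equal(diagnosticOddsRatio(0.5, 0.5), 1)
  expect_equal(diagnosticOddsRatio(1, 0.5), Inf)
  expect_equal(diagnosticOddsRatio(0, 0.5), 0)
  expect_error(diagnosticOddsRatio(1.2, 0.5), "\\[0, 1\\]")
  # published panel rows reproduce from their sens/spec within rounding
  expect_equal(diagnosticOddsRatio(0.900, 0.552), 11.1, tolerance = 0.005)
  expect_equal(diagnosticOddsRatio(0.697, 0.642), 4.12, tolerance = 0.005)
  # counts interface with continuity correction
  expect_equal(diagnosticOddsRatio(counts = c(9, 1, 2, 8)), 36)
  expect_equal(diagnosticOddsRatio(counts = c(10, 0, 2, 8)),
               (10.5 * 8.5) / (0.5 * 2.5))
})

test_that("predictive values follow Bayes' rule and its monotonicities", {
  expect_equal(unlist(predictiveValues(1, 1, 0.1)[c("ppv", "npv")]),
               c(ppv = 1, npv = 1))
  expect_error(predictiveValues(0.8, 0.8, 1.2), "prevalence")
  # PPV increases and NPV decreases with prevalence; DOR ignores it
  pv <- predictiveValues(0.8, 0.9, c(0.01, 0.1, 0.3, 0.6))
  expect_true(all(diff(pv$ppv) > 0))
  expect_true(all(diff(pv$npv) < 0))
  # at the sample prevalence the formulas reproduce the cohort's own 2x2
  set.seed(13)
  co <- randomCohort(40, 60, 1, shift = 1)
  r <- rocAnalysis(co$values[1, ], co$case, "high")
  pred <- co$values[1, ] > r@cutoff
  pv <- predictiveValues(r@sensitivity, r@specificity, 40 / 100)
  expect_equal(pv$ppv, sum(pred & co$case) / sum(pred))
  expect_equal(pv$npv, sum(!pred & !co$case) / sum(!pred))
})

test_that("accuracy index matches direct counting", {
  expect_equal(accuracyIndex(c(1, 1, 0), c(1, 1, 0)), 1)
  expect_equal(accuracyIndex(c(0, 0, 1), c(1, 1, 0)), 0)
  set.seed(14)
  pred <- rbinom(50, 1, 0.5); y <- rbinom(50, 1, 0.5)
  expect_equal(accuracyIndex(pred, y), sum(pred == y) / 50)
})

test_that("Spearman rho is tie-corrected mid-rank Pearson with t p-value", {
  expect_equal(spearmanRho(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearmanRho(1:10, -(1:10))$rho, -1)
  expect_error(spearmanRho(1:2, 1:2), "3 complete pairs")
  set.seed(15)
  for (i in 1:10) {
    x <- sample(1:5, 20, replace = TRUE) # heavy ties
    y <- x + sample(1:3, 20, replace = TRUE)
    got <- spearmanRho(x, y)
    want <- midrankSpearman(x, y)
    expect_equal(got$rho, want$rho, tolerance = 1e-12)
    expect_equal(got$pValue, want$pValue, tolerance = 1e-10)
  }
})
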