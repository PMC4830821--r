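test_that("dichotomize applies strict cutoff rules per direction", {
  vals <- rbind(a = c(5, 3), b = c(5, 3))
  colnames(vals) <- c("s1", "s2")
  flags <- dichotomize(vals, c(a = 4, b = 4), c(a = "high", b = "low"))
  expect_equal(flags["a", ], c(s1 = 1L, s2 = 0L)) # 5 > 4, 3 <= 4
  expect_equal(flags["b", ], c(s1 = 0L, s2 = 1L)) # low tail abnormal
  # missing cutoff is a configuration error; NA values stay NA
  expect_error(dichotomize(vals, c(a = 4), c(a = "high", b = "low")),
               "no cutoff")
  vals["a", 1] <- NA
  flags <- dichotomize(vals, c(a = 4, b = 4), c(a = "high", b = "low"))
  expect_true(is.na(flags["a", 1]))
})

test_that("dichotomize matches elementwise comparison on random cohorts", {
  set.seed(30)
  co <- randomCohort(15, 15, 6, ties = TRUE)
  cuts <- setNames(rnorm(6), rownames(co$values))
  dirs <- setNames(rep(c("high", "low"), 3), rownames(co$values))
  flags <- dichotomize(co$values, cuts, dirs)
  for (m in rownames(co$values)) {
    want <- if (dirs[m] == "high") co$values[m, ] > cuts[m]
            else co$values[m, ] < cuts[m]
    expect_equal(flags[m, ], setNames(as.integer(want), colnames(co$values)))
  }
})

test_that("domain thresholds maximize Youden J over integer counts", {
  set.seed(31)
  for (i in 1:10) {
    co <- randomCohort(20, 20, 5)
    flags <- (co$values > 0) * 1L
    doms <- setNames(c("d1", "d1", "d1", "d2", "d2"), rownames(flags))
    fit <- fitDomainThresholds(flags, co$case, doms)
    for (d in c("d1", "d2")) {
      tal <- colSums(flags[doms == d, , drop = FALSE])
      size <- sum(doms == d)
      J <- vapply(seq_len(size), function(k)
        mean(tal[co$case] >= k) + mean(tal[!co$case] < k) - 1, numeric(1))
      row <- fit[fit$domain == d, ]
      expect_equal(row$sensitivity + row$specificity - 1, max(J))
      # tie rule: smallest count among maximizers
      expect_equal(row$threshold, min(which(J == max(J))))
      expect_lte(row$threshold, size)
    }
  }
})

test_that("a single-marker domain reduces to the marker's own flag", {
  set.seed(32)
  co <- randomCohort(25, 25, 1, shift = 1.2)
  flags <- (co$values > 0.5) * 1L
  fit <- fitDomainThresholds(flags, co$case, c(m1 = "solo"))
  expect_equal(fit$threshold, 1L)
  expect_equal(fit$auc,
               aucPValue(empiricalROC(flags[1, ], co$case, "high"))$auc)
  expect_equal(fit$sensitivity, mean(flags[1, co$case] == 1))
})

test_that("cascade collapses to single-marker ROC in the degenerate case", {
  set.seed(33)
  co <- randomCohort(20, 20, 1, shift = 1.5)
  panel <- data.frame(name = "m1", domain = "only", direction = "high")
  m <- fitPanelModel(co$values, co$case, panel)
  r <- rocAnalysis(co$values[1, ], co$case, "high")
  expect_equal(m@variables$cutoff, r@cutoff)
  expect_equal(m@modelROC@sensitivity, r@sensitivity)
  expect_equal(m@modelROC@specificity, r@specificity)
  expect_equal(m@modelROC@accuracy, r@accuracy)
  expect_equal(m@threshold, 1L)
  lab <- classify(m, co$values)$label
  expect_equal(lab == "case",
               unname(co$values[1, ] > r@cutoff))
})

test_that("cascade separates a near-perfect cohort and not a null one", {
  panel <- defaultPanel(15)
  panel$target_auc <- 0.995; panel$missing_rate <- 0
  be <- simulateCohort(panel, seed = 34)
  m <- fitPanelModel(be)
  expect_equal(m@modelROC@sensitivity, 1)
  expect_equal(m@modelROC@specificity, 1)

  # in-sample refit inflates the null model AUC (cutoff optimism), so the
  # null calibration is assessed out-of-sample: fit on one null cohort,
  # evaluate the frozen rule on an independent one
  panel$target_auc <- 0.5 + 1e-9
  m <- fitPanelModel(simulateCohort(panel, seed = 35))
  fresh <- simulateCohort(panel, seed = 135)
  cnt <- scorePanel(m, fresh)$count
  auc <- aucPValue(empiricalROC(cnt, isCase(fresh), "high"))$auc
  se <- sqrt((67 + 67 + 1) / (12 * 67 * 67))
  expect_lt(abs(auc - 0.5), 3 * se)
})

test_that("classification is monotone in abnormality", {
  be <- simulateCohort(defaultPanel(15), seed = 36)
  m <- fitPanelModel(be)
  vals <- markerValues(be)
  sc0 <- scorePanel(m, vals)
  set.seed(37)
  for (i in 1:25) {
    j <- sample(nrow(vals), 1); s <- sample(ncol(vals), 1)
    v2 <- vals
    dir <- m@variables$direction[m@variables$name == rownames(vals)[j]]
    cut <- m@variables$cutoff[m@variables$name == rownames(vals)[j]]
    v2[j, s] <- if (dir == "high") cut + 10 else cut - 10 # force abnormal
    sc1 <- scorePanel(m, v2)
    expect_gte(sc1$count[s], sc0$count[s])
    if (!is.na(sc0$label[s]) && sc0$label[s] == "case")
      expect_equal(as.character(sc1$label[s]), "case")
  }
})

test_that("classify tallies a hand-worked toy cohort correctly", {
  panel <- toyPanel() # d1: m1,m2 high; d2: m3 low, m4 high
  vals <- matrix(c( # subjects in columns: s1..s4
    2,  2, -2,  0,   # m1 (high, cutoff will be ~1 on separated data)
    2, -2,  2,  0,   # m2
   -2,  2,  2,  0,   # m3 (low abnormal)
    2,  2,  2,  0),  # m4
    nrow = 4, byrow = TRUE,
    dimnames = list(panel$name, paste0("s", 1:4)))
  model <- methods::new("PanelModel",
    variables = data.frame(name = panel$name, domain = panel$domain,
                           direction = panel$direction,
                           cutoff = c(1, 1, -1, 1)),
    domains = data.frame(domain = c("d1", "d2"), size = c(2L, 2L),
                         threshold = c(2L, 1L)),
    threshold = 2L,
    modelROC = methods::new("ROCResult", auc = NA_real_, pValue = NA_real_,
      cutoff = 1.5, sensitivity = NA_real_, specificity = NA_real_,
      dor = NA_real_, accuracy = NA_real_, nObs = 0L, nCases = 0L,
      nControls = 0L, direction = "high"),
    options = list())
  # manual tally: s1 flags (1,1,1,1): d1 tally 2>=2 -> 1, d2 tally 2>=1 -> 1,
  #   count 2 -> case
  # s2 flags (1,0,0,1): d1 1 -> 0, d2 1 -> 1, count 1 -> control
  # s3 flags (0,1,0,1): d1 1 -> 0, d2 1 -> 1, count 1 -> control
  # s4 flags (0,0,0,0): count 0 -> control
  out <- classify(model, vals)
  expect_equal(out$count, c(2, 1, 1, 0))
  expect_equal(as.character(out$label),
               c("case", "control", "control", "control"))
})

test_that("fitting is deterministic given the cohort and options", {
  be <- simulateCohort(defaultPanel(21), seed = 38)
  m1 <- fitPanelModel(be); m2 <- fitPanelModel(be)
  expect_identical(m1@variables, m2@variables)
  expect_identical(m1@domains, m2@domains)
  expect_identical(m1@threshold, m2@threshold)
})

test_that("panel model round-trips through YAML and still classifies", {
  be <- simulateCohort(defaultPanel(15), seed = 39)
  m <- fitPanelModel(be)
  f <- tempfile(fileext = ".yaml")
  writePanelModel(m, f)
  m2 <- readPanelModel(f)
  expect_equal(m2@threshold, m@threshold)
  expect_equal(m2@variables$cutoff, m@variables$cutoff)
  expect_equal(classify(m2, be)$label, classify(m, be)$label)
})
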