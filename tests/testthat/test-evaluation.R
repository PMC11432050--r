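test_that("classification metrics match their definitions", {
  expect_identical(mcc(confusionCounts(10, 0, 1000, 0)), 1)
  expect_identical(mcc(confusionCounts(0, 10, 0, 10)), -1)
  # worked arithmetic: TP=8 FN=2 TN=95 FP=5 -> 750 / sqrt(13*10*100*97)
  expect_equal(mcc(confusionCounts(8, 5, 95, 2)),
               750 / sqrt(13 * 10 * 100 * 97), tolerance = 1e-12)
  expect_equal(tpr(confusionCounts(5, 0, 0, 5)), 0.5)
  expect_equal(tnr(confusionCounts(0, 10, 90, 0)), 0.9)
  # precision 0.8, recall 0.5 -> F = 8/13
  expect_equal(fScore(confusionCounts(8, 2, 0, 8)), 8 / 13,
               tolerance = 1e-12)
  # zero-denominator conventions
  expect_identical(mcc(confusionCounts(0, 0, 10, 0)), 0)
  expect_identical(tpr(confusionCounts(0, 0, 10, 0)), 0)
  expect_identical(fScore(confusionCounts(0, 0, 10, 0)), 0)
})

test_that("metrics agree with brute-force oracles on random confusion matrices", {
  set.seed(123)
  for (i in 1:1000) {
    cnt <- sample(0:25, 4, replace = TRUE)
    if (sum(cnt) == 0) cnt[1] <- 1
    cm <- confusionCounts(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(mcc(cm), oracleMccFromCounts(cnt[1], cnt[2], cnt[3], cnt[4]),
                 tolerance = 1e-10)
    expect_equal(tpr(cm), oracleTpr(cnt[1], cnt[4]), tolerance = 1e-10)
    expect_equal(tnr(cm), oracleTnr(cnt[3], cnt[2]), tolerance = 1e-10)
    expect_equal(fScore(cm), oracleF(cnt[1], cnt[2], cnt[4]),
                 tolerance = 1e-10)
  }
})

test_that("AUC is the all-pairs concordance probability", {
  expect_equal(rocAuc(c(0.9, 0.8, 0.4, 0.2), c("pos", "neg", "pos", "neg")),
               3 / 4)
  expect_identical(rocAuc(c(1, 1, 0, 0), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_identical(rocAuc(rep(0.3, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_error(rocAuc(1:3, c(TRUE, TRUE, TRUE)), "both classes")

  set.seed(42)
  for (i in 1:200) {
    n <- sample(5:40, 1)
    s <- round(runif(n), sample(1:3, 1))  # induce ties
    lab <- runif(n) < 0.4
    if (!any(lab)) lab[1] <- TRUE
    if (all(lab)) lab[1] <- FALSE
    expect_equal(rocAuc(s, lab), oracleAuc(s, lab), tolerance = 1e-10)
    # invariance under strictly monotone transforms
    expect_equal(rocAuc(exp(3 * s), lab), rocAuc(s, lab), tolerance = 1e-10)
  }
})

test_that("thresholded confusion uses a strict greater-than rule", {
  s <- c(-0.5, 0, 0.2, 0.5, 0.7, 1)
  lab <- c(FALSE, FALSE, TRUE, FALSE, TRUE, TRUE)
  cmAll <- confusionAtThreshold(s, lab, -1 - 1e-9)
  expect_identical(cmAll@tp + cmAll@fp, 6)
  cmNone <- confusionAtThreshold(s, lab, 1)
  expect_identical(cmNone@tp + cmNone@fp, 0)
  cm <- confusionAtThreshold(s, lab, 0.5)
  expect_identical(c(cm@tp, cm@fp, cm@tn, cm@fn), c(2, 0, 3, 1))
  # score exactly at the threshold is not predicted positive; the lone
  # decoy above 0 is the single false positive
  expect_identical(confusionAtThreshold(s, lab, 0)@fp, 1)
  expect_identical(confusionAtThreshold(s, lab, 0)@tn, 2)
})

test_that("enrichment factor follows the ratio definition", {
  scores <- c(rep(1, 10), runif(990, 0, 0.5))
  labels <- c(rep(TRUE, 10), rep(FALSE, 990))
  expect_equal(enrichmentFactor(scores, labels, 0.01), 100)
  expect_equal(enrichmentFactor(scores, labels, 1), 1)
  # random scores: EF ~ 1 in expectation
  set.seed(77)
  efs <- replicate(200, {
    s <- runif(400)
    lab <- rep(c(TRUE, FALSE), c(40, 360))
    enrichmentFactor(s, lab, 0.1)
  })
  expect_lt(abs(mean(efs) - 1), 0.15)
  expect_error(enrichmentFactor(1:3, c(FALSE, FALSE, FALSE), 0.5),
               "at least one positive")
})

test_that("threshold selection maximizes TP/FP preferring low cutoffs", {
  # separable: the lowest threshold with FP = 0 wins
  s <- c(0.9, 0.8, 0.75, 0.3, 0.2)
  lab <- c(TRUE, TRUE, TRUE, FALSE, FALSE)
  expect_equal(selectThreshold(s, lab), 0.3)
  # constructed case checked against a brute-force grid scan
  set.seed(5)
  s2 <- runif(10, -1, 1)
  lab2 <- runif(10) < 0.5
  if (!any(lab2)) lab2[1] <- TRUE
  grid <- c(0, seq(0.1, 0.9, 0.1))
  ratios <- vapply(grid, function(t) {
    tp <- sum(s2 > t & lab2); fp <- sum(s2 > t & !lab2)
    if (fp == 0) Inf else tp / fp
  }, numeric(1))
  expect_identical(selectThreshold(s2, lab2, grid),
                   grid[which.max(ratios)])
  expect_identical(selectThreshold(s, lab, grid = 0.4), 0.4)
})

test_that("cutoff reports tally successful and new predictions", {
  # hand-checkable fixture
  st <- data.frame(molecule_id = sprintf("d%02d", 1:10), model_id = "m",
                   score = c(0.95, 0.85, 0.75, 0.65, 0.55, 0.45, 0.35,
                             0.25, 0.15, -0.2))
  known <- data.frame(molecule_id = c("d01", "d03", "d09"), model_id = "m")
  rep <- cutoffReport(st, known)
  expect_identical(rep$rule[1], ">")
  expect_identical(rep$n_successful[1], 3L)   # all three known score > 0
  expect_identical(rep$n_new[1], 6L)
  expect_identical(rep$n_successful[rep$cutoff == 0.8], 1L)  # only d01
  expect_identical(rep$n_new[rep$cutoff == 0.8], 1L)         # only d02
  expect_equal(rep$pct_successful[1], 100)
  # counts non-increasing in the cutoff
  expect_true(all(diff(rep$n_successful) <= 0))
  expect_true(all(diff(rep$n_new) <= 0))
  # empty known set reports 0 percent with a note
  rep0 <- cutoffReport(st, known[0, ])
  expect_true(all(rep0$n_successful == 0L))
  expect_true(all(rep0$pct_successful == 0))
  expect_match(attr(rep0, "note"), "no known pairs")
})

test_that("cutoff-report bookkeeping holds on generated fixtures", {
  for (s in 1:25) {
    fx <- generateScoreFixture(nDrugs = 40, nTargets = 3, fracKnown = 0.3,
                               seed = s)
    rep <- cutoffReport(fx$scores, fx$known)
    expect_true(all(diff(rep$n_successful) <= 0))
    expect_true(all(diff(rep$n_new) <= 0))
    # successful + new = total predicted at each cutoff
    for (i in seq_len(nrow(rep))) {
      pred <- if (i == 1) sum(fx$scores$score > rep$cutoff[i])
              else sum(fx$scores$score >= rep$cutoff[i])
      expect_identical(rep$n_successful[i] + rep$n_new[i], pred)
    }
  }
})

test_that("cross-validation is stratified, deterministic and separates signal", {
  gen <- tinyPlantedSet(nPos = 30, nNeg = 600, seed = 12)
  cfg <- iseConfig(nBins = 3, kMin = 2, kMax = 2, maxModelFilters = 10)
  cv <- suppressMessages(crossValidate(gen$learningSet, cfg, k = 5,
                                       seed = 9))
  expect_s4_class(cv, "CVReport")
  expect_identical(nrow(cv@folds), 5L)
  expect_gt(cv@means[["mcc"]], 0.5)
  cv2 <- suppressMessages(crossValidate(gen$learningSet, cfg, k = 5,
                                        seed = 9))
  expect_identical(cv@folds, cv2@folds)
  expect_error(crossValidate(gen$learningSet, cfg, k = 50), "at least")
})
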