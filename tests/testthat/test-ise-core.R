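test_that("discretization enumerates b(b+1)/2 contiguous ranges", {
  # constant descriptor: one degenerate bin, one range
  tab <- DescriptorTable(matrix(c(5, 5, 5, 1, 2, 3), 3, 2,
                                dimnames = list(paste0("m", 1:3),
                                                c("const", "x"))))
  sc <- discretize(tab, nBins = 3)
  rc <- sc@ranges[sc@ranges$descriptor == 1, ]
  expect_identical(nrow(rc), 1L)
  expect_identical(c(rc$lo, rc$hi), c(5, 5))

  # uniform 1..100, 4 bins: interior boundaries at the type-7 quartiles
  tab2 <- DescriptorTable(matrix(1:100, 100, 1,
                                 dimnames = list(sprintf("m%03d", 1:100), "u")))
  sc2 <- discretize(tab2, nBins = 4)
  expect_equal(sc2@boundaries[[1]][2:4], c(25.75, 50.5, 75.25))
  expect_identical(nrow(sc2@ranges), 10L)  # b=4 -> 10 ranges

  # b bins -> b(b+1)/2 ranges for assorted bin counts
  set.seed(2)
  tab3 <- DescriptorTable(matrix(runif(400), 100, 4,
                                 dimnames = list(sprintf("m%03d", 1:100),
                                                 paste0("d", 1:4))))
  for (b in c(1, 2, 3, 6)) {
    sc3 <- discretize(tab3, nBins = b)
    expect_identical(nrow(sc3@ranges), as.integer(4 * b * (b + 1) / 2))
  }
})

test_that("random filters respect size, distinctness and alive flags", {
  set.seed(11)
  tab <- DescriptorTable(matrix(runif(500), 100, 5,
                                dimnames = list(sprintf("m%03d", 1:100),
                                                paste0("d", 1:5))))
  sc <- discretize(tab, nBins = 3)
  f <- sampleRandomFilter(sc, 2, 2)
  expect_identical(nrow(f), 2L)
  expect_identical(anyDuplicated(f$descriptor), 0L)

  set.seed(99)
  a <- replicate(5, sampleRandomFilter(sc, 2, 4), simplify = FALSE)
  set.seed(99)
  b <- replicate(5, sampleRandomFilter(sc, 2, 4), simplify = FALSE)
  expect_identical(a, b)

  # kill every range of d3: it must never be sampled again
  sc@ranges$alive[sc@ranges$descriptor == 3] <- FALSE
  set.seed(1)
  drawn <- unlist(lapply(1:2000, function(i)
    sampleRandomFilter(sc, 2, 3)$descriptor))
  expect_false("d3" %in% drawn)

  sc@ranges$alive <- FALSE
  expect_error(sampleRandomFilter(sc, 2, 3), "exhausted")
})

test_that("filter evaluation matches brute-force membership counts", {
  gen <- tinyPlantedSet()
  ls <- gen$learningSet
  v <- descriptorValues(learningTable(ls))
  pos <- rownames(v) %in% positives(ls)

  perf <- evaluateFilter(gen$box, ls)
  cnt <- oracleFilterCounts(v, gen$box, pos)
  expect_identical(perf$cm@tp, as.numeric(cnt["tp"]))
  expect_identical(perf$cm@fp, as.numeric(cnt["fp"]))
  expect_identical(perf$cm@tp, as.numeric(length(positives(ls))))  # noiseSd 0
  expect_gt(perf$mcc, 0.8)

  # a filter passing nothing: zero-denominator convention gives MCC 0
  none <- data.frame(descriptor = "D01", lo = 2, hi = 3)
  expect_identical(evaluateFilter(none, ls)$mcc, 0)
  # a filter passing everything: degenerate column, MCC 0
  all <- data.frame(descriptor = "D01", lo = -1, hi = 2)
  pAll <- evaluateFilter(all, ls)
  expect_identical(pAll$mcc, 0)
  expect_identical(tnr(pAll$cm), 0)
  expect_identical(tpr(pAll$cm), 1)
  expect_error(evaluateFilter(data.frame(descriptor = "nope", lo = 0, hi = 1),
                              ls), "nope")
})

test_that("batch population evaluation agrees with single-filter oracle", {
  gen <- tinyPlantedSet()
  ls <- gen$learningSet
  sc <- discretize(ls, nBins = 3)
  set.seed(4)
  pop <- sampleFilterPopulation(sc, ls, R = 200, kMin = 2, kMax = 3)
  v <- descriptorValues(learningTable(ls))
  pos <- rownames(v) %in% positives(ls)
  r <- sc@ranges
  for (f in c(1L, 57L, 200L)) {
    rid <- pop@rangeId[pop@fid == f]
    conds <- data.frame(descriptor = sc@descriptors[r$descriptor[rid]],
                        lo = r$lo[rid], hi = r$hi[rid])
    cnt <- oracleFilterCounts(v, conds, pos)
    expect_identical(pop@tp[f], unname(cnt["tp"]))
    expect_identical(pop@fp[f], unname(cnt["fp"]))
    expect_equal(pop@mcc[f],
                 oracleMccFromCounts(cnt["tp"], cnt["fp"],
                                     sum(!pos) - cnt["fp"],
                                     sum(pos) - cnt["tp"]),
                 tolerance = 1e-12)
  }
})

test_that("elimination kills bottom-concentrated values and guards the floor", {
  tab <- DescriptorTable(matrix(runif(300), 100, 3,
                                dimnames = list(sprintf("m%03d", 1:100),
                                                paste0("d", 1:3))))
  sc <- discretize(tab, nBins = 2)  # 3 ranges per descriptor
  nR <- nrow(sc@ranges)
  # 400 filters of one condition each; range 1 occupies the 40 worst,
  # every other range spread evenly across the rest
  nF <- 400L
  mcc <- seq(-1, 1, length.out = nF)
  rangeId <- integer(nF)
  rangeId[1:40] <- 1L
  rangeId[41:nF] <- rep(2:nR, length.out = nF - 40L)
  pop <- new("FilterPopulation", fid = seq_len(nF), rangeId = rangeId,
             mcc = mcc, tp = rep(1L, nF), fp = rep(1L, nF),
             nPos = 10L, nNeg = 100L)
  el <- eliminationStep(sc, pop, topFrac = 0.1, bottomFrac = 0.1,
                        alpha = 0.01, minAliveDescriptors = 2)
  # usage 40, all 40 occurrences in the bottom 40: p-value ~ 0.1^40
  expect_identical(nrow(el$killed), 1L)
  expect_false(el$scheme@ranges$alive[1])
  expect_lt(el$killed$pval, 1e-30)

  # a value spread evenly over the ranking is retained
  expect_true(all(el$scheme@ranges$alive[-1]))

  # alpha = 0 never kills
  el0 <- eliminationStep(sc, pop, alpha = 0, minAliveDescriptors = 2)
  expect_identical(nrow(el0$killed), 0L)

  # too small a population is refused
  small <- new("FilterPopulation", fid = 1:10, rangeId = rep(1L, 10),
               mcc = runif(10, -1, 1), tp = rep(1L, 10), fp = rep(1L, 10),
               nPos = 5L, nNeg = 50L)
  expect_error(eliminationStep(sc, small), "too small")

  # the guard refuses to drop below minAliveDescriptors descriptors
  sc2 <- sc
  sc2@ranges$alive <- FALSE
  sc2@ranges$alive[sc2@ranges$descriptor %in% 1:2][c(1, 4)] <- TRUE
  aliveRid <- which(sc2@ranges$alive)
  popBad <- new("FilterPopulation", fid = seq_len(nF),
                rangeId = rep(aliveRid, length.out = nF)[order(
                  rep(aliveRid, length.out = nF) != aliveRid[1])],
                mcc = mcc, tp = rep(1L, nF), fp = rep(1L, nF),
                nPos = 10L, nNeg = 100L)
  el2 <- eliminationStep(sc2, popBad, minAliveDescriptors = 2)
  expect_gte(length(unique(
    el2$scheme@ranges$descriptor[el2$scheme@ranges$alive])), 2L)
})

test_that("combination counting is exact and matches enumeration", {
  set.seed(5)
  tab <- DescriptorTable(matrix(runif(400), 100, 4,
                                dimnames = list(sprintf("m%03d", 1:100),
                                                paste0("d", 1:4))))
  sc <- discretize(tab, nBins = 3)  # 6 ranges per descriptor
  expect_identical(countRemainingCombinations(sc, 2, 2), choose(4, 2) * 36)
  # brute-force oracle over subsets
  brute <- 0
  for (k in 2:3) {
    for (ds in as.data.frame(utils::combn(1:4, k)))
      brute <- brute + prod(rep(6, k))
  }
  expect_identical(countRemainingCombinations(sc, 2, 3), brute)
  # killing all values of one descriptor
  sc@ranges$alive[sc@ranges$descriptor == 4] <- FALSE
  expect_identical(countRemainingCombinations(sc, 2, 2), choose(3, 2) * 36)
  # degenerate single descriptor, single value
  sc@ranges$alive <- FALSE
  sc@ranges$alive[1] <- TRUE
  expect_identical(countRemainingCombinations(sc, 1, 1), 1)
})

test_that("exhaustive search reproduces the brute-force ranking", {
  gen <- tinyPlantedSet()
  ls <- gen$learningSet
  sc <- discretize(ls, nBins = 2)  # 3 ranges x 4 descriptors
  res <- exhaustiveSearch(sc, ls, 2, 2)
  oracle <- oracleEnumerate(sc, ls, 2, 2)
  expect_identical(nrow(res$performance), nrow(oracle))
  # identical ranked MCC vector
  expect_equal(res$performance$mcc, sort(oracle$mcc, decreasing = TRUE),
               tolerance = 1e-12)
  # identical filter -> mcc mapping
  keys <- vapply(split(res$conditions, res$conditions$filter), filterKey, "")
  got <- data.frame(key = keys, mcc = res$performance$mcc[
    as.integer(names(keys))])
  merged <- merge(got, oracle, by = "key")
  expect_identical(nrow(merged), nrow(oracle))
  expect_equal(merged$mcc.x, merged$mcc.y, tolerance = 1e-12)
  # refuses oversized spaces
  expect_error(exhaustiveSearch(sc, ls, 2, 2, exhaustiveThreshold = 10),
               "too large")
})

test_that("indistinguishable positives and decoys give MCC 0 everywhere", {
  # each positive duplicated as 10 decoys: all pass fractions proportional
  set.seed(8)
  vp <- matrix(runif(20 * 2), 20, 2, dimnames = list(sprintf("p%02d", 1:20),
                                                     c("d1", "d2")))
  vd <- vp[rep(1:20, each = 10), ]
  rownames(vd) <- sprintf("n%03d", 1:200)
  tab <- DescriptorTable(rbind(vp, vd))
  ls <- new("LearningSet", positives = rownames(vp), decoys = rownames(vd),
            table = tab, targetId = "t", action = "agonist", ratio = 10)
  res <- exhaustiveSearch(discretize(ls, nBins = 2, "learning"), ls, 2, 2)
  expect_true(all(abs(res$performance$mcc) < 1e-12))
})

test_that("runIse on a small space equals exhaustive search plus weighting", {
  gen <- tinyPlantedSet()
  ls <- gen$learningSet
  cfg <- iseConfig(nBins = 3, kMin = 2, kMax = 2, seed = 31,
                   binSource = "learning")
  m <- suppressMessages(runIse(ls, cfg))
  res <- exhaustiveSearch(discretize(ls, nBins = 3, "learning"), ls, 2, 2)
  keep <- which(res$performance$mcc >= cfg$minFilterMcc)
  keep <- keep[seq_len(min(length(keep), cfg$maxModelFilters))]
  expect_equal(m@trainMcc, res$performance$mcc[keep], tolerance = 1e-12)
  expect_identical(m@wPass, m@trainMcc)  # MCC weighting
  expect_identical(m@metadata$iterations, 0L)  # loop skipped

  # deterministic: identical serialized model for the same seed
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  saveModel(suppressMessages(runIse(ls, cfg)), f1)
  saveModel(suppressMessages(runIse(ls, cfg)), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the elimination loop shrinks the space monotonically and recovers the signal", {
  set.seed(21)
  gen <- generatePlantedLearningSet(nPositives = 40, ratio = 25,
                                    nDescriptors = 8, seed = 21)
  ls <- gen$learningSet
  sc <- discretize(ls, nBins = 6)
  counts <- countRemainingCombinations(sc, 2, 3)
  set.seed(33)
  for (i in 1:6) {
    pop <- sampleFilterPopulation(sc, ls, 1500, 2, 3)
    el <- eliminationStep(sc, pop, minAliveDescriptors = 2)
    sc <- el$scheme
    counts <- c(counts, countRemainingCombinations(sc, 2, 3))
    if (nrow(el$killed) > 0)
      expect_lt(counts[i + 1], counts[i])
    else expect_identical(counts[i + 1], counts[i])
  }
  expect_true(all(diff(counts) <= 0))

  # full run on a space above the threshold exercises the loop and finds
  # the planted descriptors
  cfg <- iseConfig(nBins = 6, kMin = 2, kMax = 3, exhaustiveThreshold = 20000,
                   maxIterations = 40, maxModelFilters = 10, R = 1500,
                   seed = 77)
  m <- suppressMessages(runIse(ls, cfg))
  expect_gt(m@metadata$iterations, 0L)
  planted <- gen$signal$descriptors
  expect_gt(mean(m@conditions$descriptor %in% planted), 0.5)
  expect_true(all(m@trainMcc >= cfg$minFilterMcc))
  expect_true(all(m@wPass > 0 & m@wPass <= 1))
})

test_that("runIse refuses when no filter discriminates", {
  set.seed(14)
  gen <- generatePlantedLearningSet(nPositives = 25, ratio = 20,
                                    nDescriptors = 4, seed = 14)
  ls <- permuteLabels(gen$learningSet)
  cfg <- iseConfig(nBins = 2, kMin = 2, kMax = 2, minFilterMcc = 0.9,
                   seed = 3)
  expect_error(suppressMessages(runIse(ls, cfg)), "no discriminating filters")
})
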