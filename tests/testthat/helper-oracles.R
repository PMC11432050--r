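## Independent brute-force oracles and small fixtures shared across tests.
## These deliberately avoid the package's own code paths.

## MCC via the phi coefficient: Pearson correlation of 0/1 prediction and
## label vectors expanded from the confusion counts.
oracleMccFromCounts <- function(tp, fp, tn, fn) {
  pred <- c(rep(1, tp), rep(1, fp), rep(0, tn), rep(0, fn))
  lab <- c(rep(1, tp), rep(0, fp), rep(0, tn), rep(1, fn))
  if (length(unique(pred)) < 2L || length(unique(lab)) < 2L) return(0)
  stats::cor(pred, lab)
}

oracleTpr <- function(tp, fn) if (tp + fn == 0) 0 else tp / (tp + fn)
oracleTnr <- function(tn, fp) if (tn + fp == 0) 0 else tn / (tn + fp)
oracleF <- function(tp, fp, fn) {
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

## AUC as all-pairs concordance, O(n_pos * n_neg).
oracleAuc <- function(scores, lab) {
  sp <- scores[lab]
  sn <- scores[!lab]
  tot <- 0
  for (x in sp) tot <- tot + sum(x > sn) + 0.5 * sum(x == sn)
  tot / (length(sp) * length(sn))
}

## Brute-force evaluation of one conjunctive filter on a value matrix.
oracleFilterCounts <- function(values, conds, pos) {
  pass <- rep(TRUE, nrow(values))
  for (i in seq_len(nrow(conds))) {
    x <- values[, conds$descriptor[i]]
    pass <- pass & x >= conds$lo[i] & x <= conds$hi[i]
  }
  c(tp = sum(pass & pos), fp = sum(pass & !pos))
}

## Enumerate every k-condition filter over the alive ranges of a scheme and
## rank by MCC (descending) -- the reference for exhaustive-search tests.
oracleEnumerate <- function(scheme, ls, kMin, kMax) {
  v <- descriptorValues(learningTable(ls))
  pos <- rownames(v) %in% positives(ls)
  nP <- sum(pos); nN <- sum(!pos)
  r <- scheme@ranges
  aliveByDesc <- split(which(r$alive), r$descriptor[r$alive])
  descIdx <- as.integer(names(aliveByDesc))
  out <- list()
  n <- 0L
  for (k in kMin:kMax) {
    if (length(descIdx) < k) next
    for (ds in as.data.frame(utils::combn(seq_along(descIdx), k))) {
      grid <- expand.grid(aliveByDesc[ds], KEEP.OUT.ATTRS = FALSE)
      for (i in seq_len(nrow(grid))) {
        rid <- as.integer(grid[i, ])
        conds <- data.frame(
          descriptor = scheme@descriptors[r$descriptor[rid]],
          lo = r$lo[rid], hi = r$hi[rid])
        cnt <- oracleFilterCounts(v, conds, pos)
        m <- oracleMccFromCounts(cnt["tp"], cnt["fp"],
                                 nN - cnt["fp"], nP - cnt["tp"])
        n <- n + 1L
        out[[n]] <- list(key = paste(
          sort(sprintf("%s|%.17g|%.17g", conds$descriptor, conds$lo,
                       conds$hi)), collapse = ";"), mcc = m)
      }
    }
  }
  data.frame(key = vapply(out, `[[`, "", "key"),
             mcc = vapply(out, `[[`, 0, "mcc"))
}

## canonical key of a model/search filter for oracle comparison
filterKey <- function(conds) {
  paste(sort(sprintf("%s|%.17g|%.17g", conds$descriptor, conds$lo,
                     conds$hi)), collapse = ";")
}

## A small fully separable learning set: positives in a box on the first
## two of four descriptors, decoys outside.
tinyPlantedSet <- function(nPos = 25, nNeg = 250, seed = 1) {
  set.seed(seed)
  gen <- generatePlantedLearningSet(
    nPositives = nPos, ratio = nNeg / nPos, nDescriptors = 4,
    signal = plantedSignal(nPlanted = 2, noiseSd = 0), seed = seed)
  gen
}

## Benchmark configuration used by the recovery / null experiments
## (motivated in the methods vignette).
benchConfig <- function(...) {
  iseConfig(nBins = 6, kMin = 2, kMax = 3, maxIterations = 40,
            maxModelFilters = 10, ...)
}

## fixture SMILES used by chem-io / similarity tests
FIX_SMILES <- c(
  ethanol = "CCO",
  benzene = "c1ccccc1",
  acetic = "CC(=O)O",
  acetyl_chloride = "CC(=O)Cl",
  aspirin = "CC(=O)Oc1ccccc1C(=O)O",
  caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
  sodium_acetate = "CC(=O)[O-].[Na+]"
)
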