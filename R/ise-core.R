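## The Iterative Stochastic Elimination (ISE) algorithm.
##
## Descriptors are discretized into equal-frequency bins; every contiguous
## bin-range is a candidate "variable value". Random conjunctive filters are
## sampled from the alive values, screened against the learning set, and
## values that contribute consistently to the worst filters are eliminated.
## When the surviving combination count is manageable, all remaining filters
## are enumerated exhaustively and the best become the model.

#' ISE configuration
#'
#' Central, validated parameter set for model training. None of these knobs
#' is dictated by the method itself; defaults are package choices documented
#' in the methods vignette.
#'
#' @param nBins equal-frequency bins per descriptor (default 6; `b` bins
#'   yield `b(b+1)/2` candidate ranges).
#' @param kMin,kMax number of conditions per filter (defaults 2 and 5).
#' @param R random filters sampled per elimination iteration (default 3000).
#' @param alpha significance level of the elimination test (default 0.01).
#' @param topFrac,bottomFrac fractions of the ranked population counted as
#'   best/worst filters (defaults 0.1).
#' @param maxIterations cap on elimination iterations (default 20).
#' @param exhaustiveThreshold largest combination count accepted for the
#'   final exhaustive enumeration (default 200000).
#' @param minFilterMcc minimum training MCC for a filter to enter the model
#'   (default 0.2).
#' @param maxModelFilters model size cap (default 100).
#' @param uniformWeights use weight 1 for every filter instead of its
#'   training MCC.
#' @param minPopulation smallest population eliminationStep accepts
#'   (default 100).
#' @param binSource bin-boundary source passed to [discretize()]
#'   (default `"positives"`).
#' @param seed optional integer seed governing every stochastic step.
#' @return a validated list of class `"iseConfig"`.
#' @export
iseConfig <- function(nBins = 6, kMin = 2, kMax = 5, R = 3000,
                      alpha = 0.01, topFrac = 0.1, bottomFrac = 0.1,
                      maxIterations = 20, exhaustiveThreshold = 200000,
                      minFilterMcc = 0.2, maxModelFilters = 100,
                      uniformWeights = FALSE, minPopulation = 100,
                      binSource = c("positives", "learning"),
                      seed = NULL) {
  binSource <- match.arg(binSource)
  stopifnot(nBins >= 1, kMin >= 1, kMax >= kMin, R >= 1,
            alpha >= 0, alpha <= 1, topFrac > 0, topFrac <= 0.5,
            bottomFrac > 0, bottomFrac <= 0.5, maxIterations >= 0,
            exhaustiveThreshold >= 1, minFilterMcc > 0, minFilterMcc <= 1,
            maxModelFilters >= 1, minPopulation >= 1)
  structure(list(nBins = nBins, kMin = kMin, kMax = kMax, R = R,
                 alpha = alpha, topFrac = topFrac, bottomFrac = bottomFrac,
                 maxIterations = maxIterations,
                 exhaustiveThreshold = exhaustiveThreshold,
                 minFilterMcc = minFilterMcc,
                 maxModelFilters = maxModelFilters,
                 uniformWeights = uniformWeights,
                 minPopulation = minPopulation, binSource = binSource,
                 seed = seed),
            class = "iseConfig")
}

#' Discretize descriptors into candidate value-ranges
#'
#' Bin boundaries sit at equal-frequency quantiles (type 7); duplicate
#' boundaries are merged, so a constant descriptor yields a single
#' degenerate bin. All contiguous bin-ranges are enumerated as candidate
#' filter conditions, each materialized as the closed numeric interval from
#' its first bin's lower boundary to its last bin's upper boundary.
#'
#' For a [LearningSet] the default `binSource = "positives"` computes the
#' quantiles from the known actives only: filters describe the actives'
#' property ranges, and under heavy 1:100 imbalance pooled quantiles are
#' placed almost entirely by the decoys and cannot resolve where the
#' actives actually lie (the applicability-domain philosophy applied to
#' binning). `binSource = "learning"` uses all rows and is the behaviour
#' for a bare [DescriptorTable].
#'
#' @param x a [DescriptorTable] or [LearningSet].
#' @param nBins target number of bins per descriptor (default 6).
#' @param binSource `"positives"` (actives' quantiles; LearningSet only) or
#'   `"learning"` (all rows).
#' @return a [DiscretizationScheme] with all ranges alive.
#' @export
discretize <- function(x, nBins = 6,
                       binSource = c("positives", "learning")) {
  binSource <- match.arg(binSource)
  tab <- if (is(x, "LearningSet")) x@table else x
  stopifnot(is(tab, "DescriptorTable"), nBins >= 1)
  v <- tab@values
  if (is(x, "LearningSet") && binSource == "positives")
    v <- v[x@positives, , drop = FALSE]
  if (!nrow(v)) stop("empty descriptor table")
  descs <- colnames(v)
  boundaries <- lapply(seq_along(descs), function(j) {
    q <- quantile(v[, j], probs = seq(0, 1, length.out = nBins + 1),
                  names = FALSE, type = 7L)
    u <- unique(q)
    if (length(u) == 1L) u <- c(u, u)
    u
  })
  rows <- vector("list", length(descs))
  for (j in seq_along(descs)) {
    b <- length(boundaries[[j]]) - 1L
    lo <- hi <- integer(0)
    for (i in seq_len(b)) for (k in i:b) { lo <- c(lo, i); hi <- c(hi, k) }
    rows[[j]] <- data.frame(descriptor = j, loBin = lo, hiBin = hi,
                            lo = boundaries[[j]][lo],
                            hi = boundaries[[j]][hi + 1L])
  }
  ranges <- do.call(rbind, rows)
  ranges$alive <- TRUE
  new("DiscretizationScheme", descriptors = descs,
      boundaries = boundaries, ranges = ranges)
}

## list of alive range row-indices per descriptor index
.aliveIdx <- function(scheme) {
  alive <- which(scheme@ranges$alive)
  split(alive, factor(scheme@ranges$descriptor[alive],
                      levels = seq_along(scheme@descriptors)))
}

#' Sample a random filter from the alive candidate ranges
#'
#' Draws the filter size uniformly from `[kMin, kMax]` (capped at the number
#' of descriptors that still have alive values), then distinct descriptors
#' uniformly among those, then one alive range uniformly per descriptor.
#' Uses the ambient RNG stream, so sequences are reproducible under
#' [set.seed()].
#'
#' @param scheme a [DiscretizationScheme].
#' @param kMin,kMax filter size bounds.
#' @return data.frame of conditions (`descriptor`, `lo`, `hi`) with the
#'   selected range row ids as attribute `"rangeId"`.
#' @export
sampleRandomFilter <- function(scheme, kMin = 2, kMax = 5) {
  idx <- .aliveIdx(scheme)
  aliveDesc <- which(lengths(idx) > 0L)
  if (length(aliveDesc) < kMin) stop("search space exhausted")
  k <- min(resample(kMin:kMax, 1L), length(aliveDesc))
  ds <- resample(aliveDesc, k)
  rid <- vapply(idx[ds], function(ix) ix[sample.int(length(ix), 1L)],
                integer(1L))
  r <- scheme@ranges[rid, ]
  out <- data.frame(descriptor = scheme@descriptors[r$descriptor],
                    lo = r$lo, hi = r$hi)
  attr(out, "rangeId") <- rid
  out
}

## Sample R filters; returns parallel integer vectors (fid, rangeId),
## grouped contiguously by fid. Fully vectorized: descriptor picks via
## repeated max.col on a random key matrix, range picks via offset lookup.
.samplePopulation <- function(scheme, R, kMin, kMax) {
  idx <- .aliveIdx(scheme)
  aliveDesc <- which(lengths(idx) > 0L)
  nd <- length(aliveDesc)
  if (nd < kMin) stop("search space exhausted")
  ks <- pmin(resample(kMin:kMax, R, replace = TRUE), nd)
  maxk <- max(ks)
  keys <- matrix(runif(R * nd), R, nd)
  picks <- matrix(0L, R, maxk)
  for (j in seq_len(maxk)) {
    sel <- max.col(keys, ties.method = "first")
    picks[, j] <- sel
    keys[cbind(seq_len(R), sel)] <- -Inf
  }
  m <- t(picks)                       # maxk x R; columns = filters
  keep <- row(m) <= ks[col(m)]
  dpos <- m[keep]                     # position within aliveDesc, fid-grouped
  cnt <- lengths(idx)[aliveDesc]
  off <- c(0L, cumsum(cnt))
  flat <- unlist(idx[aliveDesc], use.names = FALSE)
  u <- pmax(1L, ceiling(runif(length(dpos)) * cnt[dpos]))
  list(fid = rep(seq_len(R), ks), rangeId = flat[off[dpos] + u])
}

## MCC from TP/FP count vectors, zero-denominator convention MCC = 0.
.mccFromCounts <- function(tp, fp, nPos, nNeg) {
  tp <- as.numeric(tp)
  fp <- as.numeric(fp)
  fn <- as.numeric(nPos) - tp
  tn <- as.numeric(nNeg) - fp
  num <- tp * tn - fp * fn
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  ifelse(den == 0, 0, num / den)
}

## Batch evaluation of condition rows (fid sorted ascending) on a learning
## set; returns a FilterPopulation.
.evalPopulation <- function(scheme, fid, rangeId, ls) {
  v <- ls@table@values[, scheme@descriptors, drop = FALSE]
  pos <- rownames(v) %in% ls@positives
  len <- tabulate(fid)
  start <- c(0L, cumsum(len))[seq_along(len)]
  r <- scheme@ranges
  counts <- cpp_eval_filters(v, as.integer(r$descriptor - 1L), r$lo, r$hi,
                             as.integer(start), as.integer(len),
                             as.integer(rangeId - 1L), pos)
  nPos <- sum(pos)
  nNeg <- sum(!pos)
  new("FilterPopulation", fid = as.integer(fid),
      rangeId = as.integer(rangeId),
      mcc = .mccFromCounts(counts[, 1L], counts[, 2L], nPos, nNeg),
      tp = counts[, 1L], fp = counts[, 2L],
      nPos = as.integer(nPos), nNeg = as.integer(nNeg))
}

#' Sample and evaluate a random filter population
#'
#' One ISE sampling round: `R` random filters drawn from the scheme's alive
#' values and screened against the learning set.
#'
#' @param scheme a [DiscretizationScheme].
#' @param ls a [LearningSet].
#' @param R population size.
#' @param kMin,kMax filter size bounds.
#' @return a [FilterPopulation].
#' @export
sampleFilterPopulation <- function(scheme, ls, R = 3000, kMin = 2, kMax = 5) {
  pop <- .samplePopulation(scheme, R, kMin, kMax)
  .evalPopulation(scheme, pop$fid, pop$rangeId, ls)
}

#' Evaluate a single filter against a learning set
#'
#' Positive prediction = the molecule satisfies every condition (closed
#' intervals). MCC uses the zero-denominator convention (0 when any
#' marginal is empty).
#'
#' @param filter data.frame of conditions (`descriptor`, `lo`, `hi`).
#' @param ls a [LearningSet].
#' @return list with elements `cm` (a [ConfusionMatrix]) and `mcc`.
#' @export
evaluateFilter <- function(filter, ls) {
  stopifnot(is(ls, "LearningSet"))
  v <- ls@table@values
  missing <- setdiff(filter$descriptor, colnames(v))
  if (length(missing))
    stop("descriptor(s) absent from learning table: ",
         paste(missing, collapse = ", "))
  pass <- rep(TRUE, nrow(v))
  for (i in seq_len(nrow(filter))) {
    x <- v[, filter$descriptor[i]]
    pass <- pass & x >= filter$lo[i] & x <= filter$hi[i]
  }
  pos <- rownames(v) %in% ls@positives
  cm <- confusionCounts(tp = sum(pass & pos), fp = sum(pass & !pos),
                        tn = sum(!pass & !pos), fn = sum(!pass & pos))
  list(cm = cm, mcc = mcc(cm))
}

#' Eliminate candidate values over-represented in bad filters
#'
#' Ranks the population by MCC and, for every alive value, counts its
#' occurrences in the bottom and top fractions. A value is killed when a
#' one-sided binomial test of its bottom-fraction count (against the share
#' expected from its usage, p0 = `bottomFrac`) is significant at `alpha`
#' AND its top-fraction count does not exceed the expected share. Kills are
#' applied in order of increasing p-value; a kill that would leave fewer
#' than `minAliveDescriptors` descriptors with alive values is skipped, so
#' the search space never collapses below the minimum filter size.
#'
#' @param scheme a [DiscretizationScheme].
#' @param population a [FilterPopulation] drawn from `scheme`.
#' @param topFrac,bottomFrac ranked fractions counted as best/worst.
#' @param alpha significance level (`alpha = 0` never kills).
#' @param minAliveDescriptors lower bound on descriptors with alive values
#'   (set this to the filter size minimum).
#' @param minPopulation smallest population size accepted.
#' @return list with the updated `scheme` and a data.frame `killed`
#'   (`descriptor`, `lo`, `hi`, `pval`).
#' @export
eliminationStep <- function(scheme, population, topFrac = 0.1,
                            bottomFrac = 0.1, alpha = 0.01,
                            minAliveDescriptors = 2, minPopulation = 100) {
  stopifnot(is(scheme, "DiscretizationScheme"),
            is(population, "FilterPopulation"))
  nF <- length(population@mcc)
  if (nF < minPopulation)
    stop("population too small: ", nF, " filters (minimum ", minPopulation, ")")
  nR <- nrow(scheme@ranges)
  nBot <- max(1L, floor(bottomFrac * nF))
  nTop <- max(1L, floor(topFrac * nF))
  ord <- order(population@mcc)
  botSet <- ord[seq_len(nBot)]
  topSet <- ord[seq.int(nF - nTop + 1L, nF)]
  usage <- tabulate(population@rangeId, nbins = nR)
  cBot <- tabulate(population@rangeId[population@fid %in% botSet], nbins = nR)
  cTop <- tabulate(population@rangeId[population@fid %in% topSet], nbins = nR)
  cand <- which(scheme@ranges$alive & usage > 0L)
  pval <- pbinom(cBot[cand] - 1L, usage[cand], bottomFrac,
                 lower.tail = FALSE)
  killable <- pval < alpha & cTop[cand] <= usage[cand] * topFrac
  cand <- cand[killable]
  pval <- pval[killable]
  o <- order(pval)
  cand <- cand[o]
  pval <- pval[o]
  alive <- scheme@ranges$alive
  killed <- integer(0)
  killedP <- numeric(0)
  for (i in seq_along(cand)) {
    rid <- cand[i]
    d <- scheme@ranges$descriptor[rid]
    lastOfDesc <- sum(alive[scheme@ranges$descriptor == d]) == 1L
    if (lastOfDesc) {
      nAliveDesc <- length(unique(scheme@ranges$descriptor[alive]))
      if (nAliveDesc - 1L < minAliveDescriptors) next
    }
    alive[rid] <- FALSE
    killed <- c(killed, rid)
    killedP <- c(killedP, pval[i])
  }
  scheme@ranges$alive <- alive
  r <- scheme@ranges[killed, ]
  list(scheme = scheme,
       killed = data.frame(descriptor = scheme@descriptors[r$descriptor],
                           lo = r$lo, hi = r$hi, pval = killedP))
}

#' Count the surviving filter combinations
#'
#' Exact count of all filters constructible from alive values: over every
#' filter size `k` in `[kMin, kMax]` and every `k`-subset of descriptors
#' with alive values, the product of alive-value counts. Computed through
#' elementary symmetric polynomials, exactly in double precision (integer
#' results below 2^53).
#'
#' @param scheme a [DiscretizationScheme].
#' @param kMin,kMax filter size bounds.
#' @return the combination count (numeric, exact integer value).
#' @export
countRemainingCombinations <- function(scheme, kMin = 2, kMax = 5) {
  a <- tabulate(scheme@ranges$descriptor[scheme@ranges$alive],
                nbins = length(scheme@descriptors))
  a <- a[a > 0]
  coef <- 1
  for (ai in a) coef <- c(coef, 0) + c(0, coef * ai)
  ks <- kMin:kMax
  ks <- ks[ks + 1L <= length(coef)]
  if (!length(ks)) return(0)
  sum(coef[ks + 1L])
}

#' Exhaustively enumerate and rank all surviving filters
#'
#' Evaluates every filter constructible from the alive values and ranks
#' them by training MCC (descending), ties broken by fewer conditions and
#' then by enumeration order, which is lexicographic in scheme descriptor
#' order and range order -- fully deterministic.
#'
#' @param scheme a [DiscretizationScheme].
#' @param ls a [LearningSet].
#' @param kMin,kMax filter size bounds.
#' @param exhaustiveThreshold refuse to enumerate spaces larger than this.
#' @return list of class `"iseSearchResult"`: `performance` (data.frame
#'   `rank`, `mcc`, `tp`, `fp`, `tn`, `fn`, `nConditions`) and `conditions`
#'   (data.frame `filter`, `descriptor`, `lo`, `hi`, filter ids matching
#'   `rank`).
#' @export
exhaustiveSearch <- function(scheme, ls, kMin = 2, kMax = 5,
                             exhaustiveThreshold = 200000) {
  count <- countRemainingCombinations(scheme, kMin, kMax)
  if (count > exhaustiveThreshold)
    stop("remaining search space too large for exhaustive enumeration (",
         count, " > ", exhaustiveThreshold,
         "); run more elimination iterations first")
  idx <- .aliveIdx(scheme)
  aliveDesc <- which(lengths(idx) > 0L)
  ridChunks <- list()
  lenChunks <- list()
  ci <- 0L
  for (k in kMin:kMax) {
    if (length(aliveDesc) < k) next
    combos <- combn(aliveDesc, k)
    for (j in seq_len(ncol(combos))) {
      g <- as.matrix(expand.grid(idx[combos[, j]], KEEP.OUT.ATTRS = FALSE))
      ci <- ci + 1L
      ridChunks[[ci]] <- as.integer(t(g))
      lenChunks[[ci]] <- rep(k, nrow(g))
    }
  }
  len <- unlist(lenChunks)
  rid <- unlist(ridChunks)
  nF <- length(len)
  if (!nF) stop("no alive combinations to enumerate")
  fid <- rep(seq_len(nF), len)
  pop <- .evalPopulation(scheme, fid, rid, ls)
  nCond <- len
  ord <- order(-pop@mcc, nCond, method = "radix")
  perf <- data.frame(rank = seq_len(nF), mcc = pop@mcc[ord],
                     tp = pop@tp[ord], fp = pop@fp[ord],
                     tn = pop@nNeg - pop@fp[ord],
                     fn = pop@nPos - pop@tp[ord],
                     nConditions = nCond[ord])
  newId <- integer(nF)
  newId[ord] <- seq_len(nF)
  r <- scheme@ranges
  conds <- data.frame(filter = newId[fid],
                      descriptor = scheme@descriptors[r$descriptor[rid]],
                      lo = r$lo[rid], hi = r$hi[rid])
  conds <- conds[order(conds$filter), ]
  rownames(conds) <- NULL
  structure(list(performance = perf, conditions = conds),
            class = "iseSearchResult")
}

#' Train an ISE model
#'
#' Runs the full ISE loop on a learning set: discretize, then repeat
#' {sample `R` random filters, evaluate, eliminate consistently-bad values}
#' until at most `exhaustiveThreshold` combinations survive (or
#' `maxIterations` is reached), then enumerate the surviving space
#' exhaustively. The model keeps the top-ranked filters with training MCC
#' at or above `minFilterMcc`, capped at `maxModelFilters`; each filter's
#' pass and fail weights both default to its training MCC
#' (`uniformWeights = TRUE` sets all weights to 1). With `config$seed` set,
#' repeated runs are bit-identical.
#'
#' @param ls a [LearningSet].
#' @param config an [iseConfig()].
#' @return an [IseModel].
#' @export
runIse <- function(ls, config = iseConfig()) {
  stopifnot(is(ls, "LearningSet"), inherits(config, "iseConfig"))
  withSeed(config$seed, {
    scheme <- discretize(ls, config$nBins, config$binSource)
    count <- countRemainingCombinations(scheme, config$kMin, config$kMax)
    iter <- 0L
    while (count > config$exhaustiveThreshold &&
           iter < config$maxIterations) {
      pop <- sampleFilterPopulation(scheme, ls, config$R,
                                    config$kMin, config$kMax)
      el <- eliminationStep(scheme, pop, config$topFrac, config$bottomFrac,
                            config$alpha, minAliveDescriptors = config$kMin,
                            minPopulation = min(config$minPopulation,
                                                config$R))
      scheme <- el$scheme
      count <- countRemainingCombinations(scheme, config$kMin, config$kMax)
      iter <- iter + 1L
      message("iteration ", iter, ": killed ", nrow(el$killed),
              " values, ", count, " combinations remain")
    }
    if (count > config$exhaustiveThreshold)
      stop("search space still too large after ", iter, " iterations (",
           count, " combinations); increase maxIterations or reduce ",
           "nBins/kMax")
    res <- exhaustiveSearch(scheme, ls, config$kMin, config$kMax,
                            config$exhaustiveThreshold)
    sel <- which(res$performance$mcc >= config$minFilterMcc)
    if (!length(sel))
      stop("no discriminating filters: best training MCC ",
           sprintf("%.3f", max(res$performance$mcc)), " below minimum ",
           config$minFilterMcc)
    sel <- sel[seq_len(min(length(sel), config$maxModelFilters))]
    perf <- res$performance[sel, ]
    conds <- res$conditions[res$conditions$filter %in% perf$rank, ]
    conds$filter <- match(conds$filter, perf$rank)
    conds <- conds[order(conds$filter), ]
    rownames(conds) <- NULL
    w <- if (config$uniformWeights) rep(1, nrow(perf)) else perf$mcc
    cfg <- unclass(config)
    cfg$seed <- NULL
    new("IseModel", conditions = conds, wPass = w, wFail = w,
        trainMcc = perf$mcc,
        metadata = list(targetId = ls@targetId, action = ls@action,
                        config = cfg, seed = config$seed,
                        descriptorSet = ls@table@provenance,
                        nPositives = length(ls@positives),
                        nDecoys = length(ls@decoys),
                        iterations = iter, searchSpace = count,
                        bestTrainMcc = max(perf$mcc)))
  })
}
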