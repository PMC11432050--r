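## Synthetic benchmark generators with known ground truth: planted-signal
## learning sets, random score fixtures, random fingerprints. Everything is
## deterministic under a seed, so every other module is testable without
## external databases.

#' Describe a planted descriptor-box signal
#'
#' The generator plants an axis-aligned box on a subset of descriptors:
#' positives live inside the box (plus Gaussian jitter), decoys are uniform
#' on the global `[0, 1]` domain with draws landing inside the box redrawn
#' unless a leak coin (probability `leakRate`) lets them stay. The oracle
#' filter equal to the box therefore has TPR near 1 (up to jitter escapes)
#' and FPR at most `leakRate`.
#'
#' @param descriptors planted descriptor names, or `NULL` to plant the
#'   first `nPlanted` generator descriptors.
#' @param nPlanted number of planted descriptors when `descriptors` is
#'   `NULL` (default 3).
#' @param lo,hi generating-box bounds applied to every planted descriptor
#'   (defaults 0.35 and 0.65 on the unit domain: actives concentrate in a
#'   small region of descriptor space, here the middle 30 percent of each
#'   planted axis, about 3 percent of the planted subspace).
#' @param leakRate probability that a decoy draw inside the box is kept,
#'   in `[0, 1)` (default 0.02).
#' @param noiseSd jitter standard deviation on positives (default 0.005,
#'   i.e. 1 percent of the default box width; jitter comparable to the box
#'   extent moves actives across the class boundary and turns into
#'   irreducible label noise).
#' @return list of class `"PlantedSignal"`.
#' @export
plantedSignal <- function(descriptors = NULL, nPlanted = 3,
                          lo = 0.35, hi = 0.65, leakRate = 0.02,
                          noiseSd = 0.005) {
  stopifnot(lo <= hi, leakRate >= 0, leakRate < 1, noiseSd >= 0,
            nPlanted >= 1)
  structure(list(descriptors = descriptors, nPlanted = nPlanted,
                 lo = lo, hi = hi, leakRate = leakRate, noiseSd = noiseSd),
            class = "PlantedSignal")
}

#' Generate a planted-signal learning set
#'
#' Emulates the separability an ISE model assumes between actives and
#' decoys, at the customary 1:100 imbalance: `nPositives` actives uniform
#' inside the generating box on the planted descriptors (with jitter,
#' clipped to the unit domain) and uniform elsewhere; `ratio * nPositives`
#' decoys uniform on `[0, 1]^d` rejection-resampled out of the box except
#' for the leak fraction.
#'
#' @param nPositives number of actives (default 50).
#' @param ratio decoys per active (default 100).
#' @param nDescriptors total descriptors (default 20), named `D01`, `D02`,
#'   ...
#' @param signal a [plantedSignal()].
#' @param seed optional integer seed; identical seeds give identical sets.
#' @return list with elements `learningSet` (a [LearningSet]), `signal`
#'   (with resolved descriptor names) and `box` (data.frame `descriptor`,
#'   `lo`, `hi` -- the ground-truth generating filter).
#' @export
generatePlantedLearningSet <- function(nPositives = 50, ratio = 100,
                                       nDescriptors = 20,
                                       signal = plantedSignal(),
                                       seed = NULL) {
  stopifnot(inherits(signal, "PlantedSignal"), nPositives >= 1, ratio >= 1,
            nDescriptors >= 1)
  descs <- sprintf("D%02d", seq_len(nDescriptors))
  planted <- signal$descriptors %||% descs[seq_len(signal$nPlanted)]
  if (!all(planted %in% descs))
    stop("planted descriptors must be a subset of the descriptor set")
  if (signal$lo <= 0 && signal$hi >= 1 && signal$leakRate == 0)
    stop("impossible geometry: the box covers the whole domain and leakRate is 0")
  pIdx <- match(planted, descs)
  nDec <- as.integer(ratio * nPositives)
  withSeed(seed, {
    pos <- matrix(runif(nPositives * nDescriptors), nPositives, nDescriptors)
    pos[, pIdx] <- signal$lo + (signal$hi - signal$lo) *
      matrix(runif(nPositives * length(pIdx)), nPositives)
    if (signal$noiseSd > 0)
      pos[, pIdx] <- pmin(1, pmax(0, pos[, pIdx] +
        rnorm(nPositives * length(pIdx), sd = signal$noiseSd)))
    dec <- matrix(runif(nDec * nDescriptors), nDec, nDescriptors)
    inBox <- function(m) {
      inside <- rep(TRUE, nrow(m))
      for (j in pIdx)
        inside <- inside & m[, j] >= signal$lo & m[, j] <= signal$hi
      inside
    }
    pending <- which(inBox(dec) & runif(nDec) >= signal$leakRate)
    while (length(pending)) {
      dec[pending, ] <- runif(length(pending) * nDescriptors)
      still <- inBox(dec[pending, , drop = FALSE]) &
        runif(length(pending)) >= signal$leakRate
      pending <- pending[still]
    }
    posIds <- sprintf("pos%04d", seq_len(nPositives))
    decIds <- sprintf("dec%06d", seq_len(nDec))
    values <- rbind(pos, dec)
    dimnames(values) <- list(c(posIds, decIds), descs)
    tab <- new("DescriptorTable", values = values, provenance = "synthetic")
    ls <- new("LearningSet", positives = posIds, decoys = decIds,
              table = tab, targetId = "synthetic", action = "agonist",
              ratio = ratio)
    list(learningSet = ls,
         signal = {
           s <- signal
           s$descriptors <- planted
           s
         },
         box = data.frame(descriptor = planted, lo = signal$lo,
                          hi = signal$hi))
  })
}

#' Generate a random score fixture with known annotations
#'
#' Uniform scores in `[-1, 1]` for every (drug, target) pair plus a random
#' known-pair subset; feeds cutoff-report and matrix-comparison tests.
#'
#' @param nDrugs,nTargets fixture dimensions.
#' @param fracKnown fraction of pairs marked as known, in `[0, 1]`.
#' @param seed optional integer seed.
#' @return list with `scores` (data.frame `molecule_id`, `target_id`,
#'   `action`, `model_id`, `score`) and `known` (data.frame of known
#'   pairs, same id columns).
#' @export
generateScoreFixture <- function(nDrugs = 100, nTargets = 5,
                                 fracKnown = 0.2, seed = NULL) {
  stopifnot(fracKnown >= 0, fracKnown <= 1)
  withSeed(seed, {
    drugs <- sprintf("drug%04d", seq_len(nDrugs))
    targets <- sprintf("T%02d", seq_len(nTargets))
    grid <- expand.grid(molecule_id = drugs, target_id = targets,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    grid$action <- "agonist"
    grid$model_id <- paste(grid$target_id, grid$action, sep = ":")
    grid$score <- runif(nrow(grid), -1, 1)
    nKnown <- round(fracKnown * nrow(grid))
    known <- grid[resample(seq_len(nrow(grid)), nKnown),
                  c("molecule_id", "target_id", "action", "model_id")]
    rownames(known) <- NULL
    list(scores = grid, known = known)
  })
}

#' Permute the positive/decoy labels of a learning set
#'
#' Reassigns the positive labels to a uniformly random subset of the same
#' size, keeping the descriptor table fixed: the null benchmark in which
#' any apparent signal is spurious. Uses the ambient RNG stream.
#'
#' @param ls a [LearningSet].
#' @return a [LearningSet] with permuted labels.
#' @export
permuteLabels <- function(ls) {
  stopifnot(is(ls, "LearningSet"))
  ids <- c(ls@positives, ls@decoys)
  newPos <- resample(ids, length(ls@positives))
  new("LearningSet", positives = newPos, decoys = setdiff(ids, newPos),
      table = ls@table, targetId = ls@targetId,
      action = paste0(ls@action, "-permuted"), ratio = ls@ratio)
}

#' Generate random fingerprints
#'
#' Independent Bernoulli(`density`) bits; deterministic per seed.
#'
#' @param n number of fingerprints.
#' @param nBits bits per fingerprint (default 2048).
#' @param density per-bit on-probability in (0, 1).
#' @param seed optional integer seed.
#' @return a [FingerprintSet].
#' @export
generateFingerprints <- function(n, nBits = 2048, density = 0.1,
                                 seed = NULL) {
  stopifnot(density > 0, density < 1, n >= 1, nBits >= 1)
  withSeed(seed, {
    bits <- matrix(runif(n * nBits) < density, n, nBits,
                   dimnames = list(sprintf("fp%04d", seq_len(n)), NULL))
    new("FingerprintSet", bits = bits, type = "random")
  })
}
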