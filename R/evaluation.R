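## Classification metrics, stratified cross-validation, enrichment factor,
## per-cutoff prediction reports and threshold selection.
##
## Zero-denominator conventions, used everywhere: MCC = 0 when any marginal
## factor is 0; TPR/TNR/F = 0 when their denominators are 0.

#' Construct a confusion matrix
#'
#' @param tp,fp,tn,fn non-negative counts.
#' @return a [ConfusionMatrix].
#' @export
confusionCounts <- function(tp, fp, tn, fn) {
  new("ConfusionMatrix", tp = as.numeric(tp), fp = as.numeric(fp),
      tn = as.numeric(tn), fn = as.numeric(fn))
}

#' Matthews correlation coefficient
#'
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with MCC = 0
#' when any factor of the denominator is 0. Robust to the heavy class
#' imbalance of actives-vs-decoys learning sets.
#'
#' @param cm a [ConfusionMatrix].
#' @return number in `[-1, 1]`.
#' @export
mcc <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  .mccFromCounts(cm@tp, cm@fp, cm@tp + cm@fn, cm@tn + cm@fp)
}

#' Sensitivity, specificity and F-score
#'
#' TPR = TP/(TP+FN); TNR = TN/(TN+FP); F = harmonic mean of precision and
#' recall. Each is 0 when its denominator is 0.
#'
#' @param cm a [ConfusionMatrix].
#' @return a number in `[0, 1]`.
#' @export
tpr <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  d <- cm@tp + cm@fn
  if (d == 0) 0 else cm@tp / d
}

#' @rdname tpr
#' @export
tnr <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  d <- cm@tn + cm@fp
  if (d == 0) 0 else cm@tn / d
}

#' @rdname tpr
#' @export
fScore <- function(cm) {
  stopifnot(is(cm, "ConfusionMatrix"))
  prec <- if (cm@tp + cm@fp == 0) 0 else cm@tp / (cm@tp + cm@fp)
  rec <- if (cm@tp + cm@fn == 0) 0 else cm@tp / (cm@tp + cm@fn)
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

.asLabels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels != 0)
  labels <- as.character(labels)
  if (!all(labels %in% c("pos", "neg")))
    stop("labels must be logical or 'pos'/'neg'")
  labels == "pos"
}

#' Area under the ROC curve
#'
#' Computed exactly from ranks as P(score_pos > score_neg) + 0.5 P(tie)
#' (the Mann-Whitney statistic); invariant under strictly monotone score
#' transforms.
#'
#' @param scores numeric vector.
#' @param labels logical vector (TRUE = positive) or `"pos"`/`"neg"`.
#' @return AUC in `[0, 1]`.
#' @export
rocAuc <- function(scores, labels) {
  lab <- .asLabels(labels)
  stopifnot(length(scores) == length(lab))
  nPos <- sum(lab)
  nNeg <- sum(!lab)
  if (nPos == 0 || nNeg == 0)
    stop("both classes required to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[lab]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Confusion matrix at a score threshold
#'
#' Predicted-positive iff `score > t` (strict, matching the "any positive
#' score" convention at the default `t = 0`).
#'
#' @param scores numeric scores.
#' @param labels positive-class labels (see [rocAuc()]).
#' @param t threshold, default 0.
#' @return a [ConfusionMatrix].
#' @export
confusionAtThreshold <- function(scores, labels, t = 0) {
  lab <- .asLabels(labels)
  stopifnot(length(scores) == length(lab))
  pred <- scores > t
  confusionCounts(tp = sum(pred & lab), fp = sum(pred & !lab),
                  tn = sum(!pred & !lab), fn = sum(!pred & lab))
}

#' Stratified k-fold cross-validation of an ISE model
#'
#' Positives and decoys are partitioned into `k` folds separately, so every
#' fold preserves the learning set's imbalance. For each fold a model is
#' trained with [runIse()] on the remaining folds and the held-out molecules
#' are scored; MCC/TPR/TNR/F are taken at threshold 0 and AUC from the raw
#' scores. When a training split yields no filter above the configured
#' minimum MCC, the fold predicts nothing positive and is recorded with
#' MCC 0, AUC 0.5 and `modelBuilt = FALSE`.
#'
#' @param ls a [LearningSet].
#' @param config an [iseConfig()]; its `seed` is ignored here, fold RNG is
#'   governed by `seed`.
#' @param k number of folds (default 5).
#' @param seed optional integer seed for fold assignment and training.
#' @return a [CVReport].
#' @export
crossValidate <- function(ls, config = iseConfig(), k = 5, seed = NULL) {
  stopifnot(is(ls, "LearningSet"))
  nP <- length(ls@positives)
  nN <- length(ls@decoys)
  if (nP < k || nN < k)
    stop("need at least k positives and k decoys for ", k, "-fold CV")
  config$seed <- NULL
  withSeed(seed, {
    foldP <- sample(rep_len(seq_len(k), nP))
    foldN <- sample(rep_len(seq_len(k), nN))
    rows <- vector("list", k)
    for (f in seq_len(k)) {
      trP <- ls@positives[foldP != f]
      trN <- ls@decoys[foldN != f]
      teP <- ls@positives[foldP == f]
      teN <- ls@decoys[foldN == f]
      trainLs <- new("LearningSet", positives = trP, decoys = trN,
                     table = ls@table[c(trP, trN), ],
                     targetId = ls@targetId, action = ls@action,
                     ratio = ls@ratio)
      model <- tryCatch(runIse(trainLs, config), error = function(e) {
        if (grepl("no discriminating filters|still too large",
                  conditionMessage(e))) NULL
        else stop(e)
      })
      if (is.null(model)) {
        rows[[f]] <- data.frame(fold = f, mcc = 0, auc = 0.5, tpr = 0,
                                tnr = 1, f_score = 0, modelBuilt = FALSE)
        next
      }
      st <- screenLibrary(model, ls@table[c(teP, teN), ])
      lab <- st$molecule_id %in% teP
      cm <- confusionAtThreshold(st$score, lab, 0)
      rows[[f]] <- data.frame(fold = f, mcc = mcc(cm),
                              auc = rocAuc(st$score, lab),
                              tpr = tpr(cm), tnr = tnr(cm),
                              f_score = fScore(cm), modelBuilt = TRUE)
    }
    folds <- do.call(rbind, rows)
    metr <- c("mcc", "auc", "tpr", "tnr", "f_score")
    new("CVReport", folds = folds,
        means = vapply(folds[metr], mean, numeric(1L)),
        sds = vapply(folds[metr], sd, numeric(1L)),
        k = as.integer(k),
        seed = if (is.null(seed)) NA_real_ else as.numeric(seed))
  })
}

#' Enrichment factor
#'
#' Ratio of the positive rate in the top-scoring fraction of the library to
#' the positive rate overall. The selected count is
#' `max(1, floor(topFraction * n))`; boundary ties are resolved by the
#' stable (score descending, id ascending) order.
#'
#' @param scores numeric scores.
#' @param labels positive labels (see [rocAuc()]).
#' @param topFraction fraction of the library to select, in `(0, 1]`.
#' @param ids optional molecule ids for deterministic tie-breaking
#'   (default: input order).
#' @return the enrichment factor (>= 0); `topFraction = 1` gives exactly 1.
#' @export
enrichmentFactor <- function(scores, labels, topFraction, ids = NULL) {
  lab <- .asLabels(labels)
  stopifnot(length(scores) == length(lab),
            topFraction > 0, topFraction <= 1)
  if (!sum(lab)) stop("at least one positive required")
  n <- length(scores)
  if (is.null(ids)) ids <- sprintf("%09d", seq_len(n))
  nSel <- max(1L, floor(topFraction * n))
  o <- order(-scores, ids, method = "radix")
  sel <- o[seq_len(nSel)]
  (sum(lab[sel]) / nSel) / (sum(lab) / n)
}

#' Select a score threshold by TP/FP ratio
#'
#' Returns the grid threshold maximizing TP/FP at strict `score > t`
#' classification. FP = 0 counts as an infinite ratio; among tied ratios
#' the lowest threshold wins, so separable data select the lowest
#' false-positive-free cutoff.
#'
#' @param scores numeric scores.
#' @param labels positive labels.
#' @param grid candidate thresholds (default 0, 0.1, ..., 0.9).
#' @return the selected threshold.
#' @export
selectThreshold <- function(scores, labels,
                            grid = c(0, seq(0.1, 0.9, by = 0.1))) {
  if (!length(grid)) stop("threshold grid must be nonempty")
  ratio <- vapply(grid, function(t) {
    cm <- confusionAtThreshold(scores, labels, t)
    if (cm@fp == 0) Inf else cm@tp / cm@fp
  }, numeric(1L))
  o <- order(grid)
  grid <- grid[o]
  ratio <- ratio[o]
  grid[which.max(ratio)]
}

#' Per-cutoff successful / new prediction report
#'
#' For every cutoff `c` of the grid, counts predicted (molecule, model)
#' pairs that are already known ("successful") and those that are not
#' ("new"). The first grid row uses strict `score > c`; the remaining rows
#' use `score >= c`. The percentage column is successful predictions over
#' the number of known pairs, on the 0-100 scale.
#'
#' @param scoreTable data.frame with columns `molecule_id`, `model_id`,
#'   `score`.
#' @param known data.frame of known pairs (`molecule_id`, `model_id`).
#' @param grid cutoffs, default `c(0, 0.1, ..., 0.9)` (first row strict).
#' @return data.frame with columns `cutoff`, `rule`, `n_successful`,
#'   `n_new`, `pct_successful`; counts are non-increasing in the cutoff.
#'   With an empty known set the percentage is reported as 0 and an
#'   attribute `"note"` is attached.
#' @export
cutoffReport <- function(scoreTable, known,
                         grid = c(0, seq(0.1, 0.9, by = 0.1))) {
  stopifnot(all(c("molecule_id", "model_id", "score") %in%
                names(scoreTable)))
  key <- paste(scoreTable$molecule_id, scoreTable$model_id, sep = "\r")
  knownKey <- if (nrow(known))
    unique(paste(known$molecule_id, known$model_id, sep = "\r"))
  else character()
  isKnown <- key %in% knownKey
  nKnown <- length(knownKey)
  rows <- lapply(seq_along(grid), function(i) {
    pred <- if (i == 1L) scoreTable$score > grid[i]
            else scoreTable$score >= grid[i]
    nS <- sum(pred & isKnown)
    data.frame(cutoff = grid[i],
               rule = if (i == 1L) ">" else ">=",
               n_successful = nS,
               n_new = sum(pred & !isKnown),
               pct_successful = if (nKnown) 100 * nS / nKnown else 0)
  })
  out <- do.call(rbind, rows)
  if (!nKnown)
    attr(out, "note") <- "no known pairs: pct_successful reported as 0"
  out
}

#' @rdname crossValidate
#' @param x a [CVReport].
#' @return `cvSummary()` returns a one-row data.frame of means and sds.
#' @export
cvSummary <- function(x) {
  stopifnot(is(x, "CVReport"))
  out <- as.data.frame(as.list(c(x@means,
                                 setNames(x@sds, paste0(names(x@sds), "_sd")))))
  out$k <- x@k
  out
}
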