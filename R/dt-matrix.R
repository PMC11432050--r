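## Bipartite drug-target matrices: reported vs predicted activities and
## interactions, comparison bookkeeping, degree statistics and repurposing
## candidate selection with anti-target exclusion.

.dtKey <- function(target, action) {
  ifelse(is.na(action), target, paste(target, action, sep = "|"))
}

.longScores <- function(scores) {
  need <- c("molecule_id", "target_id", "action", "score")
  if (!all(need %in% names(scores)))
    stop("score data needs columns ", paste(need, collapse = ", "))
  scores
}

#' Build a binary drug-target activity matrix from screening scores
#'
#' Cell (drug, target, action) is 1 iff the drug's score for that model is
#' at or above the cutoff (`score >= cutoff`; the customary high-score
#' cutoff is 0.7).
#'
#' @param scores long data.frame with columns `molecule_id`, `target_id`,
#'   `action`, `score` (one row per drug/model pair; duplicates are an
#'   error).
#' @param cutoff score cutoff, default 0.7.
#' @return a [DrugTargetMatrix] in activity mode.
#' @export
buildActivityMatrix <- function(scores, cutoff = 0.7) {
  scores <- .longScores(scores)
  key <- paste(scores$molecule_id, scores$target_id, scores$action)
  if (anyDuplicated(key))
    stop("duplicated (drug, target, action) entries: ",
         key[duplicated(key)][1L])
  drugs <- sort(unique(scores$molecule_id), method = "radix")
  colInfo <- unique(scores[c("target_id", "action")])
  colInfo <- colInfo[order(colInfo$target_id, colInfo$action,
                           method = "radix"), ]
  names(colInfo) <- c("target", "action")
  rownames(colInfo) <- NULL
  m <- matrix(0L, length(drugs), nrow(colInfo),
              dimnames = list(drugs, .dtKey(colInfo$target, colInfo$action)))
  hit <- scores$score >= cutoff
  m[cbind(match(scores$molecule_id[hit], drugs),
          match(.dtKey(scores$target_id[hit], scores$action[hit]),
                colnames(m)))] <- 1L
  new("DrugTargetMatrix", mat = m, mode = "activity", colInfo = colInfo)
}

#' Build the reported drug-target matrix from annotations
#'
#' @param annotations data.frame with columns `molecule_id`, `target_id`,
#'   `action`.
#' @param mode `"activity"` (target x action columns) or `"interaction"`
#'   (target columns; any action links drug and target).
#' @return a binary [DrugTargetMatrix].
#' @export
buildReportedMatrix <- function(annotations, mode = c("activity",
                                                      "interaction")) {
  mode <- match.arg(mode)
  need <- c("molecule_id", "target_id", "action")
  if (!all(need %in% names(annotations)))
    stop("annotations need columns ", paste(need, collapse = ", "))
  ann <- unique(annotations[need])
  drugs <- sort(unique(ann$molecule_id), method = "radix")
  if (mode == "activity") {
    colInfo <- unique(ann[c("target_id", "action")])
    names(colInfo) <- c("target", "action")
  } else {
    targets <- sort(unique(ann$target_id), method = "radix")
    colInfo <- data.frame(target = targets,
                          action = rep(NA_character_, length(targets)))
  }
  colInfo <- colInfo[order(colInfo$target, colInfo$action,
                           method = "radix"), ]
  rownames(colInfo) <- NULL
  m <- matrix(0L, length(drugs), nrow(colInfo),
              dimnames = list(drugs, .dtKey(colInfo$target, colInfo$action)))
  colKey <- if (mode == "activity") .dtKey(ann$target_id, ann$action)
            else ann$target_id
  m[cbind(match(ann$molecule_id, drugs), match(colKey, colnames(m)))] <- 1L
  new("DrugTargetMatrix", mat = m, mode = mode, colInfo = colInfo)
}

#' Collapse an activity matrix to an interaction matrix
#'
#' A drug interacts with a target when it is an agonist OR an antagonist
#' there: the interaction cell is the elementwise OR over that target's
#' action columns. Idempotent on interaction-mode input.
#'
#' @param m a [DrugTargetMatrix].
#' @return a [DrugTargetMatrix] in interaction mode.
#' @export
toInteractionMatrix <- function(m) {
  stopifnot(is(m, "DrugTargetMatrix"))
  if (m@mode == "interaction") return(m)
  targets <- sort(unique(m@colInfo$target), method = "radix")
  out <- matrix(0L, nrow(m@mat), length(targets),
                dimnames = list(rownames(m@mat), targets))
  for (t in targets) {
    cols <- which(m@colInfo$target == t)
    out[, t] <- as.integer(rowSums(m@mat[, cols, drop = FALSE]) > 0)
  }
  new("DrugTargetMatrix", mat = out, mode = "interaction",
      colInfo = data.frame(target = targets, action = NA_character_))
}

## pad two matrices onto the union of drug/column universes (absent cells 0)
.padUnion <- function(a, b) {
  drugs <- sort(union(rownames(a@mat), rownames(b@mat)), method = "radix")
  ci <- unique(rbind(a@colInfo, b@colInfo))
  ci <- ci[order(ci$target, ci$action, method = "radix"), ]
  rownames(ci) <- NULL
  keys <- .dtKey(ci$target, ci$action)
  pad <- function(m) {
    out <- matrix(0L, length(drugs), length(keys),
                  dimnames = list(drugs, keys))
    out[rownames(m@mat), colnames(m@mat)] <- m@mat
    out
  }
  list(a = pad(a), b = pad(b), colInfo = ci)
}

#' Compare predicted and reported drug-target matrices
#'
#' Successful predictions are predicted cells that are also reported; new
#' predictions are predicted cells absent from the reported matrix. The
#' percentage of successful predictions uses all reported cells as the
#' denominator, including drugs missing from the predicted universe.
#'
#' @param predicted,reported [DrugTargetMatrix] objects of the same mode;
#'   drug/target universes are unioned with absent cells as 0.
#' @return list of class `"ComparisonReport"`: `n_known`, `n_successful`,
#'   `n_new`, `pct_successful` (0-100), and `per_target` breakdown.
#' @export
compareMatrices <- function(predicted, reported) {
  stopifnot(is(predicted, "DrugTargetMatrix"),
            is(reported, "DrugTargetMatrix"))
  if (predicted@mode != reported@mode)
    stop("mode mismatch: ", predicted@mode, " vs ", reported@mode)
  p <- .padUnion(predicted, reported)
  succ <- p$a & p$b
  newp <- p$a & !p$b
  perTarget <- data.frame(
    target = p$colInfo$target, action = p$colInfo$action,
    n_known = colSums(p$b), n_successful = colSums(succ),
    n_new = colSums(newp), row.names = NULL)
  perTarget <- aggregate(cbind(n_known, n_successful, n_new) ~ target,
                         data = perTarget, FUN = sum)
  nKnown <- sum(p$b)
  structure(list(n_known = nKnown, n_successful = sum(succ),
                 n_new = sum(newp),
                 pct_successful = if (nKnown) 100 * sum(succ) / nKnown else 0,
                 per_target = perTarget),
            class = "ComparisonReport")
}

#' Degree statistics of a drug-target matrix
#'
#' Row and column sums of the binary matrix, the mean interactions per
#' drug, and the edge count. Edge conservation holds by construction:
#' the drug degrees and the target degrees both sum to the edge count.
#'
#' @param m a [DrugTargetMatrix].
#' @return list with `drugDegrees`, `targetDegrees`, `meanPerDrug`,
#'   `edges`.
#' @export
degreeStats <- function(m) {
  stopifnot(is(m, "DrugTargetMatrix"))
  dd <- rowSums(m@mat)
  td <- colSums(m@mat)
  list(drugDegrees = dd, targetDegrees = td,
       meanPerDrug = if (length(dd)) mean(dd) else NaN,
       edges = sum(m@mat))
}

#' Pearson correlation between two per-target count vectors
#'
#' Helper for correlating reported vs predicted interaction counts. With a
#' constant vector the correlation is undefined and `NA` is returned (with
#' a message) instead of propagating NaN.
#'
#' @param x,y numeric vectors of equal length.
#' @return Pearson r, or `NA` when undefined.
#' @export
degreeCorrelation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 2L || sd(x) == 0 || sd(y) == 0) {
    message("degree correlation undefined for constant or length-1 vectors")
    return(NA_real_)
  }
  cor(x, y)
}

#' Select repurposing candidates with anti-target exclusion
#'
#' Picks drugs scoring at or above `cutoff` on the desired (target, action)
#' AND strictly below `antiCutoff` on every anti-target. Drugs missing a
#' score for any anti-target are excluded and reported via [message()].
#'
#' @param scores long score data.frame (`molecule_id`, `target_id`,
#'   `action`, `score`).
#' @param target length-2 character vector `c(target_id, action)`.
#' @param cutoff desired-target score cutoff (default 0.7).
#' @param antiTargets optional data.frame with columns `target_id`,
#'   `action` of activities the candidates must avoid.
#' @param antiCutoff anti-target cutoff (default 0: anti scores must be
#'   negative).
#' @return character vector of candidate drug ids, sorted.
#' @export
selectCandidates <- function(scores, target, cutoff = 0.7,
                             antiTargets = NULL, antiCutoff = 0) {
  scores <- .longScores(scores)
  stopifnot(length(target) == 2L)
  key <- paste(scores$target_id, scores$action)
  tKey <- paste(target[1L], target[2L])
  if (!tKey %in% key)
    stop("unknown target: ", target[1L], " / ", target[2L])
  sel <- scores[key == tKey & scores$score >= cutoff, ]
  cand <- sel$molecule_id
  if (!is.null(antiTargets) && nrow(antiTargets)) {
    for (i in seq_len(nrow(antiTargets))) {
      aKey <- paste(antiTargets$target_id[i], antiTargets$action[i])
      if (!aKey %in% key)
        stop("unknown anti-target: ", aKey)
      aScores <- scores[key == aKey, ]
      have <- cand %in% aScores$molecule_id
      if (any(!have)) {
        message(sum(!have), " candidate(s) lack a score for anti-target ",
                aKey, " and were excluded")
        cand <- cand[have]
      }
      aVal <- aScores$score[match(cand, aScores$molecule_id)]
      cand <- cand[aVal < antiCutoff]
    }
  }
  sort(unique(cand), method = "radix")
}

#' Export a drug-target matrix
#'
#' `writeMatrixCsv()` writes the binary drugs-x-columns matrix;
#' `matrixEdgeList()` returns the 1-cells as an edge data.frame.
#'
#' @param m a [DrugTargetMatrix].
#' @param path output CSV path.
#' @export
writeMatrixCsv <- function(m, path) {
  stopifnot(is(m, "DrugTargetMatrix"))
  df <- data.frame(drug = rownames(m@mat), m@mat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeMatrixCsv
#' @export
matrixEdgeList <- function(m) {
  stopifnot(is(m, "DrugTargetMatrix"))
  idx <- which(m@mat == 1L, arr.ind = TRUE)
  data.frame(drug = rownames(m@mat)[idx[, 1L]],
             target = m@colInfo$target[idx[, 2L]],
             action = m@colInfo$action[idx[, 2L]], row.names = NULL)
}
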