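## Assembly of imbalanced actives/decoys learning sets per (target, action):
## activity threshold, deduplication, alert removal, applicability-domain
## decoy sampling.

.ACTIONS <- c("agonist", "antagonist")
.MEASURES <- c("EC50", "IC50", "Ki")

#' Validate activity records
#'
#' Activity annotations are rows of (molecule_id, target_id, action,
#' measure, value_uM). Values are potencies in micromolar and must be
#' positive; agonist records carry EC50 and antagonist records carry IC50
#' or Ki.
#'
#' @param records data.frame of activity annotations.
#' @return the validated data.frame (invisibly unchanged).
#' @export
validateActivities <- function(records) {
  need <- c("molecule_id", "target_id", "action", "measure", "value_uM")
  if (!all(need %in% names(records)))
    stop("activity records need columns ", paste(need, collapse = ", "))
  if (!all(records$action %in% .ACTIONS))
    stop("action must be one of ", paste(.ACTIONS, collapse = ", "))
  if (!all(records$measure %in% .MEASURES))
    stop("measure must be one of ", paste(.MEASURES, collapse = ", "))
  if (!is.numeric(records$value_uM) || any(!is.finite(records$value_uM)) ||
      any(records$value_uM <= 0))
    stop("value_uM must be positive and finite")
  bad <- (records$action == "agonist" & records$measure != "EC50") |
         (records$action == "antagonist" & !records$measure %in% c("IC50", "Ki"))
  if (any(bad))
    stop("measure/action mismatch in ", sum(bad), " record(s): ",
         "agonists carry EC50, antagonists IC50 or Ki")
  invisible(records)
}

#' Read an activity-annotation CSV
#'
#' Expected columns: `molecule_id,target_id,action,measure,value_uM`.
#' @param path CSV path.
#' @return validated data.frame of activity records.
#' @export
readActivityCsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE,
                 colClasses = c(value_uM = "numeric"))
  validateActivities(df)
  df
}

#' Filter activity records by potency threshold
#'
#' Keeps records with `value_uM` strictly below the threshold (the activity
#' criterion is "less than 100 uM").
#'
#' @param records activity data.frame.
#' @param thresholdUM potency threshold in micromolar (default 100).
#' @return the filtered data.frame.
#' @export
filterByActivity <- function(records, thresholdUM = 100) {
  validateActivities(records)
  records[records$value_uM < thresholdUM, , drop = FALSE]
}

#' Deduplicate activity records
#'
#' Keeps the first occurrence of each molecule in input order; optionally
#' removes molecules on an exclusion list (e.g. the ids of the screening
#' library, which must not appear in the learning set). With
#' `by = "canonical_structure"` duplicates are detected on washed canonical
#' SMILES supplied through `structures`.
#'
#' @param records activity data.frame.
#' @param by deduplication key: `"id"` or `"canonical_structure"`.
#' @param exclude character vector of molecule ids to drop.
#' @param structures named character vector mapping molecule_id to canonical
#'   SMILES (required for `by = "canonical_structure"`).
#' @return the deduplicated data.frame.
#' @export
deduplicateRecords <- function(records, by = c("id", "canonical_structure"),
                               exclude = character(), structures = NULL) {
  by <- match.arg(by)
  records <- records[!records$molecule_id %in% exclude, , drop = FALSE]
  key <- if (by == "id") records$molecule_id else {
    if (is.null(structures))
      stop("structures required for canonical_structure deduplication")
    unname(structures[records$molecule_id])
  }
  records[!duplicated(key), , drop = FALSE]
}

#' Build an applicability domain from the actives' descriptors
#'
#' The applicability domain is the axis-aligned box spanned per descriptor
#' by the (trimFraction, 1 - trimFraction) empirical quantiles of the
#' positives' values (type-7 linear interpolation; trim 0 gives min/max).
#'
#' @param positivesTable [DescriptorTable] of the known actives (>= 2 rows).
#' @param trimFraction quantile trim in `[0, 0.5)`, default 0.
#' @return an [ApplicabilityDomain].
#' @export
buildApplicabilityDomain <- function(positivesTable, trimFraction = 0) {
  stopifnot(is(positivesTable, "DescriptorTable"))
  v <- positivesTable@values
  if (nrow(v) < 2L)
    stop("at least 2 positives required to build an applicability domain")
  if (trimFraction < 0 || trimFraction >= 0.5)
    stop("trimFraction must lie in [0, 0.5)")
  q <- apply(v, 2L, quantile, probs = c(trimFraction, 1 - trimFraction),
             names = FALSE, type = 7L)
  new("ApplicabilityDomain",
      lo = setNames(q[1L, ], colnames(v)),
      hi = setNames(q[2L, ], colnames(v)),
      trimFraction = trimFraction)
}

#' Which molecules fall inside an applicability domain?
#'
#' @param ad an [ApplicabilityDomain].
#' @param table a [DescriptorTable] covering (at least) the AD's descriptors.
#' @return named logical vector, TRUE when every descriptor value lies in
#'   its closed `[lo, hi]` interval.
#' @export
adContains <- function(ad, table) {
  stopifnot(is(ad, "ApplicabilityDomain"), is(table, "DescriptorTable"))
  d <- names(ad@lo)
  missing <- setdiff(d, colnames(table@values))
  if (length(missing))
    stop("descriptor(s) absent from table: ", paste(missing, collapse = ", "))
  v <- table@values[, d, drop = FALSE]
  inside <- rep(TRUE, nrow(v))
  for (j in seq_along(d))
    inside <- inside & v[, j] >= ad@lo[j] & v[, j] <= ad@hi[j]
  setNames(inside, rownames(v))
}

#' Sample decoys inside the applicability domain
#'
#' Uniformly samples, without replacement and deterministically for a given
#' seed, exactly `ratio * nPositives` molecules from the pool members lying
#' inside the AD box on every descriptor.
#'
#' @param pool [DescriptorTable] of decoy candidates.
#' @param ad [ApplicabilityDomain] built from the positives.
#' @param nPositives number of positives the decoys will balance against.
#' @param ratio decoys per positive (default 100; 1000 is also customary).
#' @param seed optional integer seed; the caller's RNG state is preserved.
#' @return character vector of sampled decoy ids.
#' @export
sampleDecoys <- function(pool, ad, nPositives, ratio = 100, seed = NULL) {
  stopifnot(is(pool, "DescriptorTable"))
  if (ratio < 1) stop("ratio must be >= 1")
  eligible <- names(which(adContains(ad, pool)))
  need <- as.integer(ratio * nPositives)
  if (length(eligible) < need)
    stop(sprintf(paste0("eligible decoy pool too small: %d eligible inside ",
                        "the applicability domain, %d requested ",
                        "(shortfall %d); lower the ratio or enlarge the pool"),
                 length(eligible), need, need - length(eligible)))
  withSeed(seed, resample(eligible, need))
}

#' Assemble a learning set for one (target, action)
#'
#' Pipeline: restrict the activity records to the requested target and
#' action, apply the potency threshold (strict `< thresholdUM`),
#' deduplicate, optionally remove molecules carrying structural alerts,
#' build the applicability domain from the surviving positives, and sample
#' `ratio` decoys per positive from the pool inside that domain. Counts
#' surviving each stage are reported via [message()].
#'
#' A molecule with several activity values for the same (target, action) is
#' kept if any value passes the threshold.
#'
#' @param records activity data.frame (see [validateActivities()]).
#' @param positivesTable [DescriptorTable] holding descriptor rows for the
#'   candidate positives.
#' @param pool [DescriptorTable] of decoy candidates (same descriptors).
#' @param targetId,action the (target, action) pair to model.
#' @param molecules optional [MoleculeSet] with structures for alert removal.
#' @param alerts alert data.frame used when `molecules` is given
#'   (default [defaultAlerts()]); pass an empty data.frame to disable.
#' @param thresholdUM potency threshold, default 100.
#' @param ratio decoys per positive, default 100.
#' @param trimFraction applicability-domain quantile trim, default 0.
#' @param minPositives minimum positives after filtering (default 20).
#' @param exclude molecule ids to exclude (e.g. screening-library drugs).
#' @param seed optional integer seed for decoy sampling.
#' @return a [LearningSet].
#' @export
assembleLearningSet <- function(records, positivesTable, pool,
                                targetId, action,
                                molecules = NULL, alerts = defaultAlerts(),
                                thresholdUM = 100, ratio = 100,
                                trimFraction = 0, minPositives = 20,
                                exclude = character(), seed = NULL) {
  stopifnot(is(positivesTable, "DescriptorTable"), is(pool, "DescriptorTable"))
  if (!identical(colnames(positivesTable@values), colnames(pool@values)))
    stop("positives table and pool must share the same descriptors")
  validateActivities(records)
  rec <- records[records$target_id == targetId & records$action == action, ,
                 drop = FALSE]
  message("stage target/action: ", length(unique(rec$molecule_id)), " molecules")
  rec <- filterByActivity(rec, thresholdUM)
  message("stage activity < ", thresholdUM, " uM: ",
          length(unique(rec$molecule_id)), " molecules")
  rec <- deduplicateRecords(rec, by = "id", exclude = exclude)
  ids <- unique(rec$molecule_id)
  message("stage deduplicated: ", length(ids), " molecules")
  if (!is.null(molecules) && nrow(alerts)) {
    keepSet <- mseIntersect(molecules, ids)
    part <- flagAlerts(keepSet, alerts)
    flagged <- moleculeIds(part$flagged)
    ids <- setdiff(ids, flagged)
    message("stage alert removal: ", length(ids), " molecules (",
            length(flagged), " flagged)")
  }
  ids <- ids[ids %in% rownames(positivesTable@values)]
  message("stage descriptors available: ", length(ids), " molecules")
  if (length(ids) < minPositives)
    stop("insufficient actives: ", length(ids), " positives after filtering (minimum ",
         minPositives, ")")
  posTab <- positivesTable[ids, ]
  ad <- buildApplicabilityDomain(posTab, trimFraction)
  poolClean <- pool[setdiff(rownames(pool@values), ids), ]
  dec <- sampleDecoys(poolClean, ad, length(ids), ratio, seed = seed)
  message("stage decoys sampled: ", length(dec))
  tab <- new("DescriptorTable",
             values = rbind(posTab@values, pool@values[dec, , drop = FALSE]),
             provenance = positivesTable@provenance)
  new("LearningSet", positives = ids, decoys = dec, table = tab,
      targetId = targetId, action = action, ratio = ratio)
}

## subset a MoleculeSet to the given ids (order of mset preserved)
mseIntersect <- function(mset, ids) {
  keep <- mset@id %in% ids
  MoleculeSet(mset@id[keep], mset@smiles[keep], source = mset@source[keep])
}
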