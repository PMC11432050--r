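#' @import methods
#' @importFrom stats quantile rnorm runif setNames sd cor pbinom aggregate
#' @importFrom utils read.csv head combn
#' @useDynLib iseScreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## ---------------------------------------------------------------------------
## MoleculeSet
## ---------------------------------------------------------------------------

#' A collection of molecule records
#'
#' Holds parsed molecules as SMILES strings together with their identifiers
#' and a free-text source tag. Entries that failed parsing, washing or
#' descriptor calculation are carried along in the `rejects` slot so that
#' nothing is silently dropped.
#'
#' @slot id character vector of unique, non-empty molecule identifiers.
#' @slot smiles character vector of SMILES strings, parallel to `id`.
#' @slot source character vector of free-text source tags, parallel to `id`.
#' @slot rejects data.frame with columns `id`, `structure`, `reason`
#'   recording entries routed out of the set.
#' @export
setClass("MoleculeSet",
  representation(id = "character", smiles = "character",
                 source = "character", rejects = "data.frame"),
  prototype(rejects = data.frame(id = character(), structure = character(),
                                 reason = character()))
)

setValidity("MoleculeSet", function(object) {
  msg <- character()
  if (length(object@id) != length(object@smiles) ||
      length(object@id) != length(object@source))
    msg <- c(msg, "id, smiles and source must have equal length")
  if (any(!nzchar(object@id)))
    msg <- c(msg, "molecule ids must be non-empty")
  if (anyDuplicated(object@id))
    msg <- c(msg, "molecule ids must be unique within a collection")
  if (!all(c("id", "structure", "reason") %in% names(object@rejects)))
    msg <- c(msg, "rejects must have columns id, structure, reason")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## DescriptorTable
## ---------------------------------------------------------------------------

#' Numeric molecular descriptor table
#'
#' Rows are molecules, columns are named numeric 2D descriptors. All values
#' are finite after cleaning; row and column names are unique.
#'
#' @slot values numeric matrix with molecule ids as rownames and descriptor
#'   names as colnames.
#' @slot provenance single string recording the descriptor set that produced
#'   the table (e.g. `"ob2d"` or `"csv:<file>"`).
#' @export
setClass("DescriptorTable",
  representation(values = "matrix", provenance = "character"),
  prototype(provenance = NA_character_)
)

setValidity("DescriptorTable", function(object) {
  v <- object@values
  msg <- character()
  if (!is.numeric(v)) msg <- c(msg, "values must be a numeric matrix")
  if ((nrow(v) && is.null(rownames(v))) || (ncol(v) && is.null(colnames(v))))
    msg <- c(msg, "values must carry molecule ids (rownames) and descriptor names (colnames)")
  else {
    if (anyDuplicated(rownames(v))) msg <- c(msg, "duplicate molecule ids")
    if (anyDuplicated(colnames(v))) msg <- c(msg, "duplicate descriptor names")
  }
  if (is.numeric(v) && length(v) && any(!is.finite(v)))
    msg <- c(msg, "all descriptor values must be finite")
  if (length(object@provenance) != 1L)
    msg <- c(msg, "provenance must be a single string")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## ApplicabilityDomain
## ---------------------------------------------------------------------------

#' Axis-aligned applicability domain
#'
#' Per-descriptor closed interval `[lo, hi]` derived from the known actives'
#' descriptor values; decoys and predictions are considered meaningful only
#' inside this box.
#'
#' @slot lo,hi named numeric vectors of per-descriptor bounds (same names).
#' @slot trimFraction quantile trim fraction in `[0, 0.5)` used to build the
#'   box (0 means min/max).
#' @export
setClass("ApplicabilityDomain",
  representation(lo = "numeric", hi = "numeric", trimFraction = "numeric")
)

setValidity("ApplicabilityDomain", function(object) {
  msg <- character()
  if (!identical(names(object@lo), names(object@hi)))
    msg <- c(msg, "lo and hi must cover the same descriptors in the same order")
  if (any(object@lo > object@hi))
    msg <- c(msg, "lo must be <= hi for every descriptor")
  tf <- object@trimFraction
  if (length(tf) != 1L || tf < 0 || tf >= 0.5)
    msg <- c(msg, "trimFraction must be a single number in [0, 0.5)")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## LearningSet
## ---------------------------------------------------------------------------

#' Imbalanced actives/decoys learning set for one (target, action)
#'
#' @slot positives,decoys character vectors of molecule ids; disjoint, all
#'   present in `table`.
#' @slot table [DescriptorTable] covering positives and decoys.
#' @slot targetId,action single strings identifying the modelled activity.
#' @slot ratio requested decoys-per-positive ratio.
#' @export
setClass("LearningSet",
  representation(positives = "character", decoys = "character",
                 table = "DescriptorTable", targetId = "character",
                 action = "character", ratio = "numeric")
)

setValidity("LearningSet", function(object) {
  msg <- character()
  if (length(intersect(object@positives, object@decoys)))
    msg <- c(msg, "positives and decoys must be disjoint")
  ids <- rownames(object@table@values)
  missing <- setdiff(c(object@positives, object@decoys), ids)
  if (length(missing))
    msg <- c(msg, paste0("ids absent from descriptor table: ",
                         paste(head(missing, 5L), collapse = ", ")))
  if (length(object@positives) < 1L)
    msg <- c(msg, "at least one positive required")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## DiscretizationScheme
## ---------------------------------------------------------------------------

#' Descriptor discretization and candidate value-ranges
#'
#' Bins each descriptor at equal-frequency quantiles of the learning table
#' and enumerates all contiguous bin-ranges as candidate filter conditions
#' (`b` bins give `b(b+1)/2` ranges). The `alive` flag on each range is the
#' state the elimination iterations act on; flags only ever flip from alive
#' to dead.
#'
#' @slot descriptors character vector of descriptor names.
#' @slot boundaries list of numeric cut-point vectors (including the observed
#'   min and max), one per descriptor.
#' @slot ranges data.frame with columns `descriptor` (index into
#'   `descriptors`), `loBin`, `hiBin`, `lo`, `hi`, `alive`.
#' @export
setClass("DiscretizationScheme",
  representation(descriptors = "character", boundaries = "list",
                 ranges = "data.frame")
)

setValidity("DiscretizationScheme", function(object) {
  msg <- character()
  if (length(object@boundaries) != length(object@descriptors))
    msg <- c(msg, "one boundary vector per descriptor required")
  need <- c("descriptor", "loBin", "hiBin", "lo", "hi", "alive")
  if (!all(need %in% names(object@ranges)))
    msg <- c(msg, paste("ranges must have columns", paste(need, collapse = ", ")))
  else {
    r <- object@ranges
    if (any(r$loBin > r$hiBin)) msg <- c(msg, "loBin must be <= hiBin")
    if (any(r$lo > r$hi)) msg <- c(msg, "range lo must be <= hi")
    if (!is.logical(r$alive)) msg <- c(msg, "alive must be logical")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## FilterPopulation
## ---------------------------------------------------------------------------

#' A population of random filters with their training performance
#'
#' Compact representation of one ISE sampling round: condition rows link
#' filter ids to candidate-range ids of a [DiscretizationScheme]; `mcc`
#' holds each filter's Matthews correlation coefficient on the learning set.
#'
#' @slot fid integer vector, filter id per condition row.
#' @slot rangeId integer vector, row index into the scheme's `ranges`.
#' @slot mcc numeric vector of per-filter MCC values.
#' @slot tp,fp integer vectors of per-filter true/false positive counts.
#' @slot nPos,nNeg total positives and decoys evaluated against.
#' @export
setClass("FilterPopulation",
  representation(fid = "integer", rangeId = "integer", mcc = "numeric",
                 tp = "integer", fp = "integer",
                 nPos = "integer", nNeg = "integer")
)

setValidity("FilterPopulation", function(object) {
  msg <- character()
  if (length(object@fid) != length(object@rangeId))
    msg <- c(msg, "fid and rangeId must be parallel")
  n <- length(object@mcc)
  if (length(object@tp) != n || length(object@fp) != n)
    msg <- c(msg, "tp, fp and mcc must be parallel")
  if (n && (any(object@mcc < -1 - 1e-12) || any(object@mcc > 1 + 1e-12)))
    msg <- c(msg, "mcc must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## IseModel
## ---------------------------------------------------------------------------

#' Weighted filter-ensemble model for one (target, action)
#'
#' An ordered set of conjunctive range filters. Screening a molecule adds
#' `wPass[i]` when it satisfies every condition of filter `i` and subtracts
#' `wFail[i]` otherwise; the sum is divided by the number of filters, so all
#' scores lie in `[-1, +1]`.
#'
#' @slot conditions data.frame with columns `filter` (1..n), `descriptor`,
#'   `lo`, `hi`; closed intervals, one row per condition.
#' @slot wPass,wFail per-filter weights in `(0, 1]`.
#' @slot trainMcc per-filter MCC on the training learning set.
#' @slot metadata list: target id, action, config snapshot, seed, descriptor
#'   set id and training metrics.
#' @export
setClass("IseModel",
  representation(conditions = "data.frame", wPass = "numeric",
                 wFail = "numeric", trainMcc = "numeric", metadata = "list")
)

setValidity("IseModel", function(object) {
  msg <- character()
  n <- length(object@wPass)
  if (n < 1L) msg <- c(msg, "a model must contain at least one filter")
  if (length(object@wFail) != n || length(object@trainMcc) != n)
    msg <- c(msg, "wPass, wFail and trainMcc must be parallel")
  if (n && (any(object@wPass <= 0) || any(object@wPass > 1) ||
            any(object@wFail <= 0) || any(object@wFail > 1)))
    msg <- c(msg, "weights must lie in (0, 1]")
  need <- c("filter", "descriptor", "lo", "hi")
  if (!all(need %in% names(object@conditions)))
    msg <- c(msg, "conditions must have columns filter, descriptor, lo, hi")
  else if (n && !setequal(unique(object@conditions$filter), seq_len(n)))
    msg <- c(msg, "condition filter ids must cover 1..n")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## ConfusionMatrix
## ---------------------------------------------------------------------------

#' Binary-classification confusion matrix
#'
#' @slot tp,fp,tn,fn non-negative counts.
#' @export
setClass("ConfusionMatrix",
  representation(tp = "numeric", fp = "numeric", tn = "numeric", fn = "numeric")
)

setValidity("ConfusionMatrix", function(object) {
  cnt <- c(object@tp, object@fp, object@tn, object@fn)
  if (length(cnt) != 4L) return("tp, fp, tn, fn must each be a single count")
  if (any(cnt < 0)) return("counts must be non-negative")
  if (any(cnt != floor(cnt))) return("counts must be whole numbers")
  TRUE
})

## ---------------------------------------------------------------------------
## CVReport
## ---------------------------------------------------------------------------

#' Cross-validation report
#'
#' @slot folds data.frame of per-fold metrics (`fold`, `mcc`, `auc`, `tpr`,
#'   `tnr`, `f_score`, `modelBuilt`).
#' @slot means,sds named numeric summaries over folds.
#' @slot k number of folds.
#' @slot seed fold-assignment seed (NA when none given).
#' @export
setClass("CVReport",
  representation(folds = "data.frame", means = "numeric", sds = "numeric",
                 k = "integer", seed = "numeric")
)

## ---------------------------------------------------------------------------
## DrugTargetMatrix
## ---------------------------------------------------------------------------

#' Binary bipartite drug-target matrix
#'
#' In `activity` mode columns are (target, action) pairs; in `interaction`
#' mode columns are targets and a cell is the OR of that target's action
#' columns.
#'
#' @slot mat binary integer matrix, drugs as rownames.
#' @slot mode `"activity"` or `"interaction"`.
#' @slot colInfo data.frame with columns `target` and `action` (`action` is
#'   `NA` in interaction mode), one row per matrix column.
#' @export
setClass("DrugTargetMatrix",
  representation(mat = "matrix", mode = "character", colInfo = "data.frame")
)

setValidity("DrugTargetMatrix", function(object) {
  msg <- character()
  if (!object@mode %in% c("activity", "interaction"))
    msg <- c(msg, "mode must be 'activity' or 'interaction'")
  if (length(object@mat) && !all(object@mat %in% c(0L, 1L)))
    msg <- c(msg, "cells must be binary")
  if (nrow(object@colInfo) != ncol(object@mat))
    msg <- c(msg, "colInfo must describe every matrix column")
  if (object@mode == "interaction" && nrow(object@colInfo) &&
      !all(is.na(object@colInfo$action)))
    msg <- c(msg, "interaction mode carries no action labels")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## FingerprintSet
## ---------------------------------------------------------------------------

#' Fixed-length binary fingerprints
#'
#' @slot bits logical matrix, one row per molecule (unique rownames), one
#'   column per bit.
#' @slot type free-text fingerprint type tag (e.g. `"ECFP4"`).
#' @export
setClass("FingerprintSet",
  representation(bits = "matrix", type = "character"),
  prototype(type = NA_character_)
)

setValidity("FingerprintSet", function(object) {
  msg <- character()
  if (!is.logical(object@bits)) msg <- c(msg, "bits must be a logical matrix")
  if (nrow(object@bits) && is.null(rownames(object@bits)))
    msg <- c(msg, "fingerprints must carry molecule ids as rownames")
  if (!is.null(rownames(object@bits)) && anyDuplicated(rownames(object@bits)))
    msg <- c(msg, "fingerprint ids must be unique")
  if (length(msg)) msg else TRUE
})
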