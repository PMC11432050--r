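## Screening molecules through an ISE model: signed, weighted, normalized
## filter-pass scores in [-1, +1].

#' Does a molecule pass a filter?
#'
#' TRUE iff every condition's closed interval contains the molecule's
#' descriptor value (boundary values pass).
#'
#' @param filter data.frame of conditions (`descriptor`, `lo`, `hi`).
#' @param vector named numeric vector of descriptor values covering all
#'   filter descriptors.
#' @return logical scalar.
#' @export
filterPasses <- function(filter, vector) {
  missing <- setdiff(filter$descriptor, names(vector))
  if (length(missing))
    stop("descriptor(s) missing from vector: ",
         paste(missing, collapse = ", "))
  x <- vector[filter$descriptor]
  all(x >= filter$lo & x <= filter$hi)
}

## split a model's conditions into a per-filter list, cached order
.modelFilters <- function(model) {
  split(model@conditions[c("descriptor", "lo", "hi")],
        model@conditions$filter)
}

#' Score one molecule with a model
#'
#' Score = (1/n) * sum_i [ pass_i * wPass_i - fail_i * wFail_i ], where
#' `pass_i` indicates that the molecule satisfies all conditions of filter
#' `i` and `fail_i` is its complement. Normalization is by the number of
#' filters `n`, so scores lie in `[-1, +1]` and reach the bounds exactly
#' under uniform weights 1 with all filters passed (or failed).
#'
#' @param model an [IseModel].
#' @param vector named numeric descriptor vector.
#' @return the score, a number in `[-1, 1]`.
#' @export
scoreMolecule <- function(model, vector) {
  stopifnot(is(model, "IseModel"))
  pass <- vapply(.modelFilters(model), filterPasses, logical(1L),
                 vector = vector)
  sum(ifelse(pass, model@wPass, -model@wFail)) / length(model@wPass)
}

#' Screen a compound library through a model
#'
#' Applies [scoreMolecule()] to every row of the descriptor table
#' (vectorized). Scoring is pure: identical inputs give identical output.
#'
#' @param model an [IseModel].
#' @param table [DescriptorTable] providing every model descriptor.
#' @param modelId label for the score column (default
#'   `"<target>:<action>"` from the model metadata).
#' @return a score table: data.frame with columns `molecule_id`,
#'   `model_id`, `score`, in the input row order.
#' @export
screenLibrary <- function(model, table, modelId = NULL) {
  stopifnot(is(model, "IseModel"), is(table, "DescriptorTable"))
  v <- table@values
  missing <- setdiff(unique(model@conditions$descriptor), colnames(v))
  if (length(missing))
    stop("library lacks model descriptor(s): ",
         paste(missing, collapse = ", "))
  if (is.null(modelId))
    modelId <- paste(model@metadata$targetId %||% "model",
                     model@metadata$action %||% "score", sep = ":")
  n <- length(model@wPass)
  if (!nrow(v))
    return(data.frame(molecule_id = character(), model_id = character(),
                      score = numeric()))
  total <- rep(0, nrow(v))
  conds <- model@conditions
  for (f in seq_len(n)) {
    cf <- conds[conds$filter == f, ]
    pass <- rep(TRUE, nrow(v))
    for (i in seq_len(nrow(cf))) {
      x <- v[, cf$descriptor[i]]
      pass <- pass & x >= cf$lo[i] & x <= cf$hi[i]
    }
    total <- total + ifelse(pass, model@wPass[f], -model@wFail[f])
  }
  data.frame(molecule_id = rownames(v), model_id = modelId,
             score = total / n, row.names = NULL)
}

#' Order a score table by descending score
#'
#' Ties are broken by molecule id (stable, locale-independent), so ranking
#' is fully deterministic.
#'
#' @param scoreTable data.frame as returned by [screenLibrary()].
#' @return the reordered data.frame.
#' @export
topScores <- function(scoreTable) {
  scoreTable[order(-scoreTable$score, scoreTable$molecule_id,
                   method = "radix"), , drop = FALSE]
}

#' Write / read a score-table CSV
#'
#' Full float precision ("%.17g"), columns `molecule_id,model_id,score`.
#' @param scoreTable score data.frame.
#' @param path CSV path.
#' @export
writeScoreCsv <- function(scoreTable, path) {
  lines <- c("molecule_id,model_id,score",
             sprintf("%s,%s,%.17g", scoreTable$molecule_id,
                     scoreTable$model_id, scoreTable$score))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeScoreCsv
#' @export
readScoreCsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.csv(path, check.names = FALSE,
                 colClasses = c(score = "numeric"))
  need <- c("molecule_id", "model_id", "score")
  if (!all(need %in% names(df)))
    stop("score CSV needs columns ", paste(need, collapse = ", "))
  df
}
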