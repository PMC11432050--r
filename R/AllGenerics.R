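## Generics and simple accessors shared across the package.

#' Molecule identifiers of an object
#' @param x an object carrying molecule ids.
#' @return character vector of ids.
#' @export
setGeneric("moleculeIds", function(x) standardGeneric("moleculeIds"))

#' Descriptor names of an object
#' @param x an object carrying descriptors.
#' @return character vector of descriptor names.
#' @export
setGeneric("descriptorNames", function(x) standardGeneric("descriptorNames"))

#' Numeric descriptor values
#' @param x an object carrying a descriptor matrix.
#' @return numeric matrix (molecules x descriptors).
#' @export
setGeneric("descriptorValues", function(x) standardGeneric("descriptorValues"))

#' @rdname moleculeIds
#' @export
setMethod("moleculeIds", "MoleculeSet", function(x) x@id)

#' @rdname moleculeIds
#' @export
setMethod("moleculeIds", "DescriptorTable", function(x) rownames(x@values))

#' @rdname moleculeIds
#' @export
setMethod("moleculeIds", "FingerprintSet", function(x) rownames(x@bits))

#' @rdname descriptorNames
#' @export
setMethod("descriptorNames", "DescriptorTable", function(x) colnames(x@values))

#' @rdname descriptorNames
#' @export
setMethod("descriptorNames", "ApplicabilityDomain", function(x) names(x@lo))

#' @rdname descriptorValues
#' @export
setMethod("descriptorValues", "DescriptorTable", function(x) x@values)

#' @rdname descriptorValues
#' @export
setMethod("descriptorValues", "LearningSet", function(x) x@table@values)

#' SMILES strings of a molecule set
#' @param x a [MoleculeSet].
#' @return named character vector of SMILES.
#' @export
smilesOf <- function(x) {
  stopifnot(is(x, "MoleculeSet"))
  setNames(x@smiles, x@id)
}

#' Rejected entries of a molecule set
#' @param x a [MoleculeSet].
#' @return data.frame with columns `id`, `structure`, `reason`.
#' @export
rejects <- function(x) {
  stopifnot(is(x, "MoleculeSet"))
  x@rejects
}

#' Positive / decoy ids of a learning set
#' @param x a [LearningSet].
#' @return character vector of ids.
#' @export
positives <- function(x) { stopifnot(is(x, "LearningSet")); x@positives }

#' @rdname positives
#' @export
decoys <- function(x) { stopifnot(is(x, "LearningSet")); x@decoys }

#' Descriptor table of a learning set
#' @param x a [LearningSet].
#' @return the underlying [DescriptorTable].
#' @export
learningTable <- function(x) { stopifnot(is(x, "LearningSet")); x@table }

#' Number of molecules in an object
#' @param x a MoleculeSet, DescriptorTable or FingerprintSet.
#' @export
setMethod("length", "MoleculeSet", function(x) length(x@id))

#' Subset a descriptor table by molecule ids and/or descriptors
#' @param x a [DescriptorTable]; `i` molecule ids or indices, `j` descriptor
#'   names or indices.
#' @param i,j,...,drop standard subsetting arguments; `drop` is ignored.
#' @export
setMethod("[", "DescriptorTable", function(x, i, j, ..., drop = FALSE) {
  v <- x@values
  if (!missing(i)) v <- v[i, , drop = FALSE]
  if (!missing(j)) v <- v[, j, drop = FALSE]
  new("DescriptorTable", values = v, provenance = x@provenance)
})

setMethod("show", "MoleculeSet", function(object) {
  cat("MoleculeSet with", length(object@id), "molecules,",
      nrow(object@rejects), "rejects\n")
  if (length(object@id)) {
    n <- min(3L, length(object@id))
    cat(paste0("  ", object@id[seq_len(n)], ": ",
               object@smiles[seq_len(n)], collapse = "\n"), "\n")
  }
})

setMethod("show", "DescriptorTable", function(object) {
  cat("DescriptorTable:", nrow(object@values), "molecules x",
      ncol(object@values), "descriptors")
  if (!is.na(object@provenance)) cat(" [", object@provenance, "]", sep = "")
  cat("\n")
})

setMethod("show", "LearningSet", function(object) {
  cat("LearningSet for", object@targetId, "/", object@action, "\n")
  cat("  positives:", length(object@positives),
      " decoys:", length(object@decoys),
      " (requested ratio 1:", object@ratio, ")\n", sep = "")
})

setMethod("show", "DiscretizationScheme", function(object) {
  alive <- sum(object@ranges$alive)
  cat("DiscretizationScheme:", length(object@descriptors), "descriptors,",
      nrow(object@ranges), "candidate ranges (", alive, "alive )\n")
})

setMethod("show", "IseModel", function(object) {
  cat("IseModel:", length(object@wPass), "filters for",
      object@metadata$targetId %||% "?", "/",
      object@metadata$action %||% "?", "\n")
  cat("  training MCC range:",
      sprintf("%.3f-%.3f", min(object@trainMcc), max(object@trainMcc)), "\n")
})

setMethod("show", "ConfusionMatrix", function(object) {
  cat("ConfusionMatrix  TP:", object@tp, " FP:", object@fp,
      " TN:", object@tn, " FN:", object@fn, "\n")
})

setMethod("show", "DrugTargetMatrix", function(object) {
  cat("DrugTargetMatrix (", object@mode, "): ", nrow(object@mat), " drugs x ",
      ncol(object@mat), " columns, ", sum(object@mat), " edges\n", sep = "")
})

setMethod("show", "FingerprintSet", function(object) {
  cat("FingerprintSet:", nrow(object@bits), "fingerprints x",
      ncol(object@bits), "bits")
  if (!is.na(object@type)) cat(" [", object@type, "]", sep = "")
  cat("\n")
})

setMethod("show", "CVReport", function(object) {
  cat(object@k, "-fold cross-validation\n", sep = "")
  m <- object@means
  cat(sprintf("  mean MCC %.3f  AUC %.3f  TPR %.3f  TNR %.3f  F %.3f\n",
              m[["mcc"]], m[["auc"]], m[["tpr"]], m[["tnr"]], m[["f_score"]]))
})

`%||%` <- function(a, b) if (is.null(a)) b else a

## Seed-scoped evaluation: run `expr` under `seed` without disturbing the
## caller's RNG stream; with seed = NULL the ambient stream is used.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## sample() safe against the length-1 x scalar expansion
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}
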