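## Model persistence: versioned JSON documents that round-trip bit-exactly.

.MODEL_FORMAT_VERSION <- "1.0"

#' Save / load an ISE model as JSON
#'
#' The document holds a version field, the metadata snapshot and one entry
#' per filter (`conditions` with closed intervals, `w_pass`, `w_fail`,
#' `train_mcc`). Doubles are serialized at full precision, so
#' `loadModel(saveModel(m))` reproduces scores bit-exactly on any library.
#' Malformed JSON and unknown version strings are explicit errors.
#'
#' @param model an [IseModel].
#' @param path JSON file path.
#' @return `saveModel()` the path, invisibly; `loadModel()` an [IseModel].
#' @export
saveModel <- function(model, path) {
  stopifnot(is(model, "IseModel"))
  filters <- lapply(seq_along(model@wPass), function(f) {
    cf <- model@conditions[model@conditions$filter == f, ]
    list(conditions = lapply(seq_len(nrow(cf)), function(i)
           list(descriptor = cf$descriptor[i], lo = cf$lo[i],
                hi = cf$hi[i])),
         w_pass = model@wPass[f], w_fail = model@wFail[f],
         train_mcc = model@trainMcc[f])
  })
  doc <- list(version = .MODEL_FORMAT_VERSION, metadata = model@metadata,
              filters = filters)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e)
                    stop("malformed model JSON in ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  if (is.null(doc$version))
    stop("not a model file (missing version field): ", path)
  if (!identical(doc$version, .MODEL_FORMAT_VERSION))
    stop("unsupported model format version '", doc$version,
         "' (this build reads ", .MODEL_FORMAT_VERSION, ")")
  if (!length(doc$filters)) stop("model file contains no filters")
  conds <- do.call(rbind, lapply(seq_along(doc$filters), function(f) {
    cs <- doc$filters[[f]]$conditions
    data.frame(filter = f,
               descriptor = vapply(cs, `[[`, "", "descriptor"),
               lo = vapply(cs, function(c) as.numeric(c$lo), 0),
               hi = vapply(cs, function(c) as.numeric(c$hi), 0))
  }))
  num <- function(field) vapply(doc$filters, function(f)
    as.numeric(f[[field]]), 0)
  meta <- doc$metadata
  new("IseModel", conditions = conds, wPass = num("w_pass"),
      wFail = num("w_fail"), trainMcc = num("train_mcc"),
      metadata = if (is.null(meta)) list() else meta)
}
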