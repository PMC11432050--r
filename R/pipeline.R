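## End-to-end workflow: build a model per (target, action), screen a
## library, derive cutoff reports, drug-target matrices and candidate
## lists. The exec/ise script is a thin command-line wrapper over these
## functions.

#' Pipeline configuration
#'
#' Validated parameter set for [runPipeline()]. Every output carries this
#' configuration (and the seed) in its metadata; reruns with the same
#' configuration and inputs are byte-identical.
#'
#' @param seed integer seed governing decoy sampling and model training.
#' @param thresholdUM activity threshold in micromolar (default 100).
#' @param ratio decoys per positive (default 100).
#' @param trimFraction applicability-domain trim (default 0).
#' @param minPositives minimum actives per model (default 20).
#' @param cutoff high-score cutoff for the predicted matrices
#'   (default 0.7).
#' @param grid cutoff-report grid (default 0, 0.1, ..., 0.9; first row
#'   strict).
#' @param ise an [iseConfig()].
#' @param candidates optional list with elements `target`
#'   (`c(target_id, action)`), `cutoff`, `antiTargets` (data.frame),
#'   `antiCutoff` for candidate selection.
#' @return list of class `"pipelineConfig"`.
#' @export
pipelineConfig <- function(seed = 1, thresholdUM = 100, ratio = 100,
                           trimFraction = 0, minPositives = 20,
                           cutoff = 0.7,
                           grid = c(0, seq(0.1, 0.9, by = 0.1)),
                           ise = iseConfig(), candidates = NULL) {
  stopifnot(inherits(ise, "iseConfig"), thresholdUM > 0, ratio >= 1,
            minPositives >= 1, length(grid) >= 1)
  structure(list(seed = seed, thresholdUM = thresholdUM, ratio = ratio,
                 trimFraction = trimFraction, minPositives = minPositives,
                 cutoff = cutoff, grid = grid, ise = ise,
                 candidates = candidates),
            class = "pipelineConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full screening pipeline
#'
#' For every (target, action) pair present in the activity records:
#' assemble a learning set, train an ISE model and save it as JSON; then
#' screen the library through every model, write the score table, the
#' per-cutoff prediction report (against the activity annotations), the
#' predicted and reported activity/interaction matrices with their
#' comparison, and optionally a candidate list with anti-target exclusion.
#' Stage counts are reported via [message()]; any stage error aborts with
#' the stage name. Inputs are never mutated.
#'
#' @param activities activity data.frame (see [validateActivities()]).
#' @param positivesTable [DescriptorTable] covering the candidate actives.
#' @param pool [DescriptorTable] decoy pool (same descriptors).
#' @param library [DescriptorTable] of the compounds to screen.
#' @param outDir output directory (created if absent).
#' @param config a [pipelineConfig()].
#' @return invisibly, a list with the trained models, the long score
#'   table, the cutoff report, the comparison report and the candidate
#'   ids (or NULL).
#' @export
runPipeline <- function(activities, positivesTable, pool, library, outDir,
                        config = pipelineConfig()) {
  stopifnot(inherits(config, "pipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(outDir, "models"), showWarnings = FALSE)
  withSeed(config$seed, {
    pairs <- unique(activities[c("target_id", "action")])
    models <- list()
    scoreRows <- list()
    for (i in seq_len(nrow(pairs))) {
      t <- pairs$target_id[i]
      a <- pairs$action[i]
      tag <- paste(t, a, sep = ":")
      message("== model ", tag, " ==")
      ls <- .stage(paste0("learning-set ", tag),
                   assembleLearningSet(activities, positivesTable, pool,
                                       targetId = t, action = a,
                                       thresholdUM = config$thresholdUM,
                                       ratio = config$ratio,
                                       trimFraction = config$trimFraction,
                                       minPositives = config$minPositives,
                                       exclude = moleculeIds(library)))
      model <- .stage(paste0("train ", tag), runIse(ls, config$ise))
      model@metadata$pipelineSeed <- config$seed
      saveModel(model, file.path(outDir, "models",
                                 paste0(t, "_", a, ".json")))
      st <- .stage(paste0("screen ", tag), screenLibrary(model, library))
      st$target_id <- t
      st$action <- a
      models[[tag]] <- model
      scoreRows[[tag]] <- st
      message("model ", tag, ": ", length(model@wPass), " filters, ",
              sum(st$score >= config$cutoff), " library hits at cutoff ",
              config$cutoff)
    }
    scores <- do.call(rbind, scoreRows)
    rownames(scores) <- NULL
    writeScoreCsv(scores, file.path(outDir, "scores.csv"))

    known <- unique(activities[c("molecule_id", "target_id", "action")])
    known$model_id <- paste(known$target_id, known$action, sep = ":")
    known <- known[known$molecule_id %in% moleculeIds(library), ]
    rep <- .stage("cutoff-report",
                  cutoffReport(scores, known, config$grid))
    utils::write.csv(rep, file.path(outDir, "cutoff_report.csv"),
                     row.names = FALSE)

    act <- .stage("activity-matrix",
                  buildActivityMatrix(scores, config$cutoff))
    int <- toInteractionMatrix(act)
    repAct <- buildReportedMatrix(known, "activity")
    repInt <- buildReportedMatrix(known, "interaction")
    writeMatrixCsv(act, file.path(outDir, "predicted_activity.csv"))
    writeMatrixCsv(int, file.path(outDir, "predicted_interaction.csv"))
    cmpAct <- compareMatrices(act, repAct)
    cmpInt <- compareMatrices(int, repInt)
    utils::write.csv(cmpAct$per_target,
                     file.path(outDir, "comparison_activity.csv"),
                     row.names = FALSE)
    message("activity comparison: ", cmpAct$n_successful, " successful, ",
            cmpAct$n_new, " new of ", cmpAct$n_known, " known")

    cand <- NULL
    if (!is.null(config$candidates)) {
      cc <- config$candidates
      cand <- .stage("candidates",
                     selectCandidates(scores, cc$target,
                                      cutoff = cc$cutoff %||% config$cutoff,
                                      antiTargets = cc$antiTargets,
                                      antiCutoff = cc$antiCutoff %||% 0))
      writeLines(cand, file.path(outDir, "candidates.txt"))
    }
    cfg <- list(seed = config$seed, thresholdUM = config$thresholdUM,
                ratio = config$ratio, trimFraction = config$trimFraction,
                minPositives = config$minPositives, cutoff = config$cutoff,
                grid = config$grid, ise = unclass(config$ise))
    jsonlite::write_json(list(config = cfg,
                              models = names(models),
                              comparison = list(
                                activity = cmpAct[c("n_known",
                                                    "n_successful", "n_new",
                                                    "pct_successful")],
                                interaction = cmpInt[c("n_known",
                                                       "n_successful",
                                                       "n_new",
                                                       "pct_successful")])),
                         file.path(outDir, "run.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(list(models = models, scores = scores, cutoffReport = rep,
                   comparison = list(activity = cmpAct,
                                     interaction = cmpInt),
                   candidates = cand))
  })
}
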