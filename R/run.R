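# Reproducible end-to-end runs wiring the modules together; the thin
# command-line script in inst/scripts/sinusdx.R dispatches to these.

#' Simulate a synthetic scene suite to disk
#'
#' Writes COCO-style annotations, the sidecar metadata CSV and a manifest
#' JSON for \code{n} generated scenes.
#'
#' @param outDir output directory.
#' @param n number of scenes.
#' @param params a \linkS4class{SceneParams}.
#' @param cfg an \linkS4class{AlgorithmConfig}.
#' @return Invisibly, the suite (frames + manifest).
#' @export
runSimulate <- function(outDir, n, params = sceneParams(),
                        cfg = algorithmConfig()) {
  suite <- generateSuite(params, n, cfg)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  writeFramesCoco(suite$frames, file.path(outDir, "annotations.json"),
                  file.path(outDir, "metadata.csv"))
  jsonlite::write_json(list(seed = params@seed, n = n,
                            manifest = suite$manifest),
                       file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(suite)
}

#' Run the diagnostic algorithm over an annotation set
#'
#' Reads frames, applies confidence filtering, diagnoses every frame and
#' writes the per-frame results table plus run summary.
#'
#' @param annotations annotation file (COCO JSON) or directory (YOLO).
#' @param metadata sidecar metadata CSV path or data.frame.
#' @param outDir output directory for \code{results.csv} /
#'   \code{summary.json}.
#' @param format annotation dialect, as in [readFrames()].
#' @param cfg an \linkS4class{AlgorithmConfig}.
#' @return Invisibly, list(frames, results, table).
#' @export
runDiagnose <- function(annotations, metadata, outDir,
                        format = c("coco_json", "yolo_seg"),
                        cfg = algorithmConfig()) {
  frames <- readFrames(annotations, format, metadata)
  frames <- lapply(frames, filterByConfidence, cfg = cfg)
  results <- diagnoseBatch(frames, cfg)
  tab <- writeResults(frames, results, outDir, cfg)
  invisible(list(frames = frames, results = results, table = tab))
}

#' Evaluate the algorithm against ground truth
#'
#' Recomputes diagnoses and writes a full evaluation report:
#' laterality-stratified classification metrics, the trigger-pathway
#' tally with pathway statistics, and (when both classes are present) the
#' ROC curve with bootstrap AUC interval.
#'
#' @param annotations,metadata,format as in [runDiagnose()]; every frame
#'   needs a ground-truth label.
#' @param outDir output directory; writes \code{report.json},
#'   \code{classification.csv}, \code{pathways.csv} and \code{roc.csv}.
#' @param cfg an \linkS4class{AlgorithmConfig}.
#' @param seed bootstrap seed for the AUC interval.
#' @return Invisibly, the report list.
#' @export
runEvaluate <- function(annotations, metadata, outDir,
                        format = c("coco_json", "yolo_seg"),
                        cfg = algorithmConfig(), seed = 1L) {
  frames <- readFrames(annotations, format, metadata)
  gt <- vapply(frames, gtLabel, character(1))
  if (any(is.na(gt)))
    stop("evaluation requires a ground-truth label for every frame")
  frames <- lapply(frames, filterByConfidence, cfg = cfg)
  results <- diagnoseBatch(frames, cfg)

  cls <- classificationByLaterality(frames, results)
  tally <- triggerTally(frames, results)
  pstats <- pathwayStats(tally)

  roc <- NULL
  if (length(unique(gt)) == 2L)
    roc <- rocAnalysis(frames, cfg, seed = seed)

  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cls, file.path(outDir, "classification.csv"), row.names = FALSE)
  utils::write.csv(pstats, file.path(outDir, "pathways.csv"), row.names = FALSE)
  if (!is.null(roc))
    utils::write.csv(data.frame(threshold = roc@thresholds, tpr = roc@tpr,
                                fpr = roc@fpr),
                     file.path(outDir, "roc.csv"), row.names = FALSE)
  report <- list(
    n_frames = length(frames),
    classification = cls,
    trigger_tally = tally,
    pathway_stats = pstats,
    auc = if (is.null(roc)) NA else roc@auc,
    auc_ci = if (is.null(roc)) c(NA, NA) else c(roc@ciLow, roc@ciHigh),
    roc_available = !is.null(roc))
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(report)
}
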