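# Input contract and file I/O for upstream-detector outputs and
# ground-truth annotations. Laterality and expert labels travel in a
# sidecar metadata CSV (frame_id, laterality, gt_label[, width, height])
# since neither COCO nor YOLO formats carry them.

#' Default mapping from labeler category names to algorithm classes
#' @export
defaultCategoryMap <- c("middle turbinate" = "MT",
                        "inferior turbinate" = "IT",
                        "mucus" = "mucus")

readMetadata <- function(metadata) {
  if (is.character(metadata)) {
    if (!file.exists(metadata)) stop("metadata file not found: ", metadata)
    metadata <- utils::read.csv(metadata, stringsAsFactors = FALSE)
  }
  if (!all(c("frame_id", "laterality") %in% names(metadata)))
    stop("metadata needs columns frame_id and laterality")
  metadata$frame_id <- as.character(metadata$frame_id)
  bad <- !metadata$laterality %in% LATERALITIES
  if (any(bad))
    stop("invalid or missing laterality for frame(s): ",
         paste(metadata$frame_id[bad], collapse = ", "))
  if (is.null(metadata$gt_label)) metadata$gt_label <- NA_character_
  metadata$gt_label[metadata$gt_label %in% c("", "NA")] <- NA_character_
  metadata
}

metaRow <- function(meta, id) {
  i <- match(id, meta$frame_id)
  if (is.na(i))
    stop("frame '", id, "' has no metadata row (laterality is required, never guessed)")
  meta[i, , drop = FALSE]
}

# polygon parts from a COCO segmentation entry (list of flat x,y lists)
cocoSegToMask <- function(seg) {
  parts <- lapply(seg, function(fl) {
    fl <- as.numeric(unlist(fl))
    matrix(fl, ncol = 2L, byrow = TRUE)
  })
  parts <- Filter(function(p) nrow(p) >= 3L, parts)
  if (length(parts) == 0L) return(NULL)
  polygonMask(parts)
}

#' Read frames from annotation files
#'
#' Reads upstream-detector outputs or ground-truth annotations into
#' \linkS4class{EndoscopyFrame} objects. Two dialects are supported:
#' \describe{
#'   \item{\code{"coco_json"}}{one COCO-style JSON file
#'     (images / annotations / categories, polygon segmentations, optional
#'     per-annotation \code{score}; score defaults to 1 for ground truth).
#'     Frame ids are image file names without extension (or the numeric
#'     image id when no file name is present).}
#'   \item{\code{"yolo_seg"}}{a directory of per-image \code{.txt} files,
#'     one \code{class-index x1 y1 x2 y2 ...} polygon per line with
#'     coordinates normalized to \[0, 1\] (an optional trailing confidence
#'     is detected by token parity); frame ids are file names without
#'     extension.}
#' }
#' Laterality and the optional expert label come from the sidecar
#' metadata table; a frame listed there but absent from the annotations
#' yields an empty detection list, and a frame without a metadata row is
#' an error.
#'
#' @param path annotation JSON file (\code{coco_json}) or directory of
#'   label files (\code{yolo_seg}).
#' @param format \code{"coco_json"} or \code{"yolo_seg"}.
#' @param metadata sidecar CSV path or data.frame with columns
#'   \code{frame_id}, \code{laterality}, optional \code{gt_label},
#'   \code{width}, \code{height}.
#' @param categoryMap named character vector mapping annotation category
#'   names (COCO) to \code{c("MT", "IT", "mucus")}; unknown categories are
#'   an error naming the offender.
#' @param classMap character vector mapping YOLO class indices (0-based)
#'   to algorithm classes; default \code{c("MT", "IT", "mucus")}.
#' @return List of \linkS4class{EndoscopyFrame}, ordered by metadata row.
#' @export
readFrames <- function(path, format = c("coco_json", "yolo_seg"), metadata,
                       categoryMap = defaultCategoryMap,
                       classMap = DETECTION_LABELS) {
  format <- match.arg(format)
  meta <- readMetadata(metadata)
  perFrame <- switch(format,
    coco_json = readCocoDetections(path, categoryMap),
    yolo_seg  = readYoloDetections(path, meta, classMap))
  orphans <- setdiff(names(perFrame), meta$frame_id)
  if (length(orphans))
    stop("no metadata (laterality is required, never guessed) for frame(s): ",
         paste(orphans, collapse = ", "))

  lapply(seq_len(nrow(meta)), function(i) {
    row <- meta[i, ]
    info <- perFrame[[row$frame_id]]
    w <- if (!is.null(info$width)) info$width
         else if (!is.null(meta$width)) row$width else 1024
    h <- if (!is.null(info$height)) info$height
         else if (!is.null(meta$height)) row$height else 768
    endoscopyFrame(row$frame_id, width = w, height = h,
                   laterality = row$laterality,
                   detections = if (is.null(info)) list() else info$detections,
                   gtLabel = row$gt_label)
  })
}

readCocoDetections <- function(path, categoryMap) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  coco <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  catName <- vapply(coco$categories, function(ct) as.character(ct$name), character(1))
  names(catName) <- vapply(coco$categories, function(ct) as.character(ct$id), character(1))
  unknown <- setdiff(catName, names(categoryMap))
  if (length(unknown))
    stop("unknown annotation categor(ies) without mapping: ",
         paste(unknown, collapse = ", "))

  frames <- list()
  idToFrame <- character(0)
  for (img in coco$images) {
    fid <- if (!is.null(img$file_name))
      tools::file_path_sans_ext(basename(img$file_name)) else as.character(img$id)
    idToFrame[[as.character(img$id)]] <- fid
    frames[[fid]] <- list(width = img$width, height = img$height,
                          detections = list())
  }
  for (ann in coco$annotations) {
    fid <- idToFrame[[as.character(ann$image_id)]]
    if (is.null(fid)) stop("annotation references unknown image id ", ann$image_id)
    label <- unname(categoryMap[[catName[[as.character(ann$category_id)]]]])
    confidence <- if (!is.null(ann$score)) ann$score else 1
    mask <- if (!is.null(ann$segmentation) && length(ann$segmentation))
      cocoSegToMask(ann$segmentation) else NULL
    box <- if (is.null(mask)) {
      bb <- as.numeric(unlist(ann$bbox))  # COCO bbox is (x, y, w, h)
      boundingBox(bb[1], bb[2], bb[1] + bb[3], bb[2] + bb[4])
    } else NULL
    frames[[fid]]$detections <- c(frames[[fid]]$detections,
                                  detection(label, confidence, mask = mask, box = box))
  }
  frames
}

readYoloDetections <- function(path, meta, classMap) {
  if (!dir.exists(path)) stop("label directory not found: ", path)
  files <- list.files(path, pattern = "\\.txt$", full.names = TRUE)
  frames <- list()
  for (f in files) {
    fid <- tools::file_path_sans_ext(basename(f))
    row <- metaRow(meta, fid)
    w <- if (!is.null(meta$width)) row$width else 1024
    h <- if (!is.null(meta$height)) row$height else 768
    dets <- list()
    for (line in readLines(f, warn = FALSE)) {
      tok <- as.numeric(strsplit(trimws(line), "\\s+")[[1]])
      if (length(tok) < 7L) next
      # class + 2k coords is an odd token count; an appended confidence
      # (predictions saved with confidences) makes it even
      if (length(tok) %% 2L == 0L) {
        confidence <- tok[length(tok)]
        tok <- tok[-length(tok)]
      } else confidence <- 1
      cls <- classMap[tok[1L] + 1L]
      if (is.na(cls)) stop("unknown YOLO class index ", tok[1L], " in ", f)
      xy <- matrix(tok[-1L], ncol = 2L, byrow = TRUE)
      xy[, 1L] <- xy[, 1L] * w
      xy[, 2L] <- xy[, 2L] * h
      dets <- c(dets, detection(cls, confidence, mask = polygonMask(xy)))
    }
    frames[[fid]] <- list(width = w, height = h, detections = dets)
  }
  frames
}

#' Drop detections below the confidence threshold
#'
#' Retains detections with \code{confidence >= confidenceThreshold}
#' (inclusive at the boundary), preserving order. Idempotent.
#'
#' @param frame an \linkS4class{EndoscopyFrame}.
#' @param cfg an \linkS4class{AlgorithmConfig}.
#' @return The filtered frame.
#' @export
filterByConfidence <- function(frame, cfg = algorithmConfig()) {
  keep <- vapply(frame@detections, function(d)
    d@confidence >= cfg@confidenceThreshold, logical(1))
  initialize(frame, detections = frame@detections[keep])
}

#' Write frames as COCO-style JSON plus sidecar metadata CSV
#'
#' Inverse of [readFrames()] for the \code{coco_json} dialect; geometry
#' round-trips losslessly.
#'
#' @param frames list of \linkS4class{EndoscopyFrame}.
#' @param annotationsPath output JSON path.
#' @param metadataPath output CSV path.
#' @param categoryMap named map from category names to classes (inverted
#'   for writing).
#' @return Invisibly, the annotation path.
#' @export
writeFramesCoco <- function(frames, annotationsPath, metadataPath,
                            categoryMap = defaultCategoryMap) {
  classToName <- stats::setNames(names(categoryMap), categoryMap)
  cats <- lapply(seq_along(categoryMap), function(i)
    list(id = i, name = names(categoryMap)[i]))
  catId <- stats::setNames(seq_along(categoryMap), unname(categoryMap))

  images <- list(); annotations <- list(); annId <- 0L
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    images[[i]] <- list(id = i, file_name = paste0(fr@frameId, ".jpg"),
                        width = fr@width, height = fr@height)
    for (d in fr@detections) {
      annId <- annId + 1L
      seg <- if (!is.null(d@mask))
        lapply(d@mask@parts, function(p) as.numeric(t(p))) else list()
      annotations[[annId]] <- list(
        id = annId, image_id = i, category_id = unname(catId[[d@label]]),
        segmentation = seg, score = d@confidence,
        bbox = c(d@box@x1, d@box@y1, d@box@x2 - d@box@x1, d@box@y2 - d@box@y1),
        area = if (!is.null(d@mask)) maskArea(d@mask) else boxArea(d@box))
    }
  }
  jsonlite::write_json(list(images = images, annotations = annotations,
                            categories = cats),
                       annotationsPath, auto_unbox = TRUE, digits = NA)
  meta <- data.frame(
    frame_id = vapply(frames, function(f) f@frameId, character(1)),
    laterality = vapply(frames, function(f) f@laterality, character(1)),
    gt_label = vapply(frames, function(f) f@gtLabel, character(1)),
    width = vapply(frames, function(f) f@width, numeric(1)),
    height = vapply(frames, function(f) f@height, numeric(1)))
  utils::write.csv(meta, metadataPath, row.names = FALSE)
  invisible(annotationsPath)
}

#' Tabulate per-frame diagnostic results
#'
#' @param frames list of \linkS4class{EndoscopyFrame}.
#' @param results matching list of \linkS4class{DiagnosisResult}.
#' @return data.frame with one row per frame: identifiers, laterality,
#'   ground truth, call, fired pathways, both pathway IoUs, and the
#'   middle-meatus box and method.
#' @export
resultsTable <- function(frames, results) {
  if (length(frames) != length(results))
    stop("one result per frame required (", length(frames), " frames, ",
         length(results), " results)")
  rows <- lapply(seq_along(frames), function(i) {
    fr <- frames[[i]]; rs <- results[[i]]
    if (fr@frameId != rs@frameId)
      stop("frame/result id mismatch at position ", i)
    b <- rs@mm@box
    data.frame(frame_id = fr@frameId, laterality = fr@laterality,
               gt_label = fr@gtLabel, call = rs@call,
               triggers = paste(rs@triggers, collapse = "|"),
               iou_mm = rs@iouMM, iou_mt = rs@iouMT,
               mm_method = rs@mm@method, mm_clamped = rs@mm@clamped,
               mm_x1 = if (is.null(b)) NA_real_ else b@x1,
               mm_y1 = if (is.null(b)) NA_real_ else b@y1,
               mm_x2 = if (is.null(b)) NA_real_ else b@x2,
               mm_y2 = if (is.null(b)) NA_real_ else b@y2)
  })
  if (length(rows) == 0L)
    return(data.frame(frame_id = character(0), laterality = character(0),
                      gt_label = character(0), call = character(0),
                      triggers = character(0), iou_mm = numeric(0),
                      iou_mt = numeric(0), mm_method = character(0),
                      mm_clamped = logical(0), mm_x1 = numeric(0),
                      mm_y1 = numeric(0), mm_x2 = numeric(0),
                      mm_y2 = numeric(0)))
  do.call(rbind, rows)
}

#' Write per-frame results and a machine-readable run summary
#'
#' @param frames,results as for [resultsTable()].
#' @param dir output directory (created if needed); writes
#'   \code{results.csv} and \code{summary.json}.
#' @param cfg the \linkS4class{AlgorithmConfig} used, echoed into the
#'   summary.
#' @return Invisibly, the results table.
#' @export
writeResults <- function(frames, results, dir, cfg = algorithmConfig()) {
  tab <- resultsTable(frames, results)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(tab, file.path(dir, "results.csv"), row.names = FALSE)
  summary <- list(
    n_frames = length(frames),
    n_positive = sum(tab$call == "positive"),
    n_negative = sum(tab$call == "negative"),
    pathway_firings = list(
      MM_mucus = sum(grepl("MM_mucus", tab$triggers)),
      MT_mucus = sum(grepl("MT_mucus", tab$triggers))),
    mm_method = as.list(table(factor(tab$mm_method,
                                     levels = c("primary", "fallback", "failed")))),
    config = list(delta_x = cfg@deltaX, delta_y = cfg@deltaY,
                  delta_x_safe = cfg@deltaXSafe,
                  iou_threshold = cfg@iouThreshold,
                  confidence_threshold = cfg@confidenceThreshold,
                  fallback_y_rule = cfg@fallbackYRule,
                  call_mode = cfg@callMode,
                  mucus_aggregation = cfg@mucusAggregation))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(tab)
}
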