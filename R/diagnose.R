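# Conditional IoU logic: sinusitis call and trigger-pathway record.

# area of the union of a list of boxes (coordinate-compression sweep)
rectUnionArea <- function(boxes) {
  if (length(boxes) == 0L) return(0)
  xs <- sort(unique(unlist(lapply(boxes, function(b) c(b@x1, b@x2)))))
  ys <- sort(unique(unlist(lapply(boxes, function(b) c(b@y1, b@y2)))))
  if (length(xs) < 2L || length(ys) < 2L) return(0)
  cx <- (xs[-1L] + xs[-length(xs)]) / 2
  cy <- (ys[-1L] + ys[-length(ys)]) / 2
  wd <- diff(xs); ht <- diff(ys)
  covered <- matrix(FALSE, length(cx), length(cy))
  for (b in boxes)
    covered <- covered | outer(cx > b@x1 & cx < b@x2, cy > b@y1 & cy < b@y2, "&")
  sum(outer(wd, ht) * covered)
}

# IoU between one box and the union of several boxes
iouBoxUnion <- function(a, boxes) {
  if (length(boxes) == 0L) return(NA_real_)
  inter <- rectUnionArea(lapply(boxes, function(b) {
    x1 <- max(a@x1, b@x1); y1 <- max(a@y1, b@y1)
    x2 <- min(a@x2, b@x2); y2 <- min(a@y2, b@y2)
    if (x2 <= x1 || y2 <= y1) NULL else boundingBox(x1, y1, x2, y2)
  }) |> Filter(f = Negate(is.null)))
  un <- boxArea(a) + rectUnionArea(boxes) - inter
  inter / un
}

# pathway IoU between a landmark box and the frame's mucus boxes
pathwayIoU <- function(landmarkBox, mucusBoxes, aggregation) {
  if (length(mucusBoxes) == 0L) return(NA_real_)
  if (aggregation == "union") return(iouBoxUnion(landmarkBox, mucusBoxes))
  max(vapply(mucusBoxes, function(mb) iouBoxes(landmarkBox, mb), numeric(1)))
}

#' Diagnose sinusitis on one frame
#'
#' Applies the conditional IoU logic: the middle-meatus region is
#' localized with [locateMM()], then the IoU between that region and the
#' detected mucus (primary MM-mucus pathway) and between the middle
#' turbinate's box and the mucus (fallback MT-mucus pathway, for frames
#' where substantial mucus is deposited over the turbinate itself) are
#' compared against the diagnostic threshold with a strict inequality
#' (\code{IoU > 0.3} at the default). A pathway whose landmark is missing
#' reports an NA IoU and cannot fire; a frame with no middle turbinate or
#' no mucus is always a negative call.
#'
#' Both pathway IoUs are always computed and reported. Under the default
#' \code{callMode = "permissive"} either pathway firing yields a positive
#' call and all firing pathways are recorded; under \code{"strict"} the
#' MT-mucus pathway is eligible only when middle-meatus localization
#' failed.
#'
#' @param frame an \linkS4class{EndoscopyFrame}, already
#'   confidence-filtered (a frame with sub-threshold detections triggers a
#'   warning and is filtered automatically).
#' @param cfg an \linkS4class{AlgorithmConfig}.
#' @return A \linkS4class{DiagnosisResult}.
#' @examples
#' mt <- detection("MT", 0.9, mask = cbind(c(400, 600, 600, 400), c(100, 100, 400, 400)))
#' mu <- detection("mucus", 0.8, box = boundingBox(355, 100, 400, 480))
#' fr <- endoscopyFrame("ex", laterality = "right", detections = list(mt, mu))
#' diagnose(fr)
#' @export
diagnose <- function(frame, cfg = algorithmConfig()) {
  stopifnot(is(frame, "EndoscopyFrame"), is(cfg, "AlgorithmConfig"))
  conf <- vapply(frame@detections, function(d) d@confidence, numeric(1))
  if (any(conf < cfg@confidenceThreshold)) {
    warning(sprintf("frame %s: %d detection(s) below the confidence threshold; filtering",
                    frame@frameId, sum(conf < cfg@confidenceThreshold)))
    frame <- filterByConfidence(frame, cfg)
  }

  dets <- frame@detections
  mt <- selectInstance(dets, "MT")
  it <- selectInstance(dets, "IT")
  mucusBoxes <- lapply(Filter(function(d) d@label == "mucus", dets),
                       function(d) d@box)

  mm <- locateMM(mt, it, frame@laterality, frame@width, frame@height, cfg)

  iou_mm <- if (mm@method != "failed")
    pathwayIoU(mm@box, mucusBoxes, cfg@mucusAggregation) else NA_real_
  iou_mt <- if (!is.null(mt))
    pathwayIoU(mt@box, mucusBoxes, cfg@mucusAggregation) else NA_real_

  mmFire <- isTRUE(iou_mm > cfg@iouThreshold)
  mtFire <- isTRUE(iou_mt > cfg@iouThreshold)

  trg <- character(0)
  if (mmFire) trg <- c(trg, "MM_mucus")
  if (mtFire && (cfg@callMode == "permissive" || mm@method == "failed"))
    trg <- c(trg, "MT_mucus")

  new("DiagnosisResult", frameId = frame@frameId,
      call = if (length(trg)) "positive" else "negative",
      triggers = trg, iouMM = iou_mm, iouMT = iou_mt, mm = mm)
}

#' Diagnose a batch of frames
#'
#' Element-wise [diagnose()]; order preserved.
#'
#' @param frames list of \linkS4class{EndoscopyFrame}.
#' @param cfg an \linkS4class{AlgorithmConfig}.
#' @return List of \linkS4class{DiagnosisResult}, one per frame.
#' @export
diagnoseBatch <- function(frames, cfg = algorithmConfig()) {
  lapply(frames, diagnose, cfg = cfg)
}
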