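# User-facing constructors, accessors and show methods.

#' Construct a Detection
#'
#' If a mask is supplied the bounding box is derived from it (tight box);
#' a box may be supplied alone for box-only detections.
#'
#' @param label \code{"MT"}, \code{"IT"} or \code{"mucus"}.
#' @param confidence detector confidence in \[0, 1\].
#' @param mask optional \linkS4class{PolygonMask} (or vertex matrix / list
#'   of matrices, passed to [polygonMask()]).
#' @param box optional \linkS4class{BoundingBox}; ignored when a mask is
#'   given.
#' @return A \linkS4class{Detection}.
#' @examples
#' detection("MT", 0.9, mask = cbind(c(400, 600, 600, 400), c(100, 100, 400, 400)))
#' @export
detection <- function(label, confidence = 1, mask = NULL, box = NULL) {
  if (!is.null(mask) && !is(mask, "PolygonMask")) mask <- polygonMask(mask)
  if (!is.null(mask)) box <- maskToBox(mask)
  if (is.null(box)) stop("a Detection needs a mask or a box")
  new("Detection", label = label, confidence = as.numeric(confidence),
      mask = mask, box = box)
}

# clamp one detection into the frame; NULL if nothing remains
clampDetection <- function(d, width, height) {
  if (!is.null(d@mask)) {
    parts <- lapply(d@mask@parts, function(p) {
      p[, 1L] <- pmin(pmax(p[, 1L], 0), width)
      p[, 2L] <- pmin(pmax(p[, 2L], 0), height)
      p
    })
    ok <- vapply(parts, function(p) abs(shoelace_area(p)) > sqrt(.Machine$double.eps),
                 logical(1))
    if (!any(ok)) return(NULL)
    m <- polygonMask(parts[ok])
    return(detection(d@label, d@confidence, mask = m))
  }
  cl <- clampBox(d@box, width, height)
  if (is.null(cl$box)) return(NULL)
  detection(d@label, d@confidence, box = cl$box)
}

#' Construct an EndoscopyFrame
#'
#' Detection geometry is clamped to the frame on construction; detections
#' left degenerate by clamping (entirely outside the frame) are dropped
#' with a warning.
#'
#' @param frameId frame identifier.
#' @param width,height frame size in pixels (native endoscopy frames are
#'   1024 x 768).
#' @param laterality \code{"left"} or \code{"right"} nasal cavity
#'   (required metadata).
#' @param detections list of \linkS4class{Detection}.
#' @param gtLabel optional expert sinusitis label, \code{"positive"} /
#'   \code{"negative"} / NA.
#' @return An \linkS4class{EndoscopyFrame}.
#' @export
endoscopyFrame <- function(frameId, width = 1024, height = 768, laterality,
                           detections = list(), gtLabel = NA_character_) {
  laterality <- match.arg(laterality, LATERALITIES)
  kept <- lapply(detections, clampDetection, width = width, height = height)
  dropped <- vapply(kept, is.null, logical(1))
  if (any(dropped))
    warning(sprintf("frame %s: dropped %d detection(s) entirely outside the frame",
                    frameId, sum(dropped)))
  new("EndoscopyFrame", frameId = as.character(frameId),
      width = as.numeric(width), height = as.numeric(height),
      laterality = laterality, detections = kept[!dropped],
      gtLabel = as.character(gtLabel))
}

#' Construct the algorithm configuration
#'
#' @param deltaX horizontal extent of the primary middle-meatus box (px,
#'   default 50).
#' @param deltaY superior displacement above the middle-turbinate top (px,
#'   default 20).
#' @param deltaXSafe conservative horizontal extent of the fallback box
#'   (px, default 30).
#' @param iouThreshold diagnostic IoU threshold (default 0.3, strict
#'   inequality).
#' @param confidenceThreshold detection confidence cutoff (default 0.3,
#'   inclusive).
#' @param fallbackYRule lower bound of the middle-meatus box when the
#'   inferior turbinate is undetected: \code{"extended"} (default,
#'   y_MTbottom + 0.5 h_MT) or \code{"strict_mt"} (y_MTbottom).
#' @param callMode \code{"permissive"} (default; positive if either
#'   pathway fires) or \code{"strict"} (MT-mucus pathway eligible only
#'   when middle-meatus localization fails).
#' @param mucusAggregation \code{"max"} (default) or \code{"union"} over
#'   multiple mucus instances.
#' @return An \linkS4class{AlgorithmConfig}.
#' @examples
#' algorithmConfig(iouThreshold = 0.5)
#' @export
algorithmConfig <- function(deltaX = 50, deltaY = 20, deltaXSafe = 30,
                            iouThreshold = 0.3, confidenceThreshold = 0.3,
                            fallbackYRule = c("extended", "strict_mt"),
                            callMode = c("permissive", "strict"),
                            mucusAggregation = c("max", "union")) {
  new("AlgorithmConfig", deltaX = deltaX, deltaY = deltaY,
      deltaXSafe = deltaXSafe, iouThreshold = iouThreshold,
      confidenceThreshold = confidenceThreshold,
      fallbackYRule = match.arg(fallbackYRule),
      callMode = match.arg(callMode),
      mucusAggregation = match.arg(mucusAggregation))
}

## accessors -----------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("frameId", "EndoscopyFrame", function(x) x@frameId)
#' @rdname accessors
#' @export
setMethod("frameId", "DiagnosisResult", function(x) x@frameId)
#' @rdname accessors
#' @export
setMethod("laterality", "EndoscopyFrame", function(x) x@laterality)
#' @rdname accessors
#' @export
setMethod("detections", "EndoscopyFrame", function(x) x@detections)
#' @rdname accessors
#' @export
setMethod("gtLabel", "EndoscopyFrame", function(x) x@gtLabel)
#' @rdname accessors
#' @export
setMethod("frameWidth", "EndoscopyFrame", function(x) x@width)
#' @rdname accessors
#' @export
setMethod("frameHeight", "EndoscopyFrame", function(x) x@height)
#' @rdname accessors
#' @export
setMethod("mmBox", "MMRegion", function(x) x@box)
#' @rdname accessors
#' @export
setMethod("mmBox", "DiagnosisResult", function(x) x@mm@box)
#' @rdname accessors
#' @export
setMethod("mmMethod", "MMRegion", function(x) x@method)
#' @rdname accessors
#' @export
setMethod("mmMethod", "DiagnosisResult", function(x) x@mm@method)
#' @rdname accessors
#' @export
setMethod("diagnosisCall", "DiagnosisResult", function(x) x@call)
#' @rdname accessors
#' @export
setMethod("triggers", "DiagnosisResult", function(x) x@triggers)
#' @rdname accessors
#' @export
setMethod("iouMM", "DiagnosisResult", function(x) x@iouMM)
#' @rdname accessors
#' @export
setMethod("iouMT", "DiagnosisResult", function(x) x@iouMT)
#' @rdname accessors
#' @export
setMethod("aucValue", "RocCurve", function(x) x@auc)

## show methods --------------------------------------------------------------

fmtBox <- function(b) {
  if (is.null(b)) "<none>"
  else sprintf("(%.1f, %.1f, %.1f, %.1f)", b@x1, b@y1, b@x2, b@y2)
}

setMethod("show", "BoundingBox", function(object) {
  cat("BoundingBox", fmtBox(object), "area", format(boxArea(object)), "px^2\n")
})

setMethod("show", "PolygonMask", function(object) {
  cat(sprintf("PolygonMask: %d part(s), %d vertices, area %.1f px^2, bbox %s\n",
              length(object@parts), sum(vapply(object@parts, nrow, integer(1))),
              maskArea(object), fmtBox(maskToBox(object))))
})

setMethod("show", "Detection", function(object) {
  cat(sprintf("Detection <%s> conf %.2f %s bbox %s\n", object@label,
              object@confidence, if (is.null(object@mask)) "box-only" else "masked",
              fmtBox(object@box)))
})

setMethod("show", "EndoscopyFrame", function(object) {
  labs <- vapply(object@detections, function(d) d@label, character(1))
  cat(sprintf("EndoscopyFrame '%s' %dx%d px, %s cavity, gt=%s\n",
              object@frameId, as.integer(object@width), as.integer(object@height),
              object@laterality, object@gtLabel))
  cat(sprintf("  %d detection(s): %s\n", length(labs),
              if (length(labs)) paste(labs, collapse = ", ") else "none"))
})

setMethod("show", "MMRegion", function(object) {
  cat(sprintf("MMRegion [%s]%s %s\n", object@method,
              if (object@clamped) " (clamped)" else "", fmtBox(object@box)))
})

setMethod("show", "DiagnosisResult", function(object) {
  cat(sprintf("DiagnosisResult '%s': %s%s\n", object@frameId, object@call,
              if (length(object@triggers))
                paste0(" via ", paste(object@triggers, collapse = "+")) else ""))
  cat(sprintf("  IoU(MM-mucus)=%s IoU(MT-mucus)=%s MM=%s [%s]\n",
              formatC(object@iouMM, digits = 3, format = "fg"),
              formatC(object@iouMT, digits = 3, format = "fg"),
              fmtBox(object@mm@box), object@mm@method))
})

setMethod("show", "AlgorithmConfig", function(object) {
  cat(sprintf(paste0("AlgorithmConfig: deltaX=%g deltaY=%g deltaXSafe=%g ",
                     "IoU>%g conf>=%g\n  fallbackYRule=%s callMode=%s ",
                     "mucusAggregation=%s\n"),
              object@deltaX, object@deltaY, object@deltaXSafe,
              object@iouThreshold, object@confidenceThreshold,
              object@fallbackYRule, object@callMode, object@mucusAggregation))
})

setMethod("show", "RocCurve", function(object) {
  cat(sprintf("RocCurve: %d thresholds, AUC %.3f (95%% CI %.3f-%.3f)\n",
              length(object@thresholds), object@auc, object@ciLow, object@ciHigh))
})
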