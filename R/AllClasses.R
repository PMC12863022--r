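#' @import methods
NULL

DETECTION_LABELS <- c("MT", "IT", "mucus")
LATERALITIES <- c("left", "right")
TRIGGER_PATHWAYS <- c("MM_mucus", "MT_mucus")

#' Axis-aligned bounding box in pixel coordinates
#'
#' Continuous 0-based pixel coordinates, origin at the top-left of the frame,
#' x increasing rightward and y increasing downward. A valid box has strictly
#' positive width and height.
#'
#' @slot x1,y1 numeric(1), left and top edge.
#' @slot x2,y2 numeric(1), right and bottom edge.
#' @export
setClass("BoundingBox",
  representation(x1 = "numeric", y1 = "numeric", x2 = "numeric", y2 = "numeric"),
  validity = function(object) {
    v <- c(object@x1, object@y1, object@x2, object@y2)
    if (length(v) != 4L || any(!is.finite(v)))
      return("box coordinates must be four finite numbers")
    if (object@x2 <= object@x1 || object@y2 <= object@y1)
      return("degenerate box: need x2 > x1 and y2 > y1")
    TRUE
  }
)

#' Polygon segmentation mask
#'
#' A closed simple polygon, optionally with several disjoint parts for
#' fragmented instances. Each part is a two-column (x, y) vertex matrix with
#' at least three vertices and non-zero enclosed area; the polygon is closed
#' implicitly (last vertex connects back to the first).
#'
#' @slot parts list of numeric matrices, each n x 2 with columns (x, y).
#' @export
setClass("PolygonMask",
  representation(parts = "list"),
  validity = function(object) {
    if (length(object@parts) == 0L) return("mask needs at least one part")
    for (p in object@parts) {
      if (!is.matrix(p) || ncol(p) != 2L || !is.numeric(p))
        return("each mask part must be a numeric n x 2 matrix")
      if (nrow(p) < 3L) return("invalid mask: fewer than 3 vertices in a part")
      if (any(!is.finite(p))) return("mask vertices must be finite")
      if (abs(shoelace_area(p)) < sqrt(.Machine$double.eps))
        return("invalid mask: degenerate (zero-area) part")
    }
    TRUE
  }
)

setClassUnion("PolygonMaskOrNULL", c("PolygonMask", "NULL"))
setClassUnion("BoundingBoxOrNULL", c("BoundingBox", "NULL"))

#' One detected instance
#'
#' A single instance emitted by the upstream multi-class detector: class
#' label (middle turbinate \code{"MT"}, inferior turbinate \code{"IT"}, or
#' \code{"mucus"}), confidence score, optional polygon mask, and a bounding
#' box. When a mask is present the box is its tight bounding box.
#'
#' @slot label character(1), one of \code{"MT"}, \code{"IT"}, \code{"mucus"}.
#' @slot confidence numeric(1) in \[0, 1\].
#' @slot mask \linkS4class{PolygonMask} or NULL.
#' @slot box \linkS4class{BoundingBox}.
#' @export
setClass("Detection",
  representation(label = "character", confidence = "numeric",
                 mask = "PolygonMaskOrNULL", box = "BoundingBox"),
  validity = function(object) {
    if (length(object@label) != 1L || !object@label %in% DETECTION_LABELS)
      return(sprintf("label must be one of %s", paste(DETECTION_LABELS, collapse = ", ")))
    if (length(object@confidence) != 1L || is.na(object@confidence) ||
        object@confidence < 0 || object@confidence > 1)
      return("confidence must be a single value in [0, 1]")
    if (!is.null(object@mask)) {
      tight <- maskToBox(object@mask)
      if (max(abs(c(tight@x1 - object@box@x1, tight@y1 - object@box@y1,
                    tight@x2 - object@box@x2, tight@y2 - object@box@y2))) > 1e-6)
        return("box must equal the tight bounding box of the mask")
    }
    TRUE
  }
)

#' One endoscopic frame with its detections and metadata
#'
#' Holds everything the diagnostic rule needs for one image: frame size,
#' nasal-cavity laterality (required metadata, never inferred from pixels),
#' the detector's instances, and an optional expert ground-truth sinusitis
#' label.
#'
#' @slot frameId character(1) identifier.
#' @slot width,height numeric(1), frame size in pixels (native frames are
#'   1024 x 768).
#' @slot laterality character(1), \code{"left"} or \code{"right"}.
#' @slot detections list of \linkS4class{Detection}.
#' @slot gtLabel character(1), \code{"positive"}, \code{"negative"} or NA.
#' @export
setClass("EndoscopyFrame",
  representation(frameId = "character", width = "numeric", height = "numeric",
                 laterality = "character", detections = "list",
                 gtLabel = "character"),
  prototype(gtLabel = NA_character_),
  validity = function(object) {
    if (length(object@frameId) != 1L || is.na(object@frameId) || !nzchar(object@frameId))
      return("frameId must be a non-empty string")
    if (length(object@width) != 1L || length(object@height) != 1L ||
        !is.finite(object@width) || !is.finite(object@height) ||
        object@width <= 0 || object@height <= 0)
      return("width and height must be positive")
    if (length(object@laterality) != 1L || !object@laterality %in% LATERALITIES)
      return("laterality must be 'left' or 'right'")
    if (!all(vapply(object@detections, is, logical(1), "Detection")))
      return("detections must be a list of Detection objects")
    if (!is.na(object@gtLabel) && !object@gtLabel %in% c("positive", "negative"))
      return("gtLabel must be 'positive', 'negative' or NA")
    for (d in object@detections) {
      if (d@box@x1 < 0 || d@box@y1 < 0 ||
          d@box@x2 > object@width || d@box@y2 > object@height)
        return("detection geometry must lie within the frame (clamp on construction)")
    }
    TRUE
  }
)

#' Constants of the rule-based diagnostic algorithm
#'
#' All tunable constants of the middle-meatus construction and the IoU
#' decision rule, with the calibrated defaults: horizontal extents
#' \code{deltaX} = 50 px (primary) and \code{deltaXSafe} = 30 px (fallback
#' safety margin), superior displacement \code{deltaY} = 20 px, diagnostic
#' IoU threshold 0.3 (strict inequality), and detection confidence
#' threshold 0.3. Offsets are expressed in native 1024 x 768 pixels and
#' scaled proportionally for other frame sizes.
#'
#' @slot deltaX,deltaY,deltaXSafe numeric(1) pixel offsets (>= 0).
#' @slot iouThreshold,confidenceThreshold numeric(1) in \[0, 1\].
#' @slot fallbackYRule character(1), \code{"extended"} (lower bound at
#'   y_MTbottom + 0.5 h_MT when the inferior turbinate is undetected) or
#'   \code{"strict_mt"} (lower bound at the MT's inferior edge).
#' @slot callMode character(1), \code{"permissive"} (positive if either
#'   pathway fires) or \code{"strict"} (fallback pathway eligible only when
#'   middle-meatus localization fails).
#' @slot mucusAggregation character(1), \code{"max"} (maximum
#'   single-instance IoU) or \code{"union"} (IoU against the union of all
#'   mucus boxes).
#' @export
setClass("AlgorithmConfig",
  representation(deltaX = "numeric", deltaY = "numeric", deltaXSafe = "numeric",
                 iouThreshold = "numeric", confidenceThreshold = "numeric",
                 fallbackYRule = "character", callMode = "character",
                 mucusAggregation = "character"),
  prototype(deltaX = 50, deltaY = 20, deltaXSafe = 30,
            iouThreshold = 0.3, confidenceThreshold = 0.3,
            fallbackYRule = "extended", callMode = "permissive",
            mucusAggregation = "max"),
  validity = function(object) {
    offs <- c(object@deltaX, object@deltaY, object@deltaXSafe)
    if (any(!is.finite(offs)) || any(offs < 0))
      return("offsets must be finite and >= 0")
    thr <- c(object@iouThreshold, object@confidenceThreshold)
    if (any(!is.finite(thr)) || any(thr < 0) || any(thr > 1))
      return("thresholds must lie in [0, 1]")
    if (!object@fallbackYRule %in% c("extended", "strict_mt"))
      return("fallbackYRule must be 'extended' or 'strict_mt'")
    if (!object@callMode %in% c("permissive", "strict"))
      return("callMode must be 'permissive' or 'strict'")
    if (!object@mucusAggregation %in% c("max", "union"))
      return("mucusAggregation must be 'max' or 'union'")
    TRUE
  }
)

#' Localized middle-meatus region
#'
#' Output of the geometric middle-meatus construction: the region's
#' bounding box, the construction used (\code{"primary"} when both
#' turbinates were available, \code{"fallback"} when only the middle
#' turbinate was, \code{"failed"} when no valid region could be built), and
#' whether the box was clipped at a frame border.
#'
#' @slot box \linkS4class{BoundingBox} or NULL (when failed).
#' @slot method character(1), \code{"primary"}, \code{"fallback"} or \code{"failed"}.
#' @slot clamped logical(1).
#' @export
setClass("MMRegion",
  representation(box = "BoundingBoxOrNULL", method = "character",
                 clamped = "logical"),
  validity = function(object) {
    if (!object@method %in% c("primary", "fallback", "failed"))
      return("method must be 'primary', 'fallback' or 'failed'")
    if (object@method == "failed" && !is.null(object@box))
      return("a failed localization carries no box")
    if (object@method != "failed" && is.null(object@box))
      return("a successful localization must carry a box")
    TRUE
  }
)

#' Per-frame diagnostic result
#'
#' The binary sinusitis call for one frame together with the evidence
#' behind it: which trigger pathways fired (mucus overlapping the inferred
#' middle-meatus region, \code{"MM_mucus"}, and/or mucus overlapping the
#' middle turbinate, \code{"MT_mucus"}), the IoU values of both pathways,
#' and the middle-meatus region used.
#'
#' @slot frameId character(1).
#' @slot call character(1), \code{"positive"} or \code{"negative"}.
#' @slot triggers character, subset of \code{c("MM_mucus", "MT_mucus")}.
#' @slot iouMM,iouMT numeric(1), pathway IoU or NA when the pathway's
#'   landmark was unavailable.
#' @slot mm \linkS4class{MMRegion}.
#' @export
setClass("DiagnosisResult",
  representation(frameId = "character", call = "character",
                 triggers = "character", iouMM = "numeric", iouMT = "numeric",
                 mm = "MMRegion"),
  validity = function(object) {
    if (!object@call %in% c("positive", "negative"))
      return("call must be 'positive' or 'negative'")
    if (!all(object@triggers %in% TRIGGER_PATHWAYS))
      return("unknown trigger pathway")
    if ((object@call == "positive") != (length(object@triggers) > 0L))
      return("call is positive if and only if at least one pathway fired")
    if (object@mm@method == "failed" && !is.na(object@iouMM))
      return("iouMM is reported only when MM localization succeeded")
    TRUE
  }
)

#' Parameters of the synthetic scene generator
#'
#' Controls the seeded generator of endoscopy-like annotation scenes:
#' frame size, laterality mix, probability that the inferior turbinate is
#' missing from the frame (occlusion / out-of-frame), probability that a
#' frame contains mucus, the placement mix for that mucus (inside the
#' middle-meatus region, deposited on the middle turbinate, or remote from
#' both), vertex jitter, and the per-class confidence model.
#'
#' @slot width,height numeric(1) frame size in pixels.
#' @slot lateralityMix numeric(1), probability a scene is left-sided.
#' @slot pItAbsent numeric(1), probability the IT is not in the frame.
#' @slot pMucus numeric(1), probability a frame contains mucus.
#' @slot placementWeights named numeric, sampling weights for
#'   \code{c("in_mm", "on_mt", "remote")}.
#' @slot pExtraMucus numeric(1), probability of an additional remote
#'   distractor mucus blob.
#' @slot jitterSd numeric(1), Gaussian vertex jitter (px).
#' @slot confidenceMeans,confidenceSds named numeric over
#'   \code{c("MT", "IT", "mucus")}; sampled confidences are truncated to \[0, 1\].
#' @slot seed integer(1) base seed.
#' @export
setClass("SceneParams",
  representation(width = "numeric", height = "numeric",
                 lateralityMix = "numeric", pItAbsent = "numeric",
                 pMucus = "numeric", placementWeights = "numeric",
                 pExtraMucus = "numeric", jitterSd = "numeric",
                 confidenceMeans = "numeric", confidenceSds = "numeric",
                 seed = "integer"),
  validity = function(object) {
    pr <- c(object@lateralityMix, object@pItAbsent, object@pMucus, object@pExtraMucus)
    if (any(!is.finite(pr)) || any(pr < 0) || any(pr > 1))
      return("probabilities must lie in [0, 1]")
    if (!identical(sort(names(object@placementWeights)), sort(c("in_mm", "on_mt", "remote"))))
      return("placementWeights must be named in_mm, on_mt, remote")
    if (any(object@placementWeights < 0) || sum(object@placementWeights) <= 0)
      return("placementWeights must be non-negative and not all zero")
    if (!is.finite(object@jitterSd) || object@jitterSd < 0)
      return("jitterSd must be >= 0")
    for (nm in list(object@confidenceMeans, object@confidenceSds)) {
      if (!identical(sort(names(nm)), sort(DETECTION_LABELS)))
        return("confidence model must be named over MT, IT, mucus")
    }
    if (any(object@confidenceSds < 0)) return("confidence sds must be >= 0")
    if (object@width <= 0 || object@height <= 0)
      return("frame size must be positive")
    TRUE
  }
)

#' Empirical ROC curve with bootstrap confidence interval
#'
#' @slot thresholds numeric, descending grid of decision thresholds.
#' @slot tpr,fpr numeric, true/false positive rates at each threshold
#'   (strict \code{score > threshold} comparison).
#' @slot auc numeric(1), area under the full empirical curve (trapezoidal
#'   rule over all distinct scores).
#' @slot ciLow,ciHigh numeric(1), percentile bootstrap 95\% interval.
#' @export
setClass("RocCurve",
  representation(thresholds = "numeric", tpr = "numeric", fpr = "numeric",
                 auc = "numeric", ciLow = "numeric", ciHigh = "numeric"),
  validity = function(object) {
    if (length(object@tpr) != length(object@thresholds) ||
        length(object@fpr) != length(object@thresholds))
      return("tpr/fpr must align with thresholds")
    if (is.unsorted(rev(object@thresholds)))
      return("thresholds must be descending")
    if (object@auc < 0 || object@auc > 1) return("auc must lie in [0, 1]")
    TRUE
  }
)
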