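# Seeded generator of endoscopy-like annotation scenes with known ground
# truth. Scenes are geometry only (convex 8-12 vertex polygons, no pixel
# textures): that is everything the rule-based pipeline consumes.

#' Construct scene-generator parameters
#'
#' Defaults emulate the study conditions: native 1024 x 768 frames, a
#' balanced laterality mix, an inferior turbinate missing from a quarter
#' of frames (obstruction / image quality / out of frame), and a mucus
#' frequency and placement mix giving an expected 74\% ground-truth
#' positive rate, matching the positive prevalence of the clinical test
#' set. Placements: \code{in_mm} drops mucus inside the rule-derived
#' middle-meatus region (box IoU >= 0.5 before jitter), \code{on_mt}
#' deposits it on the middle turbinate (fallback-pathway positive), and
#' \code{remote} keeps it at least 2 x \code{deltaX} away from both the
#' middle-meatus region and the MT box (negative).
#'
#' @param width,height frame size in px.
#' @param lateralityMix probability a scene is left-sided.
#' @param pItAbsent probability the inferior turbinate is absent.
#' @param pMucus probability a frame contains mucus.
#' @param placementWeights named sampling weights for
#'   \code{c(in_mm, on_mt, remote)}.
#' @param pExtraMucus probability of an additional remote distractor blob.
#' @param jitterSd Gaussian vertex jitter in px (3 px default emulates
#'   annotation noise; 0 gives noiseless scenes).
#' @param confidenceMeans,confidenceSds per-class confidence model
#'   (Gaussian, truncated to \[0, 1\]).
#' @param seed integer base seed; scene i is deterministic in (seed, i).
#' @return A \linkS4class{SceneParams}.
#' @export
sceneParams <- function(width = 1024, height = 768, lateralityMix = 0.5,
                        pItAbsent = 0.25, pMucus = 0.9,
                        placementWeights = c(in_mm = 0.35, on_mt = 0.47,
                                             remote = 0.18),
                        pExtraMucus = 0.2, jitterSd = 3,
                        confidenceMeans = c(MT = 0.88, IT = 0.85, mucus = 0.78),
                        confidenceSds = c(MT = 0.05, IT = 0.05, mucus = 0.08),
                        seed = 1L) {
  new("SceneParams", width = width, height = height,
      lateralityMix = lateralityMix, pItAbsent = pItAbsent, pMucus = pMucus,
      placementWeights = placementWeights[c("in_mm", "on_mt", "remote")],
      pExtraMucus = pExtraMucus, jitterSd = jitterSd,
      confidenceMeans = confidenceMeans, confidenceSds = confidenceSds,
      seed = as.integer(seed))
}

# convex polygon with bounding box exactly `box`: points on an ellipse at
# sorted random angles, affinely rescaled to fill the box
convexPolyInBox <- function(box, nVert) {
  th <- sort(stats::runif(nVert, 0, 2 * pi))
  x <- cos(th); y <- sin(th)
  rescale <- function(v, lo, hi) (v - min(v)) / (max(v) - min(v)) * (hi - lo) + lo
  cbind(rescale(x, box@x1, box@x2), rescale(y, box@y1, box@y2))
}

shrinkBox <- function(b, f) {
  cx <- (b@x1 + b@x2) / 2; cy <- (b@y1 + b@y2) / 2
  w <- (b@x2 - b@x1) * f / 2; h <- (b@y2 - b@y1) * f / 2
  boundingBox(cx - w, cy - h, cx + w, cy + h)
}

# smallest axis gap between two boxes (0 when they overlap on both axes)
boxGap <- function(a, b) {
  dx <- max(0, b@x1 - a@x2, a@x1 - b@x2)
  dy <- max(0, b@y1 - a@y2, a@y1 - b@y2)
  max(dx, dy)
}

truncConf <- function(label, params) {
  min(1, max(0, stats::rnorm(1, params@confidenceMeans[[label]],
                             params@confidenceSds[[label]])))
}

jitterVerts <- function(v, sd, width, height) {
  if (sd > 0) v <- v + matrix(stats::rnorm(length(v), 0, sd), nrow(v), 2L)
  v[, 1L] <- pmin(pmax(v[, 1L], 0), width)
  v[, 2L] <- pmin(pmax(v[, 2L], 0), height)
  v
}

sceneSeed <- function(seed, index) {
  (abs(seed) %% 20000L) * 100003L + (index %% 100003L)
}

# builds one scene; returns frame + bookkeeping for the manifest
buildScene <- function(params, index, cfg, placement = NULL, mirror = FALSE) {
  w <- params@width; h <- params@height
  sx <- w / 1024; sy <- h / 768

  side <- if (stats::runif(1) < params@lateralityMix) "left" else "right"
  if (mirror) side <- otherSide(side)

  # canonical right-sided geometry; mirrored at the end for left scenes
  eX <- stats::runif(1, 360, 460) * sx
  wMT <- stats::runif(1, 150, 230) * sx
  yTop <- stats::runif(1, 90, 160) * sy
  hMT <- stats::runif(1, 240, 320) * sy
  mtVerts <- convexPolyInBox(boundingBox(eX, yTop, eX + wMT, yTop + hMT),
                             sample(8:12, 1))
  mtVerts <- jitterVerts(mtVerts, params@jitterSd, w, h)

  itVerts <- NULL
  if (stats::runif(1) >= params@pItAbsent) {
    x1 <- eX - stats::runif(1, 10, 40) * sx
    x2 <- eX + wMT + stats::runif(1, 0, 40) * sx
    y1 <- yTop + hMT + stats::runif(1, 40, 90) * sy
    y2 <- min(y1 + stats::runif(1, 150, 220) * sy, h - 5)
    itVerts <- convexPolyInBox(boundingBox(max(x1, 5), y1, min(x2, w - 5), y2),
                               sample(8:12, 1))
    itVerts <- jitterVerts(itVerts, params@jitterSd, w, h)
  }

  mtDet <- detection("MT", truncConf("MT", params), mask = mtVerts)
  itDet <- if (is.null(itVerts)) NULL
           else detection("IT", truncConf("IT", params), mask = itVerts)

  if (is.null(placement)) {
    placement <- if (stats::runif(1) < params@pMucus)
      sample(names(params@placementWeights), 1,
             prob = params@placementWeights) else "none"
  }

  mm <- locateMM(mtDet, itDet, "right", w, h, cfg)
  mtBox <- mtDet@box
  margin <- 2 * cfg@deltaX * sx

  sampleRemoteBox <- function() {
    for (try in 1:50) {
      x1 <- stats::runif(1, 15, 60) * sx
      bw <- stats::runif(1, 60, 110) * sx
      y2 <- h - stats::runif(1, 15, 60) * sy
      bh <- stats::runif(1, 50, 100) * sy
      cand <- boundingBox(x1, y2 - bh, x1 + bw, y2)
      okMM <- is.null(mm@box) || boxGap(cand, mm@box) >= margin
      if (okMM && boxGap(cand, mtBox) >= margin) return(cand)
    }
    stop("could not place remote mucus with the required margin")
  }

  mucusBoxes <- list()
  if (placement == "in_mm") {
    if (mm@method == "failed") stop("cannot place mucus in a failed MM region")
    mucusBoxes <- list(shrinkBox(mm@box, 0.85))
  } else if (placement == "on_mt") {
    mucusBoxes <- list(shrinkBox(mtBox, 0.72))
  } else if (placement == "remote") {
    mucusBoxes <- list(sampleRemoteBox())
  }
  if (placement != "none" && stats::runif(1) < params@pExtraMucus)
    mucusBoxes <- c(mucusBoxes, sampleRemoteBox())

  mucusDets <- lapply(mucusBoxes, function(b) {
    v <- jitterVerts(convexPolyInBox(b, sample(8:12, 1)),
                     params@jitterSd, w, h)
    detection("mucus", truncConf("mucus", params), mask = v)
  })

  dets <- c(list(mtDet), if (!is.null(itDet)) list(itDet), mucusDets)
  if (side == "left")
    dets <- lapply(dets, function(d)
      detection(d@label, d@confidence, mask = mirrorMask(d@mask, w)))

  gt <- if (placement %in% c("in_mm", "on_mt")) "positive" else "negative"
  frame <- endoscopyFrame(sprintf("scene_%05d", index), width = w, height = h,
                          laterality = side, detections = dets, gtLabel = gt)
  list(frame = frame, placement = placement, nMucus = length(mucusDets))
}

#' Generate one synthetic annotation scene
#'
#' Deterministic in \code{(seed, index)}: the scene is drawn under a
#' per-index seed derived from the base seed, so suites can be
#' regenerated frame by frame. Scenes contain one middle-turbinate
#' polygon (vertically elongated, medial side facing the septum per
#' laterality), one inferior-turbinate polygon below it unless dropped,
#' and 0-2 mucus polygons placed according to the placement mode; the
#' ground-truth label is fixed by construction against the same
#' middle-meatus rule the pipeline applies.
#'
#' @param params a \linkS4class{SceneParams}.
#' @param index scene index (>= 1).
#' @param cfg the \linkS4class{AlgorithmConfig} the ground truth is
#'   constructed against.
#' @param placement optional override of the sampled placement, one of
#'   \code{"in_mm"}, \code{"on_mt"}, \code{"remote"}, \code{"none"}.
#' @param mirror if TRUE, generate the exact horizontal mirror of the
#'   scene (laterality flipped, geometry reflected about the vertical
#'   midline).
#' @return An \linkS4class{EndoscopyFrame} with \code{gtLabel} set.
#' @export
generateScene <- function(params, index, cfg = algorithmConfig(),
                          placement = NULL, mirror = FALSE) {
  withr::with_seed(sceneSeed(params@seed, index),
    buildScene(params, index, cfg, placement, mirror))$frame
}

#' Generate a suite of synthetic scenes with a manifest
#'
#' @param params a \linkS4class{SceneParams}.
#' @param n number of scenes (> 0).
#' @param cfg the \linkS4class{AlgorithmConfig} ground truth is built
#'   against.
#' @param placements optional character vector (recycled to length n)
#'   overriding the per-scene placement draw; values as in
#'   [generateScene()].
#' @return List with \code{frames} (length n) and \code{manifest}
#'   (data.frame: frame_id, index, laterality, placement, n_mucus,
#'   gt_label, seed).
#' @export
generateSuite <- function(params, n, cfg = algorithmConfig(),
                          placements = NULL) {
  stopifnot(n > 0)
  if (!is.null(placements)) placements <- rep_len(placements, n)
  out <- lapply(seq_len(n), function(i) {
    withr::with_seed(sceneSeed(params@seed, i),
      buildScene(params, i, cfg,
                 placement = if (is.null(placements)) NULL else placements[i]))
  })
  frames <- lapply(out, `[[`, "frame")
  manifest <- data.frame(
    frame_id = vapply(frames, frameId, character(1)),
    index = seq_len(n),
    laterality = vapply(frames, laterality, character(1)),
    placement = vapply(out, `[[`, character(1), "placement"),
    n_mucus = vapply(out, `[[`, numeric(1), "nMucus"),
    gt_label = vapply(frames, gtLabel, character(1)),
    seed = params@seed)
  list(frames = frames, manifest = manifest)
}
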