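# Geometric middle-meatus localization from turbinate detections.

# pick one instance of a class: highest confidence, ties by larger mask
# (or box) area, then first occurrence
selectInstance <- function(dets, label) {
  cand <- Filter(function(d) d@label == label, dets)
  if (length(cand) == 0L) return(NULL)
  conf <- vapply(cand, function(d) d@confidence, numeric(1))
  area <- vapply(cand, function(d)
    if (!is.null(d@mask)) maskArea(d@mask) else boxArea(d@box), numeric(1))
  cand[[order(-conf, -area, seq_along(cand))[1L]]]
}

# mask if present, else the box stands in for the mask edges
detGeom <- function(d) if (!is.null(d@mask)) d@mask else d@box

#' Localize the middle-meatus region
#'
#' The middle meatus is frequently not directly visible endoscopically, so
#' its region is constructed geometrically from the detected turbinates.
#' With both turbinates available (primary construction) the box runs from
#' \code{deltaY} px above the middle turbinate's top edge down to the
#' inferior turbinate's top edge, and spans \code{deltaX} px horizontally
#' from the MT's medial edge (the leftmost mask edge in a right cavity,
#' rightmost in a left cavity), extending toward the septum. When the
#' inferior turbinate is undetected (obstruction, image quality, IT out of
#' frame) the fallback construction keeps the same top edge, bounds the
#' bottom at \code{y_MTbottom + 0.5 h_MT} (rule \code{"extended"}, the
#' default) or at the MT's bottom edge (rule \code{"strict_mt"}), and uses
#' the conservative margin \code{deltaXSafe} horizontally.
#'
#' Offsets are calibrated in native 1024 x 768 pixels and scaled by
#' \code{width/1024} (horizontal) and \code{height/768} (vertical) for
#' other frame sizes. The box is clamped to the frame; a clamp that
#' degenerates the box, a zero horizontal span, or an inferior turbinate
#' whose top lies above the region's top edge (inconsistent anatomy) all
#' yield \code{method = "failed"}.
#'
#' @param mt middle-turbinate \linkS4class{Detection} or NULL. A box-only
#'   detection is accepted; its box edges stand in for mask edges.
#' @param it inferior-turbinate \linkS4class{Detection} or NULL.
#' @param side \code{"left"} or \code{"right"} nasal cavity.
#' @param width,height frame size in pixels.
#' @param cfg an \linkS4class{AlgorithmConfig}.
#' @return An \linkS4class{MMRegion}.
#' @examples
#' mt <- detection("MT", 0.9, mask = cbind(c(400, 600, 600, 400), c(100, 100, 400, 400)))
#' it <- detection("IT", 0.8, mask = cbind(c(380, 650, 650, 380), c(500, 500, 700, 700)))
#' locateMM(mt, it, "right", 1024, 768)   # primary: (350, 80, 400, 500)
#' locateMM(mt, NULL, "right", 1024, 768) # fallback: (370, 80, 400, 550)
#' @export
locateMM <- function(mt, it, side, width = 1024, height = 768,
                     cfg = algorithmConfig()) {
  side <- match.arg(side, LATERALITIES)
  failed <- new("MMRegion", box = NULL, method = "failed", clamped = FALSE)
  if (is.null(mt)) return(failed)

  sx <- width / 1024
  sy <- height / 768
  geomMT <- detGeom(mt)
  e <- medialEdgeX(geomMT, side)
  ext <- verticalExtent(geomMT)

  y1 <- max(ext[["yTop"]] - cfg@deltaY * sy, 0)
  clamped <- y1 > ext[["yTop"]] - cfg@deltaY * sy  # top clipped at frame edge

  if (!is.null(it)) {
    method <- "primary"
    y2 <- verticalExtent(detGeom(it))[["yTop"]]
    span <- cfg@deltaX * sx
  } else {
    method <- "fallback"
    y2 <- if (cfg@fallbackYRule == "extended")
      ext[["yBottom"]] + 0.5 * ext[["height"]] else ext[["yBottom"]]
    span <- cfg@deltaXSafe * sx
  }
  if (span <= 0 || y2 <= y1) return(failed)

  if (side == "right") { x1 <- e - span; x2 <- e } else { x1 <- e; x2 <- e + span }
  cl <- clampBox(boundingBox(x1, y1, x2, y2), width, height)
  if (is.null(cl$box)) return(failed)
  new("MMRegion", box = cl$box, method = method,
      clamped = clamped || cl$clamped)
}
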