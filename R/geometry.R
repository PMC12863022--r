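# Pixel-space geometry primitives: boxes, polygon masks, medial edges, IoU.
# All downstream rules operate on these. Coordinates are continuous,
# 0-based, origin top-left, y increasing downward.

# signed shoelace area of an open vertex matrix (closure implied)
shoelace_area <- function(v) {
  x <- v[, 1L]; y <- v[, 2L]
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' Construct a bounding box
#'
#' @param x1,y1 left/top edge (px).
#' @param x2,y2 right/bottom edge (px); must satisfy \code{x2 > x1},
#'   \code{y2 > y1}.
#' @return A \linkS4class{BoundingBox}.
#' @examples
#' b <- boundingBox(0, 0, 10, 10)
#' boxArea(b)
#' @export
boundingBox <- function(x1, y1, x2, y2) {
  new("BoundingBox", x1 = as.numeric(x1), y1 = as.numeric(y1),
      x2 = as.numeric(x2), y2 = as.numeric(y2))
}

#' Construct a polygon mask
#'
#' @param vertices an n x 2 (x, y) vertex matrix, or a list of such
#'   matrices for a multi-part (fragmented) mask.
#' @return A \linkS4class{PolygonMask}.
#' @examples
#' polygonMask(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))
#' @export
polygonMask <- function(vertices) {
  if (is.matrix(vertices)) vertices <- list(vertices)
  vertices <- lapply(vertices, function(p) {
    p <- as.matrix(p)
    storage.mode(p) <- "double"
    dimnames(p) <- NULL
    p
  })
  new("PolygonMask", parts = vertices)
}

#' Area of a bounding box
#'
#' @param a a \linkS4class{BoundingBox}.
#' @return numeric(1), \code{(x2 - x1) * (y2 - y1)}.
#' @export
setMethod("boxArea", "BoundingBox", function(a) (a@x2 - a@x1) * (a@y2 - a@y1))

#' Intersection over union of two boxes
#'
#' The diagnostic statistic of the decision rule: area of overlap divided
#' by area of union. Symmetric, 0 for disjoint boxes, 1 for identical
#' boxes.
#'
#' @param a,b valid \linkS4class{BoundingBox} objects.
#' @return numeric(1) in \[0, 1\].
#' @examples
#' iouBoxes(boundingBox(0, 0, 10, 10), boundingBox(5, 5, 15, 15))  # 1/7
#' @export
setMethod("iouBoxes", signature("BoundingBox", "BoundingBox"), function(a, b) {
  iw <- min(a@x2, b@x2) - max(a@x1, b@x1)
  ih <- min(a@y2, b@y2) - max(a@y1, b@y1)
  inter <- max(0, iw) * max(0, ih)
  inter / (boxArea(a) + boxArea(b) - inter)
})

#' Tight bounding box of a polygon mask
#'
#' Minimum and maximum vertex coordinates over all parts.
#'
#' @param m a \linkS4class{PolygonMask}.
#' @return A \linkS4class{BoundingBox}.
#' @export
setMethod("maskToBox", "PolygonMask", function(m) {
  v <- do.call(rbind, m@parts)
  boundingBox(min(v[, 1L]), min(v[, 2L]), max(v[, 1L]), max(v[, 2L]))
})

#' Medial boundary of a turbinate mask
#'
#' The x-coordinate of the mask edge facing the nasal septum. In a right
#' nasal cavity the septum lies to the image left, so the medial boundary
#' is the leftmost mask edge (minimum x); in a left cavity it is the
#' rightmost edge (maximum x). Laterality is metadata and is never
#' inferred from pixels.
#'
#' @param m a \linkS4class{PolygonMask}.
#' @param side \code{"left"} or \code{"right"} nasal cavity.
#' @return numeric(1), pixel x-coordinate of the medial edge.
#' @export
setMethod("medialEdgeX", signature("PolygonMask", "character"), function(m, side) {
  side <- match.arg(side, LATERALITIES)
  v <- do.call(rbind, m@parts)
  if (side == "right") min(v[, 1L]) else max(v[, 1L])
})

#' @rdname medialEdgeX
#' @export
setMethod("medialEdgeX", signature("BoundingBox", "character"), function(m, side) {
  side <- match.arg(side, LATERALITIES)
  if (side == "right") m@x1 else m@x2
})

#' Vertical extent of a mask
#'
#' @param m a \linkS4class{PolygonMask} or \linkS4class{BoundingBox}.
#' @return Named numeric: \code{yTop} (minimum y), \code{yBottom}
#'   (maximum y) and \code{height} (their difference).
#' @export
setMethod("verticalExtent", "PolygonMask", function(m) {
  v <- do.call(rbind, m@parts)
  yt <- min(v[, 2L]); yb <- max(v[, 2L])
  c(yTop = yt, yBottom = yb, height = yb - yt)
})

#' @rdname verticalExtent
#' @export
setMethod("verticalExtent", "BoundingBox", function(m) {
  c(yTop = m@y1, yBottom = m@y2, height = m@y2 - m@y1)
})

# total enclosed area of a (multi-part) mask
maskArea <- function(m) sum(vapply(m@parts, function(p) abs(shoelace_area(p)), numeric(1)))

# even-odd point-in-polygon test, vectorized over points
point_in_poly <- function(px, py, v) {
  vx <- v[, 1L]; vy <- v[, 2L]
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

point_in_mask <- function(px, py, m) {
  inside <- logical(length(px))
  for (p in m@parts) inside <- inside | point_in_poly(px, py, p)
  inside
}

#' Pixel-rasterized IoU of two polygon masks
#'
#' Both masks are rasterized on a common integer pixel grid (pixel-center
#' sampling over their union bounding box, the convention of COCO-style
#' evaluation) and the IoU is the ratio of shared to covered pixels. Used
#' for segmentation-quality matching; the diagnostic rule itself operates
#' on bounding boxes.
#'
#' @param a,b \linkS4class{PolygonMask} objects.
#' @param maxCells upper bound on grid cells; larger union boxes are
#'   sampled at a proportionally coarser (still deterministic) step.
#' @return numeric(1) in \[0, 1\].
#' @export
iouMasks <- function(a, b, maxCells = 4e5) {
  ba <- maskToBox(a); bb <- maskToBox(b)
  x0 <- floor(min(ba@x1, bb@x1)); x1 <- ceiling(max(ba@x2, bb@x2))
  y0 <- floor(min(ba@y1, bb@y1)); y1 <- ceiling(max(ba@y2, bb@y2))
  step <- max(1, sqrt((x1 - x0) * (y1 - y0) / maxCells))
  xs <- seq(x0 + step / 2, x1, by = step)
  ys <- seq(y0 + step / 2, y1, by = step)
  px <- rep(xs, times = length(ys))
  py <- rep(ys, each = length(xs))
  ina <- point_in_mask(px, py, a)
  inb <- point_in_mask(px, py, b)
  un <- sum(ina | inb)
  if (un == 0L) return(0)
  sum(ina & inb) / un
}

# clamp a box to [0,w] x [0,h]; NULL if degenerate after clamping
clampBox <- function(box, width, height) {
  x1 <- max(box@x1, 0); y1 <- max(box@y1, 0)
  x2 <- min(box@x2, width); y2 <- min(box@y2, height)
  clamped <- any(abs(c(x1 - box@x1, y1 - box@y1, x2 - box@x2, y2 - box@y2)) > 0)
  if (x2 <= x1 || y2 <= y1) return(list(box = NULL, clamped = clamped))
  list(box = boundingBox(x1, y1, x2, y2), clamped = clamped)
}

# mirror helpers (used by the generator and the equivariance tests)
mirrorBox <- function(box, width) boundingBox(width - box@x2, box@y1, width - box@x1, box@y2)
mirrorMask <- function(m, width) {
  polygonMask(lapply(m@parts, function(p) {
    p[, 1L] <- width - p[, 1L]
    p[rev(seq_len(nrow(p))), , drop = FALSE]
  }))
}
otherSide <- function(side) ifelse(side == "left", "right", "left")
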