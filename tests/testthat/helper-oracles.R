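# Independent oracles and small fixture builders used across tests.

# pixel-counting IoU oracle for integer-coordinate boxes: rasterize both
# on a unit grid and count cells (exact for integer boxes)
rasterBoxIoU <- function(a, b) {
  x0 <- floor(min(a@x1, b@x1)); x1 <- ceiling(max(a@x2, b@x2))
  y0 <- floor(min(a@y1, b@y1)); y1 <- ceiling(max(a@y2, b@y2))
  cx <- seq(x0 + 0.5, x1 - 0.5)
  cy <- seq(y0 + 0.5, y1 - 0.5)
  inBox <- function(bb) outer(cx > bb@x1 & cx < bb@x2, cy > bb@y1 & cy < bb@y2, "&")
  ia <- inBox(a); ib <- inBox(b)
  sum(ia & ib) / sum(ia | ib)
}

randomIntBox <- function(lim = 100) {
  x <- sort(sample(0:lim, 2)); y <- sort(sample(0:lim, 2))
  while (x[1] == x[2]) x <- sort(sample(0:lim, 2))
  while (y[1] == y[2]) y <- sort(sample(0:lim, 2))
  boundingBox(x[1], y[1], x[2], y[2])
}

# concordance-pair AUC estimator (ties counted 1/2)
concordanceAuc <- function(scores, positive) {
  ps <- scores[positive]; ns <- scores[!positive]
  pairs <- outer(ps, ns, function(p, q) (p > q) + 0.5 * (p == q))
  mean(pairs)
}

# square polygon mask helper
squareMask <- function(x1, y1, x2, y2) {
  polygonMask(cbind(c(x1, x2, x2, x1), c(y1, y1, y2, y2)))
}

# canonical right-cavity landmark pair from the localization examples
exampleMT <- function(conf = 0.9) detection("MT", conf, mask = squareMask(400, 100, 600, 400))
exampleIT <- function(conf = 0.8) detection("IT", conf, mask = squareMask(380, 500, 650, 700))

exampleFrame <- function(detections, side = "right", gt = NA_character_,
                         id = "f1", width = 1024, height = 768) {
  endoscopyFrame(id, width = width, height = height, laterality = side,
                 detections = detections, gtLabel = gt)
}

# frame whose decision score (max pathway IoU) is exactly `s`:
# mucus contained in the MT box covering a fraction s of its area,
# no overlap with the (more medial) middle-meatus region
scoreFrame <- function(s, id, gt) {
  mt <- detection("MT", 0.9, mask = squareMask(400, 100, 600, 400))
  dets <- list(mt)
  if (s > 0)
    dets <- c(dets, detection("mucus", 0.9,
                              box = boundingBox(400, 100, 600, 100 + 300 * s)))
  exampleFrame(dets, id = id, gt = gt)
}

noiselessParams <- function(seed = 7L)
  sceneParams(jitterSd = 0, confidenceSds = c(MT = 0, IT = 0, mucus = 0),
              seed = seed)
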