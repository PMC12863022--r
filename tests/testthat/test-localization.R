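test_that("primary construction follows the printed box formulas", {
  mm <- locateMM(exampleMT(), exampleIT(), "right", 1024, 768)
  expect_equal(mmMethod(mm), "primary")
  b <- mmBox(mm)
  expect_equal(c(b@x1, b@y1, b@x2, b@y2), c(350, 80, 400, 500))
  expect_false(mm@clamped)
})

test_that("fallback construction extends below the MT and uses the safe margin", {
  mm <- locateMM(exampleMT(), NULL, "right", 1024, 768)
  expect_equal(mmMethod(mm), "fallback")
  b <- mmBox(mm)
  expect_equal(c(b@x1, b@y1, b@x2, b@y2), c(370, 80, 400, 550))  # y2 = 400 + 0.5*300
  # strict MT-extent variant stops at the MT's inferior edge
  mmS <- locateMM(exampleMT(), NULL, "right", 1024, 768,
                  algorithmConfig(fallbackYRule = "strict_mt"))
  expect_equal(mmBox(mmS)@y2, 400)
})

test_that("top edge clamps at zero and sets the clamped flag", {
  mt <- detection("MT", 0.9, mask = squareMask(400, 10, 600, 300))
  mm <- locateMM(mt, exampleIT(), "right", 1024, 768)
  expect_equal(mmBox(mm)@y1, 0)
  expect_true(mm@clamped)
})

test_that("left-cavity construction is the exact mirror", {
  mtL <- detection("MT", 0.9, mask = squareMask(424, 100, 624, 400))
  itL <- detection("IT", 0.8, mask = squareMask(374, 500, 644, 700))
  b <- mmBox(locateMM(mtL, itL, "left", 1024, 768))
  expect_equal(c(b@x1, b@y1, b@x2, b@y2), c(624, 80, 674, 500))
})

test_that("localization is mirror-equivariant under laterality swap", {
  width <- 1024
  withr::with_seed(21, {
    for (i in 1:40) {
      e <- runif(1, 200, 600); wmt <- runif(1, 100, 250)
      yt <- runif(1, 60, 200); hmt <- runif(1, 150, 350)
      mt <- detection("MT", 0.9, mask = squareMask(e, yt, e + wmt, yt + hmt))
      it <- if (runif(1) < 0.5) NULL else
        detection("IT", 0.8, mask = squareMask(e - 20, yt + hmt + 60,
                                               e + wmt + 20,
                                               min(yt + hmt + 200, 760)))
      for (side in c("right", "left")) {
        mm <- locateMM(mt, it, side, width, 768)
        mtM <- detection("MT", 0.9, mask = SinusDx:::mirrorMask(mt@mask, width))
        itM <- if (is.null(it)) NULL else
          detection("IT", 0.8, mask = SinusDx:::mirrorMask(it@mask, width))
        mmM <- locateMM(mtM, itM, SinusDx:::otherSide(side), width, 768)
        expect_identical(mmMethod(mm), mmMethod(mmM))
        if (mmMethod(mm) != "failed" && !mm@clamped) {
          ref <- SinusDx:::mirrorBox(mmBox(mm), width)
          got <- mmBox(mmM)
          expect_equal(c(got@x1, got@y1, got@x2, got@y2),
                       c(ref@x1, ref@y1, ref@x2, ref@y2))
        }
      }
    }
  })
})

test_that("increasing deltaX widens the box without moving the medial edge", {
  widths <- vapply(c(20, 50, 80, 120), function(dx) {
    b <- mmBox(locateMM(exampleMT(), exampleIT(), "right", 1024, 768,
                        algorithmConfig(deltaX = dx)))
    expect_equal(b@x2, 400)  # medial edge pinned to the MT mask
    b@x2 - b@x1
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("degenerate configurations fail cleanly, never crash", {
  cfg0 <- algorithmConfig(deltaX = 0, deltaXSafe = 0)
  expect_equal(mmMethod(locateMM(exampleMT(), exampleIT(), "right", 1024, 768, cfg0)),
               "failed")
  expect_equal(mmMethod(locateMM(exampleMT(), NULL, "right", 1024, 768, cfg0)),
               "failed")
  # no MT: no landmark to build from
  expect_equal(mmMethod(locateMM(NULL, exampleIT(), "right", 1024, 768)), "failed")
  # IT top above the region top: inconsistent anatomy
  itHigh <- detection("IT", 0.8, mask = squareMask(380, 10, 650, 60))
  expect_equal(mmMethod(locateMM(exampleMT(), itHigh, "right", 1024, 768)), "failed")
  # zero deltaY keeps the top undisplaced but still succeeds
  mmY <- locateMM(exampleMT(), exampleIT(), "right", 1024, 768,
                  algorithmConfig(deltaY = 0))
  expect_equal(mmBox(mmY)@y1, 100)
})

test_that("the returned box always lies inside the frame", {
  withr::with_seed(31, {
    for (i in 1:60) {
      e <- runif(1, 0, 980); wmt <- runif(1, 30, 400)
      yt <- runif(1, 0, 700); hmt <- runif(1, 30, 400)
      mt <- detection("MT", 0.9,
                      box = boundingBox(max(0, e), max(0, yt),
                                        min(1024, e + wmt), min(768, yt + hmt)))
      mm <- locateMM(mt, NULL, sample(c("left", "right"), 1), 1024, 768)
      if (mmMethod(mm) != "failed") {
        b <- mmBox(mm)
        expect_true(b@x1 >= 0 && b@y1 >= 0 && b@x2 <= 1024 && b@y2 <= 768)
      }
    }
  })
})

test_that("box-only MT detections substitute box edges for mask edges", {
  mtBoxOnly <- detection("MT", 0.9, box = boundingBox(400, 100, 600, 400))
  b <- mmBox(locateMM(mtBoxOnly, exampleIT(), "right", 1024, 768))
  expect_equal(c(b@x1, b@y1, b@x2, b@y2), c(350, 80, 400, 500))
})

test_that("multiple instances resolve by confidence, then mask area", {
  small <- detection("MT", 0.95, mask = squareMask(500, 200, 560, 300))
  big <- detection("MT", 0.60, mask = squareMask(400, 100, 600, 400))
  picked <- SinusDx:::selectInstance(list(big, small), "MT")
  expect_equal(picked@confidence, 0.95)
  tieA <- detection("MT", 0.9, mask = squareMask(400, 100, 600, 400))
  tieB <- detection("MT", 0.9, mask = squareMask(500, 200, 560, 300))
  expect_equal(SinusDx:::maskArea(SinusDx:::selectInstance(list(tieB, tieA), "MT")@mask),
               SinusDx:::maskArea(tieA@mask))
})

test_that("offsets scale with frame size", {
  # half-size frame: all offsets halve
  mtHalf <- detection("MT", 0.9, mask = squareMask(200, 50, 300, 200))
  itHalf <- detection("IT", 0.8, mask = squareMask(190, 250, 325, 350))
  b <- mmBox(locateMM(mtHalf, itHalf, "right", 512, 384))
  expect_equal(c(b@x1, b@y1, b@x2, b@y2), c(200 - 25, 50 - 10, 200, 250))
})
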