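test_that("textbook cases: identity overlap, no mucus, sub-threshold, no MT", {
  mt <- exampleMT(); it <- exampleIT()
  mmBoxRef <- mmBox(locateMM(mt, it, "right", 1024, 768))  # (350,80,400,500)

  mucusFull <- detection("mucus", 0.9, box = mmBoxRef)
  r <- diagnose(exampleFrame(list(mt, it, mucusFull)))
  expect_equal(diagnosisCall(r), "positive")
  expect_true("MM_mucus" %in% triggers(r))
  expect_equal(iouMM(r), 1)

  r2 <- diagnose(exampleFrame(list(mt, it)))
  expect_equal(diagnosisCall(r2), "negative")
  expect_length(triggers(r2), 0)

  # contained mucus covering a quarter of the MM height: IoU 0.25, below 0.3
  mucusQ <- detection("mucus", 0.9, box = boundingBox(350, 80, 400, 185))
  r3 <- diagnose(exampleFrame(list(mt, it, mucusQ)))
  expect_equal(iouMM(r3), 0.25)
  expect_equal(diagnosisCall(r3), "negative")

  # no MT: no landmark, no rule applies
  r4 <- diagnose(exampleFrame(list(it, mucusFull)))
  expect_equal(diagnosisCall(r4), "negative")
  expect_true(is.na(iouMT(r4)))
})

test_that("IoU exactly at the threshold does not trigger (strict inequality)", {
  mt <- exampleMT(); it <- exampleIT()
  # contained box with height fraction exactly 0.3 of the MM box
  mucus <- detection("mucus", 0.9, box = boundingBox(350, 80, 400, 80 + 0.3 * 420))
  r <- diagnose(exampleFrame(list(mt, it, mucus)))
  expect_equal(iouMM(r), 0.3)
  expect_equal(diagnosisCall(r), "negative")
  # a hair above fires
  mucus2 <- detection("mucus", 0.9, box = boundingBox(350, 80, 400, 80 + 0.301 * 420))
  expect_equal(diagnosisCall(diagnose(exampleFrame(list(mt, it, mucus2)))), "positive")
})

test_that("permissive mode records both pathways; strict gates the fallback", {
  mt <- exampleMT(); it <- exampleIT()
  # mucus covering most of the MT box but not the MM region
  mucusMT <- detection("mucus", 0.9, box = boundingBox(420, 120, 580, 380))
  rP <- diagnose(exampleFrame(list(mt, it, mucusMT)))
  expect_equal(diagnosisCall(rP), "positive")
  expect_identical(triggers(rP), "MT_mucus")
  # strict mode: MM localization succeeded, so the MT pathway is ineligible
  rS <- diagnose(exampleFrame(list(mt, it, mucusMT)),
                 algorithmConfig(callMode = "strict"))
  expect_equal(diagnosisCall(rS), "negative")
  expect_false(is.na(iouMT(rS)))  # still evaluated and reported
  # dual trigger: one deposit in the MM region, another over the MT
  mucusMM <- detection("mucus", 0.9, box = boundingBox(350, 80, 400, 500))
  rD <- diagnose(exampleFrame(list(mt, it, mucusMM, mucusMT)))
  expect_setequal(triggers(rD), c("MM_mucus", "MT_mucus"))
})

test_that("positives are monotone non-increasing in the IoU threshold", {
  suite <- generateSuite(sceneParams(seed = 19), 40)
  grid <- seq(0, 1, length.out = 101)
  pos <- vapply(grid, function(th) {
    cfg <- algorithmConfig(iouThreshold = th)
    sum(vapply(diagnoseBatch(suite$frames, cfg), diagnosisCall,
               character(1)) == "positive")
  }, numeric(1))
  expect_true(all(diff(pos) <= 0))
})

test_that("diagnosis is deterministic and batch equals mapped singletons", {
  suite <- generateSuite(sceneParams(seed = 23), 10)
  r1 <- diagnoseBatch(suite$frames)
  r2 <- diagnoseBatch(suite$frames)
  expect_equal(r1, r2)
  singles <- lapply(suite$frames, diagnose)
  expect_equal(r1, singles)
  expect_identical(diagnoseBatch(list()), list())
  expect_identical(vapply(r1, frameId, character(1)),
                   vapply(suite$frames, frameId, character(1)))
})

test_that("unfiltered frames warn and are auto-filtered", {
  mt <- exampleMT()
  weakMucus <- detection("mucus", 0.1, box = boundingBox(370, 80, 400, 550))
  fr <- exampleFrame(list(mt, weakMucus))
  expect_warning(r <- diagnose(fr), "below the confidence threshold")
  expect_equal(diagnosisCall(r), "negative")
})

test_that("union aggregation pools fragmented mucus that max misses", {
  mt <- exampleMT(); it <- exampleIT()
  # two disjoint halves of the MM region: each IoU < 0.5, union IoU ~ 1
  top <- detection("mucus", 0.9, box = boundingBox(350, 80, 400, 290))
  bottom <- detection("mucus", 0.9, box = boundingBox(350, 290, 400, 500))
  frame <- exampleFrame(list(mt, it, top, bottom))
  rMax <- diagnose(frame)
  expect_equal(iouMM(rMax), 0.5)
  rUnion <- diagnose(frame, algorithmConfig(mucusAggregation = "union"))
  expect_equal(iouMM(rUnion), 1)
})

test_that("filtering keeps threshold ties and is idempotent", {
  dets <- list(detection("MT", 0.9, box = boundingBox(0, 0, 10, 10)),
               detection("mucus", 0.31, box = boundingBox(0, 0, 10, 10)),
               detection("mucus", 0.29, box = boundingBox(0, 0, 10, 10)),
               detection("mucus", 0.3, box = boundingBox(0, 0, 10, 10)))
  fr <- exampleFrame(dets)
  f1 <- filterByConfidence(fr)
  expect_length(detections(f1), 3)  # 0.3 retained (inclusive)
  expect_equal(detections(filterByConfidence(f1)), detections(f1))
  f0 <- filterByConfidence(fr, algorithmConfig(confidenceThreshold = 0))
  expect_length(detections(f0), 4)
  fAll <- filterByConfidence(fr, algorithmConfig(confidenceThreshold = 0.95))
  expect_length(detections(fAll), 0)
})
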