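test_that("classification metrics match hand counts and published F1 arithmetic", {
  calls <- c(rep("positive", 3), "negative", rep("positive", 1), rep("negative", 5))
  gt <- c(rep("positive", 4), rep("negative", 6))
  m <- classificationMetrics(calls, gt)
  expect_equal(unname(m$counts), c(3, 1, 5, 1))  # tp fp tn fn
  expect_equal(m$sensitivity, 75)
  expect_equal(m$specificity, 5 / 6 * 100)
  expect_equal(m$precision, 75)
  expect_equal(m$accuracy, 80)
  # harmonic-mean arithmetic on the published overall row: P=90, R=75 -> 81.8
  expect_equal(roundHalfUp(f1Score(90, 75)), 81.8)
  # all correct
  mAll <- classificationMetrics(gt, gt)
  expect_equal(unlist(mAll[c("sensitivity", "specificity", "precision",
                             "accuracy", "f1")]),
               c(sensitivity = 100, specificity = 100, precision = 100,
                 accuracy = 100, f1 = 100))
  expect_error(classificationMetrics(calls, c(gt[-1], NA)), "ground-truth")
})

test_that("classification metrics agree with brute-force counting", {
  withr::with_seed(17, {
    for (i in 1:1000) {
      n <- sample(3:40, 1)
      calls <- sample(c("positive", "negative"), n, replace = TRUE)
      gt <- sample(c("positive", "negative"), n, replace = TRUE)
      m <- classificationMetrics(calls, gt)
      tp <- 0L; fp <- 0L; tn <- 0L; fn <- 0L
      for (j in seq_len(n)) {
        if (calls[j] == "positive" && gt[j] == "positive") tp <- tp + 1L
        else if (calls[j] == "positive") fp <- fp + 1L
        else if (gt[j] == "negative") tn <- tn + 1L
        else fn <- fn + 1L
      }
      expect_identical(unname(m$counts), c(tp, fp, tn, fn))
      if (tp + fn > 0) expect_equal(m$sensitivity, 100 * tp / (tp + fn))
      else expect_true(is.na(m$sensitivity))
      if (tp + fp > 0) expect_equal(m$precision, 100 * tp / (tp + fp))
      else expect_true(is.na(m$precision))
      if (!is.na(m$f1))
        expect_equal(m$f1, f1Score(m$precision, m$sensitivity))
    }
  })
})

test_that("undefined ratios surface as NA, never silent zero", {
  m <- classificationMetrics(rep("negative", 4), rep("negative", 4))
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$precision))
  expect_equal(m$specificity, 100)
})

test_that("segmentation matching is greedy by confidence with one GT per match", {
  gtF <- exampleFrame(list(detection("MT", 1, mask = squareMask(100, 100, 200, 200))),
                      id = "s1")
  # two predictions on one GT: best IoU wins, the other is an FP
  predHigh <- detection("MT", 0.9, mask = squareMask(100, 100, 200, 190))  # IoU 0.9
  predLow <- detection("MT", 0.8, mask = squareMask(100, 100, 200, 170))   # IoU 0.7
  predF <- exampleFrame(list(predLow, predHigh), id = "s1")
  sm <- segmentationMetrics(list(predF), list(gtF))
  mt <- sm[sm$class == "MT", ]
  expect_equal(c(mt$tp, mt$fp, mt$fn), c(1, 1, 0))
  expect_equal(mt$mean_iou, 0.9, tolerance = 0.02)
  expect_equal(mt$precision, 50)
  expect_equal(mt$recall, 100)

  # single clean match: everything 100%
  sm2 <- segmentationMetrics(list(exampleFrame(list(predHigh), id = "s1")), list(gtF))
  mt2 <- sm2[sm2$class == "MT", ]
  expect_equal(c(mt2$precision, mt2$recall, mt2$f1), c(100, 100, 100))

  # sub-threshold IoU does not match
  predPoor <- detection("MT", 0.9, mask = squareMask(160, 160, 260, 260))
  sm3 <- segmentationMetrics(list(exampleFrame(list(predPoor), id = "s1")), list(gtF))
  mt3 <- sm3[sm3$class == "MT", ]
  expect_equal(c(mt3$tp, mt3$fp, mt3$fn), c(0, 1, 1))

  expect_error(segmentationMetrics(list(predF),
                                   list(exampleFrame(list(), id = "other"))),
               "pair")
})

test_that("segmentation F1 is the harmonic mean of the published P/R rows", {
  expect_equal(roundHalfUp(f1Score(95.1, 92.2)), 93.6)  # middle turbinate
  expect_equal(roundHalfUp(f1Score(90.6, 87.1)), 88.8)  # inferior turbinate
})

test_that("ROC analysis: separation, pair-counting example, oracle equivalence", {
  # perfectly separated scores
  frames <- c(lapply(1:4, function(i) scoreFrame(0.6 + 0.05 * i, paste0("p", i), "positive")),
              lapply(1:4, function(i) scoreFrame(0.05 * i, paste0("n", i), "negative")))
  roc <- rocAnalysis(frames, nBoot = 50)
  expect_equal(aucValue(roc), 1)
  expect_true(all(diff(roc@tpr) >= 0))  # non-decreasing as threshold drops
  expect_true(all(diff(roc@fpr) >= 0))

  # 2 positives (.9,.4), 2 negatives (.5,.1): 3 of 4 concordant pairs
  frames2 <- list(scoreFrame(0.9, "p1", "positive"), scoreFrame(0.4, "p2", "positive"),
                  scoreFrame(0.5, "n1", "negative"), scoreFrame(0.1, "n2", "negative"))
  expect_equal(aucValue(rocAnalysis(frames2, nBoot = 50)), 0.75)

  # trapezoid over the empirical curve equals the concordance estimator
  withr::with_seed(29, {
    for (i in 1:20) {
      n <- 50
      scores <- round(runif(n), 2)  # rounding forces ties
      positive <- runif(n) < 0.5
      if (length(unique(positive)) < 2) next
      expect_equal(SinusDx:::empiricalAuc(scores, positive),
                   concordanceAuc(scores, positive), tolerance = 1e-9)
    }
  })

  expect_error(rocAnalysis(frames[1:4], nBoot = 10), "both positive and negative")
})

test_that("AUC matches an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(37, {
    scores <- round(runif(60), 2)
    positive <- runif(60) < 0.45
    ref <- as.numeric(pROC::auc(pROC::roc(positive, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(SinusDx:::empiricalAuc(scores, positive), ref, tolerance = 1e-9)
  })
})

test_that("near-random scores give AUC near one half", {
  withr::with_seed(53, {
    scores <- runif(4000)
    positive <- runif(4000) < 0.5
    expect_equal(SinusDx:::empiricalAuc(scores, positive), 0.5, tolerance = 0.03)
  })
})

test_that("pathway statistics reproduce the published trigger accounting", {
  tally <- data.frame(
    laterality = c("left", "left", "right", "right"),
    gt = c("positive", "negative", "positive", "negative"),
    MM_mucus = c(30, 1, 6, 1),
    MT_mucus = c(32, 2, 31, 7))
  ps <- pathwayStats(tally)
  expect_equal(roundHalfUp(ps$precision[ps$pathway == "MM_mucus"]), 94.7)
  expect_equal(roundHalfUp(ps$precision[ps$pathway == "MT_mucus"]), 87.5)
  expect_equal(roundHalfUp(ps$fp_share[ps$pathway == "MT_mucus"]), 81.8)
  expect_equal(sum(ps$usage_share), 100, tolerance = 0.1)
  expect_equal(sum(ps$fp_share), 100, tolerance = 0.1)

  # a pathway never firing in negatives has perfect precision
  clean <- data.frame(laterality = "left", gt = c("positive", "negative"),
                      MM_mucus = c(5, 0), MT_mucus = c(2, 3))
  expect_equal(pathwayStats(clean)$precision[1], 100)

  none <- data.frame(laterality = "left", gt = c("positive", "negative"),
                     MM_mucus = 0L, MT_mucus = 0L)
  expect_true(all(is.na(pathwayStats(none)$precision)))
})

test_that("trigger tally strata sum to the overall row", {
  suite <- generateSuite(sceneParams(seed = 61), 40)
  results <- diagnoseBatch(suite$frames)
  tal <- triggerTally(suite$frames, results)
  ov <- tal[tal$laterality == "overall", ]
  expect_equal(ov$MM_mucus, sum(tal$MM_mucus[tal$laterality != "overall"]))
  expect_equal(ov$MT_mucus, sum(tal$MT_mucus[tal$laterality != "overall"]))
  expect_true(all(tal$MM_mucus >= 0 & tal$MT_mucus >= 0))
})

test_that("agreement: perfect, adversarial, and a hand-computed kappa table", {
  same <- matrix("yes", 10, 3)
  agSame <- agreement(same)
  expect_equal(agSame$fleissKappa, 1)

  flip <- cbind(rep(c("a", "b"), 5), rep(c("b", "a"), 5))
  expect_lte(agreement(flip)$fleissKappa, 0)
  expect_equal(agreement(flip)$pairwiseF1Mean, 0)

  # 3 raters x 6 items: kappa from first principles on the count table
  r <- cbind(c("p", "p", "n", "n", "p", "n"),
             c("p", "n", "n", "p", "p", "n"),
             c("p", "p", "n", "n", "n", "n"))
  counts <- t(apply(r, 1, function(row) c(sum(row == "n"), sum(row == "p"))))
  n <- 3
  Pi <- (rowSums(counts^2) - n) / (n * (n - 1))
  pj <- colSums(counts) / sum(counts)
  kappaRef <- (mean(Pi) - sum(pj^2)) / (1 - sum(pj^2))
  expect_equal(agreement(r)$fleissKappa, kappaRef)

  # pairwise F1 against the reference rater, positive class "p"
  f1Of <- function(j) {
    tp <- sum(r[, j] == "p" & r[, 1] == "p")
    fp <- sum(r[, j] == "p" & r[, 1] == "n")
    fn <- sum(r[, j] == "n" & r[, 1] == "p")
    2 * tp / (2 * tp + fp + fn)
  }
  expect_equal(agreement(r, positive = "p")$pairwiseF1Mean, mean(c(f1Of(2), f1Of(3))))

  expect_error(agreement(cbind(c("a", NA), c("a", "b"))), "missing")
  expect_error(agreement(matrix("a", 3, 1)), "2 raters")
})
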