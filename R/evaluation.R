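# Evaluation stack: classification metrics, segmentation metrics,
# ROC/AUC with bootstrap CI, trigger-pathway accounting, inter-rater
# agreement.

#' Round half-up
#'
#' Reported percentages use half-up rounding to one decimal (the table
#' convention), not banker's rounding.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return numeric.
#' @export
roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' F1 score from precision and recall
#'
#' Harmonic mean \code{2PR/(P+R)}; 0 when both are 0. Scale-agnostic
#' (works on ratios or percentages).
#'
#' @param precision,recall numeric vectors.
#' @return numeric vector.
#' @examples
#' f1Score(90, 75)  # 81.8% (overall classification row)
#' @export
f1Score <- function(precision, recall) {
  ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall), 0)
}

ratioOrNA <- function(num, den) if (den > 0) 100 * num / den else NA_real_

#' Binary classification metrics against expert ground truth
#'
#' @param calls character vector of \code{"positive"}/\code{"negative"}
#'   calls, or a list of \linkS4class{DiagnosisResult}.
#' @param gtLabels character vector of expert labels (same length); any
#'   missing label is an error.
#' @return List with \code{counts} (named tp/fp/tn/fn) and
#'   \code{sensitivity}, \code{specificity}, \code{precision},
#'   \code{accuracy}, \code{f1}, all in percent; ratios with a zero
#'   denominator are NA, never silent 0/0.
#' @export
classificationMetrics <- function(calls, gtLabels) {
  if (is.list(calls))
    calls <- vapply(calls, diagnosisCall, character(1))
  if (length(calls) != length(gtLabels))
    stop("calls and gtLabels must have equal length")
  if (any(is.na(gtLabels)) || !all(gtLabels %in% c("positive", "negative")))
    stop("every frame needs a ground-truth label")
  tp <- sum(calls == "positive" & gtLabels == "positive")
  fp <- sum(calls == "positive" & gtLabels == "negative")
  tn <- sum(calls == "negative" & gtLabels == "negative")
  fn <- sum(calls == "negative" & gtLabels == "positive")
  prec <- ratioOrNA(tp, tp + fp)
  sens <- ratioOrNA(tp, tp + fn)
  list(counts = c(tp = tp, fp = fp, tn = tn, fn = fn),
       sensitivity = sens,
       specificity = ratioOrNA(tn, tn + fp),
       precision = prec,
       accuracy = ratioOrNA(tp + tn, tp + fp + tn + fn),
       f1 = if (is.na(prec) || is.na(sens)) NA_real_ else f1Score(prec, sens))
}

#' Laterality-stratified classification report
#'
#' @param frames list of \linkS4class{EndoscopyFrame} with ground truth.
#' @param results matching list of \linkS4class{DiagnosisResult}.
#' @return data.frame with rows \code{left}, \code{right}, \code{overall}
#'   and columns n, sensitivity, specificity, precision, accuracy, f1 (percent).
#' @export
classificationByLaterality <- function(frames, results) {
  calls <- vapply(results, diagnosisCall, character(1))
  gt <- vapply(frames, gtLabel, character(1))
  side <- vapply(frames, laterality, character(1))
  one <- function(sel, name) {
    m <- classificationMetrics(calls[sel], gt[sel])
    data.frame(region = name, n = sum(sel), sensitivity = m$sensitivity,
               specificity = m$specificity, precision = m$precision,
               accuracy = m$accuracy, f1 = m$f1)
  }
  rbind(one(side == "left", "left"), one(side == "right", "right"),
        one(rep(TRUE, length(side)), "overall"))
}

#' Per-class instance-segmentation metrics
#'
#' Predictions are matched to same-class ground-truth instances per frame,
#' greedily in order of descending confidence, each ground-truth instance
#' used at most once; a match requires mask IoU at or above
#' \code{matchIoU} (pixel-rasterized polygon IoU; box IoU when either
#' side lacks a mask). Matches are true positives, unmatched predictions
#' false positives, unmatched ground truth false negatives.
#'
#' @param predFrames,gtFrames lists of \linkS4class{EndoscopyFrame}
#'   paired by frame id (unpaired ids are an error).
#' @param matchIoU matching threshold (default 0.5).
#' @return data.frame with one row per class plus a pooled
#'   \code{overall} row: instance counts, mean matched IoU, precision,
#'   recall and F1 (percent).
#' @export
segmentationMetrics <- function(predFrames, gtFrames, matchIoU = 0.5) {
  pid <- vapply(predFrames, frameId, character(1))
  gid <- vapply(gtFrames, frameId, character(1))
  if (!setequal(pid, gid) || anyDuplicated(pid) || anyDuplicated(gid))
    stop("prediction and ground-truth frames must pair one-to-one by frame id")
  gtFrames <- gtFrames[match(pid, gid)]

  acc <- list()
  for (cls in DETECTION_LABELS)
    acc[[cls]] <- list(tp = 0L, fp = 0L, fn = 0L, ious = numeric(0),
                       images = 0L, instances = 0L)

  for (i in seq_along(predFrames)) {
    for (cls in DETECTION_LABELS) {
      preds <- Filter(function(d) d@label == cls, predFrames[[i]]@detections)
      gts <- Filter(function(d) d@label == cls, gtFrames[[i]]@detections)
      if (length(gts)) {
        acc[[cls]]$images <- acc[[cls]]$images + 1L
        acc[[cls]]$instances <- acc[[cls]]$instances + length(gts)
      }
      if (length(preds))
        preds <- preds[order(-vapply(preds, function(d) d@confidence, numeric(1)))]
      used <- rep(FALSE, length(gts))
      for (p in preds) {
        best <- 0; bestJ <- 0L
        for (j in seq_along(gts)) {
          if (used[j]) next
          iou <- if (!is.null(p@mask) && !is.null(gts[[j]]@mask))
            iouMasks(p@mask, gts[[j]]@mask) else iouBoxes(p@box, gts[[j]]@box)
          if (iou > best) { best <- iou; bestJ <- j }
        }
        if (bestJ > 0L && best >= matchIoU) {
          used[bestJ] <- TRUE
          acc[[cls]]$tp <- acc[[cls]]$tp + 1L
          acc[[cls]]$ious <- c(acc[[cls]]$ious, best)
        } else acc[[cls]]$fp <- acc[[cls]]$fp + 1L
      }
      acc[[cls]]$fn <- acc[[cls]]$fn + sum(!used)
    }
  }

  row <- function(cls, a) {
    p <- ratioOrNA(a$tp, a$tp + a$fp)
    r <- ratioOrNA(a$tp, a$tp + a$fn)
    data.frame(class = cls, images = a$images, instances = a$instances,
               tp = a$tp, fp = a$fp, fn = a$fn,
               mean_iou = if (length(a$ious)) mean(a$ious) else NA_real_,
               precision = p, recall = r,
               f1 = if (is.na(p) || is.na(r)) NA_real_ else f1Score(p, r))
  }
  pooled <- list(tp = sum(vapply(acc, `[[`, integer(1), "tp")),
                 fp = sum(vapply(acc, `[[`, integer(1), "fp")),
                 fn = sum(vapply(acc, `[[`, integer(1), "fn")),
                 ious = unlist(lapply(acc, `[[`, "ious")),
                 images = length(predFrames),
                 instances = sum(vapply(acc, `[[`, integer(1), "instances")))
  rbind(do.call(rbind, lapply(DETECTION_LABELS, function(cl) row(cl, acc[[cl]]))),
        row("overall", pooled))
}

# exact empirical AUC: trapezoid over the ROC built from all distinct
# scores (equals the concordance-pair estimator with ties counted 1/2)
empiricalAuc <- function(scores, positive) {
  cuts <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(cuts, function(t) mean(scores[positive] > t), numeric(1))
  fpr <- vapply(cuts, function(t) mean(scores[!positive] > t), numeric(1))
  sum(diff(fpr) * (tpr[-1L] + tpr[-length(tpr)]) / 2)
}

#' ROC threshold-sensitivity analysis
#'
#' Sweeps the diagnostic IoU threshold over a grid. The per-frame decision
#' statistic is the larger of the two pathway IoUs (MM-mucus, MT-mucus;
#' 0 when neither landmark is available), the quantity the rule compares
#' against its threshold, with the same strict \code{score > threshold}
#' comparison. The AUC is computed by the trapezoidal rule over the full
#' empirical curve (all distinct scores), and its 95\% confidence interval
#' by a seeded nonparametric percentile bootstrap over frames.
#'
#' @param frames list of \linkS4class{EndoscopyFrame}; ground truth is
#'   taken from the frames unless \code{gtLabels} is given. Both classes
#'   must be present (AUC is undefined otherwise).
#' @param cfg an \linkS4class{AlgorithmConfig}.
#' @param grid threshold grid in \[0, 1\] (sorted to descending).
#' @param gtLabels optional character vector overriding frame ground truth.
#' @param nBoot bootstrap resamples (default 2000).
#' @param seed bootstrap seed.
#' @return A \linkS4class{RocCurve}.
#' @export
rocAnalysis <- function(frames, cfg = algorithmConfig(),
                        grid = seq(0, 1, by = 0.01), gtLabels = NULL,
                        nBoot = 2000, seed = 1L) {
  results <- diagnoseBatch(frames, cfg)
  if (is.null(gtLabels)) gtLabels <- vapply(frames, gtLabel, character(1))
  if (any(is.na(gtLabels)) || length(unique(gtLabels)) < 2L)
    stop("ROC analysis needs both positive and negative ground-truth frames")
  scores <- vapply(results, function(r)
    max(r@iouMM, r@iouMT, 0, na.rm = TRUE), numeric(1))
  positive <- gtLabels == "positive"

  grid <- sort(grid, decreasing = TRUE)
  tpr <- vapply(grid, function(t) mean(scores[positive] > t), numeric(1))
  fpr <- vapply(grid, function(t) mean(scores[!positive] > t), numeric(1))
  auc <- empiricalAuc(scores, positive)

  boots <- withr::with_seed(seed, {
    vapply(seq_len(nBoot), function(b) {
      idx <- sample.int(length(scores), replace = TRUE)
      if (length(unique(positive[idx])) < 2L) return(NA_real_)
      empiricalAuc(scores[idx], positive[idx])
    }, numeric(1))
  })
  ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)

  new("RocCurve", thresholds = grid, tpr = tpr, fpr = fpr, auc = auc,
      ciLow = ci[1L], ciHigh = ci[2L])
}

#' Tally trigger-pathway firings by laterality and ground truth
#'
#' @param frames list of \linkS4class{EndoscopyFrame} with ground truth.
#' @param results matching list of \linkS4class{DiagnosisResult}.
#' @return data.frame with one row per (laterality, gt) stratum plus an
#'   \code{overall} row; columns \code{MM_mucus} and \code{MT_mucus} count
#'   pathway firings.
#' @export
triggerTally <- function(frames, results) {
  side <- vapply(frames, laterality, character(1))
  gt <- vapply(frames, gtLabel, character(1))
  if (any(is.na(gt))) stop("every frame needs a ground-truth label")
  strata <- expand.grid(laterality = LATERALITIES,
                        gt = c("positive", "negative"),
                        stringsAsFactors = FALSE)
  fired <- function(sel, pw) sum(vapply(results[sel], function(r)
    pw %in% r@triggers, logical(1)))
  tal <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
    sel <- side == strata$laterality[i] & gt == strata$gt[i]
    data.frame(laterality = strata$laterality[i], gt = strata$gt[i],
               MM_mucus = fired(sel, "MM_mucus"), MT_mucus = fired(sel, "MT_mucus"))
  }))
  rbind(tal, data.frame(laterality = "overall", gt = "all",
                        MM_mucus = sum(tal$MM_mucus), MT_mucus = sum(tal$MT_mucus)))
}

#' Pathway-level precision, false-positive share and usage share
#'
#' From a stratified firing tally: a pathway's precision is the share of
#' its firings that occurred on ground-truth-positive frames; its
#' false-positive share is its fraction of all firings on ground-truth
#' negatives; its usage share is its fraction of the grand firing total.
#'
#' @param tally a data.frame as produced by [triggerTally()] (stratum rows
#'   with \code{gt} \code{"positive"}/\code{"negative"}; any
#'   \code{overall} row is ignored and recomputed).
#' @return data.frame with one row per pathway: firings in positive and
#'   negative strata, \code{precision}, \code{fp_share} and
#'   \code{usage_share} (percent; NA when a denominator is zero).
#' @examples
#' tally <- data.frame(
#'   laterality = c("left", "left", "right", "right"),
#'   gt = c("positive", "negative", "positive", "negative"),
#'   MM_mucus = c(30, 1, 6, 1), MT_mucus = c(32, 2, 31, 7))
#' pathwayStats(tally)  # MM precision 94.7, MT precision 87.5, MT fp share 81.8
#' @export
pathwayStats <- function(tally) {
  tally <- tally[tally$gt %in% c("positive", "negative"), , drop = FALSE]
  if (nrow(tally) == 0L) stop("tally has no positive/negative strata")
  pos <- tally$gt == "positive"
  out <- do.call(rbind, lapply(TRIGGER_PATHWAYS, function(pw) {
    firedPos <- sum(tally[[pw]][pos])
    firedNeg <- sum(tally[[pw]][!pos])
    data.frame(pathway = pw, fired_positive = firedPos, fired_negative = firedNeg,
               total = firedPos + firedNeg)
  }))
  allNeg <- sum(out$fired_negative)
  grand <- sum(out$total)
  out$precision <- vapply(seq_len(nrow(out)), function(i)
    ratioOrNA(out$fired_positive[i], out$total[i]), numeric(1))
  out$fp_share <- vapply(out$fired_negative, ratioOrNA, numeric(1), den = allNeg)
  out$usage_share <- vapply(out$total, ratioOrNA, numeric(1), den = grand)
  out
}

#' Inter-rater agreement: pairwise F1 and Fleiss kappa
#'
#' Agreement of several raters assigning categorical labels to the same
#' items (e.g. class-presence labels on an image subset). Reports the mean
#' (and SD) over non-reference raters of their F1 against the reference
#' rater — for binary labels the F1 of the positive class, for more
#' categories the unweighted (macro) mean of per-category one-vs-rest F1 —
#' and Fleiss kappa over all raters.
#'
#' @param ratings items x raters matrix (or data.frame) of labels; no
#'   missing values (a rater with missing items is an error).
#' @param reference column index of the reference rater (default 1).
#' @param positive for binary ratings, the label treated as positive
#'   (default: the last level in sort order, so \code{TRUE} for logicals).
#' @return List with \code{pairwiseF1Mean}, \code{pairwiseF1Sd},
#'   \code{fleissKappa}.
#' @export
agreement <- function(ratings, reference = 1L, positive = NULL) {
  ratings <- as.matrix(ratings)
  if (anyNA(ratings)) stop("raters with missing items are not supported")
  if (ncol(ratings) < 2L) stop("agreement needs at least 2 raters")
  if (nrow(ratings) < 1L) stop("agreement needs at least 1 item")
  ratings <- matrix(as.character(ratings), nrow(ratings), ncol(ratings))
  cats <- sort(unique(as.vector(ratings)))

  f1cat <- function(a, ref, cat) {
    tp <- sum(a == cat & ref == cat)
    fp <- sum(a == cat & ref != cat)
    fn <- sum(a != cat & ref == cat)
    if (2 * tp + fp + fn == 0) return(NA_real_)
    2 * tp / (2 * tp + fp + fn)
  }
  ref <- ratings[, reference]
  others <- setdiff(seq_len(ncol(ratings)), reference)
  f1s <- vapply(others, function(j) {
    if (length(cats) == 2L) {
      posCat <- if (is.null(positive)) cats[length(cats)] else as.character(positive)
      f1cat(ratings[, j], ref, posCat)
    } else {
      mean(vapply(cats, function(ct) f1cat(ratings[, j], ref, ct), numeric(1)),
           na.rm = TRUE)
    }
  }, numeric(1))

  # Fleiss kappa from the items x categories count table
  counts <- vapply(cats, function(ct) rowSums(ratings == ct),
                   numeric(nrow(ratings)))
  counts <- matrix(counts, nrow = nrow(ratings))
  n <- ncol(ratings)
  Pi <- (rowSums(counts^2) - n) / (n * (n - 1))
  pj <- colSums(counts) / (nrow(ratings) * n)
  Pbar <- mean(Pi)
  Pe <- sum(pj^2)
  kappa <- if (abs(1 - Pe) < .Machine$double.eps) 1 else (Pbar - Pe) / (1 - Pe)

  list(pairwiseF1Mean = mean(f1s, na.rm = TRUE),
       pairwiseF1Sd = if (length(f1s) > 1L) stats::sd(f1s, na.rm = TRUE) else NA_real_,
       fleissKappa = kappa)
}
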