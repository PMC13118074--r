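test_that("confusion counting matches a brute-force per-pixel tally", {
  set.seed(3)
  truth <- matrix(sample(0:2, 2500, replace = TRUE), 50, 50)
  pred <- matrix(sample(0:2, 2500, replace = TRUE), 50, 50)
  cc <- confusionFromMaps(pred, truth, region = "fruit_only")
  tp <- fp <- fn <- tn <- 0
  for (i in 1:50) for (j in 1:50) {
    if (truth[i, j] == 0 || pred[i, j] == 0) next
    p <- pred[i, j] == 2; t <- truth[i, j] == 2
    if (p && t) tp <- tp + 1 else if (p && !t) fp <- fp + 1
    else if (!p && t) fn <- fn + 1 else tn <- tn + 1
  }
  expect_equal(c(cc@tp, cc@fp, cc@fn, cc@tn), c(tp, fp, fn, tn))
  expect_error(confusionFromMaps(pred[1:10, 1:10], truth), "shapes")
})

test_that("perfect and degenerate predictions count as expected", {
  truth <- matrix(1L, 25, 20)
  truth[1:5, 1:20] <- 2L   # 100 defect of 500
  cc <- confusionFromMaps(truth, truth)
  expect_equal(c(cc@tp, cc@tn, cc@fp, cc@fn), c(100, 400, 0, 0))
  allHealthy <- matrix(1L, 10, 20)
  t2 <- allHealthy; t2[1:3, 1:10] <- 2L   # 30 defect of 200
  cc2 <- confusionFromMaps(allHealthy, t2)
  expect_equal(c(cc2@tp, cc2@fn, cc2@tn, cc2@fp), c(0, 30, 170, 0))
})

test_that("the seven metrics match hand arithmetic", {
  m <- metricValues(metricsFromConfusion(ConfusionCounts(50, 10, 25, 915)))
  expect_equal(round(m[["accuracy"]], 4), 0.965)
  expect_equal(round(m[["error_rate"]], 4), 3.5)
  expect_equal(round(m[["precision"]], 4), 0.8333)
  expect_equal(round(m[["recall"]], 4), 0.6667)
  expect_equal(round(m[["specificity"]], 4), 0.9892)
  expect_equal(round(m[["f1"]], 4), 0.7407)
  expect_equal(round(m[["iou"]], 4), 0.5882)
})

test_that("zero-denominator metrics are undefined, not zero", {
  m <- metricValues(metricsFromConfusion(ConfusionCounts(0, 0, 0, 100)))
  expect_equal(m[["accuracy"]], 1)
  expect_true(is.na(m[["precision"]]))
  expect_true(is.na(m[["recall"]]))
  expect_true(is.na(m[["f1"]]))
  expect_true(is.na(m[["iou"]]))
})

test_that("metric identities hold over randomized confusion counts", {
  set.seed(41)
  for (k in 1:2000) {
    c4 <- sample(0:500, 4, replace = TRUE)
    if (sum(c4) == 0) c4[1] <- 1
    cc <- ConfusionCounts(c4[1], c4[2], c4[3], c4[4])
    m <- metricValues(metricsFromConfusion(cc))
    expect_equal(m[["accuracy"]] + m[["error_rate"]] / 100, 1)
    if (!any(is.na(m))) {
      expect_equal(m[["f1"]], 2 * c4[1] / (2 * c4[1] + c4[2] + c4[3]))
      expect_equal(m[["iou"]], m[["f1"]] / (2 - m[["f1"]]))
      expect_equal(m[["error_rate"]], errorRateFromAccuracy(m[["accuracy"]]))
      # harmonic-mean compositions additionally need precision + recall > 0
      if (m[["precision"]] + m[["recall"]] > 0) {
        expect_equal(m[["f1"]], f1FromPR(m[["precision"]], m[["recall"]]))
        expect_equal(m[["iou"]], iouFromPR(m[["precision"]], m[["recall"]]))
      }
    }
  }
})

test_that("closed-form identities behave at the edges", {
  expect_equal(f1FromPR(0.7, 0.7), 0.7)      # harmonic mean of equals
  expect_true(is.na(f1FromPR(0, 0)))
  expect_error(f1FromPR(1.2, 0.5), "\\[0, 1\\]")
  expect_error(errorRateFromAccuracy(1.5), "\\[0, 1\\]")
})

test_that("swapping the positive class exchanges recall and specificity", {
  set.seed(9)
  for (k in 1:50) {
    c4 <- sample(1:200, 4)
    m <- metricValues(metricsFromConfusion(ConfusionCounts(c4[1], c4[2], c4[3], c4[4])))
    swapped <- metricValues(metricsFromConfusion(
      ConfusionCounts(tp = c4[4], fp = c4[3], fn = c4[2], tn = c4[1])))
    expect_equal(m[["recall"]], swapped[["specificity"]])
    expect_equal(m[["specificity"]], swapped[["recall"]])
  }
})

test_that("the metric grid round-trips through CSV with best-cell flags", {
  mk <- function(tp, fp, fn, tn) metricsFromConfusion(ConfusionCounts(tp, fp, fn, tn))
  results <- list(
    rf = list(local = mk(80, 10, 20, 890), simultaneous = mk(90, 5, 10, 895)),
    sam = list(local = mk(50, 60, 50, 840), simultaneous = mk(60, 40, 40, 860)))
  f <- tempfile(fileext = ".csv")
  grid <- reportMetricGrid(results, file = f)
  expect_equal(nrow(grid), 2 * 2 * 7)
  back <- read.csv(f)
  expect_equal(back$value, grid$value)
  # flags: per method and metric, the best mode is the max (min for error rate)
  sel <- grid$method == "rf" & grid$metric == "f1"
  expect_equal(grid$mode[sel][grid$best[sel]], "simultaneous")
  err <- grid$method == "rf" & grid$metric == "error_rate"
  expect_equal(grid$mode[err][grid$best[err]], "simultaneous")
  # single result -> single set of rows
  expect_equal(nrow(reportMetricGrid(list(rf = list(local = mk(1, 1, 1, 1))))), 7L)
})

test_that("published metric cells obey the printed-value identities", {
  tab <- referenceMetricTable()
  rfSim <- tab[tab$method == "rf" & tab$mode == "simultaneous", ]
  expect_equal(round(f1FromPR(rfSim$precision, rfSim$recall), 4), rfSim$f1)
  samSeq <- tab[tab$method == "sam" & tab$mode == "sequential", ]
  expect_equal(round(iouFromPR(samSeq$precision, samSeq$recall), 4), samSeq$iou)
  samLoc <- tab[tab$method == "sam" & tab$mode == "local", ]
  expect_equal(round(errorRateFromAccuracy(samLoc$accuracy), 2), samLoc$error_rate)
})
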