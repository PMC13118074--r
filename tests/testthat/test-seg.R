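test_that("fruit-level split has the right sizes and is deterministic", {
  objs <- labelOnlyObjects(c(0, 0, 0, 0, 0, 40, 60, 80, 100, 120))
  s <- splitFruitwise(objs, trainFraction = 0.4, seed = 3L)
  expect_equal(length(s$train), 4L)
  expect_equal(length(s$test), 6L)
  expect_setequal(c(s$train, s$test), 1:10)
  expect_identical(s, splitFruitwise(objs, trainFraction = 0.4, seed = 3L))
  expect_error(splitFruitwise(objs[1], 0.4), "at least two")
})

test_that("the chosen split balances defect proportions at least as well as a typical random split", {
  set.seed(17)
  objs <- labelOnlyObjects(sample(0:150, 20, replace = TRUE))
  s <- splitFruitwise(objs, trainFraction = 0.4, seed = 8L)
  pd <- function(ix) {
    d <- sum(vapply(objs[ix], function(o) sum(o$labels == 2L), numeric(1)))
    t <- sum(vapply(objs[ix], function(o) sum(o$labels > 0L), numeric(1)))
    d / t
  }
  gaps <- replicate(50, {
    tr <- sample.int(20, 8)
    abs(pd(tr) - pd(setdiff(1:20, tr)))
  })
  expect_lte(s$gap, median(gaps))
})

test_that("under-sampling equalizes classes without touching defect pixels", {
  mk <- function(nh, nd) hsifruit:::PixelDataset(
    matrix(runif((nh + nd) * 3), nh + nd, 3),
    rep(c("healthy", "defect"), c(nh, nd)),
    rep(1L, nh + nd))
  b <- undersampleHealthy(mk(1000L, 100L), seed = 2L)
  expect_equal(unname(table(b@labels)["healthy"]), 100L)
  expect_equal(unname(table(b@labels)["defect"]), 100L)
  # already balanced: unchanged
  d0 <- mk(100L, 100L)
  expect_identical(undersampleHealthy(d0, seed = 2L), d0)
  # defect rows are preserved exactly
  d1 <- mk(500L, 50L)
  b1 <- undersampleHealthy(d1, seed = 4L)
  expect_equal(b1@spectra[b1@labels == "defect", ],
               d1@spectra[d1@labels == "defect", ])
})

test_that("under-sampling reproduces the study's test-set balance exactly", {
  nH <- 136267L; nD <- 27956L
  ds <- hsifruit:::PixelDataset(matrix(0.5, nH + nD, 2),
                                rep(c("healthy", "defect"), c(nH, nD)),
                                rep(1L, nH + nD))
  b <- undersampleHealthy(ds, seed = 1L)
  expect_equal(unname(table(b@labels)["healthy"]), 27956L)
  expect_equal(unname(table(b@labels)["defect"]), 27956L)
})

test_that("reference spectra are class means with unit-norm copies", {
  sp <- rbind(t(replicate(4, c(1, 0, 1))), t(replicate(4, c(0, 1, 0))))
  ds <- hsifruit:::PixelDataset(sp, rep(c("healthy", "defect"), each = 4),
                                rep(1L, 8))
  refs <- computeReferenceSpectra(ds)
  expect_equal(refs@healthy, c(1, 0, 1))
  expect_equal(sum(refs@healthyNorm^2), 1)
  expect_equal(sum(refs@defectNorm^2), 1)
})

test_that("SAM similarity reproduces closed-form cosines", {
  g <- SpectralGrid(c(500, 600, 700))
  ds <- hsifruit:::PixelDataset(rbind(t(replicate(3, c(1, 1, 0))),
                                      t(replicate(3, c(0, 1, 1)))),
                                rep(c("healthy", "defect"), each = 3),
                                rep(1L, 6))
  refs <- computeReferenceSpectra(ds)
  v <- array(0, c(1, 3, 3))
  v[1, 1, ] <- c(1, 1, 0)    # identical direction to healthy ref -> 1
  v[1, 2, ] <- c(0, 0, 1)    # orthogonal-ish
  v[1, 3, ] <- c(1, 0, 1)    # cos = 0.5 with (1,1,0)
  maps <- samSimilarityMaps(refCube(v, g), matrix(TRUE, 1, 3), refs)
  expect_equal(maps@healthy[1, 1], 1)
  expect_equal(maps@healthy[1, 2], 0)
  expect_equal(maps@healthy[1, 3], 0.5)
})

test_that("SAM similarity is invariant to positive scaling of a spectrum", {
  g <- tinyGrid()
  set.seed(2)
  base <- runif(9, 0.1, 0.9)
  v <- array(0, c(1, 4, 9))
  for (j in 1:4) v[1, j, ] <- base * c(1, 0.1, 3.7, 120)[j]
  ds <- separableDataset(20L, bands = 9L)
  refs <- computeReferenceSpectra(ds)
  maps <- samSimilarityMaps(refCube(v, g), matrix(TRUE, 1, 4), refs)
  expect_equal(rep(maps@healthy[1, 1], 3), maps@healthy[1, 2:4])
})

test_that("SAM classification thresholds the healthy map and spares glare", {
  sim <- matrix(0.9, 4, 4)
  sim[1, 1:2] <- 0.1                       # low similarity -> defect
  glare <- matrix(FALSE, 4, 4); glare[1, 2] <- TRUE
  maps <- new("SimilarityMaps", healthy = sim, defect = 1 - sim,
              glare = glare, valid = matrix(TRUE, 4, 4))
  dm <- samClassify(maps, "fixed", 0.2)
  expect_equal(dm@map[1, 1], 2L)           # below threshold
  expect_equal(dm@map[1, 2], 1L)           # glare forced healthy
  expect_true(all(dm@map[2:4, ] == 1L))
  # all-high similarity -> no defects
  ok <- new("SimilarityMaps", healthy = matrix(0.99, 2, 2),
            defect = matrix(0, 2, 2), glare = matrix(FALSE, 2, 2),
            valid = matrix(TRUE, 2, 2))
  expect_true(all(samClassify(ok, "fixed", 0.2)@map == 1L))
  expect_error(samClassify(ok, "fixed", NA), "threshold")
})

test_that("random forest separates separable classes and reports OOB error", {
  ds <- separableDataset(150L, seed = 5L)
  m <- trainRF(ds, seed = 9L)
  expect_s4_class(m, "RFModel")
  p <- predictLabels(m, ds@spectra)
  expect_equal(mean(p == ds@labels), 1)
  expect_lt(m@metadata$oobError, 0.05)
  # seeded determinism on a probe set
  probe <- separableDataset(40L, seed = 6L)@spectra
  m2 <- trainRF(ds, seed = 9L)
  expect_identical(predictLabels(m, probe), predictLabels(m2, probe))
})

test_that("a 100-tree ensemble is no worse out-of-bag than a single tree", {
  set.seed(21)
  n <- 300
  X <- rbind(matrix(rnorm(n * 10, 0.4, 0.25), n, 10),
             matrix(rnorm(n * 10, 0.6, 0.25), n, 10))
  ds <- hsifruit:::PixelDataset(X, rep(c("healthy", "defect"), each = n),
                                rep(1L, 2 * n))
  oob1 <- trainRF(ds, nTrees = 1L, seed = 2L)@metadata$oobError
  oob100 <- trainRF(ds, nTrees = 100L, seed = 2L)@metadata$oobError
  expect_lte(oob100, oob1)
})

test_that("SVM separates well-separated Gaussian classes in 81-D", {
  set.seed(13)
  n <- 300
  mk <- function(mu, n) matrix(rnorm(n * 81, mu, 0.05), n, 81)
  ds <- hsifruit:::PixelDataset(rbind(mk(0.3, n), mk(0.7, n)),
                                rep(c("healthy", "defect"), each = n),
                                rep(1L, 2 * n))
  m <- trainSVM(ds, seed = 4L)
  test <- rbind(mk(0.3, 200), mk(0.7, 200))
  p <- predictLabels(m, test)
  truth <- rep(c("healthy", "defect"), each = 200)
  expect_lt(mean(p != truth), 0.02)
})

test_that("duplicating every SVM training point leaves predictions unchanged", {
  ds <- separableDataset(60L, bands = 10L, seed = 3L)
  dup <- hsifruit:::PixelDataset(rbind(ds@spectra, ds@spectra),
                                 c(as.character(ds@labels), as.character(ds@labels)),
                                 c(ds@fruit, ds@fruit))
  probe <- separableDataset(50L, bands = 10L, seed = 8L)@spectra
  expect_identical(predictLabels(trainSVM(ds, seed = 2L), probe),
                   predictLabels(trainSVM(dup, seed = 2L), probe))
})

test_that("a two-point SVM bisects the points", {
  a <- rep(0.2, 10); b <- rep(0.8, 10)
  ds <- hsifruit:::PixelDataset(rbind(a, b), c("healthy", "defect"), c(1L, 2L))
  m <- trainSVM(ds, seed = 1L)
  mid <- matrix((a + b) / 2, 1)
  dec <- attr(predict(m@fit, mid, decision.values = TRUE), "decision.values")
  expect_lt(abs(dec), 0.05)
})

test_that("the spectral CNN has the hand-counted parameter total", {
  # conv blocks: (5*cin*8 + 8) weights+biases, batch norm 2*8 each
  convs <- (5 * c(1, 8, 8) * 8 + 8) + 16
  dense <- (8 * 64 + 64) + (64 * 16 + 16) + (16 * 2 + 2)
  expect_equal(nnParameterCount(81L), sum(convs) + dense)
  # independent of the band count (global average pooling)
  expect_equal(nnParameterCount(40L), nnParameterCount(81L))
})

test_that("the CNN learns trivially separable spectra within 20 epochs", {
  ds <- separableDataset(300L, seed = 12L)
  m <- trainNN(ds, epochs = 20L, seed = 7L)
  p <- predictLabels(m, ds@spectra)
  expect_equal(mean(p == ds@labels), 1)
})

test_that("CNN training is bit-reproducible under a fixed seed", {
  ds <- separableDataset(80L, seed = 2L)
  m1 <- trainNN(ds, epochs = 3L, seed = 5L)
  m2 <- trainNN(ds, epochs = 3L, seed = 5L)
  expect_identical(m1@metadata$finalLoss, m2@metadata$finalLoss)
  expect_identical(m1@net$params, m2@net$params)
})

test_that("the CNN rejects spectra shorter than its kernel", {
  ds <- separableDataset(20L, bands = 3L)
  expect_error(trainNN(ds, epochs = 1L), "kernel")
})

test_that("all four classifiers emit decision maps of identical shape", {
  g <- tinyGrid()
  truth <- makePhantomScene(tinyPhantom(nFruit = 2L, radius = 14,
                                        lobeAmplitude = 0, seed = 3L), g)
  set <- renderIlluminationSet(truth, noiseSd = 0)
  cube <- reflectanceSimultaneous(set)
  mask <- truth@labels > 0L
  ds <- pixelDatasetFromObjects(list(list(cube = cube, labels = truth@labels,
                                          id = 1L)))
  balanced <- undersampleHealthy(ds, seed = 1L)
  models <- list(trainSAM(balanced, thresholding = "midpoint"),
                 trainRF(balanced, seed = 1L),
                 trainSVM(balanced, seed = 1L),
                 trainNN(balanced, epochs = 10L, seed = 1L))
  maps <- lapply(models, predictMap, cube = cube, mask = mask)
  for (dm in maps) {
    expect_identical(dim(dm@map), dim(mask))
    expect_true(all(dm@map[!mask] == 0L))
    expect_true(all(dm@map[mask] %in% 1:2))
  }
  # an empty mask yields an all-zero map
  for (mod in models) {
    empty <- predictMap(mod, cube, matrix(FALSE, nrow(mask), ncol(mask)))
    expect_true(all(empty@map == 0L))
  }
  # a perfectly separable noiseless scene is reproduced exactly by RF
  expect_identical(unname(maps[[2]]@map[mask]), unname(truth@labels[mask]))
})
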