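test_that("3x3 median filter removes impulses and preserves constants", {
  g <- SpectralGrid(c(500, 600))
  const <- SpectralCube(array(7, c(6, 6, 2)), g)
  expect_equal(cubeValues(medianFilterBands(const)), cubeValues(const))

  imp <- array(0, c(7, 7, 2))
  imp[4, 4, 1] <- 100
  out <- medianFilterBands(SpectralCube(imp, g))
  expect_equal(cubeValues(out)[4, 4, 1], 0)
})

test_that("3x3 median filter matches the brute-force sort-and-pick oracle", {
  set.seed(31)
  m <- matrix(runif(49), 7, 7)
  out <- cubeValues(medianFilterBands(SpectralCube(array(m, c(7, 7, 1)),
                                                   SpectralGrid(500))))[, , 1]
  # oracle: per-pixel 5th of 9 on the replicate-padded neighborhood
  pad <- rbind(m[1, ], m, m[7, ]); pad <- cbind(pad[, 1], pad, pad[, 7])
  oracle <- matrix(0, 7, 7)
  for (i in 1:7) for (j in 1:7)
    oracle[i, j] <- sort(as.vector(pad[i:(i + 2), j:(j + 2)]))[5]
  expect_equal(out, oracle)
})

test_that("flat-field reflectance is the pixel/band-wise ratio", {
  g <- tinyGrid()
  v <- array(runif(5 * 5 * 9, 0.1, 1), c(5, 5, 9))
  obj <- SpectralCube(v, g); ref <- SpectralCube(v, g)
  expect_true(all(cubeValues(reflectanceLocal(obj, ref)) == 1))
  obj2 <- SpectralCube(0.5 * v, g)
  expect_equal(cubeValues(reflectanceLocal(obj2, ref)),
               array(0.5, c(5, 5, 9)))
  # single voxel: 120 / 240 = 0.5
  o <- array(1, c(2, 2, 9)); r <- array(2, c(2, 2, 9))
  o[1, 1, 3] <- 120; r[1, 1, 3] <- 240
  expect_equal(cubeValues(reflectanceLocal(SpectralCube(o, g),
                                           SpectralCube(r, g)))[1, 1, 3], 0.5)
})

test_that("zero reference pixels are flagged invalid, not infinite", {
  g <- SpectralGrid(500)
  o <- array(1, c(3, 3, 1)); r <- array(1, c(3, 3, 1))
  r[2, 2, 1] <- 0
  rc <- reflectanceLocal(SpectralCube(o, g), SpectralCube(r, g))
  expect_true(rc@invalidMask[2, 2])
  expect_true(is.na(cubeValues(rc)[2, 2, 1]))
  expect_false(any(is.infinite(cubeValues(rc))))
})

test_that("simultaneous reflectance sums signals before dividing", {
  g <- SpectralGrid(500)
  mk <- function(x) SpectralCube(array(x, c(2, 2, 1)), g)
  set <- IlluminationSet(list(mk(1), mk(2), mk(3)), list(mk(2), mk(2), mk(2)))
  expect_equal(cubeValues(reflectanceSimultaneous(set)),
               array(1, c(2, 2, 1)))
  expect_equal(recoveryMode(reflectanceSimultaneous(set)), "simultaneous")
})

test_that("simultaneous recovery degenerates to local for identical angle pairs", {
  g <- tinyGrid()
  truth <- makePhantomScene(tinyPhantom(nFruit = 2L, radius = 12), g)
  set <- renderIlluminationSet(truth, noiseSd = 0)
  copy <- IlluminationSet(rep(set@obj[2L], 3L), rep(set@ref[2L], 3L))
  expect_equal(cubeValues(reflectanceSimultaneous(copy)),
               cubeValues(reflectanceLocal(copy)), tolerance = 1e-14)
})

test_that("noiseless specular-free phantom reflectance equals the true volume spectrum", {
  g <- tinyGrid()
  truth <- makePhantomScene(tinyPhantom(nFruit = 2L, radius = 12,
                                        lobeAmplitude = 0), g)
  set <- renderIlluminationSet(truth, noiseSd = 0)
  expect_equal(cubeValues(reflectanceSimultaneous(set)), truth@rvol,
               tolerance = 1e-12)
})

test_that("decomposition of identical cubes attributes nothing to specular", {
  g <- tinyGrid()
  v <- array(rep(runif(9, 0.2, 0.7), each = 16), c(4, 4, 9))
  d <- fitSpecularDecomposition(list(v, v, v))
  expect_true(all(d@residual <= 1e-6))
  spec <- d@eps[, , 1] * apply(d@rsurf, c(1, 2), max)
  expect_true(all(spec <= 1e-3))
})

test_that("decomposition recovers a hand-built single-pixel specular scene", {
  nb <- 16L
  epsTrue <- c(0, 0.5, 0.9)
  rA <- lapply(epsTrue, function(e) array(0.4 + e * 0.05, c(1, 1, nb)))
  d <- fitSpecularDecomposition(rA)
  # reconstruction matches each measured spectrum
  for (i in 1:3) {
    recon <- d@rvol[1, 1, ] + d@eps[1, 1, i] * d@rsurf[1, 1, ]
    expect_lt(max(abs(recon - (0.4 + epsTrue[i] * 0.05))), 1e-6)
  }
  # gauge-invariant products and near-true volume spectrum
  for (i in 1:3)
    expect_lt(max(abs(d@eps[1, 1, i] * d@rsurf[1, 1, ] - epsTrue[i] * 0.05)),
              0.005)
  expect_lt(max(abs(d@rvol[1, 1, ] - 0.4)), 0.02)
})

test_that("fitted decompositions respect the box bounds everywhere", {
  g <- tinyGrid()
  truth <- makePhantomScene(tinyPhantom(nFruit = 3L, radius = 14,
                                        noiseSd = 0.03,
                                        shading = "lambertian"), g)
  set <- renderIlluminationSet(truth)
  d <- fitSpecularDecomposition(reflectancePerAngle(set),
                                mask = truth@labels > 0L)
  fitted <- d@mask
  sel3 <- array(rep(fitted, 3), dim(d@eps))
  selB <- array(rep(fitted, bandCount(g)), dim(d@rvol))
  expect_true(all(d@eps[sel3] >= 0 & d@eps[sel3] <= 1))
  expect_true(all(d@rvol[selB] >= 0 & d@rvol[selB] <= 1))
  expect_true(all(d@rsurf[selB] >= 0 & d@rsurf[selB] <= 0.1))
  expect_true(all(d@residual[fitted] >= 0))
})

test_that("fitting never increases the residual over its initialization", {
  g <- tinyGrid()
  truth <- makePhantomScene(tinyPhantom(nFruit = 2L, radius = 12,
                                        noiseSd = 0.05,
                                        shading = "lambertian"), g)
  set <- renderIlluminationSet(truth)
  rA <- lapply(reflectancePerAngle(set), cubeValues)
  mask <- truth@labels > 0L
  d <- fitSpecularDecomposition(rA, mask = mask)
  # independent computation of the initialization residual
  idx <- which(mask)
  nb <- bandCount(g)
  R <- lapply(rA, function(a) matrix(a, length(a) / nb, nb)[idx, , drop = FALSE])
  rvol0 <- pmin(pmax((R[[1]] + R[[2]] + R[[3]]) / 3, 0), 1)
  obj0 <- 0
  for (i in 1:3) {
    e0 <- pmin(pmax(rowSums((R[[i]] - rvol0) * 0.05) / (nb * 0.05^2), 0), 1)
    obj0 <- obj0 + rowSums((R[[i]] - rvol0 - e0 * 0.05)^2)
  }
  init <- sqrt(obj0 / (3 * nb))
  expect_true(all(d@residual[mask] <= init + 1e-12))
})

test_that("noiseless decomposition recovers volume and specular structure", {
  g <- tinyGrid()
  truth <- makePhantomScene(tinyPhantom(nFruit = 4L, radius = 16), g)
  set <- renderIlluminationSet(truth, noiseSd = 0)
  mask <- truth@labels > 0L
  d <- fitSpecularDecomposition(reflectancePerAngle(set), mask = mask)
  # R_vol within 0.02 per band where at least one angle is specular-free
  free <- apply(truth@eps, c(1, 2), min) == 0 & mask
  err <- abs(d@rvol - truth@rvol)
  expect_lt(max(err[array(rep(free, bandCount(g)), dim(err))], na.rm = TRUE),
            0.02)
  # recovered specular direction aligns with truth where lobes are strong
  strong <- which(apply(truth@eps, c(1, 2), max) >= 0.3 & mask)
  nb <- bandCount(g)
  rs <- matrix(d@rsurf, length(mask), nb)[strong, , drop = FALSE]
  cosSim <- (rs %*% truth@rsurf) /
    (sqrt(rowSums(rs^2)) * sqrt(sum(truth@rsurf^2)))
  expect_true(all(cosSim >= 0.99))
})

test_that("with 5% noise the reconstruction error tracks the noise floor", {
  g <- tinyGrid()
  # flat shading: the decomposition model is exact, so the residual is
  # driven by the detector noise alone
  cfg <- tinyPhantom(nFruit = 3L, radius = 14, noiseSd = 0.05, seed = 9L)
  truth <- makePhantomScene(cfg, g)
  noisy <- renderIlluminationSet(truth)
  clean <- renderIlluminationSet(truth, noiseSd = 0)
  mask <- truth@labels > 0L
  rN <- lapply(reflectancePerAngle(noisy), cubeValues)
  rC <- lapply(reflectancePerAngle(clean), cubeValues)
  idx <- which(mask)
  nb <- bandCount(g)
  perPixel <- function(lst) lapply(lst, function(a)
    matrix(a, length(a) / nb, nb)[idx, , drop = FALSE])
  RN <- perPixel(rN); RC <- perPixel(rC)
  noiseFloor <- sqrt(Reduce(`+`, Map(function(a, b) rowSums((a - b)^2),
                                     RN, RC)) / (3 * nb))
  d <- fitSpecularDecomposition(rN, mask = mask)
  expect_lte(median(d@residual[mask]), 2 * median(noiseFloor))
})

test_that("per-object crops round-trip exactly into the frame", {
  g <- SpectralGrid(750)
  v <- array(0.02, c(40, 80, 1))
  v[5:20, 5:20, 1] <- 0.8    # 256 px
  v[5:25, 40:70, 1] <- 0.7   # 651 px
  rc <- refCube(v, g)
  masks <- buildObjectMasks(rc, 750, minArea = 100, maxArea = 1000)
  expect_equal(length(masks@areas), 2L)
  crops <- extractObjectCubes(rc, masks)
  expect_equal(length(crops), 2L)
  expect_equal(sum(crops[[1]]$mask), masks@areas[1])
  # disjoint footprints
  f1 <- matrix(FALSE, 40, 80); f2 <- f1
  o1 <- crops[[1]]$offset; o2 <- crops[[2]]$offset
  f1[o1["row"] + seq_len(nrow(crops[[1]]$mask)) - 1,
     o1["col"] + seq_len(ncol(crops[[1]]$mask)) - 1] <- crops[[1]]$mask
  f2[o2["row"] + seq_len(nrow(crops[[2]]$mask)) - 1,
     o2["col"] + seq_len(ncol(crops[[2]]$mask)) - 1] <- crops[[2]]$mask
  expect_false(any(f1 & f2))
  # placing values back reproduces the originals on the mask
  for (cr in crops) {
    sub <- v[cr$offset["row"] + seq_len(nrow(cr$mask)) - 1,
             cr$offset["col"] + seq_len(ncol(cr$mask)) - 1, 1]
    expect_equal(cubeValues(cr$cube)[, , 1][cr$mask], sub[cr$mask])
  }
})
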