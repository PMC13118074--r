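# Pixel classifiers and the dataset protocol: fruit-level splitting,
# healthy-class under-sampling, SAM similarity maps, and wrappers around the
# random-forest and RBF-SVM learners.

maskLogical <- function(mask) {
  if (is(mask, "ObjectMask")) mask@labels > 0L else mask
}

#' Assemble a pixel dataset from per-object crops
#'
#' Flattens a list of labeled per-fruit crops (as produced by
#' [extractObjectCubes()] plus a ground-truth label crop) into a spectra
#' matrix with per-pixel class labels and fruit of origin. Background pixels
#' (label 0) are excluded.
#'
#' @param objects list; each element needs `cube` (a cube or H x W x B
#'   array), `labels` (H x W matrix in \{0,1,2\}) and `id` (fruit index).
#'   Pixels are taken where `labels > 0`, intersected with `mask` if present.
#' @return A [PixelDataset].
#' @export
pixelDatasetFromObjects <- function(objects) {
  parts <- lapply(objects, function(o) {
    v <- if (is(o$cube, "SpectralCube")) o$cube@values else o$cube
    sel <- o$labels > 0L
    if (!is.null(o$mask)) sel <- sel & o$mask
    nb <- dim(v)[3L]
    sp <- matrix(v, prod(dim(v)[1:2]), nb)[which(sel), , drop = FALSE]
    list(spectra = sp,
         labels = ifelse(o$labels[sel] == 2L, "defect", "healthy"),
         fruit = rep(o$id, sum(sel)))
  })
  PixelDataset(do.call(rbind, lapply(parts, `[[`, "spectra")),
               unlist(lapply(parts, `[[`, "labels")),
               unlist(lapply(parts, `[[`, "fruit")))
}

#' Fruit-level train/test split
#'
#' Splits whole fruit (never pixels) into training and test partitions at
#' the given fraction. Among `nCandidate` seeded random partitions, the one
#' minimizing the difference in defect-pixel proportion between the two
#' partitions is chosen, mirroring a split balanced on class composition.
#'
#' @param objects list of labeled objects (see [pixelDatasetFromObjects()]).
#' @param trainFraction fraction of fruit in the training partition
#'   (default 0.4).
#' @param seed integer seed.
#' @param nCandidate candidate partitions drawn (default 50).
#' @return list with integer element indices `train` and `test` (into
#'   `objects`) and the achieved defect-proportion `gap`.
#' @export
splitFruitwise <- function(objects, trainFraction = 0.4, seed = 1L,
                           nCandidate = 50L) {
  n <- length(objects)
  if (n < 2L) stop("at least two fruit are required to split")
  if (trainFraction <= 0 || trainFraction >= 1)
    stop("trainFraction must lie in (0, 1)")
  nTrain <- round(trainFraction * n)
  if (nTrain < 1L || nTrain >= n)
    stop("train fraction leaves an empty partition")
  counts <- vapply(objects, function(o) {
    c(defect = sum(o$labels == 2L), total = sum(o$labels > 0L))
  }, numeric(2))
  gapOf <- function(tr) {
    te <- setdiff(seq_len(n), tr)
    pd <- function(ix) {
      tot <- sum(counts["total", ix])
      if (tot == 0) 0 else sum(counts["defect", ix]) / tot
    }
    abs(pd(tr) - pd(te))
  }
  withSeed(seed, {
    best <- NULL; bestGap <- Inf
    for (c in seq_len(nCandidate)) {
      tr <- sort(sample.int(n, nTrain))
      g <- gapOf(tr)
      if (g < bestGap) { bestGap <- g; best <- tr }
    }
    list(train = best, test = setdiff(seq_len(n), best), gap = bestGap)
  })
}

#' Under-sample the healthy class
#'
#' Randomly discards healthy pixels (without replacement, seeded) until the
#' healthy and defect counts are equal. Defect pixels are never touched.
#'
#' @param data a [PixelDataset] containing both classes.
#' @param seed integer seed.
#' @return A balanced [PixelDataset].
#' @export
undersampleHealthy <- function(data, seed = 1L) {
  stopifnot(is(data, "PixelDataset"))
  ih <- which(data@labels == "healthy")
  id <- which(data@labels == "defect")
  if (length(ih) == 0L || length(id) == 0L)
    stop("both classes must be present to balance")
  if (length(ih) <= length(id)) return(data)
  keep <- withSeed(seed, sort(c(sample(ih, length(id)), id)))
  PixelDataset(data@spectra[keep, , drop = FALSE],
               data@labels[keep], data@fruit[keep])
}

#' Class reference spectra from a training set
#'
#' Per-class mean spectrum over the training pixels, with unit-norm copies
#' for cosine computation.
#'
#' @param train a [PixelDataset] containing both classes.
#' @return A [ReferenceSpectra].
#' @export
computeReferenceSpectra <- function(train) {
  stopifnot(is(train, "PixelDataset"))
  hm <- train@labels == "healthy"
  if (!any(hm) || all(hm)) stop("both classes must be present")
  healthy <- colMeans(train@spectra[hm, , drop = FALSE])
  defect <- colMeans(train@spectra[!hm, , drop = FALSE])
  unit <- function(v) v / sqrt(sum(v^2))
  new("ReferenceSpectra", healthy = healthy, defect = defect,
      healthyNorm = unit(healthy), defectNorm = unit(defect))
}

dilate1 <- function(mask) {
  out <- mask
  for (dx in -1:1) for (dy in -1:1)
    if (dx != 0L || dy != 0L)
      out <- out | shiftMatrix(mask, dx, dy, FALSE)
  out
}

#' Spectral-angle similarity maps
#'
#' Cosine similarity between each masked pixel spectrum and the normalized
#' healthy and defect reference spectra (the dot product of unit vectors,
#' i.e. the cosine of the spectral angle). A glare mask is computed and
#' recorded: pixels whose broadband mean reflectance exceeds both the
#' `glareQuantile` of masked pixels and `glareAbs` absolutely, dilated by
#' one pixel. Glare carries only the specular component and is excluded
#' from SAM decisions. Zero-norm pixel spectra are flagged undefined.
#'
#' @param cube a [ReflectanceCube].
#' @param mask logical H x W matrix or an [ObjectMask].
#' @param refs a [ReferenceSpectra].
#' @param glareQuantile,glareAbs glare rule parameters (defaults 0.995, 0.9).
#' @return A [SimilarityMaps].
#' @export
samSimilarityMaps <- function(cube, mask, refs, glareQuantile = 0.995,
                              glareAbs = 0.9) {
  stopifnot(is(cube, "ReflectanceCube"), is(refs, "ReferenceSpectra"))
  m <- maskLogical(mask)
  v <- cube@values
  nb <- dim(v)[3L]
  if (nb != length(refs@healthyNorm)) stop("band count mismatch with references")
  d <- dim(v)[1:2]
  idx <- which(m & !cube@invalidMask)
  sp <- matrix(v, prod(d), nb)[idx, , drop = FALSE]
  norms <- sqrt(rowSums(sp^2))
  ok <- norms > 0
  simH <- simD <- rep(NA_real_, length(idx))
  simH[ok] <- (sp[ok, , drop = FALSE] %*% refs@healthyNorm) / norms[ok]
  simD[ok] <- (sp[ok, , drop = FALSE] %*% refs@defectNorm) / norms[ok]

  broadband <- rowMeans(sp)
  glareV <- broadband > max(stats::quantile(broadband, glareQuantile),
                            glareAbs) & broadband > glareAbs
  healthy <- defect <- matrix(NA_real_, d[1L], d[2L])
  healthy[idx] <- simH; defect[idx] <- simD
  glare <- matrix(FALSE, d[1L], d[2L])
  glare[idx] <- glareV
  glare <- dilate1(glare) & m
  valid <- matrix(FALSE, d[1L], d[2L])
  valid[idx] <- ok
  new("SimilarityMaps", healthy = healthy, defect = defect,
      glare = glare, valid = valid)
}

#' SAM decision map from similarity maps
#'
#' Binarizes the healthy-similarity map: pixels whose cosine to the healthy
#' reference falls below the threshold become defect. Three thresholding
#' rules are available: `"fixed"` (a fixed value, default 0.2, the operating
#' point of the protocol the package models), `"otsu"` (Otsu's method on the
#' masked similarity values of the map at hand), and `"midpoint"` (a fixed
#' threshold calibrated on the training set by [trainSAM()] as the midpoint
#' between the two classes' mean similarities, passed in via `threshold`).
#' Glare pixels are always labeled healthy (a defective surface loses
#' turgor and does not glint), and undefined pixels stay excluded.
#'
#' @param maps a [SimilarityMaps].
#' @param thresholding `"fixed"`, `"otsu"` or `"midpoint"`.
#' @param threshold threshold value (required unless `"otsu"`).
#' @param illumination mode tag for the returned map.
#' @return A [DecisionMap] with method `"sam"`.
#' @export
samClassify <- function(maps, thresholding = c("fixed", "otsu", "midpoint"),
                        threshold = 0.2, illumination = NA_character_) {
  stopifnot(is(maps, "SimilarityMaps"))
  thresholding <- match.arg(thresholding)
  vals <- maps@healthy[maps@valid]
  if (length(vals) == 0L) stop("similarity maps are empty")
  thr <- if (thresholding %in% c("fixed", "midpoint")) {
    if (is.null(threshold) || is.na(threshold))
      stop("fixed thresholding requires a threshold value")
    threshold
  } else otsuThreshold(vals)
  map <- matrix(0L, nrow(maps@healthy), ncol(maps@healthy))
  map[maps@valid] <- ifelse(maps@healthy[maps@valid] < thr, 2L, 1L)
  map[maps@glare & maps@valid] <- 1L
  DecisionMap(map, "sam", illumination)
}

#' Train the spectral angle mapper
#'
#' Establishes the class reference spectra from the training pixels and
#' packages them with the thresholding rule. With
#' `thresholding = "midpoint"` the decision threshold is calibrated on the
#' training pixels as the midpoint between the mean healthy-pixel and mean
#' defect-pixel cosine similarities to the healthy reference.
#'
#' @param train a [PixelDataset].
#' @param thresholding `"fixed"` (default), `"otsu"` or `"midpoint"`.
#' @param threshold fixed cosine threshold (default 0.2; ignored for the
#'   other rules).
#' @param seed recorded training seed (SAM itself is deterministic).
#' @return A [SAMModel].
#' @export
trainSAM <- function(train, thresholding = "fixed", threshold = 0.2, seed = 1L) {
  refs <- computeReferenceSpectra(train)
  if (thresholding == "midpoint") {
    norms <- sqrt(rowSums(train@spectra^2))
    sims <- as.vector(train@spectra %*% refs@healthyNorm) / pmax(norms, 1e-300)
    threshold <- (mean(sims[train@labels == "healthy"]) +
                    mean(sims[train@labels == "defect"])) / 2
  }
  tab <- table(train@labels)
  new("SAMModel", method = "sam", seed = as.integer(seed),
      metadata = list(nHealthy = tab[["healthy"]], nDefect = tab[["defect"]],
                      thresholding = thresholding, threshold = threshold),
      refs = refs, thresholding = thresholding, threshold = threshold)
}

#' Train the random-forest pixel classifier
#'
#' Bagged ensemble of 100 decision trees (majority vote) on the training
#' spectra, default classification settings (Gini splits, sqrt(B) candidate
#' bands per split, unlimited depth), with the out-of-bag error estimate
#' recorded in the model metadata.
#'
#' @param train a [PixelDataset] with both classes.
#' @param nTrees ensemble size (default 100).
#' @param seed integer seed for bagging.
#' @return An [RFModel]; `metadata$oobError` holds the OOB error.
#' @export
trainRF <- function(train, nTrees = 100L, seed = 1L) {
  stopifnot(is(train, "PixelDataset"))
  if (nlevels(droplevels(train@labels)) < 2L)
    stop("training set must contain both classes")
  fit <- withSeed(seed, randomForest::randomForest(
    x = train@spectra, y = train@labels, ntree = as.integer(nTrees),
    mtry = max(1L, floor(sqrt(ncol(train@spectra))))))
  tab <- table(train@labels)
  new("RFModel", method = "rf", seed = as.integer(seed),
      metadata = list(nHealthy = tab[["healthy"]], nDefect = tab[["defect"]],
                      nTrees = as.integer(nTrees),
                      oobError = unname(fit$err.rate[nTrees, "OOB"])),
      fit = fit)
}

#' Train the RBF-kernel SVM pixel classifier
#'
#' Maximum-margin classifier with a radial-basis kernel. The kernel scale is
#' chosen automatically as the median pairwise Euclidean distance on a
#' seeded subsample of up to 1,000 training spectra (gamma = 1 / (2 s^2)).
#' For tractability the training set is capped at `subsampleCap` pixels by
#' seeded stratified subsampling; the cap, scale and iteration limit are
#' recorded in the metadata.
#'
#' @param train a [PixelDataset] with both classes.
#' @param maxIter iteration limit recorded in the training protocol
#'   (default 10,000).
#' @param seed integer seed.
#' @param subsampleCap training-pixel cap (default 20,000).
#' @return An [SVMModel].
#' @export
trainSVM <- function(train, maxIter = 10000L, seed = 1L, subsampleCap = 20000L) {
  stopifnot(is(train, "PixelDataset"))
  if (nlevels(droplevels(train@labels)) < 2L)
    stop("training set must contain both classes")
  n <- nrow(train@spectra)
  withSeed(seed, {
    idx <- seq_len(n)
    if (n > subsampleCap) {
      frac <- subsampleCap / n
      idx <- sort(unlist(lapply(split(idx, train@labels), function(ix)
        sample(ix, max(1L, round(frac * length(ix)))))))
    }
    x <- train@spectra[idx, , drop = FALSE]
    y <- droplevels(train@labels[idx])
    sub <- if (nrow(x) > 1000L) x[sample.int(nrow(x), 1000L), , drop = FALSE] else x
    dm <- stats::dist(sub)
    s <- stats::median(dm[dm > 0])
    if (!is.finite(s) || s <= 0) s <- 1
    fit <- e1071::svm(x = x, y = y, kernel = "radial",
                      gamma = 1 / (2 * s^2), cost = 1, scale = FALSE)
    tab <- table(y)
    new("SVMModel", method = "svm", seed = as.integer(seed),
        metadata = list(nHealthy = tab[["healthy"]], nDefect = tab[["defect"]],
                        kernelScale = s, gamma = 1 / (2 * s^2),
                        maxIter = as.integer(maxIter),
                        subsampleCap = as.integer(subsampleCap),
                        nUsed = nrow(x)),
        fit = fit)
  })
}

#' @rdname predictLabels
#' @param threshold optional override of the model's SAM threshold.
setMethod("predictLabels", "SAMModel", function(model, spectra, threshold = NULL) {
  norms <- sqrt(rowSums(spectra^2))
  sim <- rep(NA_real_, nrow(spectra))
  ok <- norms > 0
  sim[ok] <- (spectra[ok, , drop = FALSE] %*% model@refs@healthyNorm) / norms[ok]
  thr <- if (!is.null(threshold)) threshold
  else if (model@thresholding == "otsu") otsuThreshold(sim[ok])
  else model@threshold
  factor(ifelse(!is.na(sim) & sim < thr, "defect", "healthy"),
         levels = c("healthy", "defect"))
})

#' @rdname predictLabels
setMethod("predictLabels", "RFModel", function(model, spectra, ...) {
  factor(as.character(stats::predict(model@fit, spectra)),
         levels = c("healthy", "defect"))
})

#' @rdname predictLabels
setMethod("predictLabels", "SVMModel", function(model, spectra, ...) {
  factor(as.character(stats::predict(model@fit, spectra)),
         levels = c("healthy", "defect"))
})

#' Predict a decision map over an object mask
#'
#' Applies a trained classifier to every masked pixel of a reflectance cube
#' and returns the per-pixel decision map (background stays 0). For the
#' spectral angle mapper this routes through the similarity maps so the
#' glare exclusion applies; the other classifiers predict directly from the
#' pixel spectra.
#'
#' @param model a trained [ClassifierModel].
#' @param cube a [ReflectanceCube].
#' @param mask logical H x W matrix or an [ObjectMask].
#' @param illumination mode tag recorded on the map (default: the cube's).
#' @return A [DecisionMap].
#' @export
predictMap <- function(model, cube, mask, illumination = recoveryMode(cube)) {
  stopifnot(is(model, "ClassifierModel"), is(cube, "ReflectanceCube"))
  m <- maskLogical(mask)
  if (is(model, "SAMModel")) {
    if (bandCount(cube) != length(model@refs@healthyNorm))
      stop("band count mismatch between model and cube")
    if (!any(m)) return(DecisionMap(matrix(0L, nrow(m), ncol(m)), "sam", illumination))
    maps <- samSimilarityMaps(cube, m, model@refs)
    return(samClassify(maps, model@thresholding, model@threshold, illumination))
  }
  nb <- bandCount(cube)
  modelBands <- model@metadata$nBands
  if (!is.null(modelBands) && modelBands != nb)
    stop("band count mismatch between model and cube")
  map <- matrix(0L, nrow(m), ncol(m))
  idx <- which(m & !cube@invalidMask)
  if (length(idx) > 0L) {
    sp <- matrix(cube@values, prod(dim(m)), nb)[idx, , drop = FALSE]
    lab <- predictLabels(model, sp)
    map[idx] <- ifelse(lab == "defect", 2L, 1L)
  }
  DecisionMap(map, model@method, illumination)
}
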