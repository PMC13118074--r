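# Shared fixture builders. Everything is generated in code under fixed
# seeds; no files are read.

# coarse 9-band grid for tests where the band count is irrelevant
tinyGrid <- function() SpectralGrid(seq(450, 850, by = 50))

# small phantom under controlled conditions
tinyPhantom <- function(nFruit = 4L, radius = 15, seed = 7L, noiseSd = 0,
                        shading = "flat", lobeAmplitude = 0.8,
                        strayFraction = 0, ...) {
  PhantomConfig(nFruit = nFruit, fruitRadius = radius, seed = seed,
                noiseSd = noiseSd, shadingModel = shading,
                lobeAmplitude = lobeAmplitude, strayFraction = strayFraction,
                ...)
}

# scaled fruit-area window for a given radius (native window is tied to
# radius ~95 px)
areaWindow <- function(radius) c(20000, 40000) * (radius / 95)^2

# a reflectance cube holding a given array on a given grid
refCube <- function(values, grid, mode = "local") {
  hsifruit:::ReflectanceCube(values, grid, mode)
}

# synthetic per-fruit "objects" carrying only label maps (for split tests)
labelOnlyObjects <- function(defectCounts, totalPx = 400L) {
  lapply(seq_along(defectCounts), function(i) {
    side <- ceiling(sqrt(totalPx))
    lab <- matrix(1L, side, side)
    nd <- defectCounts[i]
    if (nd > 0L) lab[seq_len(nd)] <- 2L
    list(labels = lab, id = i)
  })
}

# separable two-class pixel dataset (constant-level spectra + slight noise)
separableDataset <- function(n = 200L, bands = 81L, seed = 1L, sd = 0.01) {
  withr::with_seed(seed, {
    X <- rbind(matrix(0.8, n, bands), matrix(0.25, n, bands)) +
      matrix(stats::rnorm(2 * n * bands, sd = sd), 2 * n, bands)
    hsifruit:::PixelDataset(X, rep(c("healthy", "defect"), each = n),
                            rep(c(1L, 2L), each = n))
  })
}

# brute-force Otsu oracle: exhaustive search over the 256-bin histogram
otsuBruteForce <- function(values, nbins = 256L) {
  v <- values[is.finite(values)]
  lo <- min(v); hi <- max(v)
  edges <- seq(lo, hi, length.out = nbins + 1L)
  bin <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L), nbins)
  cnt <- tabulate(bin, nbins)
  mids <- (edges[-1L] + edges[-(nbins + 1L)]) / 2
  best <- -Inf; bestK <- NA_integer_
  for (k in seq_len(nbins - 1L)) {
    n0 <- sum(cnt[1:k]); n1 <- sum(cnt) - n0
    if (n0 == 0 || n1 == 0) next
    mu0 <- sum(cnt[1:k] * mids[1:k]) / n0
    mu1 <- sum(cnt[(k + 1L):nbins] * mids[(k + 1L):nbins]) / n1
    bcv <- n0 * n1 * (mu0 - mu1)^2
    if (bcv > best) { best <- bcv; bestK <- k }
  }
  edges[bestK + 1L]
}
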