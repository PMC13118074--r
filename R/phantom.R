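#' Canonical tissue and illuminant spectra of the phantom
#'
#' Parametric smooth curves standing in for measured spectra: healthy tissue
#' rises logistically toward the red/NIR with a small green bump (ripe-fruit
#' shape); defective tissue is a darkened, spectrally flattened version of it;
#' the specular spectrum is low-amplitude and slowly varying within
#' `[0, 0.1]`; the lamp is a 3000 K Planck curve normalized to unit maximum
#' (halogen-like).
#'
#' @param grid a [SpectralGrid].
#' @return numeric vector, one value per band.
#' @name phantomSpectra
NULL

#' @rdname phantomSpectra
#' @export
healthySpectrum <- function(grid = SpectralGrid()) {
  w <- wavelengths(grid)
  0.12 + 0.55 / (1 + exp(-(w - 640) / 25)) + 0.06 * exp(-(w - 550)^2 / (2 * 30^2))
}

#' @rdname phantomSpectra
#' @param contrast (scale, offset) pair; see [PhantomConfig-class].
#' @export
defectSpectrum <- function(grid = SpectralGrid(), contrast = c(0.45, 0.12)) {
  # darkened and spectrally flattened relative to healthy tissue, with a
  # long-NIR absorption dip (collapse of scattering cell structure in
  # damaged tissue). The dip is a negative spectral feature: unlike a flat
  # brightness change it cannot be mimicked by shading, stray light or the
  # nonnegative specular term. Tissue stays far brighter than background at
  # 750 nm so object masking keeps defect regions inside the fruit.
  w <- wavelengths(grid)
  depth <- if (length(contrast) >= 3L) contrast[3L] else 0.3
  dip <- 1 - depth * exp(-(w - 820)^2 / (2 * 40^2))
  (contrast[1L] * healthySpectrum(grid) + contrast[2L]) * dip
}

#' @rdname phantomSpectra
#' @export
specularSpectrum <- function(grid = SpectralGrid()) {
  # near the 0.1 reflectance cap: surface glint on glossy fruit skin is a
  # strong, spectrally flat white feature (it saturates real detectors)
  w <- wavelengths(grid)
  0.06 + 0.04 * (w - min(w)) / max(max(w) - min(w), 1)
}

#' @rdname phantomSpectra
#' @export
halogenSpectrum <- function(grid = SpectralGrid()) {
  w <- wavelengths(grid)
  b <- w^-5 / (exp(1.4388e7 / (w * 3000)) - 1)  # Planck, T = 3000 K
  b / max(b)
}

# Frame layout for n fruit of radius r: near-square grid of cells.
phantomLayout <- function(nFruit, radius) {
  ncol <- ceiling(sqrt(nFruit))
  nrow <- ceiling(nFruit / ncol)
  cell <- ceiling(2.4 * radius)
  centers <- cbind(
    x = (((seq_len(nFruit) - 1L) %% nrow) + 0.5) * cell,
    y = (((seq_len(nFruit) - 1L) %/% nrow) + 0.5) * cell)
  list(h = nrow * cell, w = ncol * cell, centers = centers)
}

#' Generate a synthetic multi-angle hyperspectral scene
#'
#' Builds a frame of sphere-like fruit disks with known per-pixel ground
#' truth: class labels (background / healthy / defect), the true volume
#' reflectance cube, the true specular spectrum, per-lamp localized specular
#' lobes (amplitude maps), and per-lamp Lambertian shading from a
#' hemispherical height profile illuminated at 45 degree zenith. Healthy and
#' defective tissue carry smooth within-class variation; defect blobs always
#' lie inside their fruit. All randomness is fixed by `config@seed`.
#'
#' Specular lobes are 2-D Gaussian bumps, one per lamp, offset from the fruit
#' center along the lamp azimuth and truncated to zero below a small cutoff,
#' so lobes of different lamps barely overlap: at most fruit pixels at least
#' one lamp sees no specular contribution, which is what makes the volume
#' spectrum identifiable from multi-angle data.
#'
#' @param config a [PhantomConfig].
#' @param grid a [SpectralGrid] (default 450--850 nm at 5 nm).
#' @return A [PhantomTruth].
#' @examples
#' truth <- makePhantomScene(PhantomConfig(nFruit = 2L, fruitRadius = 15, seed = 7L))
#' table(truth@labels)
#' @export
makePhantomScene <- function(config, grid = SpectralGrid()) {
  stopifnot(is(config, "PhantomConfig"))
  validObject(config)
  lay <- phantomLayout(config@nFruit, config@fruitRadius)
  h <- lay$h; w <- lay$w
  nb <- bandCount(grid)
  nl <- config@nLamps
  r <- config@fruitRadius

  labels <- matrix(0L, h, w)
  fruitIndex <- matrix(0L, h, w)
  eps <- array(0, c(h, w, nl))
  shading <- array(1, c(h, w, nl))

  xs <- matrix(seq_len(h), h, w)
  ys <- matrix(seq_len(w), h, w, byrow = TRUE)
  azimuth <- (seq_len(nl) - 1L) * 2 * pi / nl + pi / 2
  zen <- pi / 4  # lamp zenith 45 degrees
  lampDir <- cbind(sin(zen) * cos(azimuth), sin(zen) * sin(azimuth), cos(zen))

  withSeed(config@seed, {
    nDef <- round(config@defectFraction * config@nFruit)
    defective <- sort(sample.int(config@nFruit, nDef))

    for (k in seq_len(config@nFruit)) {
      cx <- lay$centers[k, 1L]; cy <- lay$centers[k, 2L]
      dx <- xs - cx; dy <- ys - cy
      d2 <- dx^2 + dy^2
      inside <- d2 <= r^2
      labels[inside] <- 1L
      fruitIndex[inside] <- k

      # Lambertian shading from the hemispherical cap, per lamp
      if (config@shadingModel == "lambertian") {
        z <- sqrt(pmax(r^2 - d2, 0))
        for (i in seq_len(nl)) {
          cosInc <- (dx * lampDir[i, 1L] + dy * lampDir[i, 2L] + z * lampDir[i, 3L]) / r
          # direct Lambertian term plus an ambient fill (interreflection /
          # stray light); keeps shaded rims visible, as in real scenes
          s <- 0.25 + 0.75 * pmax(cosInc, 0)
          shading[, , i][inside] <- s[inside]
        }
      }

      # one localized specular lobe per lamp, offset along the lamp azimuth
      sig <- config@lobeSigmaFrac * r
      off <- config@lobeOffsetFrac * r
      for (i in seq_len(nl)) {
        lx <- cx + off * cos(azimuth[i]); ly <- cy + off * sin(azimuth[i])
        lobe <- config@lobeAmplitude * exp(-((xs - lx)^2 + (ys - ly)^2) / (2 * sig^2))
        lobe[lobe < 0.02 | !inside] <- 0
        eps[, , i] <- pmax(eps[, , i], pmin(lobe, 1))
      }

      # defect blobs inside defective fruit
      if (k %in% defective && config@defectCount > 0L) {
        for (j in seq_len(config@defectCount)) {
          rr <- stats::runif(1, config@defectRadiusRange[1L], config@defectRadiusRange[2L])
          ang <- stats::runif(1, 0, 2 * pi)
          rad <- stats::runif(1, 0, max(0.65 * r - rr, 0))
          px <- cx + rad * cos(ang); py <- cy + rad * sin(ang)
          blob <- ((xs - px)^2 + (ys - py)^2 <= rr^2) & inside
          labels[blob] <- 2L
        }
      }
    }

    healthy <- healthySpectrum(grid)
    defect <- defectSpectrum(grid, config@defectContrast)
    variation <- smoothField(h, w, amplitude = 0.04)

    base <- matrix(config@backgroundReflectance, h, w)
    rvol <- array(0, c(h, w, nb))
    for (b in seq_len(nb)) {
      plane <- base
      plane[labels == 1L] <- healthy[b] * variation[labels == 1L]
      plane[labels == 2L] <- defect[b] * variation[labels == 2L]
      rvol[, , b] <- pmin(pmax(plane, 0), 1)
    }

    new("PhantomTruth", labels = labels, fruitIndex = fruitIndex,
        rvol = rvol, rsurf = specularSpectrum(grid),
        eps = eps, shading = shading, grid = grid, config = config)
  })
}

#' Render a multi-angle acquisition from phantom ground truth
#'
#' Forward model of the acquisition: for each illumination angle i, the
#' reference cube is the lamp spectrum over a unit-reflectance plate filling
#' the frame, and the object cube is
#' `I_ref,i * (s_i * R_vol + eps_i * R_surf + stray)` with multiplicative
#' Gaussian detector noise of standard deviation `noiseSd` (fraction of
#' signal), clipped at zero. `stray` is the configured additive stray-light/
#' dark floor (a fraction of the reference signal): after flat-field
#' division it contaminates dark, strongly shaded pixels the most, as on a
#' real detector. Background pixels render at the configured low reflectance
#' through `R_vol`.
#'
#' @param truth a [PhantomTruth].
#' @param grid a [SpectralGrid]; must match the truth.
#' @param lampSpectrum per-band positive lamp weights (default halogen-like).
#' @param noiseSd multiplicative noise sd; default taken from the truth's config.
#' @param strayFraction additive stray-light floor as a fraction of the
#'   reference signal; default taken from the truth's config.
#' @param seed noise seed; default derived from the truth's config seed.
#' @return An [IlluminationSet].
#' @export
renderIlluminationSet <- function(truth, grid = truth@grid,
                                  lampSpectrum = halogenSpectrum(grid),
                                  noiseSd = truth@config@noiseSd,
                                  strayFraction = truth@config@strayFraction,
                                  seed = deriveSeed(truth@config@seed, "render")) {
  stopifnot(is(truth, "PhantomTruth"))
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  if (length(lampSpectrum) != bandCount(grid) || any(lampSpectrum <= 0))
    stop("lampSpectrum must be positive with one weight per band")
  d <- dim(truth@rvol)
  h <- d[1L]; w <- d[2L]; nb <- d[3L]
  nl <- dim(truth@eps)[3L]

  refPlane <- array(rep(lampSpectrum, each = h * w), c(h, w, nb))
  withSeed(seed, {
    obj <- vector("list", nl)
    ref <- vector("list", nl)
    for (i in seq_len(nl)) {
      refl <- truth@rvol * as.vector(truth@shading[, , i]) +
        outer(truth@eps[, , i], truth@rsurf) + strayFraction
      signal <- refPlane * refl
      if (noiseSd > 0)
        signal <- pmax(signal * (1 + stats::rnorm(length(signal), sd = noiseSd)), 0)
      obj[[i]] <- SpectralCube(signal, grid)
      ref[[i]] <- SpectralCube(refPlane, grid)
    }
    IlluminationSet(obj, ref)
  })
}
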