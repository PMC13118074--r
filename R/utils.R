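# Internal helpers shared across modules.

# Evaluate code under a fixed RNG seed without disturbing the caller's RNG
# stream. All stochastic stages of the package funnel through this.
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Derive a stage seed from a master seed and a stage label, so that every
# stochastic step (split, under-sampling, bagging, SVM subsample, NN init)
# consumes its own reproducible stream. Kept below 2^31 - 1.
deriveSeed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 7919 + 12345) %% 2147483647)
}

# Nearest band index for a wavelength in nm; errors if off-grid by > half a step.
bandIndex <- function(grid, nm) {
  w <- grid@wavelengths
  i <- which.min(abs(w - nm))
  step <- if (length(w) > 1L) min(diff(w)) else Inf
  if (abs(w[i] - nm) > step / 2 + 1e-9)
    stop(sprintf("wavelength %g nm is not on the spectral grid", nm))
  i
}

# Smooth unit-mean random field on an H x W frame: bilinear interpolation of
# a coarse white-noise grid. Used for within-class reflectance variation.
smoothField <- function(h, w, amplitude, cell = 16L) {
  gh <- max(2L, ceiling(h / cell) + 1L)
  gw <- max(2L, ceiling(w / cell) + 1L)
  g <- matrix(stats::rnorm(gh * gw), gh, gw)
  xi <- (seq_len(h) - 1) / (h - 1 + 1e-9) * (gh - 1) + 1
  yi <- (seq_len(w) - 1) / (w - 1 + 1e-9) * (gw - 1) + 1
  x0 <- pmin(floor(xi), gh - 1L); fx <- xi - x0
  y0 <- pmin(floor(yi), gw - 1L); fy <- yi - y0
  a <- g[cbind(rep(x0, w), rep(y0, each = h))]
  b <- g[cbind(rep(x0 + 1L, w), rep(y0, each = h))]
  cc <- g[cbind(rep(x0, w), rep(y0 + 1L, each = h))]
  d <- g[cbind(rep(x0 + 1L, w), rep(y0 + 1L, each = h))]
  fxm <- rep(fx, w); fym <- rep(fy, each = h)
  v <- a * (1 - fxm) * (1 - fym) + b * fxm * (1 - fym) +
    cc * (1 - fxm) * fym + d * fxm * fym
  matrix(1 + amplitude * v, h, w)
}
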