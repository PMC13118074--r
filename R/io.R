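# File interfaces: ENVI-style band-sequential cubes (exact, float64),
# multi-page TIFF export, label-map PNGs, and truth bundles with a YAML
# manifest.

#' Write a cube as an ENVI-style band-sequential file
#'
#' Writes `<path>.hdr` (text header with dimensions, wavelengths, data
#' type) and `<path>.bsq` (band-sequential little-endian float64 binary).
#' The round trip through [readENVI()] is exact.
#'
#' @param cube a [SpectralCube] or [ReflectanceCube].
#' @param path file path without extension.
#' @return `path`, invisibly.
#' @export
writeENVI <- function(cube, path) {
  stopifnot(is(cube, "SpectralCube"))
  v <- cube@values
  d <- dim(v)
  hdr <- c("ENVI",
           "description = {hsifruit spectral cube}",
           sprintf("samples = %d", d[2L]),
           sprintf("lines = %d", d[1L]),
           sprintf("bands = %d", d[3L]),
           "header offset = 0",
           "file type = ENVI Standard",
           "data type = 5",
           "interleave = bsq",
           "byte order = 0",
           "wavelength units = nm",
           sprintf("wavelength = {%s}",
                   paste(wavelengths(cube), collapse = ", ")))
  writeLines(hdr, paste0(path, ".hdr"))
  con <- file(paste0(path, ".bsq"), "wb")
  on.exit(close(con))
  # BSQ: band-major, line-major within band, sample fastest
  for (b in seq_len(d[3L]))
    writeBin(as.vector(t(v[, , b])), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read an ENVI-style band-sequential cube
#'
#' @param path file path without extension (expects `<path>.hdr` and
#'   `<path>.bsq`).
#' @return A [SpectralCube].
#' @export
readENVI <- function(path) {
  hdr <- readLines(paste0(path, ".hdr"))
  getNum <- function(key) {
    ln <- grep(sprintf("^%s *=", key), hdr, value = TRUE)[1L]
    as.numeric(sub(".*= *", "", ln))
  }
  samples <- getNum("samples"); lines <- getNum("lines"); bands <- getNum("bands")
  wl <- grep("^wavelength *=", hdr, value = TRUE)
  w <- if (length(wl) > 0) {
    as.numeric(strsplit(gsub(".*\\{|\\}", "", wl[1L]), ",")[[1L]])
  } else seq_len(bands)
  con <- file(paste0(path, ".bsq"), "rb")
  on.exit(close(con))
  raw <- readBin(con, numeric(), n = samples * lines * bands, size = 8L,
                 endian = "little")
  v <- array(0, c(lines, samples, bands))
  per <- samples * lines
  for (b in seq_len(bands))
    v[, , b] <- t(matrix(raw[((b - 1L) * per + 1L):(b * per)], samples, lines))
  SpectralCube(v, SpectralGrid(w))
}

#' Write a cube as a multi-page TIFF
#'
#' One 32-bit page per band. TIFF storage is defined for values in
#' `[0, 1]`; values above 1 are divided by the returned scale factor
#' before writing (record it alongside the file to invert on read).
#'
#' @param cube a [SpectralCube].
#' @param path output `.tif` path.
#' @return the scale factor applied, invisibly.
#' @export
writeCubeTIFF <- function(cube, path) {
  stopifnot(is(cube, "SpectralCube"))
  v <- cube@values
  scale <- max(1, max(v, na.rm = TRUE))
  pages <- lapply(seq_len(dim(v)[3L]), function(b) pmax(v[, , b], 0) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(scale)
}

#' Read a multi-page TIFF cube
#'
#' @param path `.tif` path written by [writeCubeTIFF()].
#' @param grid the [SpectralGrid] of the cube.
#' @param scale scale factor returned by the writer (default 1).
#' @return A [SpectralCube].
#' @export
readCubeTIFF <- function(path, grid = NULL, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  v <- array(0, c(dim(pages[[1L]])[1:2], length(pages)))
  for (b in seq_along(pages)) v[, , b] <- pages[[b]] * scale
  if (is.null(grid)) grid <- SpectralGrid(seq_len(length(pages)))
  SpectralCube(v, grid)
}

#' Write a label or decision map as an 8-bit PNG
#'
#' Values \{0, 1, 2\} (background, healthy, defect) stored as gray levels
#' 0/1/2 of 255; [readLabelMapPNG()] inverts exactly.
#'
#' @param labels integer H x W matrix in \{0,1,2\}, or a [DecisionMap].
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
writeLabelMapPNG <- function(labels, path) {
  m <- if (is(labels, "DecisionMap")) labels@map else labels
  stopifnot(all(m %in% 0:2))
  png::writePNG(m / 255, path)
  invisible(path)
}

#' @rdname writeLabelMapPNG
#' @export
readLabelMapPNG <- function(path) {
  m <- png::readPNG(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  matrix(as.integer(round(m * 255)), nrow(m), ncol(m))
}

#' Write a phantom truth bundle
#'
#' Directory with the label map (PNG), the true volume-reflectance cube
#' (ENVI), the per-angle specular amplitude and shading maps (multi-page
#' TIFF), and a YAML manifest recording the configuration, spectra and
#' class counts.
#'
#' @param truth a [PhantomTruth].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeTruthBundle <- function(truth, dir) {
  stopifnot(is(truth, "PhantomTruth"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeLabelMapPNG(truth@labels, file.path(dir, "labels.png"))
  writeENVI(SpectralCube(truth@rvol, truth@grid), file.path(dir, "rvol_true"))
  epsScale <- writeCubeTIFF(SpectralCube(truth@eps, SpectralGrid(seq_len(dim(truth@eps)[3L]))),
                            file.path(dir, "eps_true.tif"))
  shScale <- writeCubeTIFF(SpectralCube(truth@shading, SpectralGrid(seq_len(dim(truth@shading)[3L]))),
                           file.path(dir, "shading.tif"))
  cfg <- truth@config
  manifest <- list(
    kind = "phantom-truth",
    frame = dim(truth@labels),
    bands = bandCount(truth@grid),
    wavelengths_nm = range(wavelengths(truth@grid)),
    config = list(nFruit = cfg@nFruit, fruitRadius = cfg@fruitRadius,
                  defectFraction = cfg@defectFraction,
                  defectCount = cfg@defectCount,
                  defectRadiusRange = cfg@defectRadiusRange,
                  nLamps = cfg@nLamps, noiseSd = cfg@noiseSd,
                  shadingModel = cfg@shadingModel,
                  seed = cfg@seed),
    classCounts = list(background = sum(truth@labels == 0L),
                       healthy = sum(truth@labels == 1L),
                       defect = sum(truth@labels == 2L)),
    rsurf = as.numeric(truth@rsurf),
    files = list(labels = "labels.png", rvol = "rvol_true.bsq",
                 eps = "eps_true.tif", shading = "shading.tif"),
    tiffScales = list(eps = epsScale, shading = shScale))
  yaml::write_yaml(manifest, file.path(dir, "manifest.yml"))
  invisible(dir)
}

#' Reference metric table of the modeled comparative study
#'
#' The published per-method, per-illumination-mode metric table of the
#' tomato defect-segmentation benchmark the package's protocol models
#' (accuracy, error rate, F1, IoU, precision, recall, specificity for SAM,
#' RF, SVM and NN under local, simultaneous and sequential illumination).
#' Used to verify the algebraic identities between the printed metrics.
#'
#' @return data.frame with columns `method`, `mode`, and the seven metrics.
#' @export
referenceMetricTable <- function() {
  utils::read.csv(system.file("extdata", "reference_metrics.csv",
                              package = "hsifruit"),
                  stringsAsFactors = FALSE)
}
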