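#' @import methods
NULL

#' Spectral band grid
#'
#' Ordered band centers (nm) shared by all cubes in an acquisition. The
#' default grid spans 450--850 nm at 5 nm steps (81 bands), the visible/NIR
#' range of the imaging protocol the package models.
#'
#' @slot wavelengths strictly increasing numeric vector of band centers in nm.
#' @export
setClass("SpectralGrid", representation(wavelengths = "numeric"))

setValidity("SpectralGrid", function(object) {
  w <- object@wavelengths
  if (length(w) < 1L) return("grid must contain at least one band")
  if (any(!is.finite(w))) return("wavelengths must be finite")
  if (is.unsorted(w, strictly = TRUE)) return("wavelengths must be strictly increasing")
  TRUE
})

#' @param wavelengths numeric vector of band centers in nm.
#' @return A `SpectralGrid`.
#' @rdname SpectralGrid-class
#' @export
SpectralGrid <- function(wavelengths = seq(450, 850, by = 5)) {
  new("SpectralGrid", wavelengths = as.numeric(wavelengths))
}

#' Raw hyperspectral cube
#'
#' A digital-number image stack I(x, y, lambda): an H x W x B array of
#' non-negative detector values on a [SpectralGrid].
#'
#' @slot values numeric H x W x B array.
#' @slot grid the [SpectralGrid] of band centers.
#' @export
setClass("SpectralCube", representation(values = "array", grid = "SpectralGrid"))

setValidity("SpectralCube", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L) return("values must be a 3-D array (H x W x bands)")
  if (d[3L] != length(object@grid@wavelengths))
    return("third array dimension must equal the number of grid bands")
  TRUE
})

#' @param values H x W x B numeric array.
#' @param grid a [SpectralGrid]; bands must match `dim(values)[3]`.
#' @return A `SpectralCube`.
#' @rdname SpectralCube-class
#' @export
SpectralCube <- function(values, grid = SpectralGrid()) {
  new("SpectralCube", values = values, grid = grid)
}

#' Reflectance cube
#'
#' Unitless reflectance R(x, y, lambda) recovered by one of the three routes:
#' `"local"` (single-angle flat field), `"simultaneous"` (angle-summed flat
#' field), or `"sequential"` (diffuse/volume component of the multi-angle
#' decomposition). Pixels where the reference signal was non-positive are
#' flagged invalid rather than carrying infinities.
#'
#' @slot recoveryMode one of `"local"`, `"simultaneous"`, `"sequential"`.
#' @slot invalidMask logical H x W matrix, `TRUE` where reflectance is undefined.
#' @export
setClass("ReflectanceCube", contains = "SpectralCube",
         representation(recoveryMode = "character", invalidMask = "matrix"))

setValidity("ReflectanceCube", function(object) {
  if (length(object@recoveryMode) != 1L ||
      !object@recoveryMode %in% c("local", "simultaneous", "sequential"))
    return("recoveryMode must be one of 'local', 'simultaneous', 'sequential'")
  d <- dim(object@values)
  if (!identical(dim(object@invalidMask), d[1:2]))
    return("invalidMask must match the spatial frame")
  TRUE
})

ReflectanceCube <- function(values, grid, recoveryMode,
                            invalidMask = matrix(FALSE, dim(values)[1L], dim(values)[2L])) {
  new("ReflectanceCube", values = values, grid = grid,
      recoveryMode = recoveryMode, invalidMask = invalidMask)
}

#' Multi-angle acquisition set
#'
#' Object and reference-plate cubes for each of the three illumination angles,
#' all sharing one frame and one spectral grid.
#'
#' @slot obj list of three object [SpectralCube]s (one per illumination angle).
#' @slot ref list of three reference-plate [SpectralCube]s.
#' @export
setClass("IlluminationSet", representation(obj = "list", ref = "list"))

setValidity("IlluminationSet", function(object) {
  if (length(object@obj) != 3L || length(object@ref) != 3L)
    return("obj and ref must each hold three cubes (one per illumination angle)")
  dims <- lapply(c(object@obj, object@ref), function(c) dim(c@values))
  if (length(unique(dims)) != 1L) return("all cubes must share dimensions")
  TRUE
})

IlluminationSet <- function(obj, ref) new("IlluminationSet", obj = obj, ref = ref)

#' Phantom scene configuration
#'
#' Parameters of the synthetic multi-angle hyperspectral scene generator.
#' Defaults mirror the study design the package models: 24 sphere-like fruit
#' (half defective), three lamps at 45 degree zenith, an 81-band 450--850 nm
#' grid, and signal-proportional detector noise. The spatial scale is set by
#' `fruitRadius`; at full acquisition scale one object occupies roughly 250 x 250 px
#' (radius near 95 px), and smaller radii render the same scene geometry at
#' proportionally reduced resolution.
#'
#' @slot nFruit number of fruit in the frame.
#' @slot fruitRadius fruit disk radius in px.
#' @slot defectFraction fraction of fruit carrying a defect.
#' @slot defectCount number of defect blobs per defective fruit.
#' @slot defectRadiusRange min/max defect blob radius in px.
#' @slot defectContrast (scale, offset) pair, optionally with a third
#'   element, the NIR absorption-dip depth (default 0.3): defect tissue
#'   reflectance is `(scale * healthy + offset)` times a long-NIR dip.
#'   The default (0.45, 0.12, 0.3) is a pronounced lesion; values nearer
#'   (1, 0, 0.15) emulate subtle early-stage damage.
#' @slot nLamps number of illumination angles (3).
#' @slot lobeAmplitude peak specular amplitude per lamp lobe.
#' @slot lobeSigmaFrac lobe Gaussian sigma as a fraction of fruit radius.
#' @slot lobeOffsetFrac lobe center offset from fruit center, fraction of radius.
#' @slot noiseSd multiplicative detector noise sd (fraction of signal).
#' @slot strayFraction additive stray-light/dark floor as a fraction of the
#'   reference signal; distorts dark (shaded) pixels most, as on a real
#'   detector.
#' @slot backgroundReflectance background reflectance level.
#' @slot shadingModel `"lambertian"` (hemispherical cap, lamps at 45 degree
#'   zenith) or `"flat"` (no shading; the controlled condition under which
#'   the decomposition is exactly identifiable).
#' @slot seed integer; fixes all randomness of the scene.
#' @export
setClass("PhantomConfig", representation(
  nFruit = "integer", fruitRadius = "numeric",
  defectFraction = "numeric", defectCount = "integer",
  defectRadiusRange = "numeric", defectContrast = "numeric",
  nLamps = "integer",
  lobeAmplitude = "numeric", lobeSigmaFrac = "numeric", lobeOffsetFrac = "numeric",
  noiseSd = "numeric", strayFraction = "numeric",
  backgroundReflectance = "numeric",
  shadingModel = "character",
  seed = "integer"))

setValidity("PhantomConfig", function(object) {
  if (object@nFruit < 1L) return("nFruit must be positive")
  if (object@fruitRadius <= 0) return("fruitRadius must be positive")
  if (object@defectFraction < 0 || object@defectFraction > 1)
    return("defectFraction must lie in [0, 1]")
  if (length(object@defectRadiusRange) != 2L ||
      any(object@defectRadiusRange <= 0) ||
      diff(object@defectRadiusRange) < 0)
    return("defectRadiusRange must be an increasing positive pair")
  if (object@defectRadiusRange[2L] >= object@fruitRadius)
    return("defect radius must be smaller than the fruit radius")
  if (!length(object@defectContrast) %in% c(2L, 3L) ||
      object@defectContrast[1L] < 0)
    return("defectContrast must be (scale, offset) or (scale, offset, dip)")
  if (object@noiseSd < 0) return("noiseSd must be non-negative")
  if (object@strayFraction < 0) return("strayFraction must be non-negative")
  if (object@nLamps < 1L) return("nLamps must be positive")
  if (!object@shadingModel %in% c("lambertian", "flat"))
    return("shadingModel must be 'lambertian' or 'flat'")
  TRUE
})

#' @param nFruit,fruitRadius,defectFraction,defectCount,defectRadiusRange,defectContrast
#'   scene geometry; see slot docs.
#' @param nLamps,lobeAmplitude,lobeSigmaFrac,lobeOffsetFrac specular lobe layout.
#' @param noiseSd,strayFraction,backgroundReflectance,shadingModel rendering
#'   parameters.
#' @param seed integer seed fixing all scene randomness.
#' @return A `PhantomConfig`.
#' @rdname PhantomConfig-class
#' @export
PhantomConfig <- function(nFruit = 24L, fruitRadius = 30,
                          defectFraction = 0.5, defectCount = 2L,
                          defectRadiusRange = c(0.15, 0.3) * fruitRadius,
                          defectContrast = c(0.45, 0.12),
                          nLamps = 3L,
                          lobeAmplitude = 0.8, lobeSigmaFrac = 0.18,
                          lobeOffsetFrac = 0.45,
                          noiseSd = 0.01, strayFraction = 0.015,
                          backgroundReflectance = 0.02,
                          shadingModel = "lambertian",
                          seed = 1L) {
  new("PhantomConfig",
      nFruit = as.integer(nFruit), fruitRadius = as.numeric(fruitRadius),
      defectFraction = as.numeric(defectFraction),
      defectCount = as.integer(defectCount),
      defectRadiusRange = as.numeric(defectRadiusRange),
      defectContrast = as.numeric(defectContrast),
      nLamps = as.integer(nLamps),
      lobeAmplitude = as.numeric(lobeAmplitude),
      lobeSigmaFrac = as.numeric(lobeSigmaFrac),
      lobeOffsetFrac = as.numeric(lobeOffsetFrac),
      noiseSd = as.numeric(noiseSd),
      strayFraction = as.numeric(strayFraction),
      backgroundReflectance = as.numeric(backgroundReflectance),
      shadingModel = shadingModel,
      seed = as.integer(seed))
}

#' Phantom ground truth
#'
#' Everything the generator knows about a synthetic scene: the pixel-wise
#' class labels, the true volume-reflectance cube, the true specular spectrum,
#' the per-lamp specular-amplitude maps and Lambertian shading maps, and the
#' per-fruit index map linking pixels to fruit of origin.
#'
#' @slot labels H x W integer matrix: 0 background, 1 healthy, 2 defect.
#' @slot fruitIndex H x W integer matrix: 0 background, otherwise fruit id.
#' @slot rvol H x W x B true volume reflectance in `[0, 1]`.
#' @slot rsurf length-B true specular spectrum in `[0, 0.1]`.
#' @slot eps H x W x nLamps specular amplitude maps in `[0, 1]`.
#' @slot shading H x W x nLamps Lambertian shading maps in `(0, 1]`.
#' @slot grid the [SpectralGrid].
#' @slot config the generating [PhantomConfig].
#' @export
setClass("PhantomTruth", representation(
  labels = "matrix", fruitIndex = "matrix",
  rvol = "array", rsurf = "numeric",
  eps = "array", shading = "array",
  grid = "SpectralGrid", config = "PhantomConfig"))

setValidity("PhantomTruth", function(object) {
  d <- dim(object@rvol)
  if (!identical(dim(object@labels), d[1:2])) return("labels must match the frame")
  if (!all(object@labels %in% 0:2)) return("labels must be 0/1/2")
  if (length(object@rsurf) != d[3L]) return("rsurf must have one value per band")
  if (any(object@rsurf < 0 | object@rsurf > 0.1)) return("rsurf must lie in [0, 0.1]")
  if (any(object@eps < 0 | object@eps > 1)) return("eps must lie in [0, 1]")
  if (any(object@eps[object@labels == 0L] != 0))
    return("eps must vanish outside fruit")
  TRUE
})

#' Specular/diffuse decomposition result
#'
#' Per-pixel output of the constrained multi-angle reflectance decomposition
#' R_i(lambda) = R_vol(lambda) + eps_i * R_surf(lambda): the volume
#' (diffuse) spectrum, the specular spectrum, the per-angle specular
#' amplitudes, and the root-mean-square reconstruction residual over all
#' angles and bands.
#'
#' @slot rvol H x W x B volume reflectance, in `[0, 1]` at fitted pixels.
#' @slot rsurf H x W x B specular spectrum, in `[0, 0.1]` at fitted pixels.
#' @slot eps H x W x 3 per-angle specular amplitudes in `[0, 1]`.
#' @slot residual H x W RMS misfit; `NA` at unfitted pixels.
#' @slot converged H x W logical; `FALSE` flags pixels stopped at the
#'   iteration cap (best iterate kept).
#' @slot mask H x W logical; which pixels were fitted.
#' @slot grid the [SpectralGrid].
#' @export
setClass("DecompositionResult", representation(
  rvol = "array", rsurf = "array", eps = "array",
  residual = "matrix", converged = "matrix", mask = "matrix",
  grid = "SpectralGrid"))

#' Object mask
#'
#' Connected bright components of the frame retained by the area filter.
#' Component ids are 1..n in `labels`; 0 is background/rejected.
#'
#' @slot labels H x W integer matrix of retained component ids.
#' @slot areas integer vector of retained component pixel counts.
#' @slot threshold the Otsu threshold applied to the selected band.
#' @slot bandNm the wavelength (nm) of the thresholded band.
#' @export
setClass("ObjectMask", representation(
  labels = "matrix", areas = "integer", threshold = "numeric", bandNm = "numeric"))

setValidity("ObjectMask", function(object) {
  n <- length(object@areas)
  if (n > 0 && max(object@labels) != n) return("component ids must be 1..length(areas)")
  TRUE
})

#' Pixel training/test dataset
#'
#' Fruit pixels flattened to a spectra matrix with class labels and the fruit
#' each pixel came from. Background pixels are never included.
#'
#' @slot spectra N x B reflectance matrix.
#' @slot labels factor with levels `healthy`, `defect`.
#' @slot fruit integer fruit-of-origin index per pixel.
#' @export
setClass("PixelDataset", representation(
  spectra = "matrix", labels = "factor", fruit = "integer"))

setValidity("PixelDataset", function(object) {
  n <- nrow(object@spectra)
  if (n < 1L) return("dataset must contain at least one pixel")
  if (length(object@labels) != n || length(object@fruit) != n)
    return("labels and fruit must have one entry per pixel")
  if (!identical(levels(object@labels), c("healthy", "defect")))
    return("labels must be a factor with levels healthy, defect")
  TRUE
})

PixelDataset <- function(spectra, labels, fruit) {
  new("PixelDataset", spectra = spectra,
      labels = factor(labels, levels = c("healthy", "defect")),
      fruit = as.integer(fruit))
}

#' Class reference spectra
#'
#' Per-class mean training spectra for the spectral angle mapper, with
#' unit-norm copies retained for cosine computation.
#'
#' @slot healthy,defect mean class spectra (length B).
#' @slot healthyNorm,defectNorm unit-norm copies.
#' @export
setClass("ReferenceSpectra", representation(
  healthy = "numeric", defect = "numeric",
  healthyNorm = "numeric", defectNorm = "numeric"))

#' Spectral-angle similarity maps
#'
#' Cosine similarity of each masked pixel spectrum to the healthy and defect
#' reference spectra, plus the glare mask excluded from SAM decisions.
#'
#' @slot healthy,defect H x W cosine maps (`NA` off-mask or undefined).
#' @slot glare H x W logical glare mask.
#' @slot valid H x W logical; pixels with a defined similarity.
#' @export
setClass("SimilarityMaps", representation(
  healthy = "matrix", defect = "matrix", glare = "matrix", valid = "matrix"))

#' Decision map
#'
#' Per-pixel classification result on the object mask: 0 background/excluded,
#' 1 healthy, 2 defect; tagged with the classifier and illumination mode that
#' produced it.
#'
#' @slot map H x W integer matrix in \{0, 1, 2\}.
#' @slot method classifier tag (`sam`, `rf`, `svm`, `nn`).
#' @slot illumination illumination-mode tag.
#' @export
setClass("DecisionMap", representation(
  map = "matrix", method = "character", illumination = "character"))

setValidity("DecisionMap", function(object) {
  if (!all(object@map %in% 0:2)) return("decision values must be 0/1/2")
  TRUE
})

DecisionMap <- function(map, method, illumination = NA_character_) {
  new("DecisionMap", map = map, method = method, illumination = illumination)
}

#' Trained pixel classifier
#'
#' Virtual parent of the four classifier models. All subclasses answer
#' [predictLabels()] for an N x B spectra matrix and carry their training
#' metadata (seed, class counts, hyperparameters).
#'
#' @slot method classifier tag.
#' @slot seed training seed.
#' @slot metadata list of hyperparameters and class counts.
#' @export
setClass("ClassifierModel", representation(
  "VIRTUAL", method = "character", seed = "integer", metadata = "list"))

#' @rdname ClassifierModel-class
#' @slot refs the [ReferenceSpectra].
#' @slot thresholding `"fixed"` or `"otsu"`.
#' @slot threshold fixed cosine threshold on the healthy-similarity map.
#' @export
setClass("SAMModel", contains = "ClassifierModel", representation(
  refs = "ReferenceSpectra", thresholding = "character", threshold = "numeric"))

#' @rdname ClassifierModel-class
#' @slot fit underlying fitted model object.
#' @export
setClass("RFModel", contains = "ClassifierModel", representation(fit = "ANY"))

#' @rdname ClassifierModel-class
#' @export
setClass("SVMModel", contains = "ClassifierModel", representation(fit = "ANY"))

#' @rdname ClassifierModel-class
#' @slot net network parameter list (weights, batch-norm statistics).
#' @export
setClass("NNModel", contains = "ClassifierModel", representation(net = "list"))

#' Confusion counts
#'
#' Pixel-wise confusion-matrix counts with defect as the positive class.
#'
#' @slot tp,fp,fn,tn non-negative counts.
#' @export
setClass("ConfusionCounts", representation(
  tp = "numeric", fp = "numeric", fn = "numeric", tn = "numeric"))

setValidity("ConfusionCounts", function(object) {
  v <- c(object@tp, object@fp, object@fn, object@tn)
  if (any(v < 0)) return("counts must be non-negative")
  if (sum(v) <= 0) return("total count must be positive")
  TRUE
})

#' @param tp,fp,fn,tn counts with defect = positive.
#' @return A `ConfusionCounts`.
#' @rdname ConfusionCounts-class
#' @export
ConfusionCounts <- function(tp, fp, fn, tn) {
  new("ConfusionCounts", tp = as.numeric(tp), fp = as.numeric(fp),
      fn = as.numeric(fn), tn = as.numeric(tn))
}

#' Segmentation metric set
#'
#' The seven segmentation metrics: accuracy, error rate (percent), precision,
#' recall, specificity, F1 and IoU. Ratios with a zero denominator are held
#' as `NA` (undefined), never silently zeroed.
#'
#' @slot values named numeric vector with entries `accuracy`, `error_rate`,
#'   `precision`, `recall`, `specificity`, `f1`, `iou`.
#' @export
setClass("MetricSet", representation(values = "numeric"))

metricNames <- c("accuracy", "error_rate", "precision", "recall",
                 "specificity", "f1", "iou")

setValidity("MetricSet", function(object) {
  if (!identical(names(object@values), metricNames))
    return(sprintf("values must be named: %s", paste(metricNames, collapse = ", ")))
  TRUE
})

#' Experiment configuration
#'
#' Full study-protocol configuration for [runExperiment()]: the phantom scene,
#' which illumination modes and classifiers to run, the fruit-level train
#' fraction, and the master seed from which every stochastic stage derives
#' its own seed.
#'
#' @slot phantom the [PhantomConfig].
#' @slot modes subset of `c("local", "simultaneous", "sequential")`.
#' @slot methods subset of `c("sam", "rf", "svm", "nn")`.
#' @slot trainFraction fruit-level training fraction (default 0.4).
#' @slot samThresholding SAM decision rule: `"midpoint"`
#'   (training-calibrated threshold, default), `"otsu"` (adaptive per
#'   object) or `"fixed"` (fixed cosine threshold 0.2).
#' @slot masterSeed master seed.
#' @slot region evaluation region, `"fruit_only"` or `"full_frame"`.
#' @slot outputDir bundle output directory ('' keeps results in memory only).
#' @export
setClass("ExperimentConfig", representation(
  phantom = "PhantomConfig", modes = "character", methods = "character",
  trainFraction = "numeric", samThresholding = "character",
  masterSeed = "integer",
  region = "character", outputDir = "character"))

setValidity("ExperimentConfig", function(object) {
  if (length(object@modes) < 1L || length(object@methods) < 1L)
    return("at least one mode and one method are required")
  if (!all(object@modes %in% c("local", "simultaneous", "sequential")))
    return("unknown illumination mode")
  if (!all(object@methods %in% c("sam", "rf", "svm", "nn")))
    return("unknown method")
  if (object@trainFraction <= 0 || object@trainFraction >= 1)
    return("trainFraction must lie in (0, 1)")
  if (!object@samThresholding %in% c("fixed", "otsu", "midpoint"))
    return("samThresholding must be 'fixed', 'otsu' or 'midpoint'")
  TRUE
})

#' @param phantom,modes,methods,trainFraction,samThresholding,masterSeed,region,outputDir
#'   see slots.
#' @return An `ExperimentConfig`.
#' @rdname ExperimentConfig-class
#' @export
ExperimentConfig <- function(phantom = PhantomConfig(),
                             modes = c("local", "simultaneous", "sequential"),
                             methods = c("sam", "rf", "svm", "nn"),
                             trainFraction = 0.4, samThresholding = "midpoint",
                             masterSeed = 1L,
                             region = "fruit_only", outputDir = "") {
  new("ExperimentConfig", phantom = phantom, modes = modes, methods = methods,
      trainFraction = as.numeric(trainFraction),
      samThresholding = samThresholding,
      masterSeed = as.integer(masterSeed),
      region = region, outputDir = outputDir)
}
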