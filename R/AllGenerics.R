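#' Band centers of an object's spectral grid
#' @param x an object carrying a [SpectralGrid].
#' @return numeric vector of band centers in nm.
#' @export
setGeneric("wavelengths", function(x) standardGeneric("wavelengths"))

#' Number of spectral bands
#' @param x an object carrying a [SpectralGrid].
#' @return integer band count.
#' @export
setGeneric("bandCount", function(x) standardGeneric("bandCount"))

#' Underlying array of a cube
#' @param x a [SpectralCube] or [ReflectanceCube].
#' @return the H x W x B numeric array.
#' @export
setGeneric("cubeValues", function(x) standardGeneric("cubeValues"))

#' Recovery mode tag of a reflectance cube
#' @param x a [ReflectanceCube].
#' @return `"local"`, `"simultaneous"` or `"sequential"`.
#' @export
setGeneric("recoveryMode", function(x) standardGeneric("recoveryMode"))

#' Predict class labels for a matrix of pixel spectra
#' @param model a trained [ClassifierModel].
#' @param spectra N x B reflectance matrix.
#' @param ... method-specific arguments.
#' @return factor of length N with levels `healthy`, `defect`.
#' @export
setGeneric("predictLabels", function(model, spectra, ...) standardGeneric("predictLabels"))

#' Metric values as a named vector
#' @param x a [MetricSet] or [ConfusionCounts].
#' @return named numeric vector of the seven metrics.
#' @export
setGeneric("metricValues", function(x) standardGeneric("metricValues"))

#' @rdname wavelengths
setMethod("wavelengths", "SpectralGrid", function(x) x@wavelengths)
#' @rdname wavelengths
setMethod("wavelengths", "SpectralCube", function(x) x@grid@wavelengths)
#' @rdname bandCount
setMethod("bandCount", "SpectralGrid", function(x) length(x@wavelengths))
#' @rdname bandCount
setMethod("bandCount", "SpectralCube", function(x) length(x@grid@wavelengths))
#' @rdname cubeValues
setMethod("cubeValues", "SpectralCube", function(x) x@values)
#' @rdname recoveryMode
setMethod("recoveryMode", "ReflectanceCube", function(x) x@recoveryMode)
#' @rdname metricValues
setMethod("metricValues", "MetricSet", function(x) x@values)

setMethod("show", "SpectralGrid", function(object) {
  w <- object@wavelengths
  cat(sprintf("SpectralGrid: %d bands, %g-%g nm\n", length(w), min(w), max(w)))
})

setMethod("show", "SpectralCube", function(object) {
  d <- dim(object@values)
  cat(sprintf("%s: %d x %d px, %d bands (%g-%g nm)\n", class(object),
              d[1L], d[2L], d[3L],
              min(object@grid@wavelengths), max(object@grid@wavelengths)))
})

setMethod("show", "ReflectanceCube", function(object) {
  d <- dim(object@values)
  cat(sprintf("ReflectanceCube [%s]: %d x %d px, %d bands; %d invalid px\n",
              object@recoveryMode, d[1L], d[2L], d[3L], sum(object@invalidMask)))
})

setMethod("show", "PhantomTruth", function(object) {
  tab <- tabulate(object@labels + 1L, nbins = 3L)
  cat(sprintf(paste0("PhantomTruth: %d x %d px, %d bands, %d fruit\n",
                     "  background %d px, healthy %d px, defect %d px\n"),
              nrow(object@labels), ncol(object@labels), length(object@rsurf),
              max(object@fruitIndex), tab[1L], tab[2L], tab[3L]))
})

setMethod("show", "DecompositionResult", function(object) {
  cat(sprintf("DecompositionResult: %d fitted px, median residual %.3g, %d not converged\n",
              sum(object@mask), stats::median(object@residual[object@mask]),
              sum(!object@converged[object@mask])))
})

setMethod("show", "ObjectMask", function(object) {
  cat(sprintf("ObjectMask: %d component(s) retained (areas: %s), Otsu threshold %.4g at %g nm\n",
              length(object@areas), paste(object@areas, collapse = ", "),
              object@threshold, object@bandNm))
})

setMethod("show", "PixelDataset", function(object) {
  tab <- table(object@labels)
  cat(sprintf("PixelDataset: %d px x %d bands (%d healthy / %d defect), %d fruit\n",
              nrow(object@spectra), ncol(object@spectra),
              tab[["healthy"]], tab[["defect"]], length(unique(object@fruit))))
})

setMethod("show", "ClassifierModel", function(object) {
  cat(sprintf("%s (%s): trained on %s healthy / %s defect px, seed %d\n",
              class(object), object@method,
              format(object@metadata$nHealthy %||% NA),
              format(object@metadata$nDefect %||% NA), object@seed))
})

setMethod("show", "DecisionMap", function(object) {
  tab <- tabulate(object@map + 1L, nbins = 3L)
  cat(sprintf("DecisionMap [%s/%s]: %d healthy px, %d defect px\n",
              object@method, object@illumination, tab[2L], tab[3L]))
})

setMethod("show", "ConfusionCounts", function(object) {
  cat(sprintf("ConfusionCounts (defect = positive): TP %g, FP %g, FN %g, TN %g\n",
              object@tp, object@fp, object@fn, object@tn))
})

setMethod("show", "MetricSet", function(object) {
  v <- object@values
  cat("MetricSet:\n")
  for (nm in names(v))
    cat(sprintf("  %-11s %s\n", nm,
                ifelse(is.na(v[[nm]]), "undefined", sprintf("%.4f", v[[nm]]))))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
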