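# End-to-end study protocol on phantom data: generate a scene, recover
# reflectance under each illumination mode, split fruit-wise, train the
# requested classifiers on balanced training pixels, predict on held-out
# fruit, and pool the metric grid.

# map each retained mask component to the truth fruit with maximal overlap
matchComponentsToFruit <- function(masks, truth) {
  vapply(seq_along(masks@areas), function(k) {
    sel <- masks@labels == k
    ids <- truth@fruitIndex[sel]
    ids <- ids[ids > 0L]
    if (length(ids) == 0L) return(0L)
    as.integer(names(which.max(table(ids))))
  }, integer(1))
}

# labeled per-object crops for one mode's reflectance cube
labeledObjects <- function(cube, masks, truth) {
  crops <- extractObjectCubes(cube, masks)
  fruitIds <- matchComponentsToFruit(masks, truth)
  lapply(seq_along(crops), function(k) {
    o <- crops[[k]]
    r0 <- o$offset["row"]; c0 <- o$offset["col"]
    lab <- truth@labels[r0:(r0 + nrow(o$mask) - 1L),
                        c0:(c0 + ncol(o$mask) - 1L), drop = FALSE]
    lab[!o$mask] <- 0L
    o$labels <- lab
    o$id <- fruitIds[k]
    o
  })
}

# reflectance cubes for the requested modes (median-filtered input set)
recoverModes <- function(set, modes, decompMask = NULL, maxIter = 200L) {
  out <- list()
  if ("local" %in% modes) out$local <- reflectanceLocal(set)
  if ("simultaneous" %in% modes) out$simultaneous <- reflectanceSimultaneous(set)
  if ("sequential" %in% modes) {
    rAngles <- reflectancePerAngle(set)
    meanR <- Reduce(`+`, lapply(rAngles, function(r) r@values)) / 3
    mask <- decompMask
    if (is.null(mask)) {
      # fit only plausibly-foreground pixels: Otsu on the angle-averaged
      # 750 nm band (decomposing background wastes most of the runtime)
      nm <- wavelengths(rAngles[[1L]])
      b750 <- which.min(abs(nm - 750))
      plane <- meanR[, , b750]
      mask <- dilate1(plane > otsuThreshold(plane))
    }
    decomp <- fitSpecularDecomposition(rAngles, mask = mask, maxIter = maxIter)
    out$sequential <- sequentialReflectance(decomp, fill = meanR)
    attr(out, "decomposition") <- decomp
  }
  out
}

trainMethod <- function(method, balanced, masterSeed, samThresholding = "otsu") {
  seed <- deriveSeed(masterSeed, paste0("train-", method))
  switch(method,
         sam = trainSAM(balanced, thresholding = samThresholding, seed = seed),
         rf = trainRF(balanced, seed = seed),
         svm = trainSVM(balanced, seed = seed),
         nn = trainNN(balanced, seed = seed),
         stop(sprintf("unknown method '%s'", method)))
}

#' Run the full phantom experiment
#'
#' Reproduces the study protocol end to end on synthetic data: generates
#' the phantom scene and its multi-angle acquisition, median-filters all
#' cubes, recovers reflectance under each requested illumination mode,
#' extracts per-fruit cubes through Otsu masking and the area filter
#' (window scaled by the squared frame scale), makes one fruit-level
#' 40/60-style split shared by every method within each mode, balances the
#' training pixels by under-sampling the healthy class, trains each
#' requested classifier, predicts decision maps on the held-out fruit, and
#' pools confusion counts into the method-by-mode metric grid. Every
#' stochastic stage derives its seed from `config@masterSeed`, so the run
#' is fully reproducible.
#'
#' One object-mask set, built from the angle-summed (simultaneous)
#' reflectance at 750 nm, is shared by all illumination modes: the three
#' modes image the same physical scene, and sharing the geometry mask
#' scores every mode on the identical pixel set, so metric differences
#' reflect the illumination protocol rather than mode-dependent mask
#' erosion (a single-lamp 750 nm image loses its own shaded rims to the
#' threshold, which would silently exclude exactly the pixels where the
#' modes differ). It also guarantees one fruit partition across modes.
#'
#' @param config an [ExperimentConfig].
#' @param verbose print stage progress (default FALSE).
#' @return list with elements `truth`, `modes` (reflectance cubes),
#'   `masks`, `split` (per mode), `results` (`results[[method]][[mode]]`
#'   [MetricSet]s), `grid` (the long-format metric table),
#'   `decisionMaps` (`[[method]][[mode]]`, one [DecisionMap] per test
#'   fruit), and `manifest`. When `config@outputDir` is set, the grid
#'   (CSV), decision maps (PNG) and manifest (YAML) are also written there.
#' @export
runExperiment <- function(config, verbose = FALSE) {
  stopifnot(is(config, "ExperimentConfig"))
  validObject(config)
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()

  say("generating phantom scene")
  truth <- makePhantomScene(config@phantom)
  set <- renderIlluminationSet(truth)
  say("median filtering")
  set <- medianFilterSet(set)

  scale2 <- (config@phantom@fruitRadius / 95)^2
  minA <- 20000 * scale2; maxA <- 40000 * scale2

  say("recovering reflectance (%s)", paste(config@modes, collapse = ", "))
  cubes <- recoverModes(set, config@modes)

  # one geometry mask for the scene, from the angle-summed 750 nm image
  maskSource <- if (!is.null(cubes$simultaneous)) cubes$simultaneous
                else reflectanceSimultaneous(set)
  masks <- buildObjectMasks(maskSource, 750, minA, maxA)
  say("object mask: %d components retained", length(masks@areas))

  region <- config@region
  results <- list(); decisionMaps <- list()
  splitByMode <- list()
  splitSeed <- deriveSeed(config@masterSeed, "split")

  for (mode in config@modes) {
    cube <- cubes[[mode]]
    objects <- labeledObjects(cube, masks, truth)
    split <- splitFruitwise(objects, config@trainFraction, seed = splitSeed)
    splitByMode[[mode]] <- split
    say("mode %s: %d objects (%d train / %d test)", mode, length(objects),
        length(split$train), length(split$test))

    trainData <- pixelDatasetFromObjects(objects[split$train])
    balanced <- undersampleHealthy(trainData,
                                   deriveSeed(config@masterSeed, "undersample"))
    for (method in config@methods) {
      say("mode %s: training %s", mode, method)
      model <- trainMethod(method, balanced, config@masterSeed,
                           config@samThresholding)
      counts <- c(tp = 0, fp = 0, fn = 0, tn = 0)
      dms <- list()
      for (k in split$test) {
        o <- objects[[k]]
        dm <- predictMap(model, o$cube, o$mask, illumination = mode)
        cc <- confusionFromMaps(dm, o$labels, region = region)
        counts <- counts + c(tp = cc@tp, fp = cc@fp, fn = cc@fn, tn = cc@tn)
        dms[[as.character(o$id)]] <- dm
      }
      results[[method]][[mode]] <-
        metricsFromConfusion(ConfusionCounts(counts["tp"], counts["fp"],
                                             counts["fn"], counts["tn"]))
      decisionMaps[[method]][[mode]] <- dms
    }
  }

  grid <- reportMetricGrid(results)
  manifest <- list(
    kind = "experiment-bundle",
    masterSeed = config@masterSeed,
    trainFraction = config@trainFraction,
    region = region,
    modes = config@modes, methods = config@methods,
    phantomSeed = config@phantom@seed,
    areaWindow = c(minA, maxA),
    splits = lapply(splitByMode, function(s) list(
      trainFruit = vapply(s$train, function(i) i, integer(1)),
      testFruit = vapply(s$test, function(i) i, integer(1)),
      defectProportionGap = s$gap)),
    elapsedSec = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  bundle <- list(truth = truth, modes = cubes, masks = masks,
                 split = splitByMode, results = results, grid = grid,
                 decisionMaps = decisionMaps, manifest = manifest)

  if (nzchar(config@outputDir)) {
    dir.create(config@outputDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(grid, file.path(config@outputDir, "metric_grid.csv"),
                     row.names = FALSE)
    yaml::write_yaml(manifest, file.path(config@outputDir, "manifest.yml"))
    for (method in names(decisionMaps))
      for (mode in names(decisionMaps[[method]]))
        for (id in names(decisionMaps[[method]][[mode]]))
          writeLabelMapPNG(decisionMaps[[method]][[mode]][[id]],
                           file.path(config@outputDir,
                                     sprintf("decision_%s_%s_fruit%s.png",
                                             method, mode, id)))
  }
  bundle
}

# fixed class colors used by every figure: background, healthy, defect
decisionPalette <- c("#202020", "#3cb44b", "#e6194b")

#' Render truth-versus-decision figures
#'
#' One PNG per test fruit: the ground-truth map beside each method-by-mode
#' decision map, with one fixed color per class across all panels
#' (dark gray background, green healthy, red defect).
#'
#' @param bundle result of [runExperiment()].
#' @param dir output directory.
#' @return character vector of written file paths, invisibly.
#' @export
makeFigures <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  methods <- names(bundle$decisionMaps)
  modes <- names(bundle$decisionMaps[[methods[1L]]])
  ids <- names(bundle$decisionMaps[[methods[1L]]][[modes[1L]]])
  paths <- character(0)
  panel <- function(m, title) {
    graphics::image(t(m)[, nrow(m):1, drop = FALSE], col = decisionPalette,
                    breaks = c(-0.5, 0.5, 1.5, 2.5), axes = FALSE,
                    main = title, cex.main = 0.9)
  }
  for (id in ids) {
    npanel <- 1L + length(methods) * length(modes)
    f <- file.path(dir, sprintf("fruit%s_decisions.png", id))
    grDevices::png(f, width = 220 * min(npanel, 4L),
                   height = 220 * ceiling(npanel / 4L))
    graphics::par(mfrow = c(ceiling(npanel / 4L), min(npanel, 4L)),
                  mar = c(0.5, 0.5, 2, 0.5))
    fr <- which(bundle$truth@fruitIndex == as.integer(id), arr.ind = TRUE)
    rows <- range(fr[, 1L]); cols <- range(fr[, 2L])
    truthCrop <- bundle$truth@labels[rows[1L]:rows[2L], cols[1L]:cols[2L]]
    panel(truthCrop, sprintf("truth (fruit %s)", id))
    for (method in methods)
      for (mode in modes) {
        dm <- bundle$decisionMaps[[method]][[mode]][[id]]
        panel(dm@map, sprintf("%s / %s", method, mode))
      }
    grDevices::dev.off()
    paths <- c(paths, f)
  }
  invisible(paths)
}
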