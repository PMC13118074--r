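# hsifruit

Pixel-wise defect segmentation of fruit in visible/NIR hyperspectral images
(450–850 nm, 5 nm steps, 81 bands) under three illumination protocols, with
a synthetic phantom generator providing ground truth for every stage.

Automated optical sorting must find bruises and rot on curved, glossy
produce. On such objects two illumination artifacts confound per-pixel
spectral classification: *shading* (orientation-dependent signal loss) and
*specular glint* (mirror reflection of the lamps, carrying no tissue
information). Both depend on how the scene is lit, so the package compares
three acquisition protocols on identical scenes:

* **local** — one lamp at 45° zenith (standard 0/45 geometry):
  `R = I_obj,2 / I_ref,2`;
* **simultaneous** — three lamps at once:
  `R = Σᵢ I_obj,i / Σᵢ I_ref,i`;
* **sequential** — one image per lamp position, then a per-pixel constrained
  least-squares decomposition

  `Rᵢ(λ) = R_vol(λ) + εᵢ · R_surf(λ)`,  `R_vol ∈ [0,1]`, `R_surf ∈ [0,0.1]`, `εᵢ ∈ [0,1]`,

  which separates the diffuse (volume) reflectance `R_vol` — the part that
  penetrated the tissue and carries its biochemistry — from the
  angle-dependent specular part `εᵢR_surf`. The decomposition is solved by
  projected alternating least squares (each block has a closed-form
  constrained minimizer, so the misfit is monotonically non-increasing).

On each recovered reflectance cube the pipeline runs Otsu-based object
masking with an area filter, a fruit-level 40/60 train/test split,
healthy-class under-sampling, and four pixel classifiers — spectral angle
mapper (SAM), random forest (100 trees), RBF SVM, and a 1-D convolutional
network over the spectral axis (3 conv blocks of kernel 5 / 8 channels with
batch-norm and ReLU, global average pooling, dense 64–16–2 softmax; 2,402
parameters at 81 bands) — and scores decision maps with accuracy, error
rate, precision, recall, specificity, F1 and IoU (defect = positive class).

Because no instrument data ships with the package, a seeded phantom
generator renders multi-angle scenes of sphere-like fruit with known labels,
volume spectra, per-lamp Lambertian shading, localized specular lobes, a
stray-light floor, and detector noise. See the methods vignette
(`vignettes/hsifruit-methods.Rmd`) for the models, the phantom's design
rationale and its limits.

## Worked example

```r
library(hsifruit)

# a subtle shape-only defect under shading, glare and a stray-light floor:
# the conditions where the illumination protocol matters
cfg <- ExperimentConfig(
  phantom = PhantomConfig(nFruit = 8L, fruitRadius = 24, seed = 42L,
                          defectContrast = c(1, 0, 0.15),
                          noiseSd = 0.02, strayFraction = 0.03),
  modes = c("local", "simultaneous", "sequential"),
  methods = c("sam", "rf"),
  masterSeed = 7L)
bundle <- runExperiment(cfg)
subset(bundle$grid, metric == "f1")
```

```
   method         mode metric     value formatted  best
6     sam        local     f1 0.3410256    0.3410 FALSE
13    sam simultaneous     f1 0.9988138    0.9988  TRUE
20    sam   sequential     f1 0.9867947    0.9868 FALSE
27     rf        local     f1 0.3780718    0.3781 FALSE
34     rf simultaneous     f1 0.9470046    0.9470 FALSE
41     rf   sequential     f1 0.9728453    0.9728  TRUE
```

Each row is the pooled F1 over the held-out fruit for one classifier under
one illumination protocol (the `best` flag marks the best mode per
classifier and metric). Single-lamp illumination collapses both
classifiers on this subtle defect — shaded rims inside the object mask are
misread as defects — while multi-lamp averaging and the specular/diffuse
decomposition restore them. With the pronounced default defect contrast the
scale-invariant SAM is instead robust in every mode and it is the random
forest, which reads absolute band values, that degrades under single-lamp
shading. `bundle$decisionMaps` holds the
per-fruit decision maps, `makeFigures(bundle, "figs")` renders
truth-versus-prediction panels, and setting `cfg@outputDir` writes the
metric grid (CSV), decision maps (PNG) and a YAML manifest.

The same machinery is exposed piecewise: `makePhantomScene()` /
`renderIlluminationSet()` (phantom), `medianFilterBands()`,
`reflectanceLocal()` / `reflectanceSimultaneous()` /
`fitSpecularDecomposition()` (calibration), `buildObjectMasks()` /
`extractObjectCubes()` (masking), `splitFruitwise()`,
`undersampleHealthy()`, `trainSAM()` / `trainRF()` / `trainSVM()` /
`trainNN()`, `predictMap()` (classification), and `confusionFromMaps()` /
`metricsFromConfusion()` / `reportMetricGrid()` (evaluation). A thin CLI
wrapper lives at `inst/scripts/hsifruit-cli.R`.

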