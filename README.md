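# polaris3d

Quantitative 3D subcellular mapping of polarizing epithelial monolayers.

Retinal pigment epithelium (RPE) cells mature from a flat, unpolarized sheet
into a columnar monolayer with distinct apical and basal domains. Tracking
that transition quantitatively requires turning fluorescence stacks into
numbers: where every cell, nucleus and organelle sits in 3D, how their
shapes change week by week, and which structures reorganize together.
`polaris3d` implements the full analysis pipeline downstream of a 2D
instance segmenter, for image analysts and cell biologists who have
per-plane cell/nucleus masks (or want to prototype against synthetic data):

- **3D assembly (stitching).** Per-plane 2D instances are linked across
  z-planes by intersection-over-union, IoU(A,B) = |A∩B| / |A∪B|, joining
  pairs with IoU > 0.6 under the assignment that maximizes cumulative IoU.
  Objects whose terminal planes match across a gap of at most 3 planes
  (1.5 µm at 0.5 µm spacing) are merged and the gap interpolated; a final
  collision-free dilation (2 px) compensates interior-traced boundaries.
- **Classical organelle segmentation.** Composable operator presets
  (smoothing, Otsu/Li/percentile/half-max thresholds, LoG spot detection,
  Hessian filament enhancement, distance-transform watershed, size filter)
  for four structure archetypes: spots, filaments, shells, blobs.
- **Morphometry and QC.** Per object: volume, height, z-projection area,
  min/max Feret diameters by rotating calipers, aspect ratio
  (feret_max/feret_min), sphericity π^⅓(6V)^⅔/A. QC removes border-touching
  cells, volumes outside [50, 100000] µm³, widths < 1.5 µm, heights
  < 1.0 µm, then trims the top/bottom 5% per shape metric.
- **Localization and reference maps.** Apical and lateral distances of each
  organelle to its parent cell's borders; condition-level average cell and
  nucleus geometry with ±2 SD bands; 90% confidence ellipses
  (χ²₂-scaled covariance) of average locations.
- **Spatial interaction.** Cells aligned by elongated-hexagon template
  matching, signals morphed onto a mean cell shape in normalized
  (radial-fraction, height-fraction) coordinates, and structure-structure
  Pearson correlation (PCC) matrices with average-linkage clustering.
- **Trend modelling.** Per-metric quadratic GLMs y = k + m·week + n·week²
  (Gaussian, or Poisson for counts) fitted by maximum likelihood, with the
  inflection week −m/(2n), accelerating/decelerating classification by
  sign(n), and AIC / pseudo-R² comparison against the strictly linear model.
  Welch's t-test, one-way ANOVA + Tukey HSD, and Shapiro–Wilk checks cover
  the group comparisons.
- **Networks and classification.** Weighted degree of centrality (sum of
  |PCC| per structure), differential networks, first week of significant
  interaction change (|ΔPCC| ≥ 0.45), and per-organelle Random Forest
  polarity classifiers ranked by accuracy-weighted feature importance.
- **Phantom generator.** Hexagonally packed prismatic cells with ellipsoidal
  nuclei and 16 organelle classes drawn from apical/perinuclear/lateral/
  border placement laws, on the anisotropic 0.217 × 0.217 × 0.500 µm voxel
  grid, with Gaussian-PSF + Poisson/read-noise intensity channels — so the
  entire pipeline is testable without any microscopy download.

## Worked example

```r
library(polaris3d)

## the classical QC object: a hexagonal prism of known dimensions
v <- voxel_spec()                       # 0.217 x 0.217 x 0.5 um
prism <- generate_hexagonal_prism(circumradius = 10, height = 5, voxel = v)
m <- volume_height(prism, v); p <- projection_metrics(prism, v)
sprintf("volume %.1f um^3 | height %.1f um | aspect ratio %.3f | sphericity %.3f",
        m$volume, m$height, p$aspect_ratio, sphericity(prism, v))
#> "volume 1300.8 um^3 | height 5.0 um | aspect ratio 1.160 | sphericity 0.706"
```

The analytic values are 1299.0 µm³ ((3√3/2)R²h), aspect ratio 2/√3 ≈ 1.155,
and sphericity 0.702 — all reproduced within rasterization error (< 2%).

```r
## a synthetic polarized monolayer, re-stitched from its own 2D planes
ph <- generate_monolayer(4, 3, polarity_state("polarized"),
                         voxel = voxel_spec(0.434, 0.434, 0.5), seed = 1)
cells3d <- stitch(slice_volume(ph$cells), stitch_config(), ph$voxel)
max(cells3d)
#> 12                                    # all 12 cells recovered

cm  <- cell_morphometry(ph$cells, ph$voxel)
reference_map(cm, cell_morphometry(ph$nuclei, ph$voxel), condition = "polarized")
#> reference map (polarized, n=12 cells)
#>   cell: height 5.42 +/- 0.36 um, half-width 8.62 +/- 0.66 um
#>   nucleus: height 4.38 +/- 0.48 um, half-width 4.84 +/- 0.06 um, offset z -0.27 / xy 0.05 um
```

The polarized state draws cells around 5.3 µm tall and 17.1 µm wide
(half-width ≈ 8.6 µm), which the measured map recovers; the nucleus sits
slightly basal (negative z offset).

```r
## weekly height trend: fit the quadratic GLM and locate the inflection
f <- fit_quadratic_glm(c(4.6, 4.6, 5.9, 6.0, 5.6, 5.5, 5.3, 5.2),
                       week = rep(1:4, each = 2))
f
#> quadratic gaussian GLM: y = 2.887 + 2.218 x + -0.4125 x^2
#>   decelerating dynamics; inflection at week 2.69
#>   AIC 5.83 (linear 16.40); pseudo-R2 0.818 (linear 0.123); n = 8
```

Height rises early and flattens: n < 0 (decelerating), the rate of change
crosses zero near week 2.7, and the quadratic model beats the linear one
on AIC.

`run_pipeline(run_config(...))` chains every stage (phantom → stitch →
segment → morphometry/QC → maps → GLMs → networks → classifiers) and writes
one CSV per table; `inst/cli/polaris.R` exposes the same stages as a
command-line tool.

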