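---
title: "Methods: 3D subcellular mapping of epithelial polarization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 3D subcellular mapping of epithelial polarization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models and
procedures each stage implements, the parameters that matter and why their
defaults are what they are, what the synthetic phantoms do and do not
emulate, and the numerical choices made where the design was genuinely
open. It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The problem

Retinal pigment epithelium (RPE) cells polarize over weeks in culture:
they constrict laterally, elongate apically, and reorganize their
organelles along the apical–basal axis. The pipeline quantifies that
transition from multichannel 3D stacks (cell-border stain, nuclear stain,
one GFP-tagged structure per sample) given per-plane 2D instance masks of
cells and nuclei from any upstream segmenter. All geometry is
µm-denominated on an anisotropic voxel grid, by default
0.217 × 0.217 × 0.500 µm — a lateral/axial anisotropy of ≈ 2.3 that every
distance, filter scale and surface estimate must respect.

## 3D assembly from 2D planes (`stitch`)

Objects in adjacent planes are compared by intersection-over-union. Pairs
with IoU *strictly above* 0.6 are candidate links ("above a threshold"
is read as exclusive; the boundary case is exercised by a constructed
overlap of exactly 0.60, which must not join). Because one object may
overlap several, links are chosen as the one-to-one assignment that
maximizes the total IoU over all possible combinations; the candidate
graph splits into tiny connected components, each solved exactly by
branch-and-bound (a greedy variant is available via
`stitch_config(matching = "greedy")`). Chains of linked 2D objects become
one 3D label.

After chaining, an object whose top plane matches another's bottom plane
(same IoU criterion — the looser reading "matched" is resolved as the
same 0.6 threshold and exposed as `gap_iou_threshold`) across at most
`max_gap_planes = 3` empty planes (1.5 µm at dz = 0.5) is merged; each gap
plane copies the nearer terminal plane's mask, ties to the lower plane.
That is the simplest interpolation consistent with "filled from the
closest planes outside the gap", and it makes the gap rule exactly
testable: fragments separated by 3 planes merge, by 4 do not.

Finally `dilate_labels()` grows every label in-plane by 2 px (instance
masks traced on cell interiors run 2–3 px small). The structuring element
is a square (Chebyshev metric), growth is background-only, contested
pixels go to the nearest *original* label and exact ties to the lowest id
— so dilation is deterministic and abutting labels never exchange voxels.

On phantoms sliced from gap-free ground truth, stitching must equal
26-connected component labelling of the union mask up to a label
permutation; the suite checks this on 20 seeded monolayers (cells spaced
so the union mask separates — with narrow intercellular gaps the
rasterized footprints can become diagonally adjacent, where the oracle
itself breaks down, not the stitcher).

## Morphometry (`morphometry`)

2D metrics are measured on the z-projection of each object (epithelia grow
as a monolayer): area, min/max Feret diameters, aspect ratio
= feret_max/feret_min. Feret diameters use convex-hull rotating calipers
over the *corner points* of boundary pixels, so an s-pixel axis-aligned
square measures exactly s and s√2 — treating pixels as unit squares
rather than points removes a half-pixel negative bias. 3D metrics keep all
dimensions: volume = voxel count × dx·dy·dz; height = occupied-plane count
× dz (a single-plane object is dz tall).

Sphericity is π^⅓(6V)^⅔/A. The surface area A comes from a co-area
estimator: the binary mask is Gaussian-smoothed (σ floored at 0.7 voxels
per axis so the interface profile stays resolved) and |∇u| is integrated
on the physical grid. For flat axis-aligned interfaces the gradient sum
telescopes and the estimate is exact at any σ; the remaining error — the
rounding of sharp edges — is linear in σ, so the estimator is evaluated at
σ and 2σ and extrapolated to σ → 0. Calibration in the test suite: ball of
radius 20 voxels ≥ 0.95, cube within 5% of the closed form 0.806, the
hexagonal-prism QC object within 2%. This replaces an iso-surface mesh
(no 3D meshing is available in the dependency set); its known limitation
is structures thinner than the smoothing scale (≈ 1 voxel), for which A is
unreliable — the rod monotonicity test therefore uses a 3×3-voxel
cross-section, and single-plane objects report sphericity as missing.

Quality control removes, in order: border-touching cells; volumes outside
[50, 100000] µm³; widths (min Feret, the strictest reading of "width")
below 1.5 µm; heights below 1.0 µm; then trims the top and bottom 5% of
each shape metric at the single-cell level. Trimming is per-metric — the
row keeps its other metrics, preserving per-metric n for FOV averaging —
and is applied once, recorded in the table's provenance, so the filter is
idempotent. On 1000 distinct values exactly 50 are removed per tail.

Organelles are assigned to the cell containing the majority of their
voxels (background-majority objects dropped and logged; exact ties to the
lower id). Localization: lateral distance is the minimum over organelle
voxels of the 2D Euclidean distance transform of the parent footprint;
apical distance is measured from the object's highest voxel to the cell's
top occupied plane (cells are prisms in the phantom; real data inherits
the same per-cell apical-plane rule), clipped at zero; nucleolar
structures are referenced to the nucleus centroid in 3D instead.

## Reference and interaction maps (`maps`)

A reference map is the condition average of cell/nucleus height and
half-width (half of the mean of min and max Feret), with ±2 SD bands
(≈ 95% of cells for Gaussian spreads — verified by simulation, not
assumed). Organelle location scatter is summarized by covariance
confidence ellipses scaled by √χ²₂(0.90); Monte-Carlo coverage on 10⁵
points must be 90% ± 0.5%.

For interaction maps, each cell footprint is matched against a library of
elongated hexagons — elongation factors {1.0, 1.2, 1.5, 2.0}, 8 sizes
spanning 0.75–1.25 of the area-implied circumradius, 3° rotation steps,
scored by IoU between footprint and analytic hexagon (these grid choices
are engineering defaults, all config-exposed). The best rotation
re-orients the cell; if the nucleus centroid then lies more than 5% of
the max Feret to the *right* of the cell centroid (a dead-band, since no
threshold is specified), an extra 180° turn puts it at the centre or
left. Recovered angles are meaningful mod 180° for elongated templates
(mod 60° for regular hexagons) — the round-trip test asserts recovery
within one rotation step modulo that symmetry.

Morphing maps every cell voxel to normalized coordinates: angle θ around
the cell centroid, radial fraction ρ = r/R(θ) to the lateral border
(boundary radius profile in 72 angular bins), and fractional height ζ.
Intensities are averaged per bin of a fixed template grid (default
64 × 64 × 16; the pipeline demo uses 32 × 32 × 8), averaged across cells,
and interior holes filled from neighbouring bins. The testable contract is
conservation: uniform signals stay uniform, mean intensity is preserved
within 5%, and a smooth signal morphed onto its own cell and projected
back correlates ≥ 0.95 with the original. Structure–structure interaction
is then the Pearson correlation of flattened templates — symmetric, unit
diagonal, undefined (flagged) for constant signals — clustered with
average linkage on distance 1 − PCC.

## Trend models and tests (`stats`)

Each FOV-aggregated metric is fitted by maximum likelihood as
y = k + m·week + n·week², Gaussian/identity for continuous metrics,
Poisson/log for counts (FOV-mean counts are rounded to integers for the
Poisson family; the Gaussian fit on means is the default otherwise). The
rate y′ = m + 2n·week crosses zero at the inflection week −m/(2n); n > 0
is accelerating, n < 0 decelerating. A strictly linear model is always
fitted alongside and compared by AIC and pseudo-R². The pseudo-R² is
deviance-based (1 − dev/null-dev): it equals classical R² for the
Gaussian family and avoids the likelihood-ratio form's escape above 1
when the Gaussian log-likelihood is positive. Treatment arms are fitted
separately by default (`fit_trend_table`); a pooled interaction model is
ambiguous between reasonable designs, and per-arm fits report the same
per-arm curves either way.

Group comparisons delegate to the standard routines: Welch's two-sided
t-test (`stats::t.test`), one-way ANOVA with Tukey HSD at 95% family-wise
confidence (`stats::aov` + `TukeyHSD`), Shapiro–Wilk
(`stats::shapiro.test`, recorded in provenance, never gating).
Significance stars default to \*\*\* p < 0.005, \*\* p < 0.01,
\* p < 0.05 — the convention the reported tables for this system use —
and the cutoffs are an argument for workflows that prefer 0.001.

## Networks and polarity classification (`networks`, `mlpolar`)

The weighted degree of centrality of a structure is the sum of |PCC| to
all other structures — absolute, so the degree is a degree; a signed
variant is available since the original definition ("strength of
connection") does not fix the sign convention. Differential networks are
element-wise PCC differences to week 1; the first week of significant
change per pair is the earliest week with |ΔPCC| ≥ 0.45 (a fixed
threshold, not a test), reported with the signed change.

Polarity classifiers are Random Forests (500 trees), one per structure,
evaluated by seed-fixed stratified 5-fold cross-validation (a reported
accuracy alone does not fix a split protocol; k-fold CV is the
conservative default). Gini importances are averaged over folds,
normalized to sum to one, and multiplied by the model's accuracy to give
the accuracy-weighted importance ranked across organelles. The statistical
unit is the FOV by default, single cells by config. LMNB1 (nuclear
envelope, drawn as a shell) has no shape metrics and is excluded from
shape-feature models. The planted-signal check builds two states whose
lysosome placement differs *only along z* (apical-central vs its basal
mirror) and requires the apical-distance feature to top the ranking,
with label-permuted accuracy at chance.

## The phantom generator (`phantom`)

Phantoms emulate what the analysis assumes about the data: hexagonally
packed prismatic cells (regular lattice with centre jitter; spacing leaves
a thin intercellular gap that doubles as the border channel), per-cell
heights/widths jittered around a polarity state, one ellipsoidal nucleus
per cell strictly inside its parent, and organelle classes drawn as
spheres, ellipsoids, filaments or nuclear shells under five placement
laws. The named states use the reported dimensions of the study system:
polarized = week-4 PGE2 (5.3 µm tall, 17.1 µm wide), nonpolarized = week-4
HPI4 (3.5, 21.8), baseline = week 1 (4.6, 19.1); `condition_state()`
interpolates the full treatment × week table. Per-cell jitter SDs (0.4 µm
height, 1.2 µm width) are realistic single-cell spreads — the reported
dataset-level SDs (~0.2 µm) average thousands of cells and would make
phantom populations implausibly uniform. Organelle counts and volumes per
class are generator defaults, not measurements.

Intensity channels are the ground-truth indicator convolved with an
isotropic Gaussian PSF (σ = 1 voxel laterally, half a plane axially — a
stand-in, not optics simulation) plus Poisson shot noise and Gaussian read
noise at SNR 10 by default. One RNG stream per dataset with an explicit
integer seed makes every phantom bit-reproducible. What phantoms do *not*
emulate: real PSF anisotropy and depth dependence, pigment absorption,
microvilli, cell-shape irregularity beyond hexagons-with-jitter, and
spatially varying background. Passing tests therefore demonstrate
pipeline correctness on data satisfying the stated geometric assumptions,
not segmentation performance on real microscopy.

## Segmentation presets (`segops`)

No authoritative per-structure parameter table is available for the 16
classes, so the package ships four archetype presets (spot, filament,
shell, blob) as engineering defaults and provides `tune_preset()` — a grid search scored by
`evaluate_preset()` against phantom ground truth — as the automated
replacement for expert-in-the-loop tuning; the shipped defaults were
chosen with it. The "halfmax" threshold (a fraction of the 99.9th
percentile) is the workhorse for sparse uniform-amplitude structures;
LoG and Hessian operators remain available in the chain. Measured on
default-class phantoms at SNR 10, mean matched IoU is ≈ 0.87 for
separated spots but ≈ 0.6 for blobs and filaments — thin structures are
only ~2 px wide laterally and ~1 plane axially, which caps achievable
overlap; the suite asserts 0.7 and 0.55 respectively rather than
overstating.

## Problem sizes and runtime choices

Tests and the pipeline demo run phantoms at a 2×-binned lateral pitch
(0.434 µm) with 4–25 cells per field, template grids of 16³–48³ bins, 200
simulation replicates for calibration checks in the module suites and 500
in the acceptance suite, and 10⁵ samples for coverage calibration. These
sizes were chosen so each property is measured with comfortable
statistical margin; parameter-recovery tolerances (5% at n ≥ 100 cells,
2% for GLM coefficient means) are inherited from the module contracts,
not tuned to outcomes.

## Known limitations

- The surface-area estimator is unreliable for structures thinner than
  ~1 voxel; sphericity of such objects should not be interpreted.
- Gap interpolation copies terminal masks; it does not morph shapes
  across the gap.
- Hexagon alignment assumes footprints that are at least roughly
  hexagonal; heavily concave cells fall below the match-score floor and
  are flagged unaligned rather than force-fitted.
- The morphing scheme (normalized radial/height coordinates) is this
  package's canonical definition; other shape-normalization schemes exist
  and would change PCC values, though not the identities and invariances
  the tests pin down.
- Poisson trend fits on FOV-mean counts round to integers; for rates far
  below 1 per cell the Gaussian-on-means default is the safer choice.
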