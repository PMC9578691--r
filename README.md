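# gastruquant

Quantification toolkit for gastruloid experiments — 2D image morphometry,
anterior–posterior (A-P) expression profiling, and rule-based single-cell
categorization — with seeded synthetic-data generators so every stage can be
validated against known ground truth.

## What it does

Gastruloids are 3D aggregates of embryonic stem cells that break symmetry,
polarize T (brachyury) expression at a posterior pole and elongate.
Quantifying these behaviours requires a chain of bespoke measurements that
`gastruquant` implements as reusable, tested functions:

**Morphometry.** Whole structures are segmented from fluorescence
projections (Gaussian smoothing → Otsu or local-variance thresholding →
hole filling → distance-transform watershed). For each structure the
package reports area, the maximum and minimum Feret (caliper) diameters
computed by rotating calipers on the convex hull, and the elongation index

    EI = Feret_max / Feret_min  (EI ≥ 1; 1 = circular)

Nuclei are segmented from the DAPI counterstain (smoothing, morphological
background subtraction, Otsu, watershed); each nucleus carries its area,
its circularity

    circularity = sqrt(4·A / (π·Feret_max²))

and per-channel intensities normalized to nuclear area. Nuclei are flagged
by the standard filters: area 100–1000 µm² and circularity 0.6–1.

**A-P profiling.** Reporter and DAPI intensity are sampled at 1-px steps
along each structure's midline (principal-axis chord, or a drawn
polyline). Positions are divided by the structure length, the
DAPI-normalized reporter signal is averaged in 0.01-wide bins — exactly
100 bins over the axis — optionally rescaled to [0, 1], and binned profiles
are clustered with Euclidean k-means (k-means++ initialization, 10
restarts, fixed seed). Per-condition rates of "polarized-pole" structures
are summarized from the cluster occupancies.

**Single-cell rules.** On a cells × genes count table: QC filtering
(200–2500 detected features, ≤ 5% mitochondrial fraction), CPM-based gene
filtering (> 0.4 CPM in ≥ 2 samples), neural categorization with explicit
precedence (any of 28 Hox genes → Hox-positive; else ≥ 5 of 30
fore/midbrain markers and no *Fgfbp3* → brain-like; else spinal-cord-like),
mutually exclusive dorsal/midline/ventral module assignment, differential
cell-type abundance (log2 proportion ratios vs a reference condition,
excluding states with < 10 cells across conditions), and pseudo-bulk group
means.

**Synthetic data.** `simulate_gastruloid_image()` renders an elliptical
body (analytic area and Feret ground truth) with Gaussian-blob nuclei and
a logistic posterior reporter gradient; `simulate_cell_table()` plants
marker-defined cell classes with configurable dropout and library noise.
Both are deterministic given a seed and return ground-truth labels.

## Worked example

```r
library(gastruquant)

sim <- simulate_gastruloid_image(image_sim_params(
  body_semi_axes = c(150, 50), pixel_size = 2, seed = 1))
labels <- segment_structures(sim$image, "dapi")
measure_structure(labels, 1)
#>  structure_id  area feret_max feret_min elongation_index
#>             1 23660     300.2     103.9             2.89
```

The simulated body has semi-axes 150 × 50 µm, so its true area is
π·150·50 ≈ 23 562 µm², its Feret diameters are 300 and 100 µm and its true
elongation index is 3: segmentation recovers all three within a few
percent. Profiling the same structure:

```r
prof <- extract_profile(sim$image, labels == 1)
prof
#> <axial_profile structure 1: 151 samples over 299.5 µm>
b <- bin_profile(prof, normalize_to_dapi = TRUE)
round(b[c(1, 25, 50, 75, 100)], 3)
#> [1] 0.006 0.001 0.050 1.404 1.988
```

The 100-bin profile rises from ~0 at the anterior pole to its plateau past
relative position 0.7 — the planted logistic gradient midpoint. And on the
cell side, planted classes are recovered exactly when dropout is zero:

```r
rules <- default_rules()
simc  <- simulate_cell_table(cell_sim_params(
  c(hox_positive = 50, brain_like = 50, spinal_like = 50), seed = 2), rules)
table(classify_neural(simc$table, rules))
#> hox_positive   brain_like  spinal_like
#>           50           50           50
```

A command-line front end (`exec/gastruquant`) exposes the same stages as
subcommands (`simulate-image`, `morphometry`, `profile`,
`cluster-profiles`, `qc-filter`, `classify-cells`, `dv-classify`,
`abundance`, `run`), and `run_pipeline()` executes a whole chain from a
YAML config, writing a manifest with parameters, seed and output hashes.

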