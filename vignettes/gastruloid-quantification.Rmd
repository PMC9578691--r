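---
title: "Quantifying gastruloid morphology, axial polarization and cell-type composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gastruloid morphology, axial polarization and cell-type composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gastruquant)
```

`gastruquant` packages the quantitative procedures used to characterize
gastruloids — stem-cell aggregates that break symmetry, polarize reporter
expression (typically T/brachyury) at a posterior pole, and elongate — into
a tested pipeline: image morphometry, anterior–posterior (A-P) profile
analysis, and rule-based single-cell categorization. This vignette explains
the methods, their assumptions, the tunable parameters, and the design
choices made where the procedures are conventionally under-specified.

## Morphometry

### Whole-structure segmentation

`segment_structures()` applies faint Gaussian smoothing (default sigma
1 µm, configurable because the appropriate amount depends on the imaging
resolution), a global threshold, binary hole filling, and a
distance-transform watershed to split touching structures.

Two thresholding modes are provided. `"otsu"` thresholds smoothed
intensity and suits fluorescence projections, where structures are
uniformly brighter than background. `"variance"` computes a local-variance
map (square window, default 15 px) and Otsu-thresholds *that* map; it
suits brightfield-like images where objects differ from background in
texture rather than mean level. Objects smaller than `min_area`
(default 5000 µm²) are treated as debris and removed — whole gastruloids
are two orders of magnitude larger; the threshold only has to sit well
above nucleus scale.

Watershed seeds are the regional maxima of the distance transform;
`watershed_tolerance` (default 1 px on the distance scale) controls how
deep the valley between two maxima must be before they found separate
objects. The default splits bodies joined by a narrow neck while leaving
single elliptical bodies intact.

### Feret diameters and shape indices

Feret (caliper) diameters are computed by rotating calipers on the convex
hull of the object's *pixel corners* — each pixel contributes its four
corner points, so a square of side *s* pixels has Feret max exactly
*s*√2 and thin objects retain a nonzero minimum caliper. The maximum
caliper is the hull diameter; the minimum is the smallest edge-normal
width, which for a convex polygon is attained at an edge. This choice
makes the closed-form oracles exact: a rasterized disk has circularity
within 2% of 1, a square within 2% of √(2/π) ≈ 0.798, and a 3:1 ellipse an
elongation index within 3% of 3. Single-pixel objects are rejected
(`degenerate object`) because their minimum caliper is not meaningful.

The elongation index is Feret max / Feret min; circularity is
√(4·A/(π·Feret max²)), computed in pixel units (both are scale
invariant — doubling the pixel size doubles the Feret diameters and
quadruples the area but leaves both indices unchanged, a property the test
suite checks).

### Nucleus quantification

`quantify_nuclei()` segments the DAPI counterstain after background
subtraction, implemented as grayscale morphological opening with a disc of
radius `background_radius` (default 50 µm): the opened image — everything
wider than the disc — is the background estimate, and subtracting it
flattens the diffuse body signal while preserving nucleus-scale blobs.
Each nucleus record carries area (µm²), circularity, per-channel mean
intensity and integrated intensity divided by area (at 1 µm pixels the
two coincide; units are intensity/µm² otherwise). The conventional
filters — area 100–1000 µm², circularity 0.6–1 — are *flagged*, not
applied: all nuclei are returned and downstream consumers select
`passed_filters`. Because rasterization can push the circularity of a
near-perfect disk fractionally above 1, values up to 1.05 are clamped to 1
before filtering; values beyond that indicate a measurement problem and
fail the filter honestly.

## A-P profile analysis

### Extraction and orientation

`extract_profile()` samples reporter and DAPI intensity by bilinear
interpolation at 1-px steps along a midline. In `auto` mode the midline is
the principal-axis chord through the mask centroid, clipped to the mask —
a practical stand-in for the manual anterior-to-posterior line an analyst
would draw; a polyline can be supplied for exact parity with that manual
procedure. Because images alone cannot reveal which pole is anterior, the
profile is oriented so the reporter-brighter half sits at relative
position 1 (the posterior convention); an exact tie keeps the original
orientation, making the operation deterministic.

### Binning

Relative positions are absolute positions divided by total midline length.
`bin_profile()` averages samples in 100 bins of width 0.01 — bin *i*
covers [i/100, (i+1)/100), the last bin closed — after optionally dividing
each sample's reporter value by its own DAPI value (floored at 10⁻⁶ of the
DAPI maximum to avoid division blow-ups). Per-sample division *before*
averaging is the conservative reading of "normalized to DAPI and binned";
the alternative (binning both channels first, then dividing bin means) is
nearly identical for dense profiles but less local. Bins that receive no
sample — only possible for very sparse profiles — are filled by linear
interpolation from the nearest occupied bins, so the output is always
exactly 100 finite values. `minmax_scale()` maps a binned profile to
[0, 1] and refuses constant profiles, which carry no shape information.

### Clustering and the polarized-pole call

`cluster_profiles()` runs Euclidean k-means on the binned 100-vectors with
k-means++ initialization and 10 restarts under a caller-supplied seed,
keeping the restart with the lowest total within-cluster sum of squares
(Lloyd iterations). Clusters are renumbered by descending centroid mean so
that "cluster 1" is always the highest-signal group, a stable naming
convention across conditions. If fewer distinct profiles than *k* exist
(e.g. all profiles identical), the result collapses deterministically to
the distinct rows rather than failing.

A cluster is called *polarized* when its centroid's posterior-quartile
mean (bins 76–100) exceeds its anterior-quartile mean (bins 1–25) by more
than `polarized_sd_factor` (default 2) times the SD of all profile values.
The factor-of-2 default asks the posterior excess to stand well clear of
overall profile variability; no published numeric threshold exists for
"T-positive pole", so the heuristic is exposed as a parameter.
`polarization_rate()` then reports, per condition, the exact fraction of
profiles in the polarized cluster.

## Single-cell rules

All "expression" calls are made on raw counts with a configurable
threshold (default: count ≥ 1). Whether such calls should use raw or
normalized data is genuinely ambiguous in common practice; raw counts with
threshold 1 is the most reproducible reading and the threshold is a
`rule_set` field for users who prefer otherwise.

- **QC** keeps cells with 200–2500 detected features *inclusive* — the
  removal rule targets cells with *fewer than* 200 or *more than* 2500 —
  and mitochondrial fraction ≤ 5%. Mitochondrial genes are recognized by
  the case-insensitive "mt-" name prefix.
- **CPM filtering** keeps genes with CPM strictly greater than 0.4 in at
  least 2 samples; a zero-total sample is an error naming the sample.
- **Neural categorization** applies a strict precedence: any expressed Hox
  gene (from a user-editable 28-gene subset) → `hox_positive`; otherwise
  ≥ 5 expressed fore/midbrain markers (of 30) *and* no *Fgfbp3* →
  `brain_like`; everything else → `spinal_like`. Every cell gets exactly
  one label.
- **Dorsal-ventral assignment** is mutually exclusive: a cell joins a
  module iff it expresses ≥ 1 of that module's genes and none of the other
  modules'; cells hitting zero or several modules are `unassigned`, and
  the assigned fraction is reported alongside.
- **Abundance** compares per-condition state proportions as log2 ratios
  against a reference condition, excluding states with fewer than 10 cells
  in total across conditions; a state absent on one side produces an
  explicit ±Inf with a flag rather than silently disappearing. Ratios are
  invariant to duplicating every cell.
- **Pseudo-bulk** averages either raw counts or log1p(counts per 10k) per
  group.

The shipped default marker lists (28 Hox genes across the four mouse
clusters, 30 fore/midbrain markers, three-gene dorsal/midline/ventral
modules) are placeholders drawn from standard mouse nomenclature — the
curated lists used in any real analysis are study-specific and should be
supplied via `rule_set()` or a YAML file.

## The synthetic-data generators

The generators exist so that every downstream stage can be tested against
known ground truth without any external data.

`simulate_gastruloid_image()` renders an axis-aligned elliptical body —
real gastruloids are irregular, but the ellipse admits analytic oracles
(area π·a·b, Feret diameters 2a and 2b). The DAPI channel is a uniform
body plateau (default 500 intensity units, emulating the dense
out-of-focus signal of a projected 3D aggregate; this is what
whole-structure segmentation detects) plus Gaussian nucleus blobs (blob
sigma = radius/2, radii normal with mean 5 µm) placed uniformly in the
ellipse by an affine map of the uniform unit disk. The reporter channel is
a logistic gradient σ(steepness·(p − midpoint)) of relative axial position
(defaults: midpoint 0.7, steepness 20 — a clearly posterior, fairly sharp
boundary), or flat when unpolarized. Additive Gaussian noise (default SD
10, i.e. 1–2% of signal amplitude) is applied last and clipped at zero.
Intensity amplitudes are arbitrary-unit placeholders exposed as
parameters; no published intensity scales exist to match. The RNG is
consumed in documented order (nucleus positions, radii, DAPI noise,
reporter noise), so identical parameters and seed give bit-identical
images.

`simulate_cell_table()` plants one cell class per rule module: each cell
expresses *all* of its class's markers and none of the other classes'.
An "on" marker count is drawn as 1 + Poisson(m·f − 1) with m the requested
mean and f a per-cell gamma library factor — the mean is exactly m·f and
the count is guaranteed nonzero, so with dropout 0 the rule classifiers
recover planted labels with probability 1, which is the property the
recoverability tests rely on (a plain Poisson would miss single-marker
classes with probability e^(−m)). Dropout then zeroes each "on" count
independently. Background genes (including two "mt-" genes so QC
statistics are exercised) receive low Poisson counts in every cell.

What the generators deliberately do **not** model: irregular body shapes,
optics (PSF, depth attenuation), nucleus overlap in projection,
transcriptional correlation between markers, ambient RNA, or doublets.
Passing tests therefore demonstrate correctness of the measurement and
rule logic under controlled conditions, not robustness to every artifact
of real microscopy or sequencing data.

## Problem sizes and verification

The test suite and `scripts/acceptance.R` run entirely on synthetic data:
shape oracles on ~200-px rasters, segmentation recovery on 20 seeded
images (mean absolute relative error of area and elongation index both
well under 5%), profile-cluster recovery on 130 structures (30 planted
polarized among 100 in one condition, none among 30 in a control) through
the full simulate → segment → extract → bin → cluster chain, rule
recovery on a few hundred planted cells, and 100-replicate brute-force
agreement checks for the QC, CPM and abundance filters. These sizes give
stable statistics while keeping a full run in well under a minute; all
stochastic steps take explicit seeds and reproduce byte-identical results.

## Known limitations

- Morphometry is strictly 2D; projections of strongly curved structures
  underestimate length, exactly as in the manual procedure.
- The auto midline is the principal-axis chord, which underestimates arc
  length for bent structures; supply a polyline midline in that case.
- The polarized-cluster heuristic depends on the chosen threshold factor
  when polarization is weak; for clearly polarized data the call is
  insensitive to it.
- Rule-based categorization inherits the marker lists it is given; the
  defaults are nomenclature placeholders, not a curated biological truth.
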