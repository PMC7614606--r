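---
title: "Quantifying ERMES bridge architecture at ER-mitochondria contact sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying ERMES bridge architecture at ER-mitochondria contact sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcsarch)
```

## The measurement problem

Membrane contact sites (MCS) between the endoplasmic reticulum and
mitochondria are held together in budding yeast by the ERMES complex,
whose SMP-domain subunits (Mmm1, Mdm12, Mdm34) form bridge-like densities
spanning the ~24 nm gap between the ER membrane and the outer
mitochondrial membrane (OMM). Two kinds of raw data quantify this
architecture:

* **cryo-electron tomography particle coordinates** — each bridge is
  picked manually as a *dipole*: one anchor point on the ER membrane and
  one on the OMM. All downstream geometry (centre, axis, length, tilt,
  neighbour distances, per-area density) derives from these two points
  per bridge, plus triangulated segmentations of the two membranes;
* **calibrated live fluorescence microscopy** — ERMES components tagged
  with EGFP form diffraction-limited puncta whose background-corrected
  integrated intensity is proportional to the number of fluorophores.
  Against a reference strain of known copy number (the kinetochore
  protein Cse4, 80 EGFP molecules per anaphase spot), intensities convert
  to absolute molecule counts.

`mcsarch` implements both quantification chains as reusable, tested
functions, together with a synthetic-data generator that produces
ground-truthed scenes and image stacks, so every stage can be validated
without any experimental download.

## Dipole geometry and bookkeeping

A `particle_table` holds one row per bridge with the two anchors in nm.
`dipole_to_particle()` derives the centre (anchor midpoint), the unit
axis, and the length (anchor distance). Conventions:

* **Axis orientation** is fixed ER→OMM. No published convention exists;
  all angle computations use `|axis · normal|`, so the choice is
  observable only in exported tables.
* **Length classification** (`classify_by_length()`) sorts ascending by
  length and splits into equal halves (short/long). For odd N the short
  class takes the extra particle; equal lengths are tie-broken on
  `(tomogram_id, bridge_id)` so classes are identical across runs and
  platforms.
* **Flag filtering** (`filter_particles()`) removes picks flagged as
  misaligned (subtomograms that migrated onto a membrane during
  alignment) or as belonging to ER-peroxisome contact sites; counts
  removed per flag accumulate in the table's provenance, so a session
  that starts from 1133 picks and drops 25 + 10 ends, verifiably, at
  1098.
* **Units are nm throughout.** Readers accept a `pixel_size_nm` factor
  for tables picked in voxel units, since all reported statistics are in
  nm.
* **MAD everywhere means the unscaled median absolute deviation**,
  `median(|x − median(x)|)`, with no 1.4826 consistency factor — the
  convention used when medians and MADs are reported side by side on the
  same scale.

## Spatial statistics within contact sites

`nn_distances()` computes, per tomogram and per point kind (ER anchors,
centres, OMM anchors), each bridge's 3-D Euclidean distance to its
nearest same-kind neighbour. Tomograms with fewer than
`min_per_tomogram = 3` bridges are excluded (one- and two-bridge
tomograms carry no usable neighbour structure); the same eligibility rule
applies to all three point kinds. Distances are Euclidean in tomogram
space, not geodesic along the membrane.

`class_contingency()` cross-tabulates each bridge's length class against
its nearest neighbour's class and applies Pearson's chi-square without
continuity correction (df = 1). **A calibration caveat is important
here**: nearest-neighbour contingency tables contain duplicated
information because a large fraction of bridges (about 60% under complete
spatial randomness) are *reciprocal* nearest-neighbour pairs, and each
pair contributes two dependent rows. The Pearson statistic therefore runs
above its nominal chi-square(1) reference: under label permutation the
5%-level rejection rate is reproducibly near 12%, not 5%. The package
implements the statistic exactly (the 2×2 closed form
N(ad−bc)²/(r₁r₂c₁c₂) is pinned to 1e-9 in tests) and the test suite
asserts the anti-conservative behaviour rather than pretending
nominality. Conclusions should rest on effect sizes far from the
rejection boundary, as is the case for strong short/short–long/long
clustering.

`surface_area()` sums ER mesh triangles whose centroid lies within
`d_contact = 40` nm of the OMM mesh — an explicit, parameterised
counterpart of manually segmenting "the membrane in proximity" to the
other organelle. `area_per_bridge()` divides per-MCS contact area by
bridge count and pools across MCS as median ± MAD, also reporting
bridges per 10,000 nm². `uniform_spacing()` converts an area-per-bridge
A into the nearest-neighbour spacing of the *hexagonal* lattice,
`sqrt(2A/√3)`: the densest equal-spacing arrangement, chosen because
"equally distributed" names no lattice and the hexagonal form reproduces
the ≈40 nm figure at A = 1407 nm² (a square lattice gives 37.5 nm).

```{r spacing}
uniform_spacing(1407)
```

## Bridge tilt

The tilt of each bridge relative to a membrane is the acute angle between
its axis and the local membrane normal, `acos(|axis · normal|)`.
`local_normal()` estimates the normal by a total-least-squares plane fit
to mesh vertices within 20 nm of the anchor (the order of a bridge
footprint; configurable), widening once to 40 nm if fewer than three
vertices are found, and orients it toward the bridge centre (the
cytosolic side). This is a continuous geometric surrogate for the
experimental approach of re-aligning subtomograms to the membrane in 5°
zenith steps over ±60°: experimental values are quantised to 5° and
truncated at 60°, while the geometric angle is neither, so agreement with
published distributions is expected to be approximate, not exact.

On flat synthetic membranes the recovered per-bridge tilt equals the
generator's drawn tilt to machine precision; on spherical caps of radius
≥ 100 nm it is accurate within 3° (the residual is curvature bias of the
plane fit over the 20 nm neighbourhood).

## Molecule counting from fluorescence

`detect_puncta()` follows the standard spot-quantification recipe; the
reference implementation's internals are under-documented, so the
package fixes and exposes every choice:

* background subtraction by per-slice median filter, kernel radius
  `ceil(4·σ_xy)` voxels;
* candidates are 3-D local maxima (26-neighbourhood) above `k = 5`
  robust SDs of the residual (a numerical floor of 1e-4 of the residual
  peak guards noise-free images against filter quantisation ripple);
* per punctum, intensity is the raw-count sum in an ellipsoidal mask of
  radius `r_mask = 2σ_xy` minus the median of the surrounding annulus
  (`r_mask`–`2·r_mask`) times the mask voxel count, so local background
  cancels;
* intensities are measured as 3-D masked sums rather than in a single
  best-focus plane — the punctum's total signal is the quantity
  proportional to copy number.

`calibrate_counts()` converts intensities to molecules via
`molecules = 80 × I / median(I_ref)`; the calibration is exactly
invariant to any common rescaling of intensities, and negative
background-corrected intensities are retained raw (and clamped copies
reported) because medians are robust to them. `summarize_strain()`
reports per-repeat median ± MAD and the across-repeat mean of medians ±
sample SD. `intensity_correlation()` matches puncta across channels by
mutual nearest centroid within 3 voxels and reports Pearson r with its
two-sided t-transform p-value.

`total_mito_fluorescence()` reproduces the corrected-total formula per
z-slice: an adaptive local-mean threshold (block 25 px, offset 0; the
offset carries a 1e-6 numerical floor so numerically flat regions cannot
cross threshold through FFT round-off) binarises the mitochondrial
marker channel inside a circular cell ROI, and the green integrated
density inside the mask is corrected by mask area × mean background
(ROI∖mask). The correction makes the total exactly invariant to a
constant offset in the green channel; slices whose mask swallows the
whole ROI have no background estimate and are excluded with a warning.

## The synthetic generator: what it emulates, and what it does not

`generate_scene()` builds a membrane pair (flat, spherical cap, or
saddle; the OMM surface offset by the intermembrane gap along local
normals), places ER anchors by either complete spatial randomness (CSR;
homogeneous Poisson on the mesh via area-weighted triangle sampling) or
a Thomas cluster process (Poisson parents, Gaussian offspring displaced
in the tangent plane and projected back to the surface, discarded if off
the patch), then draws per-bridge lengths (truncated normal) and tilts
(folded normal, azimuth uniform) and places the OMM anchor accordingly.
Defaults mirror the measured architecture: gap 24.2 nm, lengths
24.2 ± 4.76 nm truncated to the observed 9.4–52 nm range, 24 expected
bridges per MCS on a 200 nm patch, tilt scale 16°. The tilt
*distribution shape* is a modelling choice — only medians and MADs are
published — and is exposed in the configuration.

`generate_fm_stack()` renders puncta as 3-D Gaussians (analytically
normalised, so the noise-free integral equals molecules × counts per
molecule within truncation error), adds diffuse background, and applies
a Poisson/gain/offset camera model; two-channel mode draws per-punctum
molecule counts with configurable log-scale correlation. The default
per-molecule intensity (200 counts) places default stacks at peak SNR ≈ 7,
inside the detector's specified operating regime (SNR ≥ 5). A
`min_separation` option generates stacks in which every punctum is
individually resolvable. `generate_mito_cell()` grows a random-walk tube
as the true mitochondrial mask inside a circular cell.

What passing tests on these scenes *do* show: the estimators are
unbiased and correctly calibrated on data whose generating process is
known, including CSR nulls (the pooled NN median matches the 2-D Poisson
closed form `sqrt(ln 2/(πλ))` within 5%) and clustered alternatives.
What they *do not* show: robustness to the ways real data depart from
the generator — membrane segmentation error, anisotropic tomogram
resolution and missing-wedge effects, picking bias near membrane edges,
spatially varying cytosolic background, or camera artefacts beyond
Poisson-gain-offset. Conclusions about real data still require the
controls the experimental workflow uses (reference strains imaged in the
same session, per-tomogram inspection of alignments).

**Randomness.** Every generator takes an integer seed; identical
(parameters, seed) give byte-identical outputs, which is asserted by
hash-comparison tests. Each generator call uses one seeded stream; the
pipeline derives per-tomogram sub-seeds deterministically from the run
seed, so per-tomogram scenes are independently reproducible. Per-object
sub-streams inside a single scene were considered and rejected as
needless complexity at these object counts.

## Numerical choices and degenerate inputs

* Coincident dipole anchors, non-finite coordinates, non-unit axes
  (beyond 1e-6), unknown flags, empty masks and zero-variance grids all
  raise typed errors (`mcsarch_error` subclasses) rather than producing
  numbers.
* Truncated-normal lengths are drawn by rejection (the acceptance region
  covers > 99% of the mass at default parameters); tilt draws ≥ 90° are
  redrawn; OMM anchors falling outside the scene bounding box laterally
  are redrawn up to 100 times before a degenerate-geometry error.
* The classification tie-break, the odd-N rule, and the hexagonal
  lattice choice are stated above; the `ccc` mask is taken from the
  reference grid only (threshold at its mean by default), since a mask
  defined by the model grid would let the model choose its own scoring
  region.
* The combined model score is the plain mean `(ccc + voroMQA)/2` of the
  values as given; voroMQA is consumed as an externally computed number
  and is not renormalised before averaging.

## Problem sizes used in the test-suite

Property suites run at deliberately desk-scale sizes chosen to keep the
3-SE statistical tolerances meaningful: 200 CSR scenes (~35,000 bridges
pooled) for the NN-median closed form, 100 paired scenes for the
clustering comparison, 1000 label permutations for the chi-square
calibration study, 3 repeats × 200 puncta for molecule-count recovery,
~1100 pooled bridges for tilt recovery at the in-situ scale, and 20
synthetic cells for total-fluorescence recovery.

## Known limitations

* The geometric tilt is a surrogate for the experimental re-alignment
  angle; the two agree only up to the experimental procedure's 5°
  quantisation and ±60° search bound.
* The NN class chi-square is anti-conservative (see above); the package
  reports it for comparability but the test suite documents the true
  rejection rate under permutation.
* Contact-area filtering measures centroid-to-vertex proximity, adequate
  while mesh edge lengths are well below the 40 nm contact threshold.
* The spot detector assumes an isotropic Gaussian PSF per axis pair and
  a single fluorophore species; no chromatic or flat-field corrections
  are applied.
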