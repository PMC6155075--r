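---
title: "Measuring 3D chromatin organisation from FISH stacks: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring 3D chromatin organisation from FISH stacks: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fociquant)
```

## The measurement problem

DNA FISH marks two or three genomic sites with fluorescent probes and asks,
cell by cell, how far apart the marked loci sit in the nucleus, how much
space each hybridisation signal occupies, and how strongly the signals
overlap. Changes in these readouts across cell states — for instance the
extremities of a self-interacting chromatin domain drawing together while
the domain body decompacts — are the biology; the package's job is the
quantification that sits between the microscope and those statements.

The pipeline takes multi-channel 3D stacks (deconvolved widefield at a
64.5 × 64.5 × 150 nm voxel by default), a table of seed points marking
candidate foci, and a bead-field calibration, and produces per-locus
tables of distances, volumes, Pearson coefficients and (for triples)
vertex angles, plus group-level statistics.

## Pipeline stages and their assumptions

### Chromatic calibration

Different fluorophores image through slightly different optical paths, so
the same physical object appears displaced between colour channels. The
calibration images a field of sub-resolution multi-fluorescent beads,
detects each bead in both channels, matches beads across channels by
mutual nearest neighbour within a 500 nm gate (well below bead spacing,
above plausible offsets), and takes the **mean displacement vector** as
the offset; the RMS of per-bead residuals is reported as a quality figure.

The model is translation-only. Field-dependent aberration (scaling,
rotation, higher-order distortion) is deliberately out of scope: the
correction mirrors what a single "apparent offset" calibration can
support, and the residual quantifies what the model leaves behind.
Correction is applied to the whole moving channel by trilinear
interpolation, with shifted-in border voxels filled with the channel's
background median (avoiding artificial dark rims in crops near edges). A
coordinate-level fast path (`correct_points()`) subtracts the offset from
measured centroids instead; it agrees with image-level correction to
about a tenth of a voxel — not better, because trilinear resampling
slightly flattens a spot's peak and the clip-and-threshold mask shifts
with it.

### Sub-volume extraction

Each focus is measured inside a 20 × 20 pixel × 7 z-step crop centred on
its seed (for even sizes the seed sits at index `floor(n/2)`). Crops that
would cross a stack boundary are rejected by name — the method only
measures interior loci. Positions are voxel centres and all external
coordinates are 0-based (x, y, z); neither choice shifts any distance.

### Segmentation, centroid, volume

Within a crop: clip at the nearest-rank 96.5th-percentile intensity (the
top 3.5 % of voxels saturate — on a 2800-voxel crop, exactly 98 voxels),
threshold at 90 % of the post-clip maximum (inclusive, which makes the
enumerable oracle exact), keep one 26-connected component, centroid by
post-clip intensity weighting, volume as voxel count times exact voxel
volume. Published descriptions of this family of scripts are ambiguous on
three points, so both readings ship:

- **Clip rule**: percentile (default) or fraction-of-max
  (`clip_mode = "fraction_of_max"`). The percentile reading matches the
  stated purpose of suppressing a few noisy pixels.
- **Centroid weighting**: intensity-weighted (default; the standard
  sub-voxel estimator) or binary (`centroid_weighting = "binary"`).
- **Component policy**: largest component, ties broken by proximity to the
  crop centre (default), or nearest-to-centre.

A result is flagged **degenerate** — excluded from summaries, never an
exception — when the mask has fewer than 5 voxels, covers more than half
the crop, or touches a crop border covered by `border_policy`. The default
policy checks x/y borders only. This is a deliberate choice: with the
spot scale this pipeline assumes (σ_z ≈ 300 nm against a 150 nm z-step),
the above-threshold region of a perfectly good focus spans roughly ±3
z-steps and therefore reaches the first or last plane of a 7-step crop
almost always, *without being truncated by it*. Flagging axial contact
would discard essentially every sound focus; the strict policy remains
available as `border_policy = "all"`.

Table-level drivers (`measure_pairs()`, `measure_triples()`) **re-centre
each crop once** on the first-pass centroid. Seed points emulate manual
clicks and may sit up to 2 voxels off; a 7-plane crop centred 2 z-steps
off-focus does truncate the mask and biases the axial centroid, and one
re-centring pass removes that truncation. Per-operation contracts are
unchanged; `recenter = FALSE` restores single-pass behaviour.

### Distances, colocalization, angles

Distances are Euclidean, in nm, between physical-frame centroids. Pearson
colocalization is computed on the *raw* intensities — chromatically
aligned but unclipped and unthresholded — over congruent 20 × 20 × 7 crops
of the two channels; the package takes them at the rounded midpoint of the
two measured centroids, so the same physical region enters both vectors.
Zero-variance crops yield an undefined (`NA`) coefficient, counted and
excluded. Vertex angles for probe triples come from the law of cosines on
the three centroids, with the cosine clamped to [−1, 1] against floating
error; a vertex coincident with an arm is an error because the angle is
undefined. `random_angle_baseline()` gives the null reference: for three
points placed independently and uniformly at random the three triangle
angles are exchangeable and sum to 180°, so the expected vertex angle is
60°.

### Group statistics

Summaries are medians with interquartile ranges (type-7 linear
interpolation quartiles — no convention was mandated, this is R's
default and is stated here so results are reproducible elsewhere).
Volume distributions are cumulative frequency curves with bin edges at
exact multiples of the voxel volume, right-inclusive. Group differences
use the tie-corrected Kruskal–Wallis H (via `stats::kruskal.test`) with
Dunn's pairwise z tests on mean ranks; the multiplicity adjustment is
Bonferroni by default — matching the commercial statistics package such
studies typically cite — with Holm as an option, and adjusted p values are
capped at 1. For very small samples the chi-square p is rough, so
`p_method = "permutation"` computes the global p by exhaustive enumeration
of group assignments (up to a configurable budget) or Monte-Carlo
permutation beyond it. All-identical data give the degenerate null result
(H = 0, p = 1, flagged) rather than an error.

## The synthetic-scene generator

The generator is first-class, tested code: it defines the conditions under
which every quantitative claim about the pipeline is made.

- **Spots** are anisotropic 3D Gaussians, σ_xy = 130 nm and σ_z = 300 nm
  by default, peak 200 counts — an idealisation of a deconvolved
  widefield point image chosen so a rendered focus covers well over 98
  voxels of its crop above threshold, the regime the 96.5 % clip rule
  presumes.
- **Noise** is Poisson shot noise on the signal plus Gaussian readout
  background (mean 5, sd 2 counts; deconvolved images carry near-zero
  background), with intensities rounded to integer counts as a camera
  would. No spatially correlated background, no autofluorescence, no
  deconvolution artefacts.
- **Geometry**: pair loci place one spot per channel at a drawn true
  separation in a uniformly random 3D direction; triple loci place a
  vertex spot (channel 2) and two arm spots (channel 1) with independently
  drawn arm lengths and vertex angle; `triple_random` places three i.i.d.
  uniform points for the 60° baseline experiment. Loci sit on an interior
  grid with per-axis margins — (14, 14, 8) voxels by default — sized so
  every jittered seed's crop stays inside the stack.
- **Seed points** are rendered positions rounded to voxels and jittered by
  a uniform integer in [−2, 2] per axis, emulating manual clicking without
  modelling a human.
- **Beads** are solid spheres convolved with an isotropic Gaussian
  (closed-form radial profile), stretched axially by σ_z/σ_xy to mimic
  PSF anisotropy; 100 nm diameter for calibration fields, 500 nm for
  volume validation, spaced at least four diameters (and 1.5 μm) apart.
- **Determinism**: every scene is a pure function of its parameters and
  seed; a fixed seed reproduces stacks, truth and seeds bit-for-bit.

What passing tests on these scenes shows: the measurement code recovers
known geometry to well under a voxel at realistic signal-to-noise, the
calibration recovers applied offsets, and the statistics discriminate
separations that real experiments of this kind discriminate. What it does
not
show: robustness to the features real nuclei add — textured chromatin
background, variable probe efficiency, replicated (doubled) signals,
overlapping neighbouring loci — nor anything about segmentation bias under
a mis-specified PSF. Those require real, annotated data.

## Numerical choices and degenerate inputs

- Threshold comparison is inclusive (≥); clip value is the nearest-rank
  percentile (rank `ceiling(p/100 · n)` of the sorted crop).
- Component ties go to the component nearest the crop centre.
- All-zero crops error (nothing to segment); constant non-zero crops
  return a full-coverage mask flagged degenerate.
- Volume conversion is exact arithmetic; with the default voxel,
  1 voxel = 6.240375 × 10⁻⁴ μm³, and cumulative-volume bin edges are exact
  multiples of it.
- Trilinear shifts at integer-voxel offsets reduce to exact pixel moves;
  zero offsets return the input bit-for-bit.
- z-resampling (`resample_zstep()`) linearly interpolates planes over the
  same physical depth, giving `floor(depth/dz') + 1` planes.
- The axial-tolerance report defines per-locus spread as max − min of the
  distances re-measured at the requested z-steps and summarises it by the
  median. Note that producing the variants by *resampling* one stack (the
  only option without re-acquisition) adds interpolation error of its own,
  so this tolerance is an upper bound on what matched acquisitions would
  show; the pipeline's distance accuracy itself is benchmarked directly,
  against ground truth, by `evaluate_recovery()`.

## Problem sizes

The test suite and the acceptance script run, by design, at desk scale:
10,000 random triples for the angle baseline; 100 paired-spot loci
(separations uniform on 300–1000 nm) for the distance benchmark; 20
replicate cohorts of 2 × 50 loci for the group-discrimination property;
20 seeds for estimator-bias checks; brute-force oracles on crops of at
most a few thousand voxels. These sizes give Monte-Carlo error comfortably
inside the asserted tolerances while keeping a full run to minutes on one
core.

## Known limitations

- Translation-only chromatic model; no spatially varying aberration.
- No spot-model fitting (Gaussian/ellipsoid): centroiding replaces it, by
  design, and will be biased for strongly overlapping same-channel foci —
  triples whose arm foci sit closer than the optical scale merge and are
  measured as one.
- No nucleus segmentation, no cell-cycle QC: the degeneracy flags are an
  automated stand-in for the visual per-locus inspection such pipelines
  traditionally rely on.
- Vendor image formats (`.lif`, `.dv`) must be converted to TIFF/OME-TIFF
  externally; voxel metadata travels in a JSON sidecar, and an explicit
  override always wins.
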