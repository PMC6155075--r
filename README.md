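# fociquant

Quantification of 3D chromatin organisation from multi-channel DNA FISH
image stacks: inter-probe distances, signal volumes, colocalization and
probe-triple angles, with the group statistics used to compare cell states
— plus a synthetic-scene generator so the whole pipeline is verifiable
against known ground truth without any real imaging data.

## Who this is for

Groups measuring locus-scale nuclear architecture (e.g. the formation and
decompaction of a self-interacting chromatin domain across differentiation)
by hybridising fluorescent probes to pairs or triples of genomic sites and
imaging deconvolved widefield or STED z-stacks. The package re-implements,
as tested and reusable R functions, the image-quantification procedure such
studies run as ad hoc scripts.

## The method

For each candidate locus, a **20 × 20 pixel × 7 z-step sub-volume** is
extracted around a seed point, per channel, at a voxel geometry of
**64.5 × 64.5 × 150 nm** (configurable). Segmentation of each focus then
proceeds as:

1. **Clip**: intensities above the nearest-rank **96.5th percentile** of
   the crop are saturated to that value, suppressing noisy bright pixels
   (a fraction-of-max mode is also provided).
2. **Threshold** at **90 % of the post-clip maximum** (inclusive); the
   mask keeps one 26-connected component.
3. **Centroid**: the post-clip intensity-weighted mean voxel position,
   reported in nm in the parent stack's frame.
4. **Volume**: `n_voxels × (dx·dy·dz) / 1e9` μm³ — one default voxel is
   exactly 6.240375 × 10⁻⁴ μm³.

From the segmentations the pipeline reports, per locus:

- the **inter-centroid 3D Euclidean distance** between the two channels'
  foci (the proximity readout);
- **Pearson's correlation** of the raw (aligned, unclipped, unthresholded)
  20 × 20 × 7 intensities of the two channels (the overlap readout);
- for probe triples, the **vertex angle** θ from the law of cosines,
  `c² = a² + b² − 2ab·cos θ`, where a and b are the vertex-to-arm
  distances (for randomly arranged triples the expected vertex angle is
  60°, the baseline against which measured angles are judged non-random).

Before measurement, a **chromatic offset** between colour channels is
calibrated from a two-channel field of 0.1 μm multi-fluorescent fiducial
beads (mutual-nearest-neighbour matching of bead centroids, translation
model) and the moving channel is re-aligned by trilinear interpolation.

Group comparisons use medians with interquartile ranges, cumulative volume
distributions binned in exact voxel-volume increments, and the
**Kruskal–Wallis test with Dunn's multiple comparisons** (Bonferroni
adjusted, with an exact-permutation option for small samples).

The synthetic-data module renders anisotropic Gaussian foci
(σ_xy 130 nm, σ_z 300 nm), blurred-sphere beads, per-channel chromatic
offsets, Poisson shot noise and Gaussian readout background, and emits
ground-truth tables — every measurement stage is tested against these
known truths.

## Worked example

Simulate 25 probe pairs with a (100, −50, 80) nm chromatic offset,
calibrate from a synthetic bead field, correct, measure, and score against
ground truth:

```r
library(fociquant)

sc  <- make_spot_scene(scene_params(n_loci = 25,
                                    chromatic_offset_nm = c(100, -50, 80),
                                    seed = 42))
bf  <- make_bead_field(bead_field_params(applied_offset_nm = c(100, -50, 80),
                                         seed = 1042))
cal <- estimate_offset(bf$stack)
cal
#> <chromatic_offset> ch1 -> ch2: (99.60, -49.35, 81.49) nm from 12 beads
#>   (0 unmatched), RMS residual 13.62 nm

m <- measure_pairs(sc$stack, sc$seeds, calibration = cal)
dplyr::select(m, locus_id, distance_nm, pearson_r, volume_a_um3, valid)
#> # A tibble: 25 x 5
#>   locus_id distance_nm pearson_r volume_a_um3 valid
#> 1 locus001        793.   -0.0913       0.0711 TRUE
#> 2 locus002        884.   -0.0976       0.0699 TRUE
#> 3 locus003        932.   -0.108        0.0711 TRUE
#> 4 locus004        684.    0.0405       0.0699 TRUE
#> # ...

evaluate_recovery(m, sc$truth)
#> <recovery_report> 25 loci used (0 flagged): bias 0.30 nm, RMSE 7.16 nm,
#>   median |error| 2.70 nm
```

The calibration recovers the applied offset to a few nm; after correction
the measured distances match the true 300–1000 nm separations with a
median absolute error of ~3 nm — far inside one voxel. `summarize_pairs()`
gives per-group medians/IQRs, `kruskal_dunn()` the group test (with
`tidy()`/`glance()` methods), `volume_cdf()` + `autoplot()` the cumulative
volume curves, and `run_pipeline()` orchestrates
simulate → calibrate → measure → stats from a single (YAML-able)
configuration. A thin command-line wrapper with `simulate`, `calibrate`,
`measure`, `stats`, `recover` and `demo` subcommands is installed at
`inst/cli/fociquant.R`.

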