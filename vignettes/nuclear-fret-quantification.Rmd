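---
title: "Quantifying nuclear FRET biosensors in 3D: methods and design notes"
author: "fretquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nuclear FRET biosensors in 3D: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fretquant)
```

## The measurement problem

Genetically encoded FRET biosensors report an analyte concentration through
the ratio of two fluorescence channels: donor-excited acceptor emission
(`DxAm`, the FRET channel) over donor-excited donor emission (`DxDm`).
Ligand binding changes the conformation of the sensor and with it the
efficiency of energy transfer, so the **emission ratio** `DxAm/DxDm` rises
(positive-ratio-change sensors) or falls with ligand concentration. When the
sensor carries a nuclear localization signal, the in-tissue signal is a
field of bright, roughly ellipsoidal puncta — one per nucleus — over dimmer,
spatially varying background. A third channel, acceptor-excited acceptor
emission (`AxAm`), reads sensor abundance independently of FRET and is the
preferred segmentation channel: it is bright wherever sensor is expressed
and is insensitive to the ratio itself.

`fretquant` turns a multichannel 3D stack into a per-nucleus results table:
segment the puncta, pool each nucleus's voxels, and report one emission
ratio per nucleus. Working per nucleus rather than per voxel suppresses
shot noise and avoids pathological voxelwise ratios at dim voxels.

## Segmentation pipeline

`segment()` composes, in order:

1. **Difference of Gaussians** (`dog_filter()`): the segmentation channel is
   blurred at two scales and the wide blur is subtracted. This is a
   band-pass filter matched to blob-like objects: constant background is
   annihilated exactly and structures much larger than `dog_sigma_large`
   are strongly suppressed. Defaults are `dog_sigma_small = 1` and
   `dog_sigma_large = 4` voxels, suited to nuclei of roughly 3–6 voxels
   radius; kernel size must in practice be tuned to magnification and
   noise, which is why both sigmas are first-class, logged settings. When
   the stack carries a physical `voxel_size`, sigmas are interpreted in
   units of the finest axis and divided by each axis's relative spacing, so
   one setting transfers across anisotropic acquisitions.
2. **Optional white top-hat** (`tophat_filter()`): subtracts the
   morphological opening with a voxel ball, removing residual broad
   background wider than `2 * tophat_radius`. Off by default; useful when
   autofluorescent structures survive the DoG.
3. **Thresholding** (`binarize()`): Otsu's criterion by default, with
   triangle, Yen, mean and manual alternatives. Thresholds are applied to
   the DoG response with a strict `>` comparison, and the resolved
   threshold value is recorded in the run log, so a manual re-run can
   reproduce an automatic one exactly.
4. **Optional 3D watershed** (`watershed_split()`): recommended for dense
   tissue where nuclei touch; harmless but unnecessary for sparse fields.
5. **Lost-object recovery** (`find_lost_objects()` +
   `merge_lost_labels()`): see below.
6. **Connected components** (`label_components()`): 26-connectivity by
   default (6 available), deterministic raster-scan label order.
7. **Constrained dilation** (`constrained_dilate_relabel()`): restores
   watershed-shrunken objects to their full thresholded extent.
8. **Minimum size filter**: final objects smaller than `min_voxels`
   (default 5) are discarded — a guard against hot pixels — and labels are
   renumbered contiguously. The filter runs after lost-object merging so
   recovered objects are subject to the same rule.

### Watershed construction

The splitting transform is marker-controlled: markers are the regional
maxima of the exact Euclidean distance transform (EDT) of the binary map
(plateaus merged into single markers by 26-connected components), and
Meyer's flooding algorithm runs on the negated EDT, restricted to the
binary foreground. Voxels reachable from two different markers become
watershed lines and are dropped from the split map, so touching nuclei come
apart along the neck between them. Priority ties during flooding are broken
by insertion order, making the result fully deterministic.

The regional-maximum window radius (`marker_radius`, taken as
`ceiling(dog_sigma_small)` inside `segment()`) controls marker suppression:
within that Chebyshev window, a voxel is a marker only if no neighbour has
a larger EDT value. A small object sitting close to a much larger one can
have its only maximum suppressed by the neighbour's larger EDT values, in
which case the watershed erases it entirely. This is precisely the failure
mode the lost-object stage repairs: a pre-watershed connected component
with **zero** surviving voxels is declared lost, carried through as a mask,
and appended to the label map with a fresh id after labelling. Partially
surviving components are not lost — their missing voxels are recovered by
constrained dilation instead — so no object is counted twice.

### Constrained dilation and the no-shrinkage guarantee

Watershed lines and flooding order leave split objects smaller than their
thresholded extent. Labels are therefore grown in synchronous 6-connected
single-voxel steps into *unlabelled* voxels only, masked by the original
threshold map at each step, until no unlabelled foreground voxel touches a
label. Existing labels are never overwritten, and simultaneous claims on a
voxel resolve to the lowest label id — deterministic and order-independent.
The result: the final labelled foreground equals the original threshold
foreground (union the lost components), objects are split but not shrunk,
and re-running the pipeline bit-reproduces the label map.

## Ratio measurement

`measure_rois()` reports, per nucleus: centroid and voxel count over all of
its voxels; mean `DxDm`, `DxAm` and (when present) `AxAm` over its
*analysed* voxels; and the emission ratio. Design choices that matter:

* **Saturation exclusion.** A voxel at the maximum representable value
  (`2^bit_depth - 1`) in *either* donor-excitation channel is excluded from
  the statistics of *both* channels — a clipped numerator or denominator
  invalidates the voxel's contribution to the ratio as a whole. An object
  whose every voxel is excluded keeps its row with `emission_ratio = NA`
  and `ratio_defined = FALSE`: flagged, never dropped.
* **Ratio of means, not mean of ratios.** The per-nucleus ratio is
  `mean(DxAm) / mean(DxDm)` over the analysed voxel set. Pooling before
  dividing weights each voxel by its actual signal and avoids the unstable
  voxelwise ratios of dim voxels. It also makes the ratio exactly covariant:
  scaling `DxAm` by k scales every defined ratio by exactly k.
* **`AxAm` is reported, never used in the ratio** — it is an expression
  control and segmentation channel only.

Image products mirror the results table: a ratio stack painting each
nucleus's ratio into its voxels (undefined ratios paint 0, background is
0), a maximum Z projection, and a nearest-point Z projection that shows,
per XY position, the ratio of the labelled voxel with the smallest z index.
"Nearest" is a convention, not a physical fact — which end of the stack
faces the objective depends on the acquisition — so it is configurable
(`nearest = "top"` or `"bottom"`) and logged. Ratio images are exported as
16-bit integers after multiplying by 1000 and rounding half away from zero
(bit-stable across platforms); the inverse read divides by 1000, so the
round-trip error is at most 0.0005 ratio units over the representable range
0–65.535.

## ROI categories

`assign_by_table()` and `assign_by_mask()` attach biological categories
(root zones, cell types, treatments) to segmented nuclei, replacing
interactive clicking with CSV tables and named region masks. At most **10
distinct categories** may be in play at once — a deliberate, hard-validated
capacity that keeps downstream group comparisons legible — with the
reserved category `"unlabelled"` (not counted toward the 10) marking
untouched objects. Mask assignment uses majority voxel coverage with
alphabetic tie-breaking; `remeasure()` re-runs the measurement on a new
stack and carries categories over by id, reporting orphaned ids rather than
dropping them.

## Titration calibration

`fit_hill()` calibrates a sensor from a titration series (concentration,
replicate, ratio) by least squares on the single-site isotherm

$$R(c) = R_{min} + (R_{max} - R_{min}) \frac{c^n}{K_D^n + c^n},$$

with the Hill coefficient fixed at `n = 1` by default (one independent
binding site) and optionally free in `[0.5, 4]`. The fitted dynamic range
is reported as the signed percent **ratio change**
`100 (R_max - R_min) / R_min`, computed from the fitted asymptotes rather
than from the extreme measured points, so it does not depend on how far the
titration happened to be carried.

Numerical choices: replicates are fitted as pooled points, so replicate
scatter propagates into the standard errors; concentration 0 is evaluated
exactly as `R(0) = R_min` with no log transform anywhere; starting values
come from the per-concentration means (`r_min`/`r_max` from the extremes,
`kd` from the concentration nearest the midpoint response) with `kd`
bounded in `(0, 10 * max(c)]`; optimization is Levenberg–Marquardt
(`minpack.lm`) with tight tolerances. A series with no response change
makes `kd` unidentifiable and is returned immediately with
`converged = FALSE` and an explanatory message — degenerate inputs are
flagged, never silently fitted. Emission-band ratios from spectral sweeps
(`band_ratio()`) average the 525–535 nm acceptor band over the 480–490 nm
donor band, bounds inclusive, and refuse scans that do not cover a band.

## The synthetic scene generator

Every stage above is validated against `generate_scene()`, which renders
ground-truthed scenes: solid ellipsoidal nuclei of constant expected
intensity (donor channel `dxdm_intensity`, FRET channel
`true_ratio * dxdm_intensity`, expression channel `axam_intensity`) over a
flat or linearly tilted background, with optional additive Gaussian noise,
Poisson counting noise (drawn from the noiseless expectation, then clipped
to the representable range), and injected saturation (a chosen fraction of
nucleus voxels forced to `2^bit_depth - 1` in the FRET channel, where real
detectors clip first). Voxels claimed by overlapping ellipsoids go to the
nucleus whose center is nearest in radii-scaled coordinates, with exact
ties to the lowest id — deterministic and independent of evaluation order
except at exact ties. Scenes are bit-identical for identical spec and seed.

Benchmark scenes (`random_nuclei()`) place non-overlapping spheres with
ground-truth ratios drawn on a 0.001 grid, the same milliratio resolution
as the 16-bit export convention. With the default `dxdm_intensity = 1000`
this makes every ground-truth ratio exactly representable in the integer
channels, so on noise-free, offset-free scenes the pipeline must recover
ratios *exactly* (the test suite requires agreement within 1e-6) — any
discrepancy is a real defect, not quantization. With a nonzero background
offset, thresholded halo voxels just outside a nucleus carry background
signal and introduce a small dilution bias (about 4 parts in 10⁴ at offset
50 against signal 1000 in our validation scenes); this is an inherent
property of threshold-based segmentation, stated here rather than hidden,
and is two orders of magnitude below the noisy-scene tolerance.

What the generator deliberately does **not** emulate: optics (no point
spread function, so nucleus edges are one voxel sharp where real images are
blurred), light-sheet stripe artifacts, depth-dependent attenuation,
chromatic mis-registration, and multi-timepoint drift. Passing tests
therefore demonstrate the correctness of the algorithms under controlled
conditions, not robustness to every artifact of a real microscope; on real
data the DoG sigmas and threshold method remain the user's responsibility,
which is why every run writes a settings log.

Validation problem sizes: unit tests run scenes up to 32 × 128 × 128 with
1, 5 and 20 nuclei (noise-free and 5%-of-signal Gaussian noise); the
acceptance script exercises a 64 × 256 × 256 scene with 20 nuclei, 1000
random volumes for the connected-components oracle, and 200 Monte-Carlo
titrations — sizes chosen to exercise every code path at interactive run
times.

## Known limitations

* Single-timepoint: no label propagation across frames; time courses must
  be registered upstream and processed frame by frame.
* Threshold-based foreground: no subvoxel boundaries, and systematic halo
  bias on bright backgrounds (quantified above).
* The watershed's marker rule can oversplit strongly non-convex nuclei;
  raising `marker_radius` (or switching the watershed off and accepting
  merged pairs) are the available remedies.
* Hill fitting assumes a shared `r_min`/`r_max` across replicates; strong
  per-replicate baseline drift should be normalized before fitting.
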