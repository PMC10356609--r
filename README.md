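# fretquant

Per-nucleus quantification of ratiometric FRET biosensors in multichannel
3D microscopy stacks.

Nuclear-localized FRET biosensors (for example, abscisic-acid sensors of
the ABACUS family) report ligand concentration as the **emission ratio**

    R = DxAm / DxDm

— donor-excited acceptor (FRET) emission over donor-excited donor emission.
In tissue the signal is punctate: one bright blob per nucleus over
spatially varying background. The analysis problem is to segment hundreds
of touching, variably bright nuclei in a 3D stack and report one robust
ratio per nucleus. `fretquant` provides the full pipeline:

* **Segmentation** — 3D difference-of-Gaussians filtering, automatic
  (Otsu/triangle/Yen/mean) or manual thresholding, optional
  marker-controlled 3D watershed to split touching nuclei, lost-object
  recovery, and constrained-dilation relabelling so split objects are never
  shrunk. Typically run on the acceptor-excited acceptor channel (`AxAm`),
  which reads sensor expression independently of FRET.
* **Ratiometrics** — per-nucleus intensities and emission ratios as ratios
  of channel means, with voxels saturated in either donor-excitation
  channel excluded from both; fully saturated nuclei are flagged, not
  dropped. Standardized outputs: threshold stack, label stack, ratio stack
  and maximum / nearest-point Z projections (ratio images stored as 16-bit
  integers via a ×1000 convention), plus a results CSV and a settings log
  per run.
* **ROI labelling** — scriptable assignment of nuclei to up to 10
  biological categories (tables or region masks), with remeasurement.
* **Calibration** — single-site Hill fits of titrations,
  `R(c) = R_min + (R_max − R_min)·c/(K_D + c)`, yielding K_D and the
  percent ratio change `100·(R_max − R_min)/R_min`; emission-band ratios
  (525–535 nm / 480–490 nm) from spectral sweeps.
* **Synthetic scenes** — a ground-truthed generator of noisy 3D nuclei
  fields and titrations, used throughout the test suite; no external data
  needed.

See the vignette (`vignettes/nuclear-fret-quantification.Rmd`) for the
methods and the reasoning behind each design choice.

## Worked example

```r
library(fretquant)

## a ground-truthed synthetic scene: two nuclei with known ratios
nuclei <- list(
  nucleus_spec(center = c(8, 20, 20), radii = 4,
               dxdm_intensity = 1000, true_ratio = 1.2),
  nucleus_spec(center = c(8, 44, 44), radii = c(3, 4, 4),
               dxdm_intensity = 800, true_ratio = 0.9))
scene <- generate_scene(scene_spec(c(16, 64, 64), nuclei,
                                   background_level = 20,
                                   noise = "gaussian", noise_sd = 20,
                                   seed = 4))

seg <- segment(scene$stack, segmentation_settings())
#> <fq_segmentation> 2 object(s); threshold 240.7 (otsu); watershed on; lost voxels 0

records <- measure_rois(seg$labels, scene$stack)
records[, c("roi_id", "voxel_count", "analysed_voxel_count",
            "donor_intensity", "emission_ratio")]
#>   roi_id voxel_count analysed_voxel_count donor_intensity emission_ratio
#> 1      1         251                  251           999.5         1.2001
#> 2      2         185                  185           800.3         0.8991
```

Both nuclei are found; the measured emission ratios recover the ground
truth (1.2 and 0.9) to about 0.1% despite 2% Gaussian noise, because each
ratio pools a few hundred voxels. Calibration works the same way from a
titration table:

```r
titr <- generate_titration(r_min = 1.00, r_max = 1.67, kd = 98e-9,
                           concentrations = c(0, 10^seq(-8.5, -5.5,
                                                        length.out = 8)),
                           noise_sd = 0.01, replicates = 3, seed = 1)
fit_hill(titr)
#> <fq_hill_fit> r_min 1.001, r_max 1.671, kd 9.749e-08, n 1 (converged); ratio change +66.9%
```

A sensor simulated with K_D = 98 nM and +67% ratio change is recovered as
97.5 nM and +66.9% from 27 noisy points.

A thin command-line wrapper is installed with the package
(`system.file("cli", "fretquant", package = "fretquant")`) with subcommands
`simulate`, `segment-ratio`, `label-rois` and `fit-titration`.

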