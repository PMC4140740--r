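# auriMorph

3D morphometry and measurement-quality statistics for ear-cartilage
segmentations.

## The problem

Patient-specific reconstruction of the outer ear (autologous frameworks,
tissue-engineered scaffolds) needs the 3D shape of the *cartilage sheet*
inside the auricle — a curved layer roughly 1.15 mm thick — which is
obtained clinically by manually contouring fat-saturated gradient-echo MRI
at 0.45 × 0.45 × 0.40 mm voxels. Whether those hand-drawn masks are good
enough is a measurement-science question with two halves:

* **Precision** — when several raters (or one rater, repeatedly) segment
  the same scans, how much do cartilage volume (Cg.V, mm³), surface area
  (Cg.S, mm²) and mean thickness (Cg.Th, mm) vary?
* **Accuracy** — how close are MRI-chain metrics to the true shape, using
  dissection plus contrast-enhanced micro-CT as the reference standard?

auriMorph implements the full quantitative pipeline for both halves, in
Bioconductor-style S4:

* **Morphometry** of binary masks on anisotropic voxel grids:
  `cartilageVolume()` (voxel counting), `cartilageSurface()` (triangulated
  0.5-level isosurface via marching tetrahedra), `thicknessMap()` /
  `meanThickness()` (model-independent maximal-inscribed-sphere local
  thickness over a Euclidean distance transform), bundled by
  `morphometryAll()` on an isotropic analysis grid.
* **Micro-CT reference segmentation** `segmentCT()`: truncated Gaussian
  filter (σ = 1.2 voxels, support = 1, i.e. a renormalised 3×3×3 kernel)
  plus a closed linear-attenuation window of 0.9–2.2 cm⁻¹.
* **Precision statistics** `precisionError()`, `iccAbsoluteSingle()`,
  `pairwisePearson()`, `overlapMap()`, orchestrated by
  `precisionStudy()`: Glüer precision errors
  `PE_SD = sqrt(mean(SD_j²))` and `PE_%CV = 100·sqrt(mean(CV_j²))`
  (per-subject SDs with the m−1 denominator), degrees of freedom
  n(m−1) with the ≥27 recommendation flagged, and the two-way
  random-effects absolute-agreement single-measure intraclass
  correlation `ICC(A,1) = (MSR−MSE)/(MSR+(k−1)MSE+(k/n)(MSC−MSE))`.
* **Accuracy statistics** `accuracyStudy()`: per-metric Pearson r between
  chains (plus slope/intercept and identity-line residuals, since r is
  blind to constant bias) and the 1-voxel (0.45 mm) error band on mean
  thickness.
* **Synthetic ground truth**: phantoms (`makePhantom()`: slab, spherical
  shell, auricle-like bent sheet) with analytic V/S/Th, a simulated-rater
  model (`simulateRater()`: correlated level-set perturbation),
  `emulateCT()` (partial-volume + noise), and cohort generators, so the
  whole pipeline runs end-to-end with no external data.
* **Study runners** `runPrecision()` / `runAccuracy()` writing JSON/CSV
  report bundles with seeds and config hashes for byte-identical reruns.

Volume I/O covers NIfTI (`.nii`, `.nii.gz`), MetaImage (`.mha`/`.mhd`) and
PNG/TIFF slice stacks with a JSON spacing sidecar; spacing metadata is
mandatory (no silent 1-mm default).

## Worked example

A spherical-shell phantom (inner radius 8 mm, wall 1.0 mm) rasterised at
0.1 mm has closed-form truth V = 4/3·π·(9³−8³) ≈ 908.97 mm³,
S = 4π·(9²+8²) ≈ 1822.12 mm², Th = 1.0 mm:

```r
library(auriMorph)
ph <- makePhantom(phantomSpec("spherical_shell", thickness = 1, r_inner = 8), 0.1)
morphometryAll(ph@grid, "shell")
#> MorphometryResult 'shell': Cg.V 909.4 mm^3, Cg.S 1831 mm^2, Cg.Th 1.021 mm
#>   computed at spacing 0.1 x 0.1 x 0.1 mm
```

Volume is recovered to 0.05%, surface to 0.5%, thickness to ~2% (half a
voxel) — the measurement chain, not the phantom, is what is being tested.

A toy precision table shows the statistics on hand-checkable numbers: two
subjects measured twice, `{(10, 12), (20, 22)}`:

```r
precisionError(repeatedMeasures(rbind(A = c(10, 12), B = c(20, 22))))
#> PrecisionReport [metric]
#>   mean 16, PE_SD 1.41421, PE_%CV 10.26%, dof 2 (< 27), ICC NA
```

Both subjects have SD = √2 ≈ 1.414; their CVs (1.414/11 and 1.414/21)
pool to a 10.26% precision error, and 2 degrees of freedom are far below
the recommended 27 (a 14-subject × 3-rater design reaches 28).

The full synthetic studies run from a single config:

```r
cfg <- studyConfig("precision", "out_precision", synthetic = list(), seed = 1)
runPrecision(cfg)   # precision_report.json, pairwise.csv, morphometry.csv
cfg2 <- studyConfig("accuracy", "out_accuracy", synthetic = list(), seed = 1)
runAccuracy(cfg2)   # accuracy_report.json, scatter.csv
```

The precision report contains, per metric, the mean, PE_SD, PE_%CV, dof
and ICC(A,1); the accuracy report contains per-metric r/slope/intercept
and the thickness-band table.

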