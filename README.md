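# dsseg — Derivatives-Sum 3D nuclear segmentation

`dsseg` segments cell nuclei in 3D confocal stacks of densely packed
embryonic tissue (the motivating case: zebrafish presomitic mesoderm with
histone-labelled nuclei, imaged at 0.691 × 0.691 × 1.75 µm per voxel). In
such data, nuclei whose boundaries are unresolved — especially along the
coarse z axis — merge into single objects, and the package exists to take
them apart and to *measure how well it does so* without any manual ground
truth.

Three pieces:

1. **The Derivatives Sum (DS) algorithm.** Per z-slice, three derivative
   maps of the de-noised image at scale σ_g — the Gauss gradient magnitude
   `G = √(Ix² + Iy²)`, the positive Laplacian `L = max(Ixx + Iyy, 0)`, and
   the absolute negative Hessian determinant
   `H = |min(Ixx·Iyy − Ixy², 0)|` (saddle points: exactly where two
   nuclear edges touch) — are each rescaled to [0, 1] by their slice
   maximum and combined into `S = αĜ + βL̂ + εĤ`. The tanh mask
   `m = ½[1 + tanh(δ − γS)]` darkens the edge/saddle "crown" around each
   nucleus; the mask–image product is Otsu-thresholded per slice and
   3D-connected components (≥ 10 voxels) become objects. Objects larger
   than the fused-object-volume threshold (mean + n·sd of all volumes) are
   split by recursive K-means or by Gaussian mixtures with AIC model
   selection, seeded by `mnp`, the maximum peak count of the object's
   x/y/z voxel-frequency profiles. Watershed and Laplacian-of-Gaussian
   baselines are included for comparison.

2. **A synthetic benchmark generator.** Ellipsoidal nuclei (semi-axes
   4 × 2.75 × 2.75 µm ± 15%) packed hard-core where geometrically
   possible, gamma intensity noise with SNR = mean/sd = √shape, tunable
   density (1–4 ×10⁻³ nuclei/µm³), SNR, and nematic alignment of the long
   axes — with every true centroid known.

3. **A centroid-matching evaluation framework.** Hungarian assignment with
   pairings beyond 2 µm excluded; sensitivity = N_ra/N_r,
   precision = N_ra/N_s; density/SNR/parameter/n-weight sweep drivers; a
   two-channel (sparse/dense chimera) mode for in vivo ground truth.

## Worked example

```r
library(dsseg)

# a 35 µm cube at 2e-3 nuclei/µm³, SNR 5, alignment 0.67 (86 nuclei)
scene <- render_scene(sample_scene(c(35, 35, 35), 2e-3,
                                   alignment_target = 0.67, seed = 1),
                      intensity_model(snr = 5), seed = 2)
print(scene$stack)
#> image_stack: 51 x 51 x 20 voxels (x * y * z), 16-bit
#>   spacing: 0.691 x 0.691 x 1.75 um; intensity range [1, 196]

res <- ds_segment(scene$stack, benchmark_params()$denoise,
                  benchmark_params()$mask)
print(res)
#> segmentation_result: 67 objects (volumes 46-441 voxels, median 122)

post <- postprocess_all(res, n_weight = 0.5, method = "gmm", seed = 1)
score(match_centroids(scene$truth,
                      t(sapply(post$objects, `[[`, "centroid_um")), 2))
#> eval_report: 86 true, 89 detected, 84 correct | sensitivity 0.977, precision 0.944
```

Reading: the raw DS pass under-segments (67 objects for 86 true nuclei —
fused neighbours, mostly along z); GMM+AIC splitting of the above-threshold
objects recovers 84 of the 86 within the 2 µm acceptance radius
(sensitivity 0.98), with 5 of 89 detections not matching any true nucleus
(precision 0.94).

A command-line wrapper for stacks on disk lives at
`inst/scripts/dsseg.R` (subcommands `segment`, `synth`, `eval`, `sweep`,
`log-detect`; every run writes a JSON manifest of all resolved parameters
and seeds).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates the full watershed-baseline benchmark from scratch — synthetic
scenes at SNR 5 and densities 1–4 ×10⁻³ µm⁻³, 10 replicates each, DS
segmentation with distance-transform watershed post-processing, 2 µm
minimum-cost centroid matching — and writes the density-averaged
sensitivity and the low-density-averaged precision as JSON. Runtime is a
few minutes on one CPU.
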