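# flowtomo

Holographic flow cyto-tomography in R: from off-axis holograms of cells
rolling through a 45°-tilted microfluidic channel to 3D refractive-index
(RI) tomograms and single-cell morphometrics.

Label-free flow cytometry by digital holographic tomography images each
flowing cell from many angles as it rolls along the channel. Each off-axis
hologram frame encodes a quantitative phase map (QPM)
φ(x, y) = (2π/λ) ∫ (n − n₀) dz; the rolling motion turns the frame sequence
into a sparse set of tomographic projections. `flowtomo` implements the
computational pipeline for such an instrument, for researchers in
quantitative phase imaging and computational microscopy:

- **Hologram processing** — Tukey apodization, Fourier demodulation of the
  +1 order, angular-spectrum refocusing with Tamura-coefficient
  (σ/μ of the amplitude) autofocus, cell-free reference compensation,
  quality-guided phase unwrapping, windowed-Fourier denoising.
- **Rolling-angle recovery** — centroid tracking, Tamura-similarity
  detection of the full 360° turn, and proportional angle assignment
  θ_k = 360 · l_k / L360 with l_k = √(x_k² + y_k²).
- **Sparse-view reconstruction** — filtered back projection and high-order
  total variation via polynomial annihilation (PA), solving per slice
  min_x (μ/2)‖Ax − b‖² + ‖PA_k x‖₁ with non-negativity, by a split-Bregman
  solver (orders k = 1..4, data-fidelity defaults DF = 24/48/96/192, 30
  outer × 30 inner iterations).
- **Morphometrics** — average RI, biovolume, equivalent diameter, dry mass
  (specific refraction increment α = 0.2 mL/g), 3D SSIM, repeatability
  correlation matrices.
- **Synthetic data** — seeded 3D phantom cells (random Gaussian RI texture
  in [1.334, 1.410] inside a smooth-edged spherical support) and a forward
  simulator of rolling-cell hologram sequences, so the whole chain is
  testable without instrument data.

## A worked example

Simulate a rolling monocyte-like cell, process its holograms, recover the
angles, and reconstruct:

```r
library(flowtomo)

cfg  <- optical_config()                  # 488 nm, 55x, NA 0.5, 0.1 um/px
spec <- phantom_spec(grid_size = 24L, voxel_size = 0.2, cell_radius = 1.8,
                     seed = 3L)
flow <- flow_spec(translation_per_frame = 0.3, rotation_per_frame = 5,
                  n_frames = 76, noise_sigma = 0.02, seed = 9L)

seq1  <- simulate_rolling_sequence(spec, flow, cfg, frame_size = 224L)
proc  <- process_hologram_sequence(seq1$holograms, seq1$reference, cfg,
                                   denoise = FALSE)
res   <- reconstruct_sequence(proc$qpms, tilt = 45, crop_size = 8,
                              solver = "hotv-2")
res$tomogram
#> RI tomogram: 40 x 40 x 40 voxels, 0.2 um/voxel
#>   medium RI 1.3340, RI range [1.3340, 1.3957]
compute_features(res$tomogram)
#>   average_ri biovolume equivalent_diameter dry_mass segmentation_threshold alpha
#> 1   1.369169     8.624             2.54431 1.516505             0.02035683   0.2
```

The reconstruction reports a ~2.5 µm-equivalent-diameter core of mean RI
1.369 and ~1.5 pg dry mass (the equivalent diameter is that of the
above-threshold core, segmented at the 0.33-of-maximum contrast isolevel,
not the full 3.6 µm cell) — the phantom used here is a small desk-scale
cell; `phantom_spec()` defaults describe an 8 µm cell on a 128³ grid.

Benchmark the solvers on a seeded phantom at the sparse 16° angular step
(22 projections over [0°, 360°)):

```r
bm <- benchmark_solvers(benchmark_phantom_spec(seed = 1L))
bm
#>   solver      ssim
#> 1    fbp 0.7901783
#> 2 hotv-1 0.9627773
#> 3 hotv-2 0.9889075
#> 4 hotv-3 0.9879370
#> 5 hotv-4 0.9748562
```

Higher-order TV (k = 2, 3) reconstructs the smooth intracellular texture
that both FBP (streak and noise artifacts) and first-order TV (piecewise
constant bias) degrade.

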