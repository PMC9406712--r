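---
title: "In-flow holographic tomography of rolling cells: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-flow holographic tomography of rolling cells: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement and its inverse problem

A holographic flow cytometer records off-axis holograms of single cells
rolling along a microfluidic channel. Each frame encodes, in its interference
fringes, the complex amplitude of the light transmitted through the cell; the
unwrapped phase of that amplitude is proportional to the line integral of the
refractive-index (RI) contrast along the optical axis,

$$\varphi(x, y) = \frac{2\pi}{\lambda}\int \big(n(x,y,z) - n_0\big)\, dz .$$

As the cell rolls, successive frames probe it from successive angles. A full
rotation inside the field of view therefore yields a sinogram — per-slice 1D
projections tagged with angles — from which the 3D RI distribution can be
reconstructed tomographically. The channel is tilted 45 degrees with respect
to the camera axes so that a complete 360-degree rotation fits into the field
of view at the modest frame rate (30 fps) of a compact instrument; about 35
projections per turn are available, so the inverse problem is severely
angle-sparse.

`flowtomo` implements the full computational chain: hologram processing
(`apodize`, `demodulate`, `propagate_angular_spectrum`, `autofocus`,
`compensate_reference`, `unwrap_phase`, `wft_denoise`), rolling-angle
recovery (`track_centroids`, `tamura_similarity_index`,
`find_full_rotation`, `assign_angles`), sparse-view reconstruction
(`fbp_reconstruct`, `hotv_reconstruct`), morphometrics (`segment_cell`,
`compute_features`, `ssim_3d`, `correlation_matrix`), a seeded synthetic
generator (`generate_phantom`, `simulate_rolling_sequence`), and a solver
benchmark (`benchmark_solvers`).

## Hologram processing

Each frame is apodized with a separable Tukey window (default taper fraction
0.2) to suppress border diffraction, Fourier transformed, and the +1
diffraction order — located automatically as the strongest off-center peak,
then frozen for the sequence — is cropped (default radius: half the carrier
magnitude) and re-centered; the inverse transform yields the complex
amplitude. The field is refocused by angular-spectrum propagation to the
depth minimizing the Tamura coefficient $TC = \sigma(|U|)/\mu(|U|)$ of the
amplitude; the depth is estimated on the first frame of a cell and preserved
for the rest of the sequence. The metric is evaluated on the central half of
the field because the apodized border otherwise dominates the amplitude
contrast. Some of the literature defines the coefficient as
$\sqrt{\sigma/\mu}$; both are monotone transforms with the same minimizer,
and the square-root form is available via a flag.

Aberrations are removed by complex division with a cell-free reference
hologram processed identically (division also flattens the illumination
amplitude; phase subtraction would be equivalent on phase alone). The
wrapped phase is unwrapped with a quality-guided flood-fill unwrapper:
pixels are unwrapped in decreasing order of local gradient quality, each
congruent mod $2\pi$ to its wrapped value, which recovers any surface with
gradients below $\pi$ per pixel up to a global $2\pi k$ offset. This
satisfies the same contract as graph-cut unwrappers at a fraction of the
complexity. Correlated speckle noise is attenuated by windowed-Fourier
filtering: overlapping Hamming-windowed blocks are transformed and
hard-thresholded at `threshold` times a robust per-window noise scale (the
Rayleigh-calibrated median coefficient magnitude, so the threshold is in
noise-sigma units; default 3), then overlap-added with squared-window
normalization. At threshold zero the transform is an exact partition of
unity.

## Rolling-angle recovery

Rotation is assumed proportional to translation. The cell centroid
(phase-weighted, sub-pixel, Otsu-thresholded with a 10% border margin
excluded) is tracked across frames; the displacement of frame $k$ from frame
1 is $l_k = \sqrt{x_k^2 + y_k^2}$, a definition invariant to the 45-degree
tilt. The frame completing a full turn minimizes the Tamura similarity
index — the Tamura coefficient of the absolute frame-difference map after
mean-offset removal, computed on cell-centered crops — against frame 1, with
a minimum-lag guard (default 10 frames) excluding the trivial
self-similarity minimum. Angles are then assigned as $\theta_1 = 0$,
$\theta_k = 360\, l_k / L_{360}$, and frames beyond the full turn are
dropped. The exact similarity-index formula is not fixed by the instrument
literature; the difference-map form used here is scale-invariant and
minimized when the cell returns to its initial orientation, which is the
property the detection needs.

The dominant residual of this scheme on simulated data is not tracking noise
but the orientation wobble of the projected phase centroid: a rotating,
textured cell's center of phase is not a fixed material point, so $l_k$
carries a quasi-periodic error of a fraction of the cell radius. The
angle-recovery validation therefore uses a finer rotation step (5 degrees
per frame, a 21.6 um track per turn) where the wobble contributes less than
the 6-degree acceptance bound; at the instrument's typical ~10 degrees per
frame the same wobble corresponds to roughly one angular step, which the
reconstruction tolerates.

## Tomographic reconstruction

De-tilted, centroid-centered, cropped phase maps are converted to line
integrals ($\times \lambda/2\pi$) and stacked into a sinogram; columns of
the de-tilted crop (perpendicular to the rolling axis) are independent 2D
slice problems. The projector $A$ is realized once per (grid, angle-set) as
a cached sparse matrix — pixel-driven with a linear footprint along the
detector — so its adjoint is the exact transpose; it is consistent with the
rotate-and-sum forward model of the simulator to well below the 2% test
tolerance.

`fbp_reconstruct` is the classical filtered back projection: band-limited
ramp filtering (with Shepp-Logan and Hann variants) in the detector
frequency domain and bilinear back projection with half-angle-gap weights,
supporting non-uniform angle lists over $[0, 360)$.

`hotv_reconstruct` solves, slice by slice with all slices batched,

$$\min_x \; \frac{\mu}{2}\,\|A x - b\|_2^2 + \|PA_k\, x\|_1,
  \qquad x \ge 0,$$

where $PA_k$ stacks $k$-th order finite differences along both in-slice
dimensions; $k = 1$ is standard TV, higher orders annihilate polynomials of
degree $k-1$ and so favour piecewise-smooth solutions. The solver is
split-Bregman/ADMM: outer iterations perform the shrinkage of the difference
coefficients, the dual update, and the non-negativity projection; inner
iterations are warm-started conjugate-gradient steps on the quadratic
x-subproblem. Both counts default to 30, with a relative-change stopping
tolerance of 1e-4; non-convergence is flagged in the returned log, never
raised. A best-objective safeguard makes the reported objective trace
monotone (a single early ADMM transient can otherwise raise it by ~0.1%).

Numerical normalization matters for reproducible data-fidelity settings.
The solver works on a normalized problem: $A$ scaled to unit spectral norm
(power iteration), data scaled to unit maximum, and $PA_k$ carrying the
conventional per-order factor $2^{1-k}$ that equalizes the transform's
response across orders. Under this normalization the data-fidelity weight is
$\mu = DF$ with the published defaults DF = 24, 48, 96, 192 for orders 1-4,
independent of grid size, angle count and contrast units. The ADMM penalty
defaults to $\beta = 8$ and the x-subproblem is warm-started from the
clipped FBP solution. Slices with empty data are returned as zeros without
solver invocation.

## The phantom and what the benchmark shows

`generate_phantom` draws white Gaussian noise on the grid, low-pass filters
it with a Gaussian kernel of width `correlation_length` (default 0.6 um),
rescales the field inside a spherical (optionally ellipsoidal) support
affinely into the declared RI range [1.334, 1.410], and blends the support
edge with a raised-cosine profile of width `edge_width`. The phantom is a
stand-in for a tomogram as it appears *after* a band-limited reconstruction
pipeline, so its boundary is resolution-limited rather than sharp: the
default edge (0.8 um) mirrors the $0.82\lambda/NA \approx 0.8$ um lateral
resolution of the default optics. This choice is load-bearing: with a hard
one-voxel edge the boundary term dominates both regularizers' cost and the
benchmark becomes TV-favourable, inverting the expected solver ranking.
Generation is bit-reproducible from (spec, seed); background voxels equal
the medium index exactly.

The solver benchmark (`benchmark_solvers`) projects a phantom on the uniform
schedule $\theta_j = j\,\Delta\theta$ over $[0, 360)$ — 60 projections at
$\Delta\theta = 6^\circ$, 22 at $16^\circ$ — adds Gaussian phase noise, and
scores each solver by 3D SSIM (Gaussian window, sigma 1.5 voxels, standard
constants, dynamic range from the ground truth) over the entire tomogram.
Its declared conditions (`benchmark_phantom_spec`): 48^3 grid at 0.2 um
voxels, 7.2 um cell, 0.6 um texture, 1.2 um boundary, noise sigma 0.025 rad.
The grid is a desk-scale choice; the noise level is the benchmark's
calibration knob (no instrument value exists for it). Under these
conditions the sparse-angle ranking is stable seed by seed:
HOTV-2 $\ge$ HOTV-3 $\ge$ HOTV-4 $>$ HOTV-1 $>$ FBP, with FBP near 0.78 and
the order-2/3 solvers near 0.99. One caveat is documented rather than hidden:
the first-order (TV) solver converges here to SSIM around 0.96, retaining
most of the smooth texture, whereas the reference instrument work reports a
much stronger TV flattening (0.87). Driving this implementation's TV into
that regime (by starving the data term) simultaneously degrades the order-2
solver and flips the order-2/order-3 ranking, so the discrepancy is accepted
and reported as is; it appears to trace to internal scalings of the original
third-party solver that were never published.

What passing the benchmark does and does not show: the simulator shares its
straight-ray projection model with the reconstruction (no diffraction within
the sample, no partial coherence, no camera MTF), phantoms are single
spherical cells, and noise is white Gaussian phase noise. Results transfer
to real data only to the extent that those idealizations hold; the benchmark
validates the pipeline's internal consistency and the relative merits of the
solvers, not absolute instrument accuracy.

## Morphometrics and repeatability

Cells are segmented at a contrast threshold (default: the 0.33-of-maximum
isolevel, on the contrast scale — the fraction-of-absolute-RI reading would
select everything, though it is available via a flag). The largest
6-connected component is kept and cavities filled. Features follow their
closed forms: mean RI over the mask; biovolume $V$; equivalent diameter
$(6V/\pi)^{1/3}$; and dry mass $\alpha^{-1}\sum \Delta n\, v^3$ with the
conventional specific refraction increment $\alpha = 0.2$ mL/g (not an
instrument-specific value; configurable). With $\alpha$ in mL/g and volumes
in um^3 the mass comes out in picograms.

The repeatability experiment re-observes one phantom through independently
noisy simulated sequences, each processed independently end to end
(holograms through angle recovery to HOTV-2), and reports the pairwise
Pearson correlation of the tomograms after centroid alignment (integer-voxel
shifts; simulated observations share the initial orientation, so no
principal-axes alignment is needed). On the declared desk-scale conditions
(32^3 phantom, 34 frames per observation, noise 0.05 rad) the mean pairwise
correlation exceeds 0.95, mirroring the consistency analysis used for the
real instrument — though the real-cell figure includes biological and
hydrodynamic variability no simulation reproduces.

## Degenerate inputs and tie-breaks

Autofocus ties resolve toward the smallest |z|; full-rotation ties toward
the earliest frame. A degenerate RI range produces a uniform cell; an empty
sinogram slice reconstructs to zeros without solver invocation; a constant
tomogram is an error for correlation (undefined) and for tracking (no
cell). `dz = 0` propagation is exactly the identity; evanescent components
are zeroed otherwise. The 360-degree frame itself is dropped from the
tomographic angle set (it duplicates 0 degrees), as is any frame whose
recovered angle does not increase.

## Problem sizes used by the shipped checks

The test-suite and the acceptance script run entirely from seeded synthetic
data: the solver benchmark averages 10 phantom seeds at 48^3; the
end-to-end phase-recovery check uses 8 frames of 128^2 holograms; angle
recovery uses 76 frames of 224^2; repeatability uses five observations of 34
frames at 160^2 with 40^3 reconstructions. These sizes are the package's
declared desk-scale working points; all scale linearly if changed in the
corresponding configuration objects.
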