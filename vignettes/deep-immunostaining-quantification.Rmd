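---
title: "Modeling and quantifying deep immunostaining"
author: "deepstain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and quantifying deep immunostaining}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deepstain)
```

# The problem

Antibodies penetrate thick tissue poorly: as free antibody diffuses
inward it is captured by its antigen, so staining accumulates in a
bright rim near the surface while the interior stays dark. Raising the
temperature weakens the antibody–antigen association equilibrium
(K~a~ = k~on~/k~off~ drops steeply with temperature) and, if the
antibody itself is protected from heat denaturation, lets it diffuse
deep before binding on cooling. `deepstain` provides (i) a
reaction–diffusion simulator that quantifies this mechanism and (ii)
the 3D image quantification pipeline used to evaluate deep staining in
cleared-tissue volumes — distance-from-surface depth maps, SNR-by-depth
profiles, blob segmentation with per-cell depth statistics, detection
and removal of intravascular reagent precipitates, and structure-tensor
fiber orientation — exercised end to end on a seeded, ground-truthed
synthetic volume generator.

# The reaction–diffusion model

Free antibody [Ab] diffuses radially into an antigen-bearing cylinder
(radius 1, domain radius 2, all quantities dimensionless) and binds the
immobile antigen [Ag] reversibly:

$$
\begin{aligned}
\frac{\partial [\mathrm{Ab}]}{\partial t} &=
  D_\mathrm{eff}\,\frac{1}{r}\frac{\partial}{\partial r}
  \left(r\,\frac{\partial [\mathrm{Ab}]}{\partial r}\right)
  + k_\mathrm{off}[\mathrm{Ab{-}Ag}] - k_\mathrm{on}[\mathrm{Ab}][\mathrm{Ag}] \\
\frac{\partial [\mathrm{Ag}]}{\partial t} &=
  k_\mathrm{off}[\mathrm{Ab{-}Ag}] - k_\mathrm{on}[\mathrm{Ab}][\mathrm{Ag}] \\
\frac{\partial [\mathrm{Ab{-}Ag}]}{\partial t} &=
  -k_\mathrm{off}[\mathrm{Ab{-}Ag}] + k_\mathrm{on}[\mathrm{Ab}][\mathrm{Ag}]
\end{aligned}
$$

Initial conditions: [Ab] = 50 outside the cylinder and 0 inside,
[Ag] = 50 inside and 0 outside, complex 0 everywhere; [Ab] is held at
50 at the outer boundary (an antibody reservoir), with zero-flux
symmetry at r = 0. D~eff~ inside the cylinder is 1/7 of the outside
value (hindered diffusion in dense tissue). Two temperature-labeled
parameter sets are built in: at 22 °C, D~eff~ = 1, k~on~ = 1,
k~off~ = 1 (K~a~ = 1); at 55 °C, D~eff~ = 1.11 (the Stokes–Einstein
ratio of absolute temperatures, `stokes_einstein_ratio(22, 55)`),
k~on~ = 2 and k~off~ = 60.75, so K~a~ collapses to ≈ 0.033. The 55 °C
values are adopted as given constants; no denaturation kinetics are
simulated (full thermal protection is assumed).

A piecewise schedule assigns a parameter set to each time phase over
t ∈ [0, 1], with a temperature change at t = 0.95. The heat-facilitated
scenario runs the hot kinetics through the long first phase and returns
to 22 °C binding at t = 0.95 — stain hot (weak binding, deep
penetration), then cool to capture — which is the order that models the
protocol; the reversed assignment remains constructible via
`two_phase_schedule()` for comparison. Two isolation scenarios complete
the factorial: elevating only D~eff~ (1 → 1.11, kinetics at 22 °C) and
changing only the kinetics (D~eff~ kept at 1).

```{r scenarios, eval = FALSE}
rd_scenarios(sim_config())   # the four canonical runs, 1000 x 500 grid
```

The bound-complex profile at t = 1 is summarized by
`penetration_metrics()`: mean, SD and CV inside the cylinder, and the
center/edge ratio. On the production grid the heated run lowers the CV
from ≈ 1.02 to ≈ 0.64 and raises the center/edge ratio by more than two
orders of magnitude, while the diffusivity-only run barely moves either
metric — the depth gain is a binding-equilibrium effect, not a
diffusivity effect.

## Numerics

* **Method of lines** on the fixed radial grid (default 1,000 points);
  time integration by `deSolve::ode.1D` (lsoda, banded Jacobian),
  relative/absolute tolerances 10^-8^. The antigen/complex equations
  are purely local, so the sum [Ag] + [Ab–Ag] is conserved by
  construction of the equations and to integrator accuracy in the
  solution (observed ≈ 10^-13^, bound 5 × 10^-5^).
* **Finite-volume diffusion** with harmonic-mean interface diffusivity,
  which conserves flux across the 7-fold step change at the cylinder
  wall. At r = 0 the cylindrical Laplacian is evaluated by its
  symmetric limit (4D(u₁ − u₀)/Δr²).
* **Phase switching** restarts the integrator at each phase start so
  the parameter jump lands exactly at t = 0.95; output grid times that
  coincide with a boundary to within 10^-12^ are collapsed.
* **Independent oracle**: in the zero-kinetics uniform-diffusivity
  limit the solver is checked against a separate explicit
  finite-difference scheme (central differences on the expanded form,
  10× finer grid, stability-limited steps) written in C++; relative L2
  disagreement is ≈ 2 × 10^-4^ against a 1% bound.
* **Degenerate profile metrics**: an all-zero profile reports CV 0 and
  center/edge ratio 1; a zero edge with nonzero center reports Inf.
  This keeps parameter sweeps NaN-free.

# The synthetic volume generator

No public imaging data accompany the quantification procedures, so the
generator is the test bed: it emulates the statistical structure of
cleared-tissue fluorescence stacks with voxel-level ground truth.
Conventions: arrays are (z, y, x); the physical coordinate of voxel
index i (0-based) is i × voxel size; intensities are dimensionless,
roughly in [0, 1].

* **Tissue geometry.** A box with a non-tissue rim on all faces, or a
  slab with a single cut surface at low z. The canonical cell scene is
  a slab — the geometry of a sectioned block stained from its cut
  face — which makes the depth field planar. (In a box, depth is the
  minimum over several faces; the mean of a minimum over a cell's
  voxels is biased low near edges, an effect of the geometry rather
  than of the measurement.) Non-tissue voxels carry a dimmer baseline
  (mounting medium) than tissue autofluorescence.
* **Cells** are isotropic Gaussians (σ = radius/2, truncated at 3σ)
  placed by rejection sampling with a pairwise separation constraint;
  the rendered peak is the sampled nominal intensity times a
  configurable depth profile — a constant for uniform staining, a
  decaying curve (or a bound-complex profile exported from the
  simulator via `depth_profile_from_rd()`) for penetration-limited
  staining. The canonical scene: 50 cells of radius 8–12 µm in a
  64 × 160 × 160 volume at 2 µm isotropic sampling.
* **Vessels** are randomly oriented tubes of dim signal clipped to the
  tissue; **precipitates** are bright ellipsoids (max diameter ≤ 8 µm
  by default, hard cap 10 µm) seeded inside the lumen as a Poisson
  process over the vessel volume and clipped to it, so the precipitate
  mask is a subset of the vessel mask by construction. Centers keep a
  minimum separation (sum of semi-diameters + 2 µm): aggregates are
  individually resolvable objects, consistent with the per-object
  diameter contract of the precipitate report.
* **Fibers** are parallel cylinders with small per-fiber angular
  jitter; each fiber voxel records its true unit direction.
* **Acquisition artifacts**: a sinusoidal per-plane gain with
  configurable period (default 10 planes) and amplitude (no
  quantitative amplitude is established for this artifact, so it is a
  parameter, not an assertion), a parabolic multiplicative vignette,
  and Poisson–Gaussian noise (scaled shot noise plus Gaussian read
  noise). Everything is seeded and byte-deterministic.

What the generator does **not** emulate: optics (PSF anisotropy,
light-sheet stripes), tissue deformation or clearing-induced shrinkage,
autofluorescence texture, and cell shape variability. Passing tests on
these volumes therefore demonstrate correctness of the measurement
pipeline on known geometry and realistic noise — not performance on
real acquisitions, where segmentation parameters in particular would
need retuning.

# Depth quantification

* **Distance from surface.** An exact anisotropic Euclidean distance
  transform (three-pass lower-envelope algorithm in C++) gives every
  tissue voxel its distance in µm to the nearest non-tissue voxel
  center; internal cavities marked non-tissue count as surface, and an
  `open_boundary` flag treats the array border as non-tissue for
  cropped volumes. The transform is checked exactly (10^-9^ µm)
  against a brute-force all-pairs oracle on random masks.
* **SNR.** 10 log₁₀ of the ratio of summed squared intensities between
  a positive-staining ROI and a background ROI; per-slice profiling
  returns mean, SD and SNR through z, omitting and flagging slices
  without both ROIs. Because the definition uses summed (not mean)
  squares, comparisons assume ROIs of commensurate size.
* **Cell segmentation.** Gaussian pre-smoothing at σ~G~, negated
  Laplacian-of-Gaussian response at σ~L~ (defaults 10 and 5, in pixels
  as in the original macro, with a physical-unit option), thresholded
  at mean + k·SD of the response (k = 3; a deterministic stand-in for
  interactive local-background-contrast thresholding, with an absolute
  alternative), 26-connected labeling, then volume and sphericity
  filters. Detected components are then **re-delineated by local
  contrast**: each object becomes the connected region around its seed
  where the smoothed image exceeds background + 50% of the local peak
  contrast. Without this step the object extent is a superlevel set of
  the filter response, which "threshold-locks" per-object mean
  intensities (dim cells get small, core-only masks whose mean is as
  high as a bright cell's) and inflates volumes; with it, extents track
  the cells, so volumes, sphericities and intensity-versus-depth
  correlations are meaningful.
* **Sphericity** is π^{1/3}(6V)^{2/3}/A with A estimated from exposed
  voxel faces scaled by 2/3 — face counting overestimates the area of a
  smooth surface by 3/2 on average over orientations, so digitized
  balls score ≈ 1.
* **Depth per cell** is the mean of the distance map over the object's
  voxels (the distance-transformation-channel reading), and depth
  distributions are summarized by median, IQR, and moment-based
  skewness and excess kurtosis. Population (n-denominator) formulas are
  the default, with sample-adjusted versions behind a flag; kurtosis is
  reported in the excess convention (normal = 0), the only convention
  consistent with negative reported values for unimodal distributions.
  Distributions are compared with the two-sample Kolmogorov–Smirnov
  test (asymptotic p-values; exact small-sample enumeration is out of
  scope).

# Precipitate filtering

Bright intravascular aggregates are detected by local contrast: white
top-hat with a box of half-width max_diameter/2 (removes everything
wider than the object scale, including tissue background and — by the
subsequent threshold — the dim vessel signal), Gaussian smoothing at
the surface-detail scale, thresholding at half the response maximum
(bright aggregates are near-uniform in brightness; mean + k·SD and
absolute policies are available), 26-connected labeling, a maximum
Feret-diameter filter at 10 µm (computed by brute force over each
component's surface voxels), and an optional vessel-overlap filter
standing in for manual curation against the vasculature channel.

"Surface detail" (1 µm for precipitates, 5 µm for the tissue surface)
is interpreted as the smallest resolved feature size, i.e. the FWHM of
the Gaussian smoothing (σ = detail/2.355). Interpreting it as σ
directly blurs 4–8 µm objects so much that no threshold recovers both
voxel recall and precision at 0.9 on the canonical scene (best
0.95/0.86); the FWHM reading is at least as faithful to the interactive
setting being emulated and recovers both at ≈ 1.0.

Tissue volume uses the same smoothing with no background subtraction, a
global threshold, and the largest connected component. The default
policy runs Otsu on log intensities (so the tiny bright-label tail
cannot hijack the split) refined to the midpoint of the two class
medians, which places the cut at the half-level of the blurred tissue
edge; an absolute threshold is available. Limitation: when the empty
border of the volume is thinner than the smoothing scale, the edge
cannot be resolved and the estimate inflates by a few percent.

Removal sets voxels under any accepted label to exactly zero and leaves
every other voxel bit-identical; it is idempotent. The load report
gives per-object volumes, Feret diameters and centroids, and the
precipitate-to-tissue volume ratio.

# Stack normalization and fiber orientation

* **Section equalization** rescales each z-slice affinely to the stack
  reference (median of slice means and SDs), clipping at zero;
  zero-variance slices pass through flagged.
* **Periodic artifact smoothing** follows the de-interleave recipe
  exactly: split into odd/even slices, Gaussian-filter each half along
  z (σ = 1 px), project consecutive slice pairs, re-interleave, filter
  once more (σ = 1 px). The pair "projection" operator is not named in
  the original description; the mean is used (the smoothing-consistent
  reading), with max available. The output z-extent is halved; odd
  trailing slices are dropped and flagged. A pure period-2 oscillation
  is attenuated well over 10-fold away from the stack ends.
* **Shading correction** builds a per-slice reference by 2D median
  filtering (kernel 37) and Gaussian blurring (σ = 2), normalizes it to
  unit mean (the brightness adjustment, so correction is purely
  multiplicative), floors it, and divides. Global scalars commute with
  the correction.
* **Orientation fields** come from the 3D structure tensor: gradients
  by derivative-of-Gaussian at σ = 0.6, tensor smoothing at σ = 2.3,
  per-voxel eigendecomposition, fiber direction = eigenvector of the
  smallest eigenvalue, sign-canonicalized. Coherence is
  (λ_mid − λ_min)/(λ_max + λ_mid + λ_min): 0 for isotropic
  neighborhoods, ≈ 0.5 for clean tubes. Voxels below the coherence
  threshold (default 0.2, a declared addition — the original exposes
  only an angular threshold) or with degenerate tensors carry no
  orientation; on pure-noise volumes fewer than 10% of voxels survive,
  on synthetic bundles the median angular error is ≈ 1.5° at every
  tested orientation including oblique.
* **Streamline tracking** is a deliberately simple deterministic
  fixed-step integrator (bidirectional, nearest-voxel orientation
  lookup, sign chosen to minimize turning, termination on the 25°
  turning threshold, mask exit, bounds, or length). It exists to test
  orientation fields; it is not claimed to match the streamline output
  of a full tractography engine, and anatomical seeding is out of
  scope. Block-average downscaling (e.g. 10× in-plane, 2× in z to
  isotropy) is provided as a utility.

# Problem sizes and determinism

The canonical scenes (64 × 160 × 160 cells at 2 µm, 64 × 128 × 128
vessels and 48 × 64 × 64 fibers at 1 µm) are sized so that every object
class appears at realistic scale separation (cells ≈ 5 voxel radii,
precipitates 2–4, fibers 2) while a full pipeline run stays
interactive; the simulator's production grid is the full 1,000 × 500
discretization. All stochastic stages draw from a single integer seed
per scene, and fixed seeds give byte-identical volumes, masks and
tables. Statistical checks (moment recovery at n = 10⁵, Poisson count
bands) use tolerances of three Monte-Carlo standard errors estimated by
replication.

# Known limitations

* Dimensionless simulation only: no mapping to absolute diffusion
  coefficients, real geometries, or antibody concentrations.
* The synthetic volumes omit optics and deformation (above); absolute
  real-data quantities (mean cell depths, counts) are not reproduced
  here because the underlying imaging data are not public.
* Segmentation defaults (threshold multiplier, volume and sphericity
  gates, local-contrast fraction) are explicit stand-ins for
  interactive settings that have no published values.
* The tissue-volume estimator degrades when the empty border is thinner
  than the surface-detail scale.
* KS p-values are asymptotic; for very small samples they are
  approximate.
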