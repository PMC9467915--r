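# deepstain

Simulation and 3D quantification of deep immunostaining.

Conventional immunostaining of thick tissue fails in a characteristic
way: free antibody is captured by antigen as soon as it enters, so
label piles up in a rim near the surface and the interior stays dark.
Heating shifts the antibody–antigen association equilibrium
(K<sub>a</sub> = k<sub>on</sub>/k<sub>off</sub>) strongly toward free
antibody, letting thermostable probes diffuse deep before binding on
cooling. `deepstain` is for researchers developing or evaluating such
deep-staining protocols and for image analysts quantifying them. It
provides:

* a solver for the radially symmetric reaction–diffusion system

  d[Ab]/dt = D<sub>eff</sub> (1/r) d/dr (r d[Ab]/dr) + k<sub>off</sub>[Ab–Ag] − k<sub>on</sub>[Ab][Ag]
  d[Ag]/dt = k<sub>off</sub>[Ab–Ag] − k<sub>on</sub>[Ab][Ag]
  d[Ab–Ag]/dt = −k<sub>off</sub>[Ab–Ag] + k<sub>on</sub>[Ab][Ag]

  with an antigen-bearing cylinder (interior diffusivity 1/7 of
  exterior), a fixed antibody reservoir at the outer boundary, and
  piecewise-in-time temperature schedules (22 °C set: D = 1,
  k<sub>on</sub> = 1, k<sub>off</sub> = 1; 55 °C set: D = 1.11 by
  Stokes–Einstein scaling, k<sub>on</sub> = 2, k<sub>off</sub> = 60.75);
* the 3D quantification pipeline for cleared-tissue image stacks:
  exact anisotropic Euclidean distance-from-surface maps, per-slice
  SNR profiles (10·log10 of summed-square intensity ratios),
  Laplacian-of-Gaussian cell segmentation with local-contrast mask
  refinement, per-cell depth assignment and depth-distribution
  statistics (skewness, excess kurtosis, two-sample KS), detection /
  digital removal / load reporting of bright intravascular
  precipitates, serial-section equalization, periodic-artifact
  smoothing, shading correction, structure-tensor fiber orientation
  and a simple deterministic streamline tracker;
* a seeded generator of ground-truthed synthetic volumes (cells,
  vessels with precipitates, fiber bundles, acquisition artifacts) so
  the whole pipeline is testable without external data.

## Worked example

Temperature-dependent binding kinetics versus diffusivity:

```r
library(deepstain)

stokes_einstein_ratio(22, 55)
#> [1] 1.111808   # D_eff gain from heating is ~11%

rd_scenarios(sim_config())   # 1000 x 500 grid, four scenarios
#>         scenario       first_phase D_out k_on k_off mean_in sd_in cv_in center_edge_ratio
#> 1   conventional               22C  1.00    1   1.0    21.0  21.4 1.020          0.000195
#> 2 diffusion_only         22C_highD  1.11    1   1.0    22.4  21.4 0.957          0.000506
#> 3  kinetics_only 55C_kinetics_only  1.00    2  60.8    21.0  14.9 0.708          0.053679
#> 4         heated               55C  1.11    2  60.8    22.6  14.4 0.636          0.083751
```

Reading the table: `cv_in` is the coefficient of variation of the
bound-complex profile inside the cylinder at the end of the run (lower
= more homogeneous staining) and `center_edge_ratio` compares the
cylinder center to its surface (1 = fully penetrated). Running the hot
kinetics during the long first phase drops the CV from 1.02 to 0.71 and
improves center penetration by two orders of magnitude; the 11%
diffusivity gain alone (row 2) accomplishes almost none of that.

Quantifying a synthetic stained volume:

```r
scene <- synthetic_cell_scene(seed = 1)       # 50 cells, slab geometry
seg <- segment_cells_log(scene$volume, sigma_L = 10, sigma_G = 5,
                         sigma_units = "um",
                         voxel_size = scene$spec$voxel_size,
                         min_volume = 100, min_sphericity = 0.5)
dmap <- distance_from_surface(scene$truth$tissue_mask,
                              scene$spec$voxel_size)
seg <- assign_depths(seg, dmap)
nrow(seg$cells)
#> [1] 50        # all 50 seeded cells recovered
depth_stats(seg$cells$depth_um)[c("mean", "skewness")]
#> $mean     [1] 56.2
#> $skewness [1] 0.241
```

The numbered scripts under `analysis/` run the full study: `01`
simulates penetration scenarios, `02` generates the ground-truthed
volumes, `03` quantifies cell depths and depth distributions, `04`
detects and removes intravascular precipitates (voxel recall and
precision 1.00 on the canonical scene), `05` estimates fiber
orientation (median angular error ≈ 1–1.5°) and tracks streamlines.
Each writes its tables under `results/`.

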