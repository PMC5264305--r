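# myofiber

Quantification of microstructural remodeling in the chronically infarcted
left ventricle from ex-vivo diffusion tensor imaging (DTI) and late
gadolinium enhancement (LGE) volumes — for imaging scientists and
cardiac-modeling groups who need reproducible, testable fiber-architecture
metrics rather than interactive workflows.

## What it computes

After myocardial infarction the collagenous scar thins the wall, yet the
primary diffusion eigenvector largely keeps the healthy helical pattern:
left-handed fibers at the epicardium rotating smoothly to right-handed
fibers at the endocardium. `myofiber` measures that reorganization:

- **Tensor stage.** Log-linear least-squares fit of the Stejskal–Tanner
  model `S_i = S0 exp(-b g_i' D g_i)` per voxel, eigendecomposition, mean
  diffusivity `MD = (e1+e2+e3)/3` and fractional anisotropy
  `FA = sqrt(3/2) ||λ − λ̄|| / ||λ||`, finite-strain tensor reorientation
  under a supplied affine (`D' = R D R'`, R from the polar decomposition),
  and Rayleigh-corrected SNR measurement.
- **Angle stage.** A local frame tangential to the endocardial surface:
  `n` (surface normal, endo→epi), `t = z × n` (circumferential),
  `f = n × t`. The *inclination* (helix) angle is the angle of the
  eigenvector's tangent-plane projection against `t`; the *imbrication*
  (transverse) angle is its tilt out of the tangent plane. Wall depth is
  measured from the epicardium by Euclidean distance transforms.
- **Segment stage.** Otsu thresholding of the LGE channel (plus
  morphological refinement) marks fibrosis; each 1.2-mm short-axis slab is
  divided into 36 polar segments of 10°; per segment the package reports
  wall thickness, scar transmurality, the slope/intercept/r² of the linear
  inclination-vs-depth profile, the [1–99]% inclination range, the
  left-handed/circumferential/right-handed voxel ratios (±15° boundaries),
  the mean imbrication angle and the intervoxel incoherency (mean acute
  angular difference over 6-connected neighbour pairs).
- **Statistics.** Wilcoxon rank-sum comparisons per heart and per segment,
  Pearson correlations (including slope vs inverse wall thickness), percent
  changes, and a Monte-Carlo analysis of primary-eigenvector uncertainty
  versus FA and SNR.
- **Synthetic LV phantom.** A cylindrical-annulus ventricle with a linear
  epi→endo inclination law, a thinned fibrotic sector, prolate tensors with
  prescribed MD/FA, Rician-noise DWI simulation and an LGE-like channel —
  the ground truth against which every stage is validated.

## Worked example

```r
library(myofiber)
library(dplyr)

params <- phantom_params(grid_shape = c(64, 64, 16), long_axis_extent_mm = 6)
heart  <- build_phantom(params)       # DWI at SNR 120 + LGE channel
heart
#> <phantom_bundle> wall 22824 voxels, scar 1164 voxels, SNR 120

result <- analyze_heart(heart, heart_id = "pig01", heart_type = "infarcted")
result
#> <heart_analysis> pig01 (infarcted): 144 segments (144 non-excluded)

result$metrics |>
  filter(!excluded) |>
  summarise(across(c(thickness_mm, transmurality, slope_deg_per_mm,
                     intercept_deg, inclination_range_deg, lh_ratio),
                   ~ round(mean(.x, na.rm = TRUE), 2)),
            .by = status)
#> # A tibble: 2 × 7
#>   status    thickness_mm transmurality slope_deg_per_mm intercept_deg
#> 1 infarcted         4.92           0.4             22.6         -58.4
#> 2 other             6.83           0               17           -59.2
```

Reading the numbers: the scar sector was generated with its wall thinned
from 7.0 mm to 5.1 mm while keeping the same epicardial-to-endocardial
angle span, so the transmural gradient of the inclination angle steepens
from ≈ 16 °/mm (≈ 112.5°/7 mm) to ≈ 22 °/mm (≈ 112.5°/5.1 mm); the
intercept stays near the generated epicardial angle of −60°, and the
transmurality of ≈ 0.4 reflects the endocardial-half fibrotic layer after
annular area weighting. Ray-cast thickness carries the ~2% voxelization
bias of a 0.5 mm grid.

`summarize_groups()` compares infarcted against control segments per heart
or per segment, `metric_correlations()` reports the slope–thickness
associations, `uncertainty_curve()` runs the eigenvector Monte-Carlo, and
`autoplot()` / `plot_transmural_profile()` / `plot_slice_map()` provide
ggplot2 views of the results. `run_pipeline()` chains everything from a
YAML/list configuration and writes CSV, NIfTI and a JSON manifest;
`inst/cli/myofiber` exposes `phantom`, `fit` and `run` subcommands for
shell use.

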