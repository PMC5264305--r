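---
title: "Quantifying infarct microstructure from ex-vivo cardiac DTI: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying infarct microstructure from ex-vivo cardiac DTI: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myofiber)
```

## The scientific question

Chronic myocardial infarction replaces myocytes with collagenous scar.
Diffusion tensor imaging of fixed hearts shows two robust signatures: the
scalar signature (mean diffusivity rises, fractional anisotropy falls as
cellular barriers disappear) and, more subtly, an *architectural*
signature. The primary diffusion eigenvector — which tracks the dominant
fiber direction in both myocardium and aligned collagen — largely preserves
the healthy helical organization: left-handed fibers at the epicardium
rotating to right-handed fibers at the endocardium. Because the infarcted
wall is thinner while the epi-to-endo angle span is preserved, the
*transmural gradient* (slope) of the inclination angle steepens, and local
intervoxel disarray (incoherency) increases. `myofiber` turns that analysis
into a tested pipeline and provides a synthetic left ventricle with known
ground truth to validate every stage.

## Signal model and tensor estimation

Diffusion-weighted magnitude signals follow the monoexponential
Stejskal–Tanner model
$S_i = S_0 \exp(-b_i\, g_i^\top D\, g_i)$
with unit encoding directions $g_i$, b-value $b_i$ (s/mm²) and the
symmetric positive-definite tensor $D$ (mm²/s). Estimation is ordinary
least squares on $\ln S_i$ against the design
$(1, -b g_x^2, -b g_y^2, -b g_z^2, -2b g_x g_y, -2b g_x g_z, -2b g_y g_z)$,
solving jointly for $\ln S_0$ and the six tensor elements. OLS rather than
weighted LS is the default because at the SNR of fixed ex-vivo
acquisitions (>100) the heteroscedasticity of log-transformed Rician noise
is negligible; a one-pass IRLS option (`weighted = TRUE`) exists for
low-SNR use. Degenerate inputs are handled explicitly: non-positive
signals are clamped to $10^{-6} S_0$ and the voxel flagged (never dropped),
collinear direction sets abort the fit, and negative fitted eigenvalues are
kept but flagged in `valid_mask` so QC can count them.

Scalar maps follow the standard definitions
$\mathrm{MD} = (e_1+e_2+e_3)/3$ and
$\mathrm{FA} = \sqrt{3/2}\,\lVert \lambda - \bar\lambda \rVert / \lVert
\lambda \rVert$. Under affine registration, tensors are reoriented by the
finite-strain rule $D' = R D R^\top$ with $R$ the rotation factor of the
polar decomposition of the affine's linear part; estimating the affine is
out of scope — it is an input. Resampling is nearest-neighbour, avoiding
tensor-interpolation ambiguity; this is exact for the registered-by-
construction phantoms and a documented approximation elsewhere. SNR is
measured as mean tissue signal over the noise standard deviation estimated
from a signal-free background, $\sigma = \mathrm{sd}(\text{bg})/0.6551$,
the Rayleigh correction for magnitude images.

## The local frame and the two fiber angles

Angles are referenced to a per-voxel orthonormal triad tangential to the
endocardial surface: $n$ is the endocardial surface normal pointing toward
the epicardium, $t = z \times n$ (normalized) is circumferential with $z$
the global apex-to-base axis, and $f = n \times t$ completes the triad.
The *inclination* angle is
$\alpha = \operatorname{atan2}(e_1\!\cdot\!f,\; e_1\!\cdot\!t)$
after flipping the sign-ambiguous eigenvector so $e_1\!\cdot\!t \ge 0$
(ties broken toward $e_1\!\cdot\!f \ge 0$, so $\pm 90$ is reported as
$+90$); the *imbrication* angle replaces $f$ with $n$. With this sign
convention positive inclination is right-handed (endocardial-type) and
positive imbrication tilts toward the epicardium. Both angles are
invariant under $e_1 \to -e_1$. Voxels with $e_1$ parallel to $n$ are
undefined; voxels with $|e_1\!\cdot\!t| < 0.05$ get a low-confidence flag
because imbrication is ill-conditioned for near-longitudinal fibers.

How the normal is computed matters more than it looks. We use the gradient
of the signed Euclidean distance transform to the endocardial surface,
with two numerical safeguards chosen from a noiseless accuracy sweep of
the normal error itself: the distance field is smoothed with a Gaussian of
2 voxels, and the gradient components are smoothed again at twice that
scale. The discrete surface's lattice "staircase" otherwise produces
angular errors that are coherent within a 10° segment — invisible to
segment averages of inclination (which is second-order insensitive to
normal error) but directly biasing segment-mean imbrication, which is
first-order sensitive. The residual floor at 0.5 mm voxels is ≈1°–1.5° of
segment-mean imbrication on a wall-parallel ground truth; the package's
tests assert that bound. Two boundary rules keep distance fields honest on
image stacks: the exterior used for the epicardial distance is restricted
to slices containing wall, and the blood pool is continued axially past
the coverage boundary, so the ends of the stack are never mistaken for
anatomical surfaces.

Wall depth uses the same transforms: `depth_mm` is the distance to the
epicardial surface (half-voxel-corrected so distances refer to the
continuous interface), and `depth_norm = d_epi / (d_epi + d_endo)`. Depth
fields are *not* smoothed by default: the fields are piecewise linear, and
smoothing across their zero-floored boundaries compresses the transmural
scale, which we measured to inflate profile slopes by 3–6%.

## Fibrosis segmentation and polar partition

Fibrosis is segmented on the LGE channel by two-class Otsu thresholding
computed over wall voxels only (256-bin histogram, cumulative-moment
maximization of between-class variance; ties broken at the first maximum;
constant histograms return an empty mask with a warning). A two-threshold
multi-level mode exists behind `levels = 3` for bimodal-plus-background
distributions. The interactive level-set cleanup of manual workflows is
replaced by a deterministic morphological refinement: 6-connected closing
then opening (radius 1), then removal of connected components below 10
voxels. Segmentation quality is assessed as Dice overlap against the
generating mask on the phantom.

The LV wall is partitioned per 1.2-mm short-axis slab into 36 polar
segments of 10°, with the origin at the slab's blood-pool centroid and
angle measured counterclockwise from image $+x$; anatomical labels are a
configuration mapping, since image-to-anatomy registration is not part of
the package. Apical slabs (no blood pool, plus the apical 10% of the
long-axis extent) are excluded. Segments are *infarcted* if they contain
at least one fibrotic voxel (infarcted hearts) and *control* inside a
configurable 180° anteroseptal span (control hearts). Wall thickness per
segment is the mean, over rays at 1° steps from the slab origin, of the
epicardial-minus-endocardial radial intersection length with the wall
mask, sampled at quarter-voxel steps on the wall-bearing slice nearest the
slab midplane; segments thinner than 2 mm, or with fewer than 4 valid
transmural voxels, are excluded from angle statistics.

## Per-segment metrics

For each included segment the package reports: scar transmurality
(fibrotic voxel fraction); the OLS line of inclination versus depth from
the epicardium (slope in °/mm, intercept in degrees, r²); the [1–99]%
inclination range (linear-interpolation percentiles — stated explicitly
because percentile conventions differ materially at segment sample
sizes); the mean signed imbrication angle; the left-handed
($\alpha < -15°$), circumferential ($|\alpha| \le 15°$) and right-handed
($\alpha > 15°$) voxel ratios, with the boundary values assigned to the
circumferential class so the three ratios always sum to one (strict
inequalities on all three classes would leave ±15° unassigned); and the
inclination and imbrication *incoherencies*, defined here as the mean
acute angular difference $\min(|\Delta|, 180-|\Delta|)$ over all
6-connected in-segment voxel pairs. The incoherency definition is this
package's own (the quantity is conventionally described but not
standardized); it is deterministic, symmetric, and reduces to zero on a
constant field.

Two internal consistencies are tested rather than assumed: slope ×
thickness approximates the full angle span on linear noiseless profiles,
and slope correlates positively with inverse thickness when the range is
held fixed — the mechanism by which wall thinning, not angle
reorganization, drives the steeper infarct gradient.

## The synthetic left ventricle

The phantom is a cylindrical annulus (default endocardial radius 8 mm,
epicardial 15 mm — a 7.0 mm wall; 0.5 mm isotropic voxels on a 64×64×96
grid; 40.8 mm long axis). A 60° sector is thinned by 5.1/7.0 with the
epicardial surface moved inward, and the endocardial half of that sector's
depth span is fibrotic. The ground-truth inclination rotates linearly with
normalized depth from −60° at the epicardium through +52.5° at the
endocardium (range 112.5°); ground-truth imbrication is 0 (a nonzero
option exists for stress tests). Tensors are prolate
($\lambda_2 = \lambda_3$) with eigenvalues solved in closed form from the
prescribed (MD, FA) — normal tissue 6.33×10⁻⁴ mm²/s at FA 0.37, fibrotic
9.08×10⁻⁴ at 0.24. The acquisition is 15 electrostatically-repelled
hemisphere directions at b = 800 s/mm² plus one b = 0 image, with Rician
noise (magnitude of a complex Gaussian, $\sigma = S_0/\mathrm{SNR}$,
default SNR 120); the LGE channel is Gaussian with means 200 (scar) and
100 (wall) at SD 10. All randomness is seed-controlled and bit-for-bit
reproducible.

What the phantom deliberately does **not** emulate: real ventricular
anatomy (no apex closure, no papillary or trabecular structures — their
exclusion is mask-based, as in manual contouring), partial-volume and
fixation-shrinkage effects, k-space reconstruction, eddy-current or
susceptibility artifacts, and — most importantly — *microstructural*
disarray: the phantom's incoherency arises only from the transmural
gradient plus estimation noise. Passing tests therefore demonstrate that
the pipeline measures what it claims on data obeying its model, not that
real scars behave this way.

For the cohort-level directional comparison (8 infarcted vs 4 control
hearts, the study design), per-group inclination endpoints are taken from
the groups' printed regression parameters — control: epicardial −54.0°,
range 112.5°; infarcted: epicardial −60.4°, range 111.0° — with infarct
thinning 5.1/7.0 and fibrotic MD/FA in the scar. Identical endpoints in
both groups would *not* reproduce a higher left-handed ratio in infarcts
(thinning preserves the depth profile, so handedness fractions barely
move); the group intercepts do. Per-heart biological jitter is SD 2° on
the endpoints and 0.05 on the thinning factor — deliberately smaller than
printed per-heart dispersions, which already include measurement noise
that the simulation regenerates itself.

## Statistics

Group comparisons use the two-sided Wilcoxon rank-sum test: exact null
enumeration for tie-free samples with $\min(n,m) \le 8$, tie-corrected
normal approximation with continuity correction otherwise (the continuity
correction keeps the approximation within 0.02 of exact enumeration at
n = m = 7, which the tests verify). Comparisons run *per heart* (metrics
averaged within heart, tested across heart means) and *per segment*
(pooled records); no multiple-testing correction is applied, and the
output metadata says so. Percent changes are signed,
$100\,(a - b)/b$ against the control reference, rounded to integer percent
only at presentation. The Monte-Carlo eigenvector-uncertainty analysis
simulates a single-voxel prolate tensor at given (FA, MD), adds Rician
noise at given SNR, refits, and summarizes the angular deviation of the
fitted primary eigenvector over paired-seed repetitions — quantifying how
much incoherency could stem from estimation noise alone at scar-level FA.

## Numerical choices and problem sizes

Eigendecomposition uses a compiled symmetric 3×3 solver with descending
eigenvalues and a deterministic sign rule (first non-negligible component
positive); downstream angles are sign-invariant regardless. Distance
transforms are an exact Felzenszwalb lower-envelope implementation with
anisotropic spacing. Gradient-scheme optimisation runs 300 seeded
electrostatic-repulsion iterations with antipodal symmetry and requires a
design condition number below 10; `n = 6` returns the classic dual-gradient
preset. Validity tolerances: eigenvector orthonormality 1e−8, negative-
eigenvalue flagging with a roundoff guard of 1e−9 relative, frame
degeneracy $\lVert z \times n\rVert < 10^{-6}$.

The test suite exercises short phantoms (64×64×16, 6 mm of long axis) for
unit-level checks, the full default geometry for angle-recovery and
partition checks, a 64³ noiseless volume for the exact simulate→fit round
trip, five noisy phantoms for seed-averaged slope recovery, 1000-repetition
Monte-Carlo sweeps, and the full 8-vs-4 cohort for the directional
comparison — sizes chosen to validate each property at the smallest scale
where its effect is unambiguous.

## Known limitations

Voxel-grid normals carry a ~1° coherent imbrication floor at 0.5 mm
resolution (see above); ray-cast thickness is biased low by ~2–3% of a
voxel-limited boundary; the phantom's handedness ratios inherit an annular
area weighting (outer-radius voxels are more numerous), so its left-handed
ratio sits above the naive depth-fraction value; incoherency magnitudes on
the phantom are dominated by the transmural gradient and estimation noise
and are therefore smaller than in real scar, where structural disarray
adds to them; and no secondary/tertiary eigenvector (sheet) analysis is
attempted.
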