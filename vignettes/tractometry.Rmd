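---
title: "Along-tract quantification of SLF branches: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Along-tract quantification of SLF branches: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fiberquant` implements a complete diffusion-tensor tractometry chain for
the superior longitudinal fasciculus (SLF) and its language-related II and
III branches: tensor estimation from diffusion-weighted MRI, deterministic
whole-brain streamline tracking, virtual dissection with coronal waypoint
regions of interest, 100-node tract profiles of four diffusion metrics,
and node-wise two-group comparison under family-wise error control. A
synthetic phantom and cohort generator makes every stage testable end to
end without any imaging data. This vignette documents the models, the
tunable parameters and the design decisions, in that order.

## The diffusion tensor model

Each voxel's diffusion-weighted signal is modeled by the Stejskal-Tanner
equation

$$S_i = S_0 \, \exp(-b_i \, g_i^\top D \, g_i),$$

where $b_i$ (s/mm$^2$) and the unit vector $g_i$ describe frame $i$ of the
acquisition and $D$ is the symmetric positive $3\times3$ diffusion tensor
(mm$^2$/s). Taking logarithms linearizes the model, and
`build_design_matrix()` produces the classical design with rows
$-b_i(g_x^2, g_y^2, g_z^2, 2g_xg_y, 2g_xg_z, 2g_yg_z)$ plus an intercept
for $\ln S_0$. `fit_tensor()` solves the system by ordinary (unweighted)
least squares per voxel, vectorized over the whole grid.

*Why OLS.* Weighted or nonlinear variants differ mainly at low SNR; at the
SNR regime the package targets (simulated at SNR 30, matching a clinical
3T protocol) the OLS fit recovers noiseless tensors to machine precision
and keeps the estimator deterministic and fast. The eigen-decomposition is
computed by a closed-form trigonometric solver for symmetric $3\times3$
matrices with spectral-projector eigenvectors, which agrees with `eigen()`
to ~1e-16 while being vectorizable over hundreds of thousands of voxels.

From the sorted eigenvalues $\lambda_1 \ge \lambda_2 \ge \lambda_3$,
`compute_scalar_maps()` derives

- FA $= \sqrt{\tfrac12}\,\sqrt{(\lambda_1-\lambda_2)^2 +
  (\lambda_2-\lambda_3)^2 + (\lambda_3-\lambda_1)^2} \big/
  \sqrt{\lambda_1^2+\lambda_2^2+\lambda_3^2}$ (0 for the zero tensor),
- MD $= (\lambda_1+\lambda_2+\lambda_3)/3$,
- AD $= \lambda_1$, and RD $= (\lambda_2+\lambda_3)/2$.

Numerical choices: signals are floored at $10^{-6}\max S$ before the
logarithm so background voxels cannot produce $-\infty$; negative
eigenvalues (possible under noise) are clamped to zero and counted in the
QC field `n_clamped`, which also guarantees FA $\le 1$.

## Deterministic tracking (FACT)

`track_whole_brain()` seeds one streamline at the center of every voxel
with FA $\ge$ `seed_fa_min` (default 0.3) and follows the per-voxel
principal eigenvector bidirectionally — the fiber assignment by continuous
tracking scheme, where the direction field is read by nearest-voxel lookup
rather than interpolation. A streamline stops when

1. the next point would enter a voxel with FA below `fa_stop`
   (default **0.2**),
2. the turn between the last path segment and the next step exceeds
   `max_angle_deg` (default **30°**),
3. it leaves the grid, or
4. it exceeds `max_len_mm` (default 250 mm).

Tracks shorter than `min_len_mm` (default 20 mm) are discarded. The two
FA/angle defaults are the termination rules of the emulated protocol; the
remaining bounds are conventional and configurable.

Design decisions worth knowing:

- **Step size** defaults to 0.75 mm — half the 1.5 mm voxel. Classical
  FACT steps from boundary to boundary; a fixed sub-voxel step with
  nearest-voxel direction lookup reproduces that behavior closely while
  keeping the angle criterion meaningful and the implementation
  vectorizable across all active streamlines at once.
- **Terminal points.** The point reached by the last valid step is always
  recorded, so a streamline's endpoint may sit in the low-FA look-ahead
  voxel that triggered termination. This makes a 30 mm high-FA slab track
  to 30 mm within one step instead of systematically undershooting.
- **Eigenvector sign.** The eigenvector of each entered voxel is
  sign-aligned with the previous direction; at the seed both polarities
  are tracked and concatenated.
- Tracking is fully deterministic: identical inputs and parameters yield
  byte-identical tractograms.

## Virtual dissection with waypoint ROIs

The SLF II and III branches are dissected by the two-ROI rule: a
streamline belongs to a tract iff it intersects both ROIs of the tract's
pair. `define_slf_rois()` returns, per hemisphere, a dorsal (SLF II) and a
ventral (SLF III) box on the coronal plane at the anterior commissure
(y = 2 mm) and a shared box on the posterior-commissure plane
(y = −25 mm); the whole SLF uses the merged anterior box. The plane
y-coordinates follow the published convention; the in-plane box extents
are configurable defaults without anatomical validation, which is why all
shipped tests run in phantom space with phantom-calibrated ROIs.

ROIs live either as analytic plane slabs or as binary masks.
`transform_rois()` maps plane ROIs analytically under axis-aligned
affines (sufficient for the supported affine-registration contract —
nonlinear warping is explicitly out of scope and must be applied upstream)
and mask ROIs either by affine composition or nearest-neighbor resampling
onto a target grid.

Bundles are then refined in two steps mirroring common practice:

- `score_against_probability_map()` scores each streamline as the mean
  trilinearly interpolated value of a fiber probability map along its
  points; `clean_bundle()` discards the lowest `score_quantile` (default
  0.05) of scores.
- Length outliers with $|z| >$ `length_z_max` (default 3) relative to the
  bundle's length distribution are removed, iterating to a fixpoint
  (max 5 rounds) because extreme lengths distort the initial mean and SD.

`lesion_overlap_screen()` implements the patient-selection rule: a lesion
affects a tract when any lesion voxel lies where the tract's probability
map exceeds 0.5. The wording of such rules is ambiguous between
"any voxel" and "majority of voxels"; the default is the more sensitive
any-voxel rule, with `rule = "majority"` available.

## Tract profiles

`compute_tract_profile()` resamples every cleaned streamline to
`n_nodes = 100` equally spaced arc-length positions (piecewise-linear,
endpoints preserved exactly), orients all streamlines anterior-to-posterior
(decreasing y, ties broken by distance to the anterior ROI centroid), and
averages the trilinearly sampled FA/MD/AD/RD values per node across
streamlines. The default is the unweighted mean for transparency; a
`gaussian_distance` mode down-weights spatial stragglers by
$\exp(-d^2/2\sigma^2)$, with $d$ the distance to the node's mean position
and $\sigma$ the node's point-cloud SD, and reduces exactly to the uniform
mean when all streamlines coincide. Trilinear (not nearest-voxel) scalar
sampling avoids voxel-edge artifacts in the profiles.

Because sampling is linear, the identity MD = (AD + 2 RD)/3 survives from
the voxel maps into every profile node, which the tests assert at 1e-9.

## Group statistics

`nodewise_ttest()` runs a two-sided, equal-variance two-sample t-test per
node on subject-level node values (Welch via `var_equal = FALSE`); a node
with zero pooled variance reports p = 1 rather than NaN. `fwe_correct()`
controls the family-wise error over the 100 nodes by the permutation
max-T procedure: group labels are permuted (`n_perm` default 10,000, or
exhaustively enumerated when the group sizes admit fewer distinct splits),
the maximum |t| over nodes forms the null distribution, and each node's
adjusted p is the null tail probability at its observed |t|. Bonferroni
(`p_adj = min(1, 100 p)`) is the conservative alternative. Adjusted
p-values are floored at the raw p-value: with small samples the discrete
permutation distribution can otherwise dip below the parametric raw p,
violating the monotonicity users expect of an adjustment. Sampled (not
exhaustive) permutation p-values include the +1 correction so a true null
can never report p = 0.

`summarize_table()` reproduces the familiar cohort summary: per group,
tract and metric, the subject-level tract means (averaged over all 100
nodes) as mean ± SD to two decimals, star-marked when more than
`min_sig_nodes` (default 10) nodes are FWE-significant. The "more than 10
nodes" star rule is a reporting convention for sustained significance; the
tract mean itself always averages all nodes.

## The synthetic phantom and what it does (not) show

`make_slf_like_scene()` builds the geometry all tests run on: per
hemisphere, two tubes of radius 4 mm around arched centerlines running
anterior (y = 22 mm) to posterior (y = −40 mm), a dorsal one emulating
SLF II (base z = 20 mm) and a ventral one emulating SLF III (base
z = 6 mm), both arching 8 mm in z. Inside a tube the tensor is prolate
with eigenvalues (1.7, 0.3, 0.3)×10⁻³ mm²/s (FA ≈ 0.80) aligned with the
local tangent; the background is isotropic at 0.7×10⁻³ mm²/s (FA = 0,
MD matching parenchyma). The scene also provides phantom-space waypoint
ROIs, per-bundle probability maps (Gaussian-smoothed bundle density,
normalized to [0, 1]), and a 6 mm spherical lesion overlapping the left
dorsal bundle.

`make_gradient_table()` reproduces the emulated acquisition — 3 b = 0
frames plus 64 directions at b = 1,000 s/mm² on a 1.5 mm isotropic grid —
with directions spread by antipodally-symmetric electrostatic repulsion
from a deterministic golden-spiral start (minimum pairwise angle ≈ 15.8°).
`simulate_dwi()` adds Rician noise — the magnitude-MRI noise model — as
$\sqrt{(S+\varepsilon_1)^2 + \varepsilon_2^2}$ with
$\varepsilon \sim N(0, S_0/\mathrm{SNR})$.

`make_cohort()` draws two groups (default 15 subjects each, SNR 30): each
subject's bundle geometry is rigidly jittered (SD 0.5 mm), group effects
from `effect_spec()` are injected **on the eigenvalues** within a node
range — an AD effect scales $\lambda_1$, an RD effect $\lambda_{2,3}$, an
MD effect all three, an FA effect the deviations from their mean (MD
preserved) — so the four metrics remain mutually consistent, and a ledger
records the exact per-node truth. Cohort defaults (n = 15/group, SNR 30,
0.5 mm jitter) are the study conditions the package emulates; the jitter
SD is the one free parameter, chosen as a plausible residual
misregistration after affine alignment.

What the phantom does **not** emulate: crossing or kissing fibers (a known
limitation of single-tensor FACT), partial-volume mixtures beyond the
tube boundary, anatomically realistic bundle shapes, susceptibility or
motion artifacts, and inter-subject anatomical variability beyond rigid
jitter. Passing tests therefore demonstrate algorithmic correctness and
statistical calibration of the chain, not anatomical accuracy on real
brains.

## Problem sizes and reproducibility

The default scene is a 60×72×60 grid at 1.5 mm. The test suite and the
acceptance script run the cohort-scale experiments on a 24×48×24
single-hemisphere cut of the same geometry, which keeps a full 30-subject
cohort (simulate, fit, track, dissect, profile, test) near half a minute
while preserving ~90-node profiles and realistic streamline counts; the
statistical calibration experiments run at the profile level
(15 + 15 subjects × 100 nodes per replicate) with 200-500 replicates.
All randomness — noise, jitter, permutations, jittered seeding — flows
through explicit integer seeds, and every generator restores the caller's
RNG state; reruns are byte-identical.

## Known limitations

- Single-tensor FACT cannot resolve crossing fibers; profiles through
  crossing regions on real data inherit that bias.
- Waypoint box extents are not anatomically validated; users analyzing
  real brains must supply ROIs (or extents) appropriate to their template
  and an upstream-estimated affine into subject space.
- Whole-SLF profiles share streamlines with the branch profiles, so their
  statistics are not independent across tracts.
- FWE control is per (tract, hemisphere, metric) comparison over the 100
  nodes, matching the emulated analysis; no additional correction is
  applied across the metrics and tracts reported side by side.
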