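# fiberquant

Along-tract quantification ("tractometry") of the superior longitudinal
fasciculus (SLF) and its language-related **SLF II** and **SLF III**
branches from diffusion tensor imaging, in R.

Most white-matter studies treat the SLF as a single bundle, which can hide
branch-specific microstructural change — for example the opposite-signed
diffusivity patterns reported in the right SLF II vs SLF III of patients
whose left-hemisphere language network developed around a congenital
lesion. `fiberquant` is for researchers who want to reproduce that style
of analysis — branch-resolved, node-resolved group comparison — on their
own diffusion data, and for methodologists who want every stage of the
chain testable against a ground-truth phantom.

## What the package computes

1. **Tensor model.** Per voxel, the Stejskal–Tanner model
   `S = S₀ exp(−b gᵀ D g)` is fitted by log-linear least squares;
   from the eigenvalues λ₁ ≥ λ₂ ≥ λ₃ it derives
   FA = √½ √((λ₁−λ₂)² + (λ₂−λ₃)² + (λ₃−λ₁)²) / √(λ₁²+λ₂²+λ₃²),
   MD = (λ₁+λ₂+λ₃)/3, AD = λ₁, RD = (λ₂+λ₃)/2.
2. **Deterministic tractography (FACT).** Whole-brain streamlines follow
   the per-voxel principal eigenvector, stopping at FA < 0.2 or a turn
   > 30° per step.
3. **Virtual dissection.** Streamlines passing both ROIs of a waypoint
   pair form a tract: dorsal/ventral anterior-commissure boxes (y = 2 mm)
   for SLF II / SLF III, a shared posterior-commissure box (y = −25 mm),
   and a merged anterior box for the whole SLF — then probability-map
   scoring and length-outlier cleaning.
4. **Tract profiles.** Every bundle is resampled to 100 equally spaced
   nodes; FA/MD/AD/RD are averaged per node across streamlines.
5. **Group statistics.** Node-wise independent-sample t-tests with
   family-wise error control over the 100 nodes (permutation max-T by
   default, Bonferroni as alternative), plus the star-marked
   mean ± SD summary table.
6. **Synthetic phantom.** SLF-like bundle scenes, the 3 × b0 + 64-direction
   b = 1,000 s/mm² acquisition, Rician noise, and two-group cohorts with
   node-localized eigenvalue effects and an exact ground-truth ledger.

Standard formats are supported throughout: NIfTI (via RNifti), FSL
`.bval`/`.bvec`, TrackVis `.trk`, and a long-format profile CSV.

## Worked example

A full subject-level run on a synthetic single-hemisphere scene:

```r
library(fiberquant)

scene <- make_slf_like_scene(grid_shape = c(24, 48, 24),
                             center_mm = c(-18, -9, 17), hemispheres = "L")
gtab <- make_gradient_table()
gtab
#> gradient_table: 67 frames (3 b0, 64 weighted), b up to 1000 s/mm^2

dwi <- simulate_dwi(scene$field, gtab, s0 = 1000, snr = 30, rng_seed = 1)
res <- run_subject(dwi, scene$rois, pipeline_config(),
                   subject_id = "demo", group = "control",
                   prob_maps = list(union = scene$prob_map$union))
res$profiles[["SLF_II|L"]]
#> tract_profile SLF_II (L) subject demo [control]: 100 nodes, 712 streamlines

head(res$profile_df[res$profile_df$tract == "SLF_II",
                    c("node", "fa", "md", "ad", "rd")], 3)
#>   node    fa       md      ad       rd
#> 1    1 0.275 0.000725 0.00103 0.000573
#> 2    2 0.567 0.000748 0.00141 0.000420
#> 3    3 0.747 0.000763 0.00164 0.000327
```

The whole-brain tractogram holds 1,674 streamlines, of which 1,410 thread
the merged SLF waypoints and 712 / 697 the SLF II / SLF III pairs. The
node-1 FA (0.28) is depressed by partial volume with the isotropic
background at the bundle end; by node 3 it approaches the in-bundle value
(true FA 0.80, MD 0.77×10⁻³ mm²/s). Diffusivities are in mm²/s.

Group-level comparison takes a long profile table for two groups and
returns node-wise FWE-corrected statistics and the summary table:

```r
out <- run_group(profile_df_all_subjects, pipeline_config())
out$table          # mean ± SD per group/tract/metric, starred when > 10
                   # nodes are FWE-significant
out$stats[["SLF_II|L|ad"]]$sig   # per-node significance flags
```

`plot_profile_comparison()` renders the group mean ± SE node curves with
significance asterisks.

## Scope

Inputs are assumed preprocessed (eddy-current/motion/bias corrected) and
registration into subject space is accepted only as an affine; nonlinear
warping, crossing-fiber models, probabilistic tracking, and tracts outside
the SLF family are out of scope. See the methods vignette
(`vignettes/tractometry.Rmd`) for the models, parameter defaults, design
decisions, and what phantom-based validation does and does not show.
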