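# shellcontrast

Quantitative comparison of regional tumor contrast across breast MRI
protocols.

When a breast tumor is segmented on contrast-enhanced MRI, how clearly it
stands out from the tissue around it determines how reliably its extent can
be delineated — the quantity that matters for surgical planning, and the
quantity that degrades when a supine scan is acquired late after contrast
injection, because tumor signal washes out while normal fibroglandular
enhancement persists. `shellcontrast` turns that question into numbers:

1. **Equal-volume boundary shell.** Around the tumor mask it grows a shell
   of surrounding voxels, stratum by stratum of the spacing-aware Euclidean
   distance transform, stopping at the smallest margin thickness whose shell
   volume first reaches the tumor volume. Tumor and boundary are then
   volumetrically equivalent regions.
2. **Tissue partition.** Shell voxels are classified by Otsu's threshold on
   the shell's intensity histogram (256 bins): the dark class is adipose
   (fat-suppressed), the bright class fibroglandular. The fibroglandular
   boundary composition is the fibroglandular fraction of the shell volume.
3. **Contrast metrics.** For mean intensities \(\bar I_T\) (tumor) and
   \(\bar I_B\) (boundary or one tissue compartment), the normalized
   contrast is the Michelson contrast

   \[ C = \frac{\bar I_T - \bar I_B}{\bar I_T + \bar I_B} \in [-1, 1], \]

   reported tumor-to-boundary, tumor-to-adipose, and
   tumor-to-fibroglandular, alongside SNR (mean/σ), CNR (Δmean/σ),
   voxelwise ROC AUC (identical to Mann–Whitney \(U/n_1n_2\)), and tumor
   size/shape metrics (volume, maximum extent, face-counted surface area,
   sphericity).
4. **Cohort statistics.** Per-metric cohort comparisons with Welch t-tests
   (α = 0.05, unequal variances), Mann–Whitney U tests, one-sample KS
   normality checks, post-hoc power via the noncentral t distribution, and
   one-sided non-inferiority tests of each protocol against a reference
   cohort at a margin of −0.1 normalized contrast units (α = 0.025, verdict
   equivalent to the lower 95% Welch CI bound lying above the margin), plus
   Pearson correlations with Fisher-z 95% CIs between tumor-to-boundary
   contrast and boundary composition or tumor shape.
5. **Synthetic phantoms.** A 3D phantom generator (ellipsoidal tumor,
   smoothed-random-field adipose/fibroglandular texture with exact labels,
   Gaussian or Rician noise, delayed-acquisition washout regime) provides
   ground-truth cases and whole cohorts so every stage is testable without
   clinical data.

## Worked example

```r
library(shellcontrast)

ph <- make_phantom(phantom_spec(seed = 7))          # 48x48x32 @ 1x1x2 mm
sh <- build_boundary_shell(ph$tumor, ph$volume, body = ph$body)
pt <- partition_shell(ph$volume, sh)
rep <- case_report(ph$volume, ph$tumor, sh, pt,
                   air = region_mask(!ph$body$mask, ph$body$spacing),
                   case_id = "demo_001", cohort_label = "early")
print(sh); print(pt); print(rep)
```

```
<boundary_shell> thickness 2.449 mm, shell 2164 mm^3 vs tumor 2074 mm^3
<boundary_partition> threshold 49.53, fibro fraction 0.300
<case_report> demo_001 (early)
  contrast  t-boundary 0.803 | t-adipose 0.907 | t-fibro 0.601
  fibro fraction 0.300, AUC t-fibro 1.000, CNR t-fibro 30.04
```

The shell matched the 2074 mm³ tumor with a 2.45 mm margin; Otsu found the
adipose/fibroglandular split at intensity 49.5, recovering the phantom's
nominal 30% fibroglandular composition (true realized fraction 0.3004), and
the recovered tumor-to-fibroglandular contrast 0.601 matches the analytic
value 0.6 for the phantom's means (400 vs 100).

Cohort-level, simulated end to end (20 cases per arm; early phase vs
delayed acquisition with washout factor 0.5):

```
  non-inferiority vs 'early' (margin -0.10):
    contrast_tumor_fibro     delayed   diff -0.171 [-0.182, -0.161] -> inferior_not_shown
    contrast_tumor_adipose   delayed   diff -0.054 [-0.066, -0.042] -> non_inferior
```

Washout erodes tumor-to-fibroglandular contrast past the margin while
tumor-to-adipose contrast — anchored by near-zero fat signal — stays
non-inferior, the qualitative signature of a delayed supine acquisition.

A thin command-line front end with `simulate-cohorts`, `analyze-cohort` and
`compare` subcommands is installed at `inst/cli/shellcontrast.R`.

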