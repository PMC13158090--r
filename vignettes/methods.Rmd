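---
title: "Methods: equal-volume boundary-shell contrast and cohort non-inferiority"
author: "shellcontrast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: equal-volume boundary-shell contrast and cohort non-inferiority}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# The measurement problem

A segmented breast tumor is only as useful for surgical planning as it is
distinguishable from the tissue immediately around it. On fat-suppressed
contrast-enhanced T1 MRI that surrounding tissue is a patient-specific
mixture of dark adipose and bright, enhancing fibroglandular tissue, and
the conspicuity of the tumor against it changes with acquisition timing:
at later post-injection times tumor signal washes out while normal
parenchymal enhancement persists. `shellcontrast` quantifies this with a
ratiometric, orientation-agnostic measurement that can be compared across
scanners, sequences and patient positions, and a cohort-level framework
that asks whether one protocol's contrast is *non-inferior* to another's.

All computation happens in voxel space on one grid: the volume and its
masks are never resampled, because every quantity used — mean intensities
over voxel sets and spacing-aware distances and volumes — is well defined
there. The only geometric assumptions are a common grid for volume and
masks (enforced at load time; spacing disagreement beyond 1e-3 mm per axis
is an error, since a silent mismatch would corrupt every mm³ quantity) and
whole-voxel mask membership.

# Equal-volume boundary shell

The boundary region is the layer of non-tumor voxels nearest the tumor,
grown until its physical volume first reaches the tumor's physical volume,
so that tumor and boundary means are averages over volumetrically
equivalent regions. Concretely:

1. Compute the Euclidean distance from every voxel centre to the nearest
   tumor voxel centre with an exact anisotropic distance transform
   (separable lower-envelope algorithm, implemented in C++). The transform
   is spacing-aware because axial breast MRI is typically ~1×1 mm in-plane
   with 2 mm slices; a voxel-step dilation would grow the shell twice as
   fast (in mm) along the slice axis.
2. Group eligible voxels (non-tumor; intersected with the body mask when
   one is supplied) into *strata* of equal distance and absorb whole
   strata in increasing distance order until the shell volume first
   reaches the tumor volume.

The realized margin thickness is the distance of the last absorbed
stratum. Including the final stratum whole keeps the construction
deterministic and mask-reproducible — no random sub-sampling of the last
stratum — at the cost of a small overshoot (bounded by one stratum), which
the reported `shell_volume_mm3` makes visible. Minimality is an invariant:
dropping the outermost stratum always leaves less than the tumor volume.
Two degenerate situations are handled explicitly: a tumor filling its
entire grid/body has no boundary (error), and an eligible region smaller
than the tumor yields the full eligible shell with a `volume_deficit`
flag.

Numerical detail: strata are formed on distances rounded to 10 significant
digits. Equal distances can be computed along different axis orders of the
separable transform and may differ in the last bit; without the rounding a
single stratum could split in two and the tie-break (absorb whole strata)
would depend on floating-point noise.

No pectoral-muscle exclusion is attempted: muscle falling inside the shell
is tolerated and ends up in the bright (fibroglandular) class. Air
exclusion is delegated to the optional body mask; without one the shell
may include air, which is the caller's modelling choice for tumors near
the skin.

# Tissue partition

Shell intensities are split by Otsu's method: a 256-bin equal-width
histogram over the shell's intensity range, and the bin edge maximizing
the between-class variance ω₀ω₁(μ₀−μ₁)². Binning is right-closed so a
value equal to the returned threshold belongs to the lower class,
consistent with the labelling rule *adipose ≤ threshold <
fibroglandular*; the low class is adipose because fat suppression is what
makes adipose the dark compartment on every sequence this measurement
targets. Ties in the variance scan are broken toward the lowest
qualifying edge, which makes the threshold deterministic; on a cleanly
bimodal histogram the variance is flat across the empty inter-mode gap,
so the returned edge sits at the gap's lower end — the classification,
which is all that matters downstream, is identical anywhere in the gap.
The bin count is a configuration knob (`otsu_bins`); 256 is the standard
default and the partition is invariant under any strictly increasing
affine intensity map when bins are recomputed on the mapped range.

A shell whose voxels are all one intensity has no threshold. The whole
shell is then assigned to a single tissue by comparing its mean to the
tumor mean (darker than the tumor reads as adipose) and flagged
`degenerate_partition`; the affected tissue metrics propagate as missing
values with `no_fibro`/`no_adipose` flags, never as silent zeros, so
cohort statistics run on the defined subset.

The fibroglandular boundary composition is the fibroglandular share of the
shell's physical volume (identical to the voxel-count share on a single
grid, but stated as volume for generality).

# Per-case metrics

For regions tumor/boundary/adipose/fibroglandular with means
$\bar I$, the package reports Michelson contrast
$(\bar I_a - \bar I_b)/(\bar I_a + \bar I_b)$ for tumor-to-boundary,
tumor-to-adipose and tumor-to-fibroglandular; it is bounded in [−1, 1]
and invariant to global intensity scaling, which is the point of a
ratiometric metric. Companion metrics:

* **SNR and CNR.** These need a noise scale σ, and no single convention is
  universal, so the definition is explicit and configurable: σ is (in
  order of preference) a user-supplied value, the SD of a supplied air
  background region, or a robust MAD estimate over the darkest decile of
  shell intensities. SNR = mean/σ per region, CNR = (mean difference)/σ
  per tissue pair. If no positive σ is obtainable the SNR/CNR are missing
  with a `noise_estimation_failed` flag; contrasts and AUCs never depend
  on σ. For Rician noise the air-background SD underestimates the
  Gaussian σ (Rayleigh background); the provided-σ mode exists for that
  case.
* **ROC AUC.** Voxelwise intensity as the score, tumor voxels as
  positives, one tissue compartment as negatives, ties counted ½ — the
  rank formulation identical to Mann–Whitney U/(n₁n₂), asserted against
  all-pairs counting in the tests.
* **Shape.** Volume; maximum extent as the largest pairwise spacing-aware
  distance between surface-voxel centres, floored at the largest voxel
  edge so a single-voxel mask reports a physical extent; surface area by
  exposed-face counting; sphericity π^{1/3}(6V)^{2/3}/A. Face counting is
  simple and deterministic but overestimates smooth surface area: a
  digitized ball converges to 3/2 of its smooth area, so its sphericity
  converges to ≈ 2/3 rather than 1 (a unit cube gives 0.806). Sphericity
  is therefore a relative shape index, comparable across tumors measured
  the same way, not an absolute roundness on [0, 1]; the tests assert
  convergence to the face-counting constant.

The tumor mean uses all tumor voxels — enhancing rim and necrotic core
alike — with no trimming rule.

# Cohort statistics

Per metric and cohort pair: Welch two-sample t-tests (α = 0.05, unequal
variances, Welch–Satterthwaite df), Mann–Whitney U tests (exact for small
tie-free samples, tie-corrected normal approximation otherwise), and
one-sample Kolmogorov–Smirnov normality checks. The KS test is run
against a normal with the sample's own mean and SD; with estimated
parameters its p-value is conservative, and a Lilliefors-corrected
variant is available (`ks_normality(x, lilliefors = TRUE)`).

**Non-inferiority.** For a new protocol vs a reference, with differences
oriented new-minus-reference and a margin of −0.1 normalized contrast
units (lower contrast is worse), the test is the one-sided Welch test of
H₀: μ_diff ≤ margin at α = 0.025. The implemented rejection rule is the
standard one — reject inferiority when the one-sided p < 0.025,
equivalently when the lower bound of the two-sided 95% CI on the
difference lies entirely above the margin; both forms are computed and
their agreement is asserted on every call. Verdicts are `non_inferior`
or `inferior_not_shown` (failing to reject inferiority is not evidence
of inferiority). Type-I error at the margin is verified by Monte Carlo
in the test suite (10,000 replicates at n = 61/78, SD 0.12).

**Post-hoc power** is computed at the observed effect via the noncentral
t distribution with Welch df (noncentrality relative to the margin for
non-inferiority tests). It is a monotone transform of the observed p and
is reported as a descriptive companion, not an inferential quantity.

**Correlations** between tumor-to-boundary contrast and fibroglandular
composition (and tumor volume / maximum extent / sphericity) use Pearson
r with the Fisher-z 95% CI, tanh(atanh r ± z₀.₉₇₅/√(n−3)). Tumor-to-
boundary contrast itself is never compared across cohorts: it depends on
per-case boundary composition, which is exactly the dependence the
correlation analysis quantifies (more bright fibroglandular tissue in
the boundary raises the boundary mean and must lower the normalized
contrast — the tests confirm the strongly negative correlation).
Flagged/missing per-case metrics are excluded listwise per metric. No
multiple-testing correction is applied; every test is reported
individually. The non-inferiority reference cohort is always named in
the configuration, never inferred from the data.

# Synthetic phantoms and what they do (not) show

The generator builds: an ellipsoidal tumor of elevated mean inside an
ellipsoidal body; peritumoral tissue labelled adipose/fibroglandular by
thresholding a Gaussian-smoothed white-noise field (correlation length in
mm; default 4 mm), which yields the spatially clumped, bimodal shell
histograms the partition stage must handle while keeping ground-truth
labels exact; near-zero air outside the body; additive Gaussian noise
(default; magnitude MRI at moderate SNR) or Rician noise.

The texture threshold is taken at the empirical quantile *within the
equal-volume peritumoral layer* (the same deterministic construction the
analysis uses), so the nominal fibroglandular fraction governs exactly
the region the pipeline measures; with the default correlation length a
body-wide quantile would leave the shell-local fraction fluctuating by
tenths, which would confound any parameter-recovery assessment of the
classifier.

Default study conditions, chosen once: 48×48×32 voxels at 1×1×2 mm
(typical axial acquisition geometry), tumor semi-axes 8 mm (~16 mm
lesion), intensity means tumor 400, fibroglandular 100, adipose 20, air 2
(arbitrary scanner units), noise σ = 10. Adipose sits near the noise
floor because that is what fat suppression does, and it is what gives the
delayed-acquisition regime its characteristic asymmetry: the
tumor-to-adipose Michelson contrast is near saturation and insensitive to
tumor washout, while tumor-to-fibroglandular contrast is eroded directly.

Cohorts draw per-case jitter (5% SD on intensity means, 15% on tumor
size, truncated at ±3 SD; fibroglandular fraction uniform on
[0.15, 0.6]). The delayed regime applies a washout factor w ∈ [0, 1]:
tumor mean → fibro mean + (tumor − fibro)(1 − w), with an optional
fibroglandular persistence multiplier applied afterwards. Per-case
randomness derives from the cohort seed and case index only, so two
cohorts sharing a seed share geometry and noise and differ only through
the washout transform: w = 0 reproduces the early cohort byte for byte,
and the expected tumor-to-fibroglandular contrast is strictly decreasing
in w case by case. Linear parameterization in w is deliberate;
pharmacokinetic enhancement curves are out of scope.

What passing on phantoms does **not** show: the phantoms have no
prone↔supine deformation, no bias field or coil-profile shading, no
motion or streak artifacts, no partial-volume mixing at tissue borders,
no multi-focal disease, and anatomically unrealistic (stationary,
isotropic) tissue texture. Results on phantoms validate the machinery —
geometry, classification, metric identities, statistical calibration —
not clinical performance.

# Problem sizes and numerical choices

The test suite and the acceptance script run at deliberately modest
sizes: 28×28×18 to 32×32×20 grids, 20 cases per cohort arm in end-to-end
demonstrations, 10,000 Monte-Carlo replicates for non-inferiority
calibration and 1,000 for CI coverage. These sizes were chosen so the
full validation runs in minutes on one core while keeping every
statistical check comfortably powered; all scale linearly if enlarged.

Other numerical choices collected in one place: distance strata rounded
to 10 significant digits before grouping; Otsu ties to the lowest edge;
right-closed histogram binning; Welch tests delegated to `stats::t.test`
and cross-checked against hand-computed formulas in the tests; the
degenerate zero-variance two-sample case returns p = 1 (equal means) or
p = 0 with a flag rather than erroring; perfectly linear correlations
return a collapsed Fisher CI at ±1; empty tissue compartments propagate
as flagged missing values everywhere.

# Known limitations

* NIfTI is the only supported interchange format (adopted as the neutral
  standard; DICOM series assembly is out of scope).
* The SNR/CNR noise conventions are package definitions, stated above;
  when comparing against other software, supply σ explicitly.
* Isocentricity is not implemented; sphericity uses face-counted area
  with the bias discussed above.
* The boundary shell is a single equal-volume layer; multi-shell or
  distance-weighted variants are not provided.
* Statistical comparisons assume independent cases; the paired design
  (same patient imaged under two protocols) is supported only through
  shared per-case seeds in simulation, not by paired tests.
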