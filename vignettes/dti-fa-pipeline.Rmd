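---
title: "Comparing diffusion-tensor fitting algorithms in voxel-based FA group studies"
author: "dtivba"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing diffusion-tensor fitting algorithms in voxel-based FA group studies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Voxel-based analyses of fractional anisotropy (FA) in neurodegenerative
cohorts — healthy controls (HC), mild cognitive impairment (MCI) and
Alzheimer's disease (AD) — depend on a chain of choices that are rarely
examined together: which regression estimates the diffusion tensor, how FA
maps are smoothed and masked, which effect-size thresholds define a
"significant" cluster, and how much results move when any of these is
swapped. `dtivba` packages that chain as reusable, tested components and
pairs it with a synthetic cohort generator with known ground truth, so each
stage can be validated quantitatively rather than by visual inspection.

## The signal model and the four fit families

Single-shell diffusion MRI measures, per voxel and gradient direction
$g_i$ with b-value $b_i$,

$$S_i = S_0 \exp(-b_i\, g_i^\top D\, g_i),$$

where $D$ is the symmetric positive-semidefinite diffusion tensor. With
$\beta = (\ln S_0, D_{xx}, D_{yy}, D_{zz}, D_{xy}, D_{xz}, D_{yz})$ the
log-model is linear: $\ln S_i = x_i^\top \beta$ with design row
$x_i = (1, -b g_x^2, -b g_y^2, -b g_z^2, -2b g_x g_y, -2b g_x g_z,
-2b g_y g_z)$. The package implements the four estimation families in
common use:

* **LLS** — ordinary least squares of $\ln S$ on the design. Fast, but the
  log transform turns homoscedastic signal noise into heteroscedastic
  log-noise (variance $\propto 1/S_i^2$), which penalizes strongly
  attenuated measurements.
* **WLLS** — two-pass weighted least squares with weights
  $w_i = \hat S_i^2$, the *predicted* squared signals from the LLS pass.
  Predicted rather than observed signals are used because observed weights
  are correlated with the noise they are meant to correct; the pass count
  is fixed at two.
* **NLLS** — damped Gauss–Newton (a Levenberg–Marquardt schedule:
  multiplicative damping, $\times 10$ on a failed step, $\div 10$ on a
  successful one) minimizing $\sum_i (S_i - e^{x_i^\top\beta})^2$ directly
  in the signal domain, initialized at the LLS solution. Convergence is
  declared at relative step norm $<10^{-8}$ or 100 iterations; on
  non-convergence the LLS estimate is returned with a diagnostic flag so a
  fit never silently fails. The `nlls-pos` variant re-parameterizes
  $D = R^\top R$ through its Cholesky factor, which constrains the estimate
  to the positive-semidefinite cone while leaving the optimum unchanged
  whenever the unconstrained optimum is itself PSD.
* **RESTORE** — robust fitting for acquisitions with sporadic artifacts
  (motion, cardiac pulsation, slice dropout). An initial NLLS fit is
  accepted outright when all absolute residuals lie within $3\sigma$;
  otherwise the fit is iteratively reweighted with Geman–McClure weights
  $w_i = 1/(r_i^2 + C^2)$, $C = 1.4826\,\mathrm{median}|r|$ recomputed each
  iteration (stop at weight change $<10^{-6}$ or 50 iterations), points
  with $|r_i| > 3\sigma$ are excluded, and the remainder is refit
  unweighted. If fewer than $\max(7, n_\text{DWI}/2)$ diffusion-weighted
  measurements survive, the voxel reverts to its WLLS estimate and is
  flagged. $\sigma$ defaults to `"auto"`: the SD of successive $b=0$
  differences divided by $\sqrt 2$ over a high-signal mask, falling back to
  $1.4826\,\mathrm{median}|r_\text{LLS}|$ for single-$b_0$ schemes.

Numerical guards: non-positive magnitudes (possible after artifact
corruption) are clamped to machine-epsilon times the voxel maximum before
logs are taken, and all-zero voxels return a zero tensor plus a flag. Both
conditions are recorded in the per-voxel diagnostic bitmask.

FA is computed from the tensor spectrum $\lambda_1 \ge \lambda_2 \ge
\lambda_3$ as

$$\mathrm{FA} = \sqrt{\tfrac32}\;
\frac{\sqrt{\sum_i (\lambda_i - \bar\lambda)^2}}{\sqrt{\sum_i \lambda_i^2}},$$

with negative eigenvalues clamped to zero first and the result clipped to
$[0,1]$, which keeps the map invariant testable; the unclamped spectrum is
kept as a diagnostic.

## Group statistics

The analysis order is fit → FA → smoothing → masking → statistics; all
subjects must already share one grid (registration is deliberately out of
scope and is enforced rather than computed).

* **Smoothing**: isotropic Gaussian, $\sigma$ = 3 mm by default, truncated
  at 4 SD, mask-normalized (`smooth(map·mask)/smooth(mask)`) so values do
  not bleed across the analysis boundary and constants are preserved.
* **WM mask**: voxels whose cohort-mean FA strictly exceeds 0.20.
* **Bartlett gate**: Bartlett's test of equal variance across groups,
  computed on one scalar per subject (mean WM FA). It is advisory — logged
  as an ANCOVA assumption check, never aborting an analysis. The scalar
  choice follows from the single p-value such studies report per
  comparison.
* **ANCOVA effect size**: per voxel, FA ~ group + age + gender with the
  three-level group factor effect-coded; the group factor's partial
  eta-squared is computed by Type-III model comparison,
  $\eta^2_p = (\mathrm{SSE}_\text{reduced} -
  \mathrm{SSE}_\text{full})/\mathrm{SSE}_\text{reduced}$. Type III was
  chosen because the emulated cohorts are unbalanced, making Type-I sums
  order-dependent. A constant covariate (single-gender cohort) is dropped
  with a warning.
* **Post hoc Hedges' g**: covariate-adjusted standardized difference
  $g = J\,\hat\Delta/\sqrt{\mathrm{MS}_\text{resid}}$ with
  $J = 1 - 3/(4(n_1+n_2)-9)$ on $n_1+n_2$ only — the covariate-adjusted
  degrees of freedom would change $J$ imperceptibly at these sample sizes.
  The sign convention is first-listed minus second, so AD vs HC is negative
  where AD is lower. A raw (unadjusted) variant is available by flag since
  published analyses do not always state which was used.
* **Partial Spearman**: FA and score are rank-transformed (average ranks on
  ties), each residualized on age and gender, and correlated. Missing
  scores are excluded pairwise, not listwise, to keep the largest usable n
  per score.
* **Clusters**: connected components of strictly supra-threshold voxels
  (defaults: $\eta^2_p > 0.15$ one-sided; $|g| > 0.85$ and $|\rho| > 0.50$
  two-sided with signs kept separate), 26-connectivity, retained when their
  size strictly exceeds 100 voxels. Both the statistic and the size
  thresholds are read as strict inequalities exactly as printed in the
  convention they follow. Clusters are labeled against a user-supplied
  integer atlas with coverage percentages in both directions.
* **Averaging**: per-fit (and per-acquisition) statistic maps are averaged
  voxelwise before re-thresholding, giving the pooled "all fits" analysis;
  the region-by-contrast coverage table is derived from those averaged-map
  clusters.

## Cross-fit consistency

Treating fit variants as fixed raters and subjects as random, agreement is
quantified by the consistency form of the intraclass correlation,

$$\mathrm{ICC}(3,1) = \frac{\mathrm{MS}_S - \mathrm{MS}_E}
{\mathrm{MS}_S + (k-1)\mathrm{MS}_E},$$

computed per voxel from the subjects × variants FA matrix and averaged over
the WM mask (the "r-ICC"). Degenerate voxels (zero variance) are excluded
rather than zero-filled, which would bias the mask mean downward. The
leave-one-out sweep recomputes the voxelwise ICC without each variant in
turn and reports the change in mean r-ICC (positive when removing a variant
*increases* agreement — the signature of an outlying algorithm) plus the
correlation between full and reduced ICC maps. Regional agreement across
variants is summarized by pairwise $r^2$ matrices of significant-cluster
volumes and effect sizes, with regions absent from a variant counted as
zero.

## The synthetic cohort generator

The phantom is the package's test instrument, and its defaults *are* the
emulated study conditions:

* **Geometry**: a 20×20×12 grid of 2 mm voxels — a desk-scale stand-in for
  a template space. A "fornix-like" high-FA ellipsoid
  ($\lambda = (1.7, 0.4, 0.4)\times10^{-3}$ mm²/s, FA ≈ 0.73, ~200 voxels)
  sits inside a cavity of a surrounding white-matter shell
  ($\lambda = (1.2, 0.58, 0.58)\times10^{-3}$, FA ≈ 0.43) so the 0.20 FA
  mask stage is non-trivially exercised; remaining voxels are nearly
  isotropic background (FA ≈ 0.07) that must stay outside the mask.
* **Acquisition**: a GE-like 48-direction, $b = 1000$ s/mm² scheme with six
  leading $b=0$ volumes. Direction sets come from a deterministic
  spherical-Fibonacci construction on the hemisphere — reproducible with no
  iterative electrostatic solver, and uniform enough that the minimum
  pairwise separation exceeds 10° at 48 directions. 30+1 and 54+7 scheme
  variants mirror the other two emulated protocols.
* **Groups and effect**: 41 HC / 20 MCI / 12 AD. Between-subject
  variability is a multiplicative factor (mean 1, SD 0.25) on the
  anisotropic eigenvalue component $\lambda_1 - \lambda_2$, applied per
  subject and ROI — monotone in FA and ordering-preserving, which
  independent per-eigenvalue jitter is not. The AD deficit multiplies the
  same component by 0.655 in the fornix ROI, i.e. true FA 0.62 vs 0.73;
  with the jitter this yields a true standardized deficit of
  $g \approx -1.5$, the magnitude such studies report for the fornix. MCI
  carries no effect by default, making HC-vs-MCI an intentional null
  contrast.
* **Noise and artifacts**: Rician magnitude noise at SNR
  $S_0/\sigma = 25$ (no SNR is published for the emulated scanners; 25 is a
  realistic mid-range choice, and results should be read as functions of
  it). Sporadic dropout corrupts whole (DWI volume × axial slice) blocks
  (probability 0.02, signal × 0.3), mimicking the artifacts robust fitting
  targets; $b=0$ volumes are never corrupted. Ground truth (per-subject
  tensors, true FA, corrupted positions) is returned alongside the data.
* **Covariates**: ages and gender proportions per group match the emulated
  GE cohort; MoCA/MMSE/ADAS are linear in the subject's true fornix FA plus
  Gaussian noise, with slope and intercept solved so the HC and AD group
  means hit the emulated clinical values (e.g. MMSE 29.3 vs 23.7). The
  coupling is monotone by construction so the sign of the Spearman stage is
  known. With the default AD-only effect, MCI scores come out HC-like —
  one linear coupling cannot match three group means when only two groups
  differ in FA.

What the phantom deliberately does *not* emulate: crossing fibers,
registration error, scanner bias fields, spatially varying noise, and —
most consequentially for interpretation — spatially rich between-subject
variation. The jitter is constant within an ROI, so null fluctuations are
coherent across a whole ROI and the >100-voxel cluster rule is a weaker
null guard here than on real data (measured null rate for the HC-vs-MCI
contrast: about one seed in fifteen shows a spurious cluster, consistent
with the ~95% clean-seed calibration the pipeline is checked against).
Passing tests therefore demonstrate correctness of the machinery and
realistic orderings between methods, not clinical effect sizes.

## Reproducibility and problem sizes

Every random draw descends from one master seed through fixed per-subject,
per-stage sub-seeds, so a `RunConfig` plus seed reproduces every output
file bit-identically (the run seed overrides the phantom's own seed; the
provenance hash covers the scientific configuration but not the output
path). The validation suite runs the full default cohort — 73 subjects,
54 volumes, 4 800 voxels, all five fit variants — in a few minutes on one
CPU; unit tests use smaller 12×12×8 cohorts. These sizes are the package's
choice of desk-scale defaults; all statistics are vectorized across voxels
(one QR per analysis), and the per-voxel fitting loops are compiled.

## Known limitations

* Single-shell tensor model only; no multi-shell or kurtosis extensions,
  and group analyses cover FA only (not MD/AxD/RxD).
* b-vectors are taken in the image frame as stored; gradient-frame rotation
  compensation belongs to preprocessing, which is out of scope along with
  motion/eddy correction, brain extraction and template registration.
* The informed variant of robust fitting (iRESTORE) is not implemented.
* Effect-size thresholds are reporting conventions, not calibrated
  hypothesis tests; no familywise error control is attempted.
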