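---
title: "Models and methods for leakage-corrected rCBV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for leakage-corrected rCBV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dscleak)
```

## The measurement model

DSC-MRI records the T2\*-weighted signal drop caused by a gadolinium
bolus transiting the vasculature. Under the standard linearity
assumption, contrast concentration is proportional to the change in the
effective transverse relaxation rate,

$$\Delta R_2^*(t) = -\frac{1}{T_E}\,\ln\frac{S(t)}{S_0},$$

where $S_0$ is the mean pre-bolus signal of the voxel. Relative cerebral
blood volume is the trapezoidal integral of $\Delta R_2^*(t)$ between the
bolus entry $t_0$ and exit $t_1$, later divided by the mean over
normal-appearing white matter (NAWM) so that maps are dimensionless with
NAWM $\equiv 1$.

When the blood–brain barrier is disrupted, contrast extravasates into the
extravascular extracellular space (EES). The leak adds a slowly varying
component to the voxel curve whose sign depends on whether T1 shortening
(signal gain, apparent $\Delta R_2^* < 0$) or T2\* shortening (signal
loss, apparent $\Delta R_2^* > 0$) dominates. Two nested models describe
the voxel curve as a function of the whole-brain reference curve
$\bar{R}(t)$ of nonenhancing tissue:

* unidirectional (intra- to extravascular flux only):
  $\Delta R_2^*(t) \approx K_1 \bar{R}(t) - K_2 \int_0^t \bar{R}(t')\,dt'$
* bidirectional (adds EES-to-vascular back-transfer at rate $K_{ep}$):
  $\Delta R_2^*(t) \approx K_1 \bar{R}(t) -
  K_2 \int_0^t \bar{R}(t')\,e^{-K_{ep}(t-t')}\,dt'$

No sign constraints are imposed on $K_1$, $K_2$ or $K_{ep}$: a negative
$K_2$ captures T2\*-dominant leakage, a positive one T1-dominant leakage.
$K_1$ is dimensionless (a susceptibility scaling between the voxel and
the tissue average); $K_2$ and $K_{ep}$ carry units of s$^{-1}$. The
corrected curve adds $K_2 \cdot(\text{kernel integral of } \bar R)$ back
to the measured curve, cancelling the fitted leakage term; corrected rCBV
integrates the corrected curve over the same window.

## Fitting

The unidirectional model is linear and solved by QR-based ordinary least
squares. The bidirectional model is solved by variable projection: the
profiled objective over $K_{ep}$ is scanned on a 41-point grid spanning
$[-0.2, 1.0]$ s$^{-1}$ augmented with 0, then refined by golden-section
search between the neighbours of the best grid point (absolute tolerance
$10^{-7}$ s$^{-1}$); at every candidate the inner $(K_1, K_2)$ problem is
solved exactly. Because the grid contains $K_{ep} = 0$ and ties are broken
toward 0 (parsimony), the bidirectional residual sum of squares can never
exceed the unidirectional one, and data generated with $K_{ep} = 0$
return the unidirectional coefficients exactly. The grid bounds are a
practical choice — the physiologic back-transfer rates of interest are a
few times $10^{-2}$ s$^{-1}$ — while the model itself stays unconstrained
within them; the 1-D profiled objective is smooth and unimodal in
practice, which makes this more robust than multi-start nonlinear least
squares.

Both integral operators use causal trapezoidal discretization at the
repetition time $T_R$; the exponential kernel obeys the one-step
recursion $I_i = d I_{i-1} + \tfrac{dt}{2}(f_i + d f_{i-1})$ with
$d = e^{-K_{ep} dt}$, and per-step exponents are clipped at $\pm 50$ to
keep strongly negative $K_{ep}$ candidates finite. The forward simulator
uses the identical operators, so noiseless parameter recovery is exact to
solver tolerance rather than quadrature accuracy. Fits use all retained
timepoints — the leakage signature lives in the post-bolus tail — except
samples that had to be clamped before the log transform.

## Quality control and the reference curve

The processing chain applies, in order:

1. **Leading-volume discard** (default 2) before any analysis, because
   the gradient-echo signal has not reached steady state.
2. **Bolus-window location** on the whole-brain mean relaxivity curve:
   the baseline grows iteratively from the first 8 samples while new
   samples stay within 2 SD of the running mean; the first sample
   exceeding that threshold marks the upslope, $t_0$ is the last
   sub-threshold sample (excluded from the baseline as a 1-point guard),
   and $t_1$ is the earlier of the first post-peak sample below 20% of
   (peak − baseline) and the pre-recirculation local minimum. One global
   window is applied to all voxels; no per-voxel arrival model is used,
   matching the uniform-window definition of the integrals. Whether a
   guard point should be excluded at all is genuinely open; one point
   costs little baseline data and protects the $S_0$ estimate from
   partial-upslope contamination.
3. **5-SD drop rule**: a voxel is analysed only if its in-window signal
   drops at least 5 baseline SDs below $S_0$.
4. **Nonenhancing selection**: brain voxels whose tail mean (final 10
   timepoints, or all post-$t_1$ points when fewer remain) lies within 1
   baseline SD of $S_0$, intersected with the drop-rule survivors. Their
   relaxivity curves are averaged into the reference curve; the window is
   then re-located on that reference curve for the integration stage. The
   per-voxel baseline SD (not a global one) is used for the tail
   tolerance — the voxelwise reading of the criterion — because a global
   SD would couple the selection to coil-profile intensity variations.
5. **Log-transform guard**: non-positive samples are clamped to
   $10^{-6} S_0$ and flagged; a voxel with more than 10% clamped
   in-window samples is excluded. With noiseless synthetic data the SD
   thresholds degenerate gracefully (an absolute epsilon of $10^{-9}$
   signal units replaces a zero SD), so the same rules remain meaningful
   in tests.
6. **Normalization**: each rCBV variant is divided by its own NAWM mean,
   computed over usable voxels only. Excluded voxels are `NaN` in all
   maps and never enter medians or divisors, since silent zeros would
   bias group medians.

Voxelwise goodness of fit is summarized as
$R^2_{adj} = 1 - (1 - R^2)(n-1)/(n-k-1)$ with $k = 2$ or $3$ parameters
and $n$ the number of unclamped timepoints in the fit; VOI summaries are
means of voxel $R^2_{adj}$.

## Cohort statistics

Per patient, the median of each normalized map and each permeability map
over the tumor VOI is recorded. Within a patient group the three paired
comparisons (uncorrected vs unidirectional, uncorrected vs bidirectional,
unidirectional vs bidirectional) use the Wilcoxon signed-rank test —
exact null for up to 25 tie-free nonzero differences, normal
approximation otherwise, zero differences dropped, all-zero case $p = 1$
by convention — with Holm step-down correction inside that
three-comparison family at $\alpha = 0.05$. Shapiro–Wilk normality
p-values of the paired differences are reported for audit, but the
analysis always proceeds nonparametrically. Percentage differences
$100\,(\text{uncorrected} - \text{corrected})/\text{uncorrected}$ are
computed per patient and then averaged, not derived from group means.
Grade association uses Spearman rank correlation with mid-ranks for the
inevitable ties among WHO grades.

## The digital phantom

The synthetic module emulates exactly the statistical structure the
analysis assumes, which is what makes the pipeline testable without data
downloads:

* the reference bolus is a peak-normalized gamma variate
  $A\,((t-t_0)/(s\sigma))^s e^{s-(t-t_0)/\sigma}$ (analytic peak $A$ at
  $t_0 + s\sigma$), plus a delayed, dispersed, scaled recirculation bump
  of the same family and a smooth constant steady-state term emulating
  elevated intravascular contrast after first passage;
* voxel signals are generated by the forward leakage models above with
  per-voxel ground-truth $(K_1, K_2, K_{ep})$, inverted through
  $S = S_0 e^{-T_E \Delta R_2^*}$;
* noise is additive Gaussian in signal space — the magnitude-MR regime at
  moderate SNR — so the log transform is genuinely exercised;
* geometry is a block layout (background shell, normal brain, NAWM and
  tumor blocks), with $K_2 = K_{ep} = 0$ everywhere outside the tumor.

Defaults are one fixed set of study conditions: a $16 \times 16 \times 4$
grid with 100 dynamics at $T_R = 1.1$ s and $T_E = 30$ ms (a desk-scale
version of the public glioma protocol with 120 dynamics at the same
timing), baseline SNR 50, bolus arrival after 15 samples with shape 3 and
scale 1.5 s, peak amplitude 8 s$^{-1}$, 25% recirculation and a
0.2 s$^{-1}$ steady-state level; tumor truth $K_1 = 2.5$,
$K_2 = -0.03$ s$^{-1}$, $K_{ep} = 0.02$ s$^{-1}$, values typical of
enhancing glioma with T2\*-dominant leakage. The cohort generator draws
per-patient tumor parameters around the values reported for enhancing
($K_2 \sim \mathcal{N}(-0.03, 0.015)$ s$^{-1}$,
$K_{ep} \sim |\mathcal{N}(0.02, 0.01)|$ s$^{-1}$, $K_1$ lognormal and
increasing with WHO grade) and nonenhancing (near-unity $K_1$,
near-zero leakage) disease. No acquisition SNR or curve-shape statistics
are published for the clinical cohorts, so these defaults are plausible
rather than calibrated — they were chosen once and are not tuned against
test outcomes.

What the phantom deliberately omits: anatomy, arterial input function
modelling, k-space/MR physics, motion and susceptibility artefacts,
per-voxel bolus delay and dispersion, and spatial noise correlation.
Passing tests therefore demonstrate the correctness of the estimators and
the pipeline logic under the model's own assumptions, not robustness to
everything real acquisitions do.

## Numerical and design choices

* Problem sizes in the test and acceptance runs — 500-voxel recovery
  panels, 20- and 14-patient cohorts on the default grid — were chosen as
  the smallest sizes at which group statistics are stable.
* The profiled bidirectional objective is evaluated through shared
  precomputed normal-equation blocks when a whole map is fitted (the
  design depends on the voxel only through the response); the final
  reported fit is always re-solved by QR for accuracy, and both paths are
  cross-checked against a brute-force normal-equations oracle in the
  tests.
* Rank-deficient designs (for example, an identically zero reference
  curve) yield a flagged non-converged fit; such voxels are excluded from
  corrected maps rather than silently zeroed.
* $R^2$ is undefined for a constant observed curve ($SS_{tot} = 0$) and
  reported as missing.
* Negative rCBV values in pathological voxels are preserved, not
  clipped: clipping would bias VOI medians.
* With fewer than 10 post-$t_1$ samples the tail uses all remaining
  points with a warning, which keeps short (about 50-dynamic) protocols
  usable.

## Known limitations

* $K_1$ is estimated with noticeably more variance than $K_2$ or
  $K_{ep}$ at SNR 50 (median absolute error about 0.06 in the recovery
  panel, versus about 0.005 and 0.01 for $K_2$ and $K_{ep}$); rCBV
  summaries are medians over hundreds of voxels and are much more
  stable.
* The bidirectional model roughly doubles the per-case fitting cost
  relative to the unidirectional one.
* Masks are consumed as delivered: no registration, resampling or
  segmentation is performed, and the NAWM mask is trusted to be
  contralateral and representative.
* The bolus-window rule assumes a single dominant first pass; pathologic
  reference curves without a detectable peak abort the run with an
  explicit error rather than guessing a window.
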