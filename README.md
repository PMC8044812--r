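# dscleak

Leakage-corrected relative cerebral blood volume (rCBV) from dynamic
susceptibility contrast (DSC) MRI.

## The problem

rCBV is the most widely used DSC-MRI perfusion marker for grading brain
tumors: it is the area under the first-pass relaxivity curve of a voxel,
normalized to normal-appearing white matter (NAWM). In glioma the
blood–brain barrier can be disrupted, so gadolinium leaks into the
extravascular extracellular space (EES) during the acquisition. The leak
adds T1- or T2\*-weighted signal components that bias the relaxivity curve
tail and therefore the rCBV integral — upward when T2\* effects dominate,
downward when T1 effects dominate.

`dscleak` implements the two standard model-based corrections and the full
measurement pipeline around them, for neuroimaging researchers who want an
auditable, scriptable implementation with every threshold exposed:

* **Uncorrected**: `rCBV = ∫_{t0}^{t1} ΔR2*(t) dt` with
  `ΔR2*(t) = -(1/TE)·ln(S(t)/S0)`, integrated between bolus entry `t0` and
  exit `t1` by the trapezoidal rule.
* **Unidirectional** (Boxerman–Schmainda–Weisskoff): each voxel curve is
  modelled against the whole-brain reference curve `ΔR2*_ref(t)` of
  nonenhancing tissue as

  ```
  ΔR2*(t) ≈ K1·ΔR2*_ref(t) − K2·∫₀ᵗ ΔR2*_ref(t') dt'
  ```

  with `(K1, K2)` from unconstrained ordinary least squares. `K1` is a
  dimensionless susceptibility scaling; `K2` (s⁻¹) is the leakage rate,
  negative for T2\*-dominant and positive for T1-dominant leakage. The
  corrected curve is `ΔR2*(t) + K2·∫₀ᵗ ΔR2*_ref`.
* **Bidirectional**: adds back-transfer from the EES at rate `Kep` (s⁻¹),

  ```
  ΔR2*(t) ≈ K1·ΔR2*_ref(t) − K2·∫₀ᵗ ΔR2*_ref(t')·e^{−Kep(t−t')} dt'
  ```

  solved by variable projection (1-D search over `Kep` with the exact
  linear subproblem at each candidate). `Kep = 0` recovers the
  unidirectional model, so the bidirectional fit never has a larger
  residual sum of squares.

Around the models the package provides the standard processing chain:
discarding pre-steady-state dynamics, 5-SD bolus-drop voxel QC,
tail-vs-baseline selection of nonenhancing voxels for the reference curve,
first-pass bolus-window location, NAWM normalization, voxelwise adjusted
R² diagnostics, and nonparametric cohort statistics (Wilcoxon signed-rank
with Holm correction, Spearman correlation with WHO grade). A seedable
gamma-variate digital phantom generates complete synthetic cases with
known ground truth, so the entire pipeline is testable without any
patient data.

## Worked example

```r
library(dscleak)

# a 16 x 16 x 4 phantom, 100 dynamics at TR = 1.1 s / TE = 30 ms;
# tumor truth: K1 = 2.5, K2 = -0.03 s^-1 (T2*-dominant), Kep = 0.02 s^-1
spec <- phantom_spec(seed = 1)
sim  <- simulate_cohort(spec)

case <- run_case(sim$series, sim$vois, model = "all")
case_summary(case, patient_id = "phantom-1")
```

```
  patient_id group grade median_rcbv median_rcbv_unidir median_rcbv_bidir
1  phantom-1  <NA>    NA    2.666654           2.581743          2.493635
  median_k2_unidir median_k2_bidir median_kep_bidir mean_adj_r2_unidir
1      -0.01321931      -0.0284248       0.01867327          0.9623636
  mean_adj_r2_bidir
1         0.9693226
```

Read it as: the uncorrected tumor rCBV (2.67) is inflated by the
T2\*-dominant leak; the unidirectional correction lowers it to 2.58 and
the bidirectional correction to 2.49, close to the ground-truth blood
volume ratio of 2.5. The recovered medians of `K2` (bidirectional,
−0.028 s⁻¹) and `Kep` (0.019 s⁻¹) match the simulated truth, and both
models fit the voxel curves with mean adjusted R² above 0.96.

Single-voxel fits are ordinary model objects with `coef`, `summary`,
`predict`, `fitted`, `residuals` and `plot` methods:

```r
ref <- make_reference_curve(spec)          # noiseless reference curve
y <- 1.2 * ref$values -
  0.03 * cumulative_integral(ref$values, ref$time_step)
f <- leakage_fit(y, ref, model = "unidirectional")
coef(f)
#>   k1   k2
#>  1.2 0.03
```

A command-line front end over the same functions is installed at
`inst/cli/dscleak.R` with `run`, `simulate` and `cohort` subcommands; the
`cohort` mode consumes a TSV manifest (columns `patient_id`, `dsc`,
`brain`, `tumor`, `nawm`, `tr_seconds`, `te_seconds`, `group`, `grade`)
and writes per-case maps plus the cohort tables. All pipeline thresholds
live in a single YAML-serializable configuration (`dsc_config()`), which
is written alongside every run directory for audit.

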