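---
title: "Connectome-based lesion-symptom mapping: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome-based lesion-symptom mapping: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connlsm)
```

## Scope and model

`connlsm` relates three kinds of brain features to aphasia severity scores
in a stroke cohort, one feature at a time (mass-univariate):

1. **Region lesion-symptom mapping** — per-ROI lesion load (damaged
   fraction), controlling for total lesion volume, restricted to ROIs
   damaged in at least `min_damage_subjects` (default 10) subjects.
2. **Structural edges** — tractography fiber counts for every ROI pair
   ("all possible connections"; no damage-based edge exclusion, but
   zero-variance edges are flagged undefined and skipped).
3. **Functional edges** — Pearson correlations of ROI mean BOLD time
   courses, under three anatomical covariate modes: (a) total lesion
   volume as GLM covariate; (b) behavior pre-residualized on lesion
   volume and each edge pre-residualized on its own fiber count;
   (c) as (b) with critical-area lesion load replacing total volume.

Each fit is ordinary least squares `y ~ 1 + feature + covariates`; the
feature t statistic (dof = n − 2 − #covariates) is mapped to a signed z by
the probability-preserving transform `z = qnorm(pt(t, dof))`, evaluated on
the log scale so tails keep precision. Family-wise error is controlled by
the permutation max-statistic method: the threshold is the empirical
`1 − alpha` order statistic (ceiling-rank convention, so permutation p
values never reach 0) of the per-permutation maximum |z| across features.

**Covariate styles differ by mode on purpose.** Mode (a) keeps lesion
volume inside the GLM; modes (b) and (c) residualize it out of the response
beforehand. The two styles are not equivalent, and both appear in the
applied literature for the respective analyses; the package reproduces each
where it is conventionally used and records the choice in the result's
provenance. After pre-residualization the GLM does not re-count the
removed covariates in its degrees of freedom — a deliberate approximation
matching common practice (the permutation calibration is unaffected, since
the same statistic is used for observed and permuted data).

**Permutation scheme.** With covariates present, raw-response permutation
mixes nuisance signal into the null. The default is therefore
Freedman-Lane-style: the covariate-residualized response is permuted and
re-residualized each round. A `raw_y` scheme is available behind a switch;
the choice is stored in every `glm_result`. Permutation indices are
pre-generated from one seed, so results are reproducible and independent of
evaluation order.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `n_perm` | 5000 | permutations | standard choice for stable 5% thresholds; tests and demos scale it down for runtime |
| `alpha` | 0.05 | FWE level | conventional |
| `sidedness` | two-sided | — | effects of both signs are reported in this literature (e.g. damage effects with negative z) |
| `min_damage_subjects` | 10 | subjects | lesion-symptom power is meaningless in ROIs almost nobody has damaged |
| band-pass | 0.01–0.1 | Hz | canonical rsfMRI fluctuation band |
| ICA map threshold | p < 0.05 two-sided (`|z| > 1.96`) | — | artifact maps can load negatively; two-sided reading of the z-map threshold |
| Jaccard cutoff | > 0.05 strict | — | verbatim "greater than 5%" reading |
| lesion-mask smoothing | 3 mm FWHM, 50% cutoff | mm | removes jagged manual-drawing edges without dilating or eroding (volume conserved within 2% on a solid ball) |

## The synthetic cohort: what it emulates

Real cohorts of ~97 chronic left-hemisphere stroke patients with WAB-R
scores, tractography and rsfMRI are only available by request from their
authors; the generator supplies a stand-in with the statistical structure
the analyses assume. Per subject:

- **Lesion**: a per-subject extent `Beta(2, 4)` thinned per left ROI by
  `Beta(0.6, 1.8)`; right-hemisphere loads are identically zero. Total
  lesion volume is the load-weighted sum of ROI volumes (mean ≈ 12 ml on
  the 30-ROI demo parcellation, ≈ 50 ml at 108 ROIs — a realistic
  middle-cerebral-artery range).
- **Structural connectome**: baseline fiber counts are rounded lognormal
  (meanlog 4, sdlog 1: median ≈ 55 streamlines, heavy right tail),
  suppressed multiplicatively by `(1 − load_i)(1 − load_j)`.
- **Time courses** (427 samples at TR = 1.65 s): ROI signals are linear
  mixtures of latent signals whose target correlation is
  `coupling × S/(S + median(S))` — saturating in fiber count, projected to
  the nearest PSD correlation matrix by eigenvalue clipping. The
  saturation matters: it lets every edge's expected correlation track its
  own fiber count across subjects (the coupling invariant below), which a
  low-rank node-strength factor model cannot achieve. At `coupling = 0`
  the ROI series are independent.
- **Planted effects**: a functional edge can receive extra private
  coherence with per-subject loading `u ~ U(0, 1)` (adding ≈ `0.5·u` to
  that edge's correlation, independent of structure); structural edges and
  single-ROI lesion loads can drive behavior directly.
- **Behavior**: `baseline − coef·volume + Σ beta·feature + N(0, sd)`,
  discretized into the WAB-R subtests (integers) and truncated to legal
  ranges; composites are then recomputed from the subtests, so the scoring
  identities hold exactly. Defaults: `noise_sd = 1` AVC point,
  `lesion_behavior_coef = 3e-5` per mm³ (≈ 1.5 AVC points for a mean
  lesion), `avc_baseline = 8.5` (mildly impaired cohort mean ≈ 7).

What it does **not** emulate: atlas geometry, hemodynamics, spatially
contiguous lesion shapes, distance-dependent connectivity, scanner noise,
or subject motion. A green recovery test therefore establishes that the
*statistical machinery* finds planted effects at the calibrated power under
the generator's assumptions — not that it would on any particular scanner's
data.

## Effect-size calibration for recovery experiments

The planted-edge recovery criterion requires an effect with theoretical
power ≥ 0.95 at the family-wise threshold. Two facts make the naive
`y = beta·e + noise` power formula optimistic:

1. a planted edge's measured correlation also contains base coupling
   driven by the structural backbone — variance that feeds the behavioral
   score but is *removed from the feature* by structural residualization
   in mode (b); and
2. WAB-R scores are discretized and truncated.

`calibrate_planted_beta()` therefore simulates a pilot cohort *without*
the planted effect, estimates the edge's base level/variance and its
structural-residualized variance, and solves analytically for `beta` in
the mode-(b) partial correlation (the harder mode; mode (a) then has
higher power automatically). Recovery experiments run at design power
0.98 — satisfying the ≥ 0.95 requirement with an a-priori margin for
discretization, truncation tails and pilot estimation error — and with
`avc_baseline = 6` rather than the cohort default 8.5, because at 8.5 the
planted effect pushes ~40% of subjects onto the AVC ceiling of 10 and the
Gaussian power model no longer describes the experiment.

## Numerical choices

- **Band-pass**: zero-phase forward-backward 4th-order Butterworth
  (analog prototype → LP-to-BP transform → bilinear transform), with
  odd-reflection padding and steady-state initial conditions. No DSP
  dependency is available in the target environment, so the filter is
  implemented in-package and verified against an FFT oracle (passband
  gain within 10% at 0.05 Hz; ≥ 90% attenuation one octave outside the
  band; DC removed to machine precision).
- **Projections**: all residualization uses an SVD-based projector, so
  rank-deficient (collinear) designs degrade gracefully instead of
  erroring.
- **Zero-variance features** are flagged `undefined` (relative tolerance
  1e-10 on the residual norm) and excluded from the max statistic —
  never silently reported as z = 0.
- **Empty masks**: the Jaccard index of two empty masks is defined as 0,
  so an empty thresholded ICA map can never trigger component removal.
- **Tie-breaking**: survivors are sorted by |z| descending, ties broken by
  ROI label order; the permutation threshold uses the ceiling-rank order
  statistic.
- **Seeds**: one master seed per cohort; per-subject seeds are derived by
  a counter-based affine map (kept inside 32-bit range), so cohorts are
  bit-reproducible and independent of generation order. The generator
  restores the caller's RNG state.

## Design decisions taken where the design was open

- Pipeline step order defaults to: ICA lesion filter → detrend →
  band-pass → ROI averaging. Published descriptions do not pin a strict
  order; each step is exposed separately so callers can compose
  differently, and analysis provenance records what ran.
- Fiber counts enter the GLM raw; a `log1p` transform is easy to apply to
  the feature matrix by the caller but is not the default, because the
  residualization-based modes are invariant to affine rescaling anyway
  (property-tested).
- Pearson r is used untransformed as the FC feature (no Fisher z) —
  matching the measure's definition in this pipeline; permutation
  calibration does not require variance-stabilization.
- Whether WAB-R subtests allow half-points is unspecified in the sources
  this package follows; the generator emits integers.
- The study design this package mirrors dropped Spontaneous Speech from
  the structural-adjusted analyses after it produced no survivors in mode
  (a). That gate is a study decision, not an algorithm: the pipeline runs
  any behavior in any mode, and the example configs document the gate
  instead of enforcing it.

## Known limitations

- No NIfTI I/O: masks and 4-D series are plain R arrays (`voxel_ts`);
  no affine/world-coordinate handling. The analyses consume only
  ROI-level quantities.
- No ICA estimation: `lesion_component_filter()` consumes a decomposition
  (`ica_decomposition`) produced by any backend.
- ROI-level lesion loads are the native representation; the voxel-mask
  operations exist to exercise the preprocessing contract, not to
  replicate image registration.
- Mass-univariate only: no multivariate lesion-symptom mapping, no
  cluster/TFCE statistics, no graph-theoretic summaries.
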