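---
title: "Breath-hold CVR mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breath-hold CVR mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvrkit)
```

## The measurement

Cerebrovascular reactivity (CVR) is the capacity of cerebral vessels to
dilate in response to a vasoactive stimulus. A practical, non-invasive
protocol uses repeated voluntary breath holds during BOLD fMRI: apnea
raises arterial CO~2~, a potent vasodilator, and the BOLD signal rises
wherever the vasculature can respond. The end-tidal CO~2~ partial
pressure (PetCO~2~), sampled at each expiration from a nasal cannula, is
a surrogate of arterial CO~2~ tension, so regressing the BOLD signal on a
hemodynamically delayed PetCO~2~ model yields CVR in interpretable units:
percent BOLD change per mmHg of CO~2~.

`cvrkit` implements this pipeline end to end, together with the
longitudinal cohort statistics used to study CVR in multiple-sclerosis
(MS) patients starting an anti-inflammatory therapy, and a synthetic-data
module that generates every input with known ground truth.

## Task and acquisition model

The default paradigm is paced breathing with five end-expiration breath
holds of 16 s, each followed by 34 s of recovery, preceded by a 26 s
lead-in (`bh_paradigm()`). The lead-in is our choice: it makes the task
duration (26 + 5×50 = 276 s) exactly fill the default acquisition of 92
volumes at TR = 3 s (`acq_params()`).

## From raw CO~2~ trace to GLM regressor

`build_regressor()` chains four stages, each exported on its own:

1. **End-tidal detection** (`detect_end_tidal`): expiratory maxima are
   local maxima with topographic prominence ≥ 5 mmHg and a 2 s refractory
   interval. Prominence gating suppresses cardiogenic ripples; the
   refractory interval enforces one sample per breath. During a hold
   there is no airflow and no peak, so the deliberate post-hold full
   expiration supplies the end-of-hold PetCO~2~ sample.
2. **Resampling** (`interpolate_to_grid`): linear interpolation between
   end-tidal samples, evaluated at volume-acquisition midpoints, constant
   beyond the first/last breath. Linear interpolation is standard PetCO~2~
   practice; nothing in the data supports a fancier scheme.
3. **Quadratic detrending** (`detrend_quadratic`): OLS residuals against
   {1, t, t²}, removing baseline and slow drift of the capnograph while
   retaining >90% of the task-frequency energy.
4. **Canonical HRF convolution** (`canonical_hrf`, `convolve_hrf`): a
   double-gamma kernel (peak delay 6 s, undershoot delay 16 s,
   dispersions 1 s, peak:undershoot 6:1, truncated at 32 s) normalised to
   **unit sum**, so a sustained CO~2~ step keeps its mmHg amplitude after
   convolution and the GLM β stays in %BOLD/mmHg.

One numerical choice deserves emphasis: detrending and convolution run on
the kernel's fine grid (`dt_s` = 0.1 s) and the result is then sampled at
the volume midpoints. Sampling the kernel at the 3 s TR first would
quantise its 6 s peak onto two coarse taps and shift the post-hold
response maxima by up to a TR; with the fine-grid model the regressor's
block maxima lag each hold end by the HRF peak delay within sampling
resolution. This mirrors how mainstream fMRI tools build their design
matrices.

No PetCO~2~→BOLD lag optimisation is performed by default (`lag_s = 0`);
a global shift can be supplied when a user has an independent lag
estimate.

```{r regressor, eval = FALSE}
trace <- make_capno_trace(bh_paradigm(), bh_rise = 8, noise_sd = 0)
reg <- build_regressor(trace, acq_params())
plot(volume_times(acq_params()), reg$values, type = "l",
     xlab = "time (s)", ylab = "PetCO2 model (mmHg)")
```

## BOLD preprocessing and the voxel-wise GLM

`fractional_bold()` expresses each voxel as percent change about its
temporal mean; `highpass_gaussian()` subtracts a Gaussian-weighted
running mean with σ = 60 s (reflective boundaries), the
subtract-the-smooth realisation of a high-pass filter. At the 50 s task
period the smoother's transfer gain is essentially zero, so the task
component passes almost untouched while drifts are removed.

`fit_cvr_map()` then fits, per voxel, ordinary least squares of the
filtered percent-BOLD series on the demeaned regressor plus an intercept
(optional confound columns are available but off by default — the
described method uses the PetCO~2~ regressor alone). β is the CVR
estimate; t-statistics, residual SD and degrees of freedom are kept.

By default `run_subject()` applies the **same temporal filter to the
regressor** as to the data. Filtering only the data would make the
estimator slightly inconsistent (the filter is not exactly identity at
all retained frequencies); filtering both makes noiseless recovery exact
to machine precision, which our round-trip tests verify at ~1e-16.

ROI summaries (`summarize_cvr()`) are **medians** of β within the GM and
WM argmax masks, excluding lesion voxels, plus the median within the
lesion mask; the even-count median is the midpoint of the central pair.
Tissue masks come from `classify_tissue()` — per-voxel argmax of the
GM/WM/CSF probabilities with the fixed tie order GM > WM > CSF and a 0.05
background threshold. Normalised tissue volumes multiply voxel volume by
the summed probability map; the normalisation scaling is 1 for synthetic
subjects sharing one grid.

Motion correction and registration are intentionally out of scope: the
synthetic data are motion-free on a common grid, and real-data users must
realign and register upstream.

## The synthetic-data generator

The generator defines the conditions under which the pipeline is tested;
it is deliberately the *minimal* model consistent with the analysis:

- **Phantom** (`make_phantom`): concentric shells (WM core, GM shell, CSF
  rim) with logistic transitions, plus disjoint spherical lesions placed
  fully inside the WM-argmax region. It stands in for a probabilistic
  segmentation and manual lesion masks.
- **Capnograph** (`make_capno_trace`): triangular breath envelopes whose
  apices are the scheduled end-tidal values — baseline 40 mmHg in paced
  breathing, baseline + `bh_rise` (default 8 mmHg, a typical 16 s
  end-expiration hold excursion) at the single post-hold expiration, with
  a 2 s exhale delay; near zero during holds; 20 Hz sampling resolves
  individual breaths; additive Gaussian noise clamped at zero.
- **BOLD** (`make_bold`): `y = s0·(1 + cvr/100·x̃ + drift + noise)` with
  `x̃` the demeaned regressor — the exact generative inverse of the GLM,
  which makes the estimator's target identifiable and round trips exact.
- **Cohort** (`make_cohort`): 18 HC (one session) and 23 MS (three
  sessions) with subject-level tissue CVRs drawn at the study's group
  means/SDs; the on-treatment change is
  `Δi = 0.016 − 0.6·(prei − 0.091) + ηi` in GM (analogously in WM), the
  negative slope encoding a restoration effect; η's SD is set so the
  marginal change SD is 0.030. Gd+ positivity is assigned to 12/8/3
  subjects at sessions 1/2/3 with **nested persistence** — the simplest
  longitudinal structure consistent with a declining lesion count; the
  original study does not state whether positivity was nested, so this is
  a flagged assumption. Lesion-voxel truth is half the subject's WM truth,
  matching the direction and magnitude of the reported session-1 lesion
  depression. One subject misses session 2 and two miss session 3.

What the generator does **not** emulate: motion, spin history,
distortion, physiological aliasing, scanner drift structure beyond
polynomials, lesion evolution, or any spatial heterogeneity of CVR within
a tissue class. Passing tests therefore demonstrate correctness of the
estimator and statistics under the stated model, not robustness to
real-world artifacts. Two further desk-scale concessions: the shared
phantom grid can host at most two disjoint lesion spheres, so a session's
lesion *mask* draws `min(gd_count, 2)` components while the `gd_count`
column keeps the full 1–5 counts used by the lesion-count analyses; and
the generator does not couple lesion-count changes to CVR changes (the
corresponding correlation is computed but has no built-in effect).

## Cohort statistics

`analyze_cohort()` runs the full battery on a subject-session table:
Lilliefors-type normality screens (Kolmogorov–Smirnov distance with
parameters estimated from the sample and Monte-Carlo p-values — testing
against a fully specified normal is rarely what is meant; the naive KS
variant is available by flag); pooled-variance unpaired t (HC vs
pre-treatment MS); one-way repeated-measures ANOVA across the three MS
sessions on complete cases (no sphericity correction by default,
Greenhouse–Geisser by flag) with post-hoc paired t-tests; the
pre-treatment average of sessions 1–2 with the stated single-session
fallback; paired pre-vs-on comparison; Pearson correlations of the
on-minus-pre change with the pre-treatment level and with the change in
Gd+ lesion count (session 3 − session 1); paired lesion-vs-WM CVR per
session among lesion-positive subjects; and CVR-vs-volume correlations
per group/phase with Fisher z-transforms. P-values are reported
uncorrected, with listwise deletion per test and logged exclusions.

Every test is validated against closed-form oracles on toy inputs to
1e-9 and holds its nominal type-I error (0.05 ± 0.02 over 2000 null
replicates) in the test suite.

## Voxel-wise inference: TFCE + permutations

`tfce_enhance()` integrates cluster extent and height over all
thresholds: `TFCE(v) = Σ_h e(h,v)^E · h^H · dh` with the standard
E = 0.5, H = 2, dh = max/100, 26-connectivity; negative values are
enhanced on the negated map and negated back. The C++ implementation
sweeps thresholds downward with an incremental union-find, and is checked
against a brute-force per-threshold flood-fill oracle to 1e-6.

`permutation_pmap()` smooths subject maps (σ = 4 mm when requested),
computes the observed t-map, and builds the null distribution of the
*maximum* TFCE statistic under sign flips (paired/one-sample) or
group-label exchanges (two-sample), enumerated exhaustively when there
are no more than `n_perm` distinct permutations. Corrected p-values are
`(1 + #{max ≥ TFCE_obs}) / (n_perm + 1)`; inference is one-sided in the
contrast direction. The default `n_perm = 1000` (500 in the family-wise
error simulations) trades the conventional 5000 for desk-scale runtimes;
the attainable minimum p is reported accordingly. Family-wise error
control is verified by simulation (12 subjects, 500 permutations, 50
null datasets).

## Problem sizes used by the test suite

All simulations run on 12³–28³ grids with the full 92-volume time series:
round-trip subjects at 16³ and the lesion-recovery subject at 28³ (two ~2 cm³ lesions, so the lesion median has a sampling SD well below the reported value), one full 41-subject
cohort (84 subject-sessions) through the complete imaging pipeline,
200 cohort replicates at generator level with the measured
imaging-estimation error added (that error's SD is ~10× below the
between-subject SD, so the replicates' verdicts are unchanged), 2000-fold
null calibrations for every statistical test, and 50 null datasets for
the FWE check. These sizes were chosen so the estimator's sampling error
is small relative to each quantity being checked.

## Known limitations

- The generator's linearity means lag heterogeneity, nonlinear
  BOLD-CO~2~ coupling and voxelwise HRF variability are untested.
- Tissue medians are computed on the native (single) grid; with real
  multi-subject data the choice of space for the medians matters and is
  the user's responsibility before calling `summarize_cvr()`.
- The two-sample permutation t uses pooled variance; heteroscedastic
  groups would need a Welch-type statistic.
- Normalised volumes use a caller-supplied scaling standing in for
  intracranial-volume normalisation.
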