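# cvrkit

Cerebrovascular reactivity (CVR) mapping from breath-hold BOLD fMRI, for
researchers studying vascular function in the brain — in particular
longitudinal cohorts such as multiple-sclerosis (MS) patients followed
across treatment.

Repeated voluntary breath holds transiently raise arterial CO₂ and
dilate cerebral vessels; the BOLD signal rises wherever the vasculature
can respond. With the end-tidal CO₂ partial pressure (PetCO₂) recorded
at the nostril as a surrogate of arterial CO₂, CVR is estimated by a
voxel-wise general linear model,

    y(v, t) = β₀(v) + β(v) · x(t) + ε(v, t)

where `y` is the percent BOLD signal (high-pass filtered, σ = 60 s) and
`x` the PetCO₂ model: end-tidal peaks detected on the raw capnograph
trace, linearly resampled, quadratically detrended and convolved with a
unit-sum canonical double-gamma HRF, so that `β(v)` is CVR in
**%BOLD/mmHg**. Tissue summaries are medians of `β` within the GM and WM
argmax masks (excluding Gd-enhancing lesions), and the lesion median is
reported separately. Cohort-level inference includes repeated-measures
ANOVA, paired/unpaired t-tests, Pearson correlations with Fisher
z-transforms, Lilliefors-type normality screening, and voxel-wise
permutation testing with threshold-free cluster enhancement (TFCE,
max-statistic family-wise error control).

A first-class synthetic-data module (`make_phantom`, `make_capno_trace`,
`make_bold`, `make_cohort`) generates phantoms, capnograph traces, BOLD
series, lesion masks and whole longitudinal cohorts with known ground
truth, so every stage is testable without external data.

## Worked example

Simulate one subject with two white-matter lesions whose true lesion CVR
(0.027 %BOLD/mmHg) is half the surrounding WM value (0.054), add 0.2%
BOLD noise, and run the full pipeline:

```r
library(cvrkit)

acq <- acq_params(grid_shape = c(16, 16, 16))      # 92 volumes, TR 3 s
ph  <- make_phantom(c(16, 16, 16), lesion_count = 2, seed = 1)
tm  <- make_truth_maps(ph, cvr_gm = 0.091, cvr_wm = 0.054,
                       lesion_cvr = 0.027, noise_sd = 0.002)
tr  <- make_capno_trace(noise_sd = 0.3, seed = 1)  # 5 × 16 s holds
reg <- build_regressor(tr, acq)
bold <- make_bold(ph, tm, reg, acq, seed = 2)

res <- run_subject(bold, trace = tr,
                   prob_maps = list(gm = ph$prob_gm, wm = ph$prob_wm,
                                    csf = ph$prob_csf),
                   acq = acq, lesion_mask = ph$lesion_mask)
unlist(res$summary[c("cvr_gm", "cvr_wm", "cvr_lesion")])
#>     cvr_gm     cvr_wm cvr_lesion
#> 0.09165431 0.05342761 0.02852579
```

The tissue medians land on the generating truths (GM 0.091, WM 0.054,
lesion 0.027) to within the noise floor, and the depressed lesion CVR is
visible directly. A whole synthetic cohort — 18 controls, 23 patients
with two pre-treatment sessions and one on-treatment session — runs
through the same pipeline and into the statistical battery:

```r
co  <- make_cohort(cohort_spec(seed = 1), acq = acq)
est <- run_cohort(co)
ana <- analyze_cohort(est)
ana$tests$hc_vs_ms_gm      # controls vs pre-treatment patients, GM
#> unpaired_t: stat = 2.145, dof = 39, p = 0.03822, n = 41 [a > b]
ana$tests$delta_vs_pre_gm  # restoration effect: change vs baseline
#> pearson: stat = -3.172, dof = 19, p = 0.005023, n = 21 [negative]
ana$tests$lesion_vs_wm_s1  # lesion CVR below WM at session 1
#> paired_t: stat = -8.355, dof = 11, p = 4.314e-06, n = 12 [x < y]
```

Lower CVR in patients than controls, an on-treatment change that is
larger for subjects starting lower, and depressed CVR inside enhancing
lesions — the generated cohort carries these effects and the pipeline
recovers them.

A thin command-line front end is included:

```sh
Rscript inst/cli/cvrkit.R simulate --out simdir --seed 1
Rscript inst/cli/cvrkit.R fit --bold b.nii.gz --trace capno.tsv \
    --gm gm.nii.gz --wm wm.nii.gz --csf csf.nii.gz --out outdir
Rscript inst/cli/cvrkit.R analyze --cohort cohort.tsv --out analysis
```

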