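# silkfit

Quantitative analysis of serial-sampling **Stable Isotope Labeling
Kinetics (SILK)** studies of CSF amyloid-beta, built for small randomized
trials of APP-production inhibitors. After a primed ^13C6-leucine infusion,
the labeled fraction of Aβ40 in lumbar CSF (sampled every 2 h for 36 h)
traces how fast new peptide is made and cleared. silkfit implements:

- a **linear compartmental model** of Aβ40 production, interstitial
  clearance and CSF transport (ISF → ventricles → cisterna → cranial/spinal
  subarachnoid space) with bi-hourly 6-mL withdrawal events, propagated
  exactly (no integration tolerances; C++ core with an R reference engine);
- the **grid-multistart fitting procedure**: 4 `f_VCSF` × 4 `V_SP` ×
  4 `Q_leak` × 2 `k_BPD40` regimes = 128 constrained Nelder–Mead
  optimizations per subject over (`k_BPD40`, `Q_CSF`, `Q_osc`) with the APP
  production rate `R_APP` profiled from the lumbar concentration scale, an
  ISF:lumbar ratio > 10 penalty, and band-filtered averaging (keep fits
  within 20% of the best SILK and concentration sums of squares, average
  their `R_APP`);
- **FSR** (fractional synthesis rate): OLS slope of the labeled-fraction
  upslope (prespecified hours 6–16, or an automated window detector) divided
  by the plasma leucine plateau enrichment, plus newly-synthesized-Aβ AUC
  and ANOVA group comparisons;
- **noncompartmental PK** (AUC0–24, Cmax/Tmax, suffix-selected terminal
  `lambda_z`, t½, V/F, Cl/F, geometric mean / %GCV summaries, plasma–CSF
  Spearman correlations);
- **trial statistics**: uncorrected Pearson χ² and Fisher-exact baseline
  tables, pooled-t from summaries, covariate-adjusted change ANCOVA,
  dose–response contrasts with a pre-drug concentration covariate, and
  noncentral-t power;
- a **synthetic cohort generator** (site-stratified 5:3 permuted-block
  randomization in sequential dose cohorts, primed-infusion enrichment,
  model-driven SILK/concentration series, steady-state drug PK, draw-level
  missingness, truth tables) so the whole pipeline runs with no external
  data.

## Worked example

```r
library(silkfit)

study <- generate_cohort(seed = 42)          # 24 randomized subjects
table(study$subjects$arm)
#> BID120 placebo    QD60  TID180
#>      6       9       5       4

# FSR by arm (fixed hours 6-16 window)
fsr <- compute_fsr_table(study)
f40 <- fsr[fsr$isoform == "Ab40", ]
aggregate(fsr_fixed ~ arm, f40, function(x) round(mean(x), 4))
#>       arm fsr_fixed
#> 1  BID120    0.0408
#> 2 placebo    0.0406
#> 3    QD60    0.0443
#> 4  TID180    0.0370

# fit one subject's production rate on the reduced 8-combination grid
silk <- split_silk_series(study$silk)[["S001/Ab40"]]
conc <- split_concentration_series(study$conc)[["S001/Ab40/CSF"]]
fit <- fit_subject(silk, conc, grid_config("test"),
                   enrichment = study$enrichments[["S001"]],
                   age = study$subjects$age[1])
fit$summary[c("R_APP", "n_kept")]
#> $R_APP
#> [1] 1.036149
#>
#> $n_kept
#> [1] 6

study$truth$R_APP_true[1]       # the generating value for this subject
#> [1] 0.8897394
```

The FSR values sit on the scale reported for amyloid-positive cohorts
(~0.036/h); the fitted production rate (nmol/h) is the band-filtered
average over 6 kept grid combinations, here 16% above the simulated truth —
typical of the per-subject uncertainty at the study's 7.5% measurement
noise (the vignette quantifies this identifiability limit). An end-to-end report
(baseline table, FSR + ANOVA, NCA summaries, biomarker-change ANCOVA, grid
fits, dose-response, JSON manifest) is one call:

```r
res <- run_end_to_end("report/", seed = 42)
```

A thin command-line wrapper with the same stages lives at
`inst/cli/silkfit.R` (subcommands `simulate-cohort`, `fsr`, `fit-subject`,
`nca`, `table1`, `run-all`).

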