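# mitomethyl

Analysis of cytosine-level DNA methylation in the circular mitochondrial
genome, aimed at three questions asked of postmortem brain tissue: do two
brain regions (nucleus accumbens, NAcc; prefrontal cortex, PFC) carry
distinguishable methylation signatures; does mitochondrial methylation
track chronological age; and does illicit drug use leave a detectable
methylation imprint. The package ships a synthetic-data generator with
planted effects, so the entire pipeline is testable without sequencing
data, and a pipeline that runs from per-cytosine bisulfite calls to
classifier evaluation.

## What it computes

Per-cytosine bisulfite calls (Bismark-style cytosine reports) are filtered
by depth and presence — a site enters the analysis matrix only with
coverage ≥ 30 in **every** sample of a brain area — and annotated with
strand (H/L chain) and sequence context (CpG/CHG/CHH, H ∈ {A,C,T}), with
circular wraparound at the origin. The methylation level at site *i* is

    M_i = 100 · numC_i / (numC_i + numT_i)   (percent)

Three weighted indices are built over sites selected by per-site tests at
a p-value threshold (default 0.05, no multiplicity adjustment — the
threshold itself is swept in sensitivity analyses):

| Index | Per-site test | Weight β_i | Score |
|---|---|---|---|
| BA_index | paired Wilcoxon, NAcc vs PFC (controls) | log fold change of NAcc over PFC | Σ β_i·M_i |
| Age_index | covariate-adjusted linear model (controls) | age slope (%/year) | Σ β_i·M_i |
| DU_index | covariate-adjusted logistic regression | log odds ratio | Σ β_i·M_i |

Covariates are age, batch, collector, alcohol intake, and postmortem
interval dichotomised at 6 h. The epigenetic clock regresses chronological
age on the Age_index score in controls; **age acceleration** is predicted
minus chronological age, with heroin-positive individuals excluded from
group contrasts. The DU_index classifies a sample as drug-exposed when its
score exceeds `mean(control) + 1.96·SD(control)`; performance is reported
as sensitivity/specificity/PPV/NPV at that threshold and as a full ROC
curve whose trapezoid AUC equals the tie-adjusted Mann–Whitney
`U/(n₁·n₀)`.

## Worked example

```r
library(mitomethyl)

cfg <- simulation_config(
  genome_length = 3000, du_effect = 1.5,
  coverage_mean_H = 100, coverage_mean_L = 100,
  coverage_dispersion = 50, seed = 7
)
report <- run_pipeline(cfg)

report$ba$contrasts
#>   contrast                  p_value direction
#> 1 NAcc_vs_PFC_control  0.0000000526         1
#> 2 NAcc_vs_PFC_drug     0.000244             1

report$age$NAcc$clock
#> <clock_model> predicted age = 33.678 + 2.2200 x score (R^2 = 0.8971, p = 7.38e-20)

report$age$NAcc$contrasts
#>   subgroup n_drug n_control median_shift p_value
#> 1 drug_all     12        39         8.53  0.0121
#> 2 ketamine      7        39        11.0   0.0227
#> 3 ats           9        39         7.97  0.0555

report$du$NAcc$eval[, c("sensitivity", "specificity", "ppv", "npv")]
#>   sensitivity specificity   ppv   npv
#> 1           1       0.949 0.875     1
report$du$NAcc$roc
#> <roc_curve> 54 points, AUC = 1.0000
```

Reading the output: the brain-area index separates NAcc from PFC in
controls (planted 1-logit NAcc hypermethylation at 105 sites); the clock
fitted on controls tracks age (R² here is high because the planted age
slope is strong and noise-free relative to tissue data); the drug-use
classifier recovers the planted 1.5-logit drug shift with AUC 1.0 at this
simulation size. `report$counts` traces how many sites survive each filter
and selection stage, and `cohort_summary(...)` reproduces a demographic
table with Mann–Whitney / chi-square group comparisons.

A thin command-line wrapper with `simulate`, `run`, `sweep`, and `summary`
subcommands is installed at `inst/scripts/mitomethyl` (YAML config,
`--seed`, `--out`, `--alpha`, `--context`).

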