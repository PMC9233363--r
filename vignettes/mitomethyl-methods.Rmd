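---
title: "Methods: mitochondrial methylation indices, clock, and classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mitochondrial methylation indices, clock, and classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitomethyl)
```

## The analysis model

The package analyses per-cytosine bisulfite calls from the 16,569-bp
circular mitochondrial genome of paired brain samples (nucleus accumbens,
NAcc, and prefrontal cortex, PFC) from a forensic cohort of control and
illicit-drug-using individuals. The unit of observation is a cytosine site
identified by its 1-based position and strand: `+` is the heavy (H) chain,
read directly off the reference, and `-` the light (L) chain, read off the
reverse complement, so an L-chain cytosine corresponds to a reference `G`
and its downstream neighbours lie at decreasing positions. All context
calls honour circularity: position 16,569 is followed by position 1.
Context is CpG when the next base on the cytosine's own strand is G, CHG
when the next-but-one is G, else CHH (H being A, C, or T). Mitochondrial
methylation is predominantly non-CpG and low — around 2% with site means
below 8% — which shapes several numerical choices below.

The methylation level at site $i$ is $M_i = 100\,\mathrm{num}C_i /
(\mathrm{num}C_i + \mathrm{num}T_i)$ percent. A site enters the analysis
matrix for an area only if its read depth is at least `min_coverage`
(default 30) in *every* sample of that area; the matrix therefore has no
missing cells by construction, and `methylation_level()` treats zero
coverage as an error rather than returning a sentinel. Input counts are
assumed to be base-quality-filtered upstream (Q ≥ 30 trimming happens at
the read level before cytosine reports are produced), and coordinates are
assumed to be on the unpadded circular reference.

Three weighted indices summarise per-site signals, each of the form
$\sum_i \beta_i M_i$ over the sites selected at a p-value threshold
$\alpha$ (default 0.05):

* **BA_index** — sites where the paired Wilcoxon signed-rank test finds
  NAcc and PFC levels to differ across control individuals; $\beta_i$ is
  the natural-log fold change of the NAcc over the PFC control mean.
* **Age_index** — sites whose level is associated with chronological age
  in controls, by a per-site linear model with batch, collector, alcohol,
  and postmortem-interval class as covariates; $\beta_i$ is the age
  coefficient in percent per year. Without covariates this equals the
  Pearson-correlation slope $r\,s_M/s_{\text{age}}$.
* **DU_index** — sites where a per-site logistic regression of group on
  level (adjusting for age and the covariates above) separates drug users
  from controls; $\beta_i$ is the log odds ratio per percentage point.

Selection applies no multiple-testing adjustment. This is deliberate: the
indices are built from a thresholded screen whose threshold is itself a
tuning parameter, and the sensitivity sweep (`sensitivity_sweep()`)
re-runs selection, index construction, and evaluation at 0.05/0.02/0.005
and on CpG-only and non-CpG-only subsets, checking that selected-site sets
nest across thresholds and that qualitative conclusions persist.

The epigenetic clock is an ordinary least-squares regression of
chronological age on the Age_index score, trained on controls only; drug
samples are scored with the frozen control model. Age acceleration is
predicted minus chronological age. Heroin-positive individuals are
excluded from acceleration contrasts (heroin has a reported rejuvenating
rather than accelerating effect); amphetamine-type-stimulant and ketamine
subgroup contrasts reuse the same acceleration vector under subgroup
masks. The DU classifier calls a sample positive when its score strictly
exceeds `mean + 1.96 · SD` of the control scores (sample SD, $n-1$); ties
at the threshold are negative, preserving the one-sided 97.5% null
specificity of the rule. The ROC sweeps all distinct scores, accumulating
by unique value so tied scores contribute diagonal segments; the trapezoid
area then equals the tie-adjusted Mann–Whitney $U/(n_1 n_0)$ exactly,
which the test suite asserts to 1e-12.

## Inference machinery and numerical choices

* **Paired Wilcoxon.** Zero differences are dropped, absolute differences
  are mid-ranked, and for up to 25 non-zero pairs the null distribution is
  computed exactly by a generating-function convolution over doubled
  ranks (doubling makes tied mid-ranks integral). Beyond 25 pairs a
  normal approximation with the mid-rank variance $\sum r_i^2/4$ is used,
  without continuity correction. The all-zero case returns p = 1 with a
  degeneracy flag.
* **Mann–Whitney.** Exact via the rank-sum distribution when
  $m+n \le 20$ without ties; otherwise a tie-corrected normal
  approximation, again without continuity correction so the $U$/AUC
  identity stays exact.
* **Chi-square.** Pearson, without continuity correction; this is the
  convention that reproduces the published demographic-table p-values
  (0.754 for alcohol, 0.173 for postmortem interval, 0.015 for cause of
  death), which the acceptance suite recomputes from the printed counts.
* **Logistic p-values** are Wald. At the study scale (39 + 14 with nine
  covariate parameters) Wald p-values are conservative — under a fully
  null simulation the fraction below 0.05 falls well short of 5% — while
  the likelihood-ratio test is anti-conservative at the same size; neither
  small-sample behaviour is a coding defect, so the calibration check for
  the logistic runs at 100 + 100 samples, where the asymptotics hold and
  the p-values are uniform. The paired-Wilcoxon and age-association
  checks run at the study's own n = 39.
* **Degenerate fits** (constant predictor, non-finite or absurd standard
  error on the methylation coefficient, SE > 50) are flagged and excluded
  from selection rather than emitted as infinite effects. The flag
  inspects only the methylation coefficient: quasi-separation on a sparse
  nuisance cell (say, a batch with no drug members) inflates that
  covariate's standard error without invalidating the site test.
* **Fold changes** use a pseudocount of 0.01 percent, keeping effects
  finite when a group mean is exactly 0 without dominating the ~2%
  regime. Natural logarithms are used for both fold changes and odds
  ratios (the logistic-regression native scale).
* **Power.** The design's power claim is computed by the Fisher-z
  closed form $\Phi(\sqrt{n-3}\,\mathrm{atanh}\,r - z_{1-\alpha/2})$,
  which a 100,000-replicate Monte-Carlo oracle confirms to ±0.01. Note
  the formula's $r \to 0$ limit is $\alpha/2$, not $\alpha$: it
  deliberately neglects the far-tail rejection region, which is
  negligible for any design-relevant $r$.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
not reads or alignments. Its defaults are the study conditions: 39
controls and 14 drug users (two heroin, five ATS-only, three
ketamine-only, four ATS+ketamine), control ages N(54.9, 21.5²) and drug
ages N(37.5, 12²) truncated at 18, a 16,569-bp circular reference at 44%
GC, and one missing PFC sample among the drug users. Methylation is
assembled on the logit scale per site and individual:

$$\eta = \eta_{\text{site}} + u_{\text{ind}} +
  \beta_{BA}\,[NAcc] + \beta_{age}(a - \bar a) + \beta_{DU}\,[drug]$$

with site baselines $\eta_{\text{site}}$ drawn around logit(0.02) with SD
0.5 and capped at 8%, a per-individual biological deviation
$u_{\text{ind}}$ (SD 0.5 logit) shared between the two areas of one
individual — this is what induces the within-individual pairing
correlation the paired Wilcoxon exploits — and planted effects confined
to three pairwise-disjoint site sets. An optional `drug_age_shift` adds
years to a drug user's effective age at the age sites, planting an
age-acceleration signal. Coverage is negative-binomial with
strand-dependent means (defaults H = 100, L = 50, size 20), chosen so
that under the ≥30-in-all-samples rule most H-chain sites survive while
the L-chain is heavily depleted, reproducing the strand asymmetry real
mitochondrial bisulfite data show; methylated counts are binomial given
coverage. One RNG stream per dataset is derived from the config seed,
with deterministic sub-streams per individual, so a fixed seed yields
byte-identical output files.

What the generator does **not** model: read-level error, bisulfite
conversion failure, NUMT contamination, linkage between neighbouring
sites, or heavy-tailed coverage from library artefacts. Passing tests
therefore demonstrate that the pipeline's logic and inference behave
correctly under its stated assumptions — they are not evidence about any
particular tissue dataset.

## Problem sizes used by the test and acceptance suites

Simulation-backed checks run on reduced genomes so the suite stays quick
while keeping at least ~1000–2000 analysable sites where calibration is
asserted: null-calibration runs use a 9,000-bp genome (~2000 H-chain
sites), recovery experiments 3,000–4,000 bp with coverage raised to
100–120 on both strands (so planted L-chain sites are not lost to the
presence filter), and determinism checks 800–1,200 bp. Strong-effect
regimes plant 2-logit brain-area shifts, 0.04 logit/year age slopes, and
1.5-logit drug shifts. These sizes are the package's own choices for its
test harness; the pipeline itself runs at full genome scale.

## Known limitations

* **Clock shrinkage bias.** Because the clock regresses age on score,
  predicted ages are compressed toward the training mean; a contrast
  group younger than the controls therefore shows spuriously positive
  "acceleration" even with no planted effect (we observe +4 to +12 years
  median at zero planted shift when the drug group is ~17 years younger,
  compounded by the logit-scale nonlinearity of the generative model).
  The planted-shift detection experiment demonstrates detection on top of
  this bias, not an unbiased estimate of it. Any application comparing
  groups of different mean age inherits this artifact; age-adjusting the
  acceleration (regressing it on age before the contrast) would remove
  it, but is deliberately not done because the pipeline reproduces the
  published procedure.
* **Wald conservatism at n = 53**, discussed above: at the study size the
  per-site logistic screen under-selects, so DU-index site counts at
  α = 0.05 should be read as conservative.
* **L-chain dropout.** With stringent depth-and-presence filtering and
  realistic strand-asymmetric coverage, most L-chain sites never reach
  the matrix; planted L-chain effects are unrecoverable at default
  coverage. This mirrors the real data regime, not a pipeline defect.
* **Selection at an unadjusted threshold** admits false-positive sites
  into every index; with strong planted effects the weighted sum is
  robust to this, but at weak effects index composition is unstable
  across thresholds, which is exactly what the sensitivity sweep is for.
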