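---
title: "Methods: endophenotype-enriched SNP-diagnosis mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: endophenotype-enriched SNP-diagnosis mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endomap)
```

## The model

`endomap` scores a SNP not by its direct association with a binary
diagnosis, but by how similarly the SNP and the diagnosis disturb a panel of
regional brain measures (imaging quantitative traits, QTs). Three stages:

**Stage 1 (diagnostic map).** For each region's QT $y$, ordinary least
squares of $y = \beta x + \Gamma Z + \varepsilon$, where $x$ is diagnosis
coded 0 = control / 1 = case and $Z$ holds the nuisance covariates (age in
years, sex as 0/1, education in years). The exact two-sided $t$-test of
$\beta \ne 0$ (on $n - k - 2$ degrees of freedom, $k$ covariates, intercept
always included) gives a per-region p-value; the map entry is $-\log_{10}p$.

**Stage 2 (genetic maps).** The same regression with the additive genotype
$g \in \{0, 1, 2\}$ (copies of the minor allele) in place of $x$, once per
SNP-region pair, over the pooled cases and controls of the contrast. One
$-\log_{10}p$ map per SNP.

**Stage 3 (map correlation).** Pearson correlation $r$ between each SNP's
map and the diagnostic map across regions, a two-sided p-value from
$t = r\sqrt{(n_\mathrm{ROI} - 2)/(1 - r^2)}$, Bonferroni correction over the
SNP family, and a significance call at corrected $p < \alpha$ (default
0.05).

The assumptions are those of OLS per region (linear additive effects,
homoscedastic errors) plus — for the stage-3 analytic p-value —
independence and near-normality of the paired map entries. The latter is
the method's weakest link; see *Calibration of the map-correlation p-value*
below.

Maps are **unsigned**: the per-region coefficient signs are recorded in
every `effect_map` but the correlation uses the $-\log_{10}p$ magnitudes
only. Two predictors that disturb the same regions in opposite directions
therefore still correlate; sign concordance can be inspected afterwards
from the stored signs.

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.05 | level applied to Bonferroni-corrected p |
| `m` (family size) | SNPs tested per contrast | each diagnostic contrast is its own family; configurable for stricter policies (e.g. SNPs x contrasts) |
| QC thresholds | call rate > 0.95, MAF > 0.05, HWE p > 1e-6 | strict inequalities; cohort-wide, applied once before any contrast subsetting (a per-contrast option exists) |
| `p_method` | `"analytic"` | stage-3 p-value route; `"permutation"` gives the calibrated ROI-permutation alternative |
| p-value floor | 1e-300 | clamp before $-\log_{10}$, so exact fits give finite map entries (300) |

The Hardy-Weinberg criterion uses the exact conditional test: given the
minor-allele count, the heterozygote count has the distribution
$P(n_{Aa}) \propto \binom{n}{n_{aa}}\binom{n-n_{aa}}{n_{Aa}} 2^{n_{Aa}}$,
and the p-value sums all configurations no more probable than the observed
one (standard tail definition, no mid-p). It is computed in log space via
`lgamma` and renormalised, stable into the thousands of alleles; ties are
matched with a `1e-12` relative tolerance. The test suite verifies it
against an independent full-enumeration oracle for every genotype table up
to 400 alleles.

## The synthetic cohort generator

Real imaging-genetics cohorts with verified genetics are access-restricted,
so the package ships a generator whose defaults define the study
conditions for every simulation-based test:

* **Genotypes**: independent loci at Hardy-Weinberg proportions, minor
  allele frequencies uniform on `maf_range` (default 0.05-0.5), optional
  missing calls at a fixed rate. No linkage disequilibrium.
* **Covariates**: age ~ U(65, 85) years, sex ~ Bernoulli(0.5), education ~
  U(12, 20) years — magnitudes typical of an elderly memory-clinic cohort —
  entering every QT linearly (defaults 0.02/SD-year, 0.1, −0.02).
* **QTs**: per-region standard-normal noise plus the planted per-allele
  shifts (`snp_effect_size`, in noise-SD units) on each causal SNP's target
  regions.
* **Diagnosis**: a liability threshold. The liability is
  `liability_weights · QT + N(0, 1)`, thresholded at the `case_fraction`
  quantile; this is the standard quantitative-genetics construction and
  makes the QTs literal endophenotypes — the *only* path from genotype to
  diagnosis runs through them. Cases then receive an extra shift
  (`dx_effect_size`) on the affected regions. Ordering matters and is
  deliberate: QTs are generated first without the case shift, liability is
  computed from those pre-shift QTs, and the shift is added afterwards —
  the only acyclic reading of "QTs carry a diagnosis effect" and
  "diagnosis is thresholded QT liability" simultaneously.
* **Disease stages**: with several case classes (e.g. EMCI/LMCI/AD), cases
  are split into tiers by liability rank and class $k$ of $K$ receives
  $k/K$ of the case shift — graded severity against a single control group.
* **Seeds**: one integer seed; genotypes, covariates, QT noise, liability
  noise and null-set draws use streams derived from it by fixed offsets, so
  each stage is independently reproducible.

What the generator does *not* emulate: spatial correlation between regions,
linkage disequilibrium, covariate-genotype confounding (population
structure), heteroscedastic or heavy-tailed imaging noise, and
direct genotype-to-diagnosis effects. Passing tests therefore demonstrate
correctness of the machinery and the method's behaviour under clean
mediation, not performance on real imaging genetics data — in particular,
spatially correlated maps make the stage-3 independence assumption worse,
not better, than in these simulations.

## Calibration of the map-correlation p-value

The analytic stage-3 p-value treats the region pairs as independent
near-Gaussian observations. Map entries are $-\log_{10}$ of p-values —
right-skewed (exponential-like under the null) — and under a null cohort
this skew makes the analytic p anti-conservative deep in the tail: in our
null simulations the family-wise error over 54 Bonferroni-corrected SNPs
runs about twice the nominal 0.05 when the analytic p is used. This is a
property of the published procedure, not an implementation artifact.

`correlate_maps(..., p_method = "permutation")` replaces the analytic p
with an ROI-label permutation p: the diagnostic map is permuted over
regions (a single shared set of permutations, correlated against every SNP
map by one matrix product, so $10^4$ draws cost milliseconds), and the
two-sided p is the fraction of permutations with $|r|$ at least the
observed one, with the usual $(h+1)/(B+1)$ correction. This p is exactly
valid under exchangeability of region labels regardless of the maps'
marginal shape. The package's family-wise-error and percentile-monotonicity
guarantees are asserted under this calibrated option; the analytic route
remains the default because it is the published procedure and is what the
reported correlations and corrected p-values refer to. Note permutation of
region labels still assumes exchangeability — genuinely spatially
autocorrelated maps violate it, and no spatial model is attempted here.

A related discreteness note: when correlating a SNP with a 0/1 diagnosis
directly (the Pearson baseline), the permutation distribution has sizeable
atoms; the analytic p approximates the permutation *mid-p*, and the test
suite compares against that quantity.

## Comparator analyses

* `gwas_logistic()`: logistic regression of case status on genotype plus
  covariates (IRLS, tolerance 1e-8, max 100 iterations), two-sided Wald
  test on the genotype log-odds — the standard covariate-adjusted GWAS
  model for a binary trait. Complete or quasi-complete separation is
  flagged (`converged = FALSE`, p missing) rather than reported as a
  spuriously extreme result; no penalised fallback is attempted. A
  linear-probability variant can be had by passing the 0/1 outcome to
  `fit_linear_effect()`.
* `pearson_snp_dx()` / `partial_corr_snp_dx()`: correlation of genotype
  with the numeric 0/1 diagnosis, the partial version correlating
  OLS residuals after regressing both on the covariates (df
  $n - 2 - k$). With no covariates the partial version reduces exactly to
  the Pearson one.

All methods are Bonferroni-corrected over the same per-contrast SNP family
as the map correlation, so detection counts are directly comparable.

## The random-SNP-set experiment

`run_null_experiment()` draws `set_size` SNPs without replacement from a
background pool, runs stages 2-3 on each draw, and records the number of
significant SNPs; the hypothesis set's count is ranked as the fraction of
draws it strictly exceeds (ties do not count as outperformed — the
conservative reading). Draws are independent across replicates and
deterministic given the seed. The default is 1,000 draws; 10,000 matches a
publication-grade histogram and costs linearly more.

## Numerical and degenerate-input choices

* All stage-1/2 fits for one predictor share a design matrix, so a map is
  one QR decomposition applied to every region column at once; the
  single-trait `fit_linear_effect()` runs the same code path. Full rank is
  checked explicitly and collinear columns are named in the error.
* Missing data: complete cases per fitted model (per SNP, per region);
  `n_used` is recorded in every result row.
* Constant predictors (a SNP monomorphic within a contrast subset) are
  excluded with a warning and listed, never silently dropped; constant
  maps likewise. Region-order mismatches between maps are an error — the
  package never re-indexes silently.
* Genotype readers fold every SNP to minor-allele coding (flip when the
  counted allele's frequency exceeds 0.5), so VCF and dosage-TSV input
  yield identical matrices; association p-values are invariant to the
  fold.
* Outputs are written with fixed formatting; rerunning a pipeline with the
  same config and seed reproduces every artifact byte for byte.

## Test problem sizes

Simulation-based checks in the test suite use cohorts of 100-600 subjects,
3-116 regions and 1-80 SNPs, with 20-1,000 replicates per property: type-I
calibration and family-wise error at 1,000 replicates, the HWE oracle over
all tables to 400 alleles, the permutation oracle at $10^5$ draws, and the
method-comparison property at 60 replicates of the mediation fixture
(`n = 600`, six causal SNPs on disjoint 10-region blocks, 0.5 SD per-allele
effects, 1.0 SD case shift, liability weights $0.5/\sqrt{60}$). That
fixture was chosen by a design-time power analysis to sit in the regime the
method targets — brain maps individually strong, composite SNP-diagnosis
channel weak — and is deliberately not tuned further.

## Known limitations

* No spatial model of inter-region correlation; both stage-3 p-value
  routes assume exchangeable regions.
* No subject-level QC (relatedness, ancestry PCs) and no population
  stratification control in the GWAS baseline.
* Region panels are treated as fixed and complete; irrelevant regions
  dilute the map correlation and no region-selection step is attempted.
* The generator's independence assumptions (no LD, independent regional
  noise) make simulated power an optimistic ceiling for real data.
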