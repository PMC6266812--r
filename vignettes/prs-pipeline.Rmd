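---
title: "Cross-trait polygenic risk scoring in small case-control cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-trait polygenic risk scoring in small case-control cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prscross)
```

## The method

`prscross` implements the classical P-value-threshold ("P+T without
clumping") polygenic risk score analysis used to ask whether a small patient
cohort carries an elevated genetic liability for *other* traits. Given GWAS
summary statistics for a trait, the additive score of individual $i$ is

$$\mathrm{PRS}_i \;=\; \sum_{j \in S(P_T)} w_j \, d_{ij},$$

where $d_{ij} \in [0, 2]$ is the effect-allele dosage, $w_j$ the published
per-allele effect (beta, or log odds ratio), and $S(P_T)$ the set of
variants with association $P$-value strictly below a threshold $P_T$. The
analysis is repeated across the grid
$P_T \in \{0.001, 0.005, 0.01, 0.05, 0.1, 0.5, 1\}$ because no single
threshold is optimal a priori. Scores are standardized to mean 0 / SD 1
before any inference, so all downstream effects are "per SD of PRS":

* **Case/reference shift** $\delta$: difference in mean standardized PRS
  between cases and the reference set, tested with a pooled-variance
  two-sample $t$-test (Welch available via `var_equal = FALSE`).
* **Odds ratio per SD**: maximum-likelihood logistic regression of case
  status on the standardized score; $\mathrm{OR} = e^{\hat\beta}$ with 95%
  Wald interval $e^{\hat\beta \pm 1.96\,\mathrm{SE}}$ and two-sided Wald
  $P$. No covariates are included. Non-convergence and separation are
  flagged, never silently reported with a fabricated interval.
* **Symptom-level validation**: for prospective binary follow-up outcomes,
  a one-way two-level ANOVA compares the mean PRS of subjects positive
  versus negative for each symptom (identical to the squared pooled
  $t$-test). Because allergic outcomes in one child are strongly
  correlated, no multiple-testing correction is applied by default
  (nominal $P < 0.05$); a Bonferroni option exists.

## Quality control and harmonization

Before scoring, imputed genotypes pass the standard post-imputation
filters: variants are kept only when MAF $> 0.01$ **and** INFO $> 0.9$,
with strict inequalities so boundary values are removed. Sample call rates
are reported and samples below 95% are *flagged but retained* — exclusion
is an explicit opt-in (`drop_flagged_samples()`), reflecting the practice
of keeping borderline samples that pass all other array QC.

Summary statistics and genotypes rarely agree on allele orientation.
`harmonize()` aligns every variant to the effect allele: when the effect
allele is the VCF ALT the dosage is used as-is, when it is the REF the
dosage becomes $2 - d$. The flip acts on dosages, not on the published
weights, so exported weights always match the source GWAS.
Strand-ambiguous variants (A/T, C/G) are dropped by default because the
two strand readings produce genuinely different scores and cannot be
disambiguated without strand metadata; `drop_ambiguous = FALSE` is
appropriate only when both files are known to share a strand, as for data
simulated by this package.

Two deliberate deviations from common PRS practice, chosen to match the
scoring model actually used here:

* **No LD clumping or pruning.** Scores are plain sums over all selected
  variants. With clumping absent, effect sizes of correlated variants are
  double-counted; results should be read as relative liability contrasts,
  not absolute risk.
* **Combined-cohort standardization.** Scores are standardized over cases
  and reference together (sample SD, $n-1$), which makes "the reference
  set centred near 0" an approximation that is excellent when cases are a
  small fraction of the cohort (22 of 329 here). Reference-only centring
  is available (`standardize_with = "reference"`). Standardization is done
  per (trait, threshold) cell.

Other fixed numerical conventions: threshold selection is strict
(`p < P_T`); OR-scale inputs are log-transformed exactly once at ingest;
missing dosages are mean-imputed per variant by default (alternatives:
zero contribution, or excluding any variant with missingness); variants
with all dosages missing are dropped with a warning; standardization of a
constant score is a hard error rather than a silent zero-division.

## The synthetic-data generator

The genotype and follow-up data this design targets are restricted, so the
package ships a generator that reproduces the *statistical structure* the
analysis assumes, at its exact design: 22 cases, 307 population reference
subjects, 19 cases with six-year follow-up.

**Summary statistics.** Each variant gets an effect-allele frequency
$f \sim U(0.05, 0.5)$; a fraction (default 0.1) is causal with true
effects $\sim N(0, 0.05^2)$ on the log-odds scale. The reported effect
adds estimation noise with $\mathrm{SE} = 1/\sqrt{2 f (1-f)\, n_{\rm gwas}}$
(default $n_{\rm gwas} = 20{,}000$, the order of mid-2010s disease GWAS),
and the reported $P$ is the two-sided normal probability of the Wald
ratio. Under a fully null configuration the $P$-values are exactly
uniform, which the tests exploit.

**Calibrated case enrichment.** Case/control status is modelled
retrospectively: cases draw genotypes from tilted allele frequencies
$f'_j = f_j + \lambda w_j f_j (1 - f_j)$, with $\lambda$ solved in closed
form so that the expected raw-score mean difference equals
$\delta \times$ the raw-score SD under independence,
$\lambda = \delta / \sqrt{\sum_j w_j^2\, 2 f_j (1 - f_j)}$. Tilted
frequencies are clipped to $[10^{-4}, 1 - 10^{-4}]$ and the clip count is
reported, since clipping shrinks the realized shift. The default target is
$\delta = 0.41$ SD, the magnitude of the asthma-score shift this design is
built around; recovery within $\pm 0.05$ SD over 500 replicates is an
acceptance property of the test suite. A score-level shortcut
(`simulate_score_cohort()`: reference $N(0,1)$, cases $N(\delta, 1)$)
exercises the association layer in isolation.

**What the generator does *not* emulate** — and hence what green tests do
not certify about real data: linkage disequilibrium (variants are
independent, which is also what makes the calibration closed-form),
population stratification and ancestry mismatch between cases and
reference, Hardy–Weinberg violations, imputation error structure (INFO
scores are drawn $U(0.5, 1]$ merely so the filter sees both outcomes), and
genotyping batch effects. On real data these produce confounded or
attenuated shifts that no amount of simulation passing can rule out.

**Follow-up phenotypes.** Binary symptoms arise from
$\Pr(\text{symptom}) = \operatorname{logit}^{-1}(\operatorname{logit}(\text{base rate}) + \beta_s \cdot \mathrm{PRS})$
over twelve symptoms in four domains (asthma, allergic rhinitis, atopic
dermatitis, food allergy). Default base rates are the observed follow-up
prevalences of the emulated cohort (e.g. nightly coughing 5/19, eczema
7/19; three symptoms have one missing response, so their denominator is
18). `followup_reference_table()` is a deterministic synthetic
reconstruction pinned to those margins — 6 female / 13 male, two
IgE-positive of 16 with IgE data — with an arbitrary assignment of which
subject is positive for what; it exists so prevalence arithmetic and IO
round-trips can be tested against published-style margins. In
`simulate_study_files()` the five asthma-domain symptoms depend on the
asthma PRS with +0.8 log-odds per SD by default, the order of the
symptom-level shifts (0.7–0.9 SD) this design anticipates; all other
symptoms are null.

**End-to-end study.** `simulate_study_files()` writes five trait panels
(default: only `asthma` carries a shift, at 0.58 SD, the largest
threshold-specific shift in the motivating design), one dosage VCF over
the union of panels, a phenotype CSV and a ready pipeline YAML. Note that
the realized end-to-end shift is *attenuated* relative to the calibration
target: calibration spans the whole panel, while the pipeline then drops
variants at QC (INFO $\le 0.9$ removes roughly 80% of variants by
construction) and drops strand-ambiguous variants (about a third of random
allele pairs). The pipeline-level acceptance check is therefore
directional (OR > 1 at a majority of cells) rather than a magnitude
recovery; magnitude recovery is asserted where it is well-defined, on the
unfiltered score path.

## Determinism and problem sizes

Every stochastic operation is a pure function of (inputs, seed); the RNG
state of the session is saved and restored around each draw, and the
analysis pipeline itself is deterministic, so a fixed configuration
reproduces byte-identical output files. Result tables are written at full
double precision (`%.17g`) so write/read round-trips are exact.

The test suite runs at desk scale by choice: panels of 100–400 variants,
500-replicate shift-recovery and 1000-replicate null-calibration loops,
2000-replicate OR recovery at the 22/307 design, and $10^5$ per group for
the logistic discriminant-limit identity. These sizes keep every
Monte-Carlo standard error several times smaller than the asserted
tolerance while completing in minutes.

## Known limitations

* No LD-aware scoring or shrinkage estimators; scores from dense real
  panels will overweight long haplotypes.
* The logistic OR per SD is slightly biased away from 1 at 22 cases
  (small-sample MLE bias plus Jensen's inequality on $e^{\hat\beta}$); the
  simulation-based checks measure the estimator as used, not a
  bias-corrected version.
* The reference set is modelled as one homogeneous population; the
  frequency provenance of a real reference panel is not represented.
* BGEN/PLINK binary genotype formats and indexed region queries are out of
  scope; inputs are summary-stat TSV, (optionally gzipped) VCF with DS or
  GT, and phenotype CSV.
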