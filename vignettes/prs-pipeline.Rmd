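---
title: "Weighted polygenic risk scores for case-control cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted polygenic risk scores for case-control cohorts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prspipe)
```

# The model

`prspipe` implements the weighted polygenic risk score (PRS) analysis used
in multi-locus risk prediction for psoriasis and similar case-control
settings. The score of individual $j$ is

$$\mathrm{PRS}_j = \sum_{i} w_i \, g_{ij}, \qquad w_i = \ln \mathrm{OR}_i,$$

where $g_{ij} \in \{0,1,2\}$ counts copies of the risk allele of variant
$i$ and $\mathrm{OR}_i$ is a *published* per-allele odds ratio — the
weights are taken as given, never re-estimated from the analysed cohort.
Four nested score models are supported: the 13 small-effect non-HLA SNPs
(`SNP`), the single large-effect HLA locus (`HLA`), all 14 variants
(`SNP_HLA`), and all variants plus an environmental ever-drinking term
(`SNP_HLA_DRINK`), which adds $w_E \cdot \mathrm{drinker}_j$ with $w_E$
the log odds ratio of ever-drinking from meta-analytic evidence.

Downstream of scoring, the pipeline follows the standard epidemiological
toolkit:

* **Risk groups.** Subjects are binned by the quartiles of the PRS among
  healthy controls (groups 0-3); a single logistic regression with group
  indicators plus age and sex yields per-group odds ratios against the
  bottom quartile with Wald 95% intervals.
* **Continuous effect.** A logistic fit of status on the raw PRS plus
  age/sex gives the per-unit log-odds $\beta$, and Nagelkerke's pseudo-$R^2$
  summarises "phenotypic variation explained".
* **Discrimination.** ROC curves and AUCs per model, compared pairwise by
  DeLong's structural-component test for paired AUCs; the Youden point
  provides an operating sensitivity/specificity.
* **Onset.** Among cases, age of onset is analysed by Kaplan-Meier curves,
  log-rank tests between risk groups, Cox proportional-hazards models, a
  one-way ANOVA of onset age across groups, and the difference of KM
  median onset between extreme groups.

# Quality control and association

Genotype QC mirrors common array practice with the defaults the pipeline
ships: per-sample call rate > 90%, then per-SNP call rate > 90%, then an
exact Hardy-Weinberg test among controls at $p > 10^{-3}$. The filters run
in that fixed order, and every dropped entity is logged with the one
threshold that removed it. The HWE test is the exact conditional test:
given the observed allele counts, the p-value sums the probabilities of
all heterozygote counts no more probable than the observed one (the
conventional definition, not mid-p).

Single-variant association uses the 1-df Pearson chi-square on the 2x2
allele-count table without continuity correction (the allelic test of the
standard GWAS toolkit), with the cross-product odds ratio and Woolf
confidence interval $\exp(\ln\mathrm{OR} \pm 1.96\sqrt{\sum 1/n_{kl}})$;
zero cells fall back to the Haldane-Anscombe 0.5 correction and are
flagged. Design power for a replication cohort is computed from the
noncentral chi-square with the noncentrality implied by the case allele
frequency $p\,\mathrm{OR}/(1-p+p\,\mathrm{OR})$.

# The synthetic cohort generator

No individual-level genotype data are distributable, so every stage is
exercised against `simulate_cohort()`, whose defaults *are* the study
conditions the pipeline targets:

* 3621 cases and 3350 controls;
* 14 independent biallelic SNPs (linkage equilibrium), controls in HWE at
  allele frequencies 0.12-0.48, with the HLA-like locus at 0.15;
* one large additive effect (OR 8) and 13 small ones (OR 1.11-1.58),
  which is the magnitude pattern of the psoriasis panel (the package's
  `synthetic_panel()` is a clearly labelled stand-in — only two rs
  identifiers are public in the main text of the motivating study);
* ever-drinking with control prevalence 0.25 and case-control OR 2.49,
  independent of genotype given status (no interaction is simulated; the
  motivating data reported none);
* positive family history among cases following a logistic model in the
  PRS (slope 0.35 per unit), with the intercept calibrated so the marginal
  rate is 31.34%;
* onset age among cases from an exponential proportional-hazards model
  with hazard ratio 1.08 per PRS unit and baseline scale 43 years, chosen
  so the median onset is near 21 years;
* uniform genotype missingness at 0.4% per call, so that about 5% of
  subjects miss at least one of 14 genotypes — the order of magnitude of
  the complete-genotype filter in the motivating study.

**Retrospective sampling.** Case genotypes are drawn from
$P(g \mid \mathrm{case}) \propto P(g \mid \mathrm{control})\,\mathrm{OR}^g$,
the genotype law implied by case-control (outcome-dependent) sampling
under the additive logistic model. This makes the marginal per-allele odds
ratios exact by construction — the case allele frequency is analytically
$p\,\mathrm{OR}/(1-p+p\,\mathrm{OR})$ — which is what lets the tests treat
effect recovery as a sharp check rather than a qualitative one. A
liability-threshold model would have been the main alternative; it was
rejected because its marginal ORs are only approximate and the analysis
under test is itself the additive logistic model.

**Onset and enrolment age.** Cases are ascertained after onset, so the
generator draws onset from the proportional-hazards model (floored at 1
year) and sets a case's enrolment age to onset plus an exponential
recruitment delay with mean 9 years, capped at 81; controls draw age from
a normal (mean 30, sd 11.5) truncated to 3-81. Drawing age first and
truncating onset to it — the superficially simpler choice — conditions the
onset time on an independent variable and destroys the marginal hazard
structure: in experiments at study scale the fitted hazard ratio attenuated
from 1.08 to ~1.02. The delay construction preserves `onset <= age`
exactly and leaves the marginal hazard recoverable. A consequence worth
knowing: since enrolment age is onset plus delay, age is outcome-dependent
in the generator, and the package's *parameter-recovery* tests adjust the
onset Cox model for sex only; the pipeline's default onset analysis still
adjusts for age and sex, as the field convention dictates for real data.
A second consequence is that the simulated case age and onset
distributions have heavier right tails than a real clinic cohort
(exponential baseline); the generator targets the hazard structure and the
median, not the full onset shape.

**Determinism.** One seed drives everything, with a documented stream
order (control genotypes, case genotypes, missingness mask; then age, sex,
drinking, family history, onset, recruitment delay), so
`write_fixture_bundle()` emits byte-identical PLINK text + TSV bundles for
a given configuration.

**What passing tests do and do not show.** The generator has independent
SNPs, no population structure, no genotyping error beyond uniform
missingness, and exact HWE in controls. Tests passing on it demonstrate
the *statistical machinery* is correct under the model the analysis
assumes; they say nothing about robustness to linkage disequilibrium,
stratification or differential genotyping error in real data.

# Numerical choices

* **Percentiles** for the control quartiles use linear interpolation
  between order statistics (R's default type 7); group boundaries are
  lower-inclusive at Q1, i.e. group 0 is `score <= Q1`, matching the
  "<=" convention of the published group table.
* **Logistic regression** is fitted by iteratively reweighted least
  squares (`stats::glm`) with a tightened convergence tolerance
  (`epsilon = 1e-14`) so a saturated single-predictor fit reproduces the
  closed-form 2x2 log-OR and Woolf standard error to 1e-6. Rank-deficient
  designs and complete separation raise explicit errors naming the term.
* **Wald intervals and p-values** are reported throughout, matching the
  "OR (95% CI)" presentation convention; the likelihood-ratio test is
  reserved for the joint group-by-exposure interaction.
* **Missing genotypes** default to dropping the sample from scoring (the
  complete-genotype filter of the motivating study); expected-dosage
  imputation (2 x control allele frequency) is available and is what the
  end-to-end pipeline uses on simulated data so that sample sizes stay
  stable across the four models.
* **AUC** uses the midrank Mann-Whitney statistic; the trapezoidal area
  under the constructed curve equals it exactly, ties included. DeLong
  variances use placement values computed from midranks (O(n log n)).
  Degenerate constant scores return AUC 0.5 with a flag.
* **Youden ties** break toward higher specificity.
* **Survival** uses the Efron tie correction by default (onset ages are
  heavily tied once rounded); Breslow is available by flag. All cases are
  events; right-censoring is supported for generality.
* **Pseudo-$R^2$** is Nagelkerke's rescaled Cox-Snell; the convention is
  stated because "variance explained" claims are method-dependent.

# Problem sizes

The shipped test-suite exercises reduced cohorts (hundreds to a few
thousand subjects) and bounded replicate counts (e.g. 2000 bootstrap or
permutation draws, 10-60 seeds for recovery/coverage properties); these
sizes were chosen so the whole suite completes in a couple of minutes
while keeping binomial slack on every stochastic bound explicit in the
test. The acceptance script runs the full pipeline once at complete study
scale (3621 cases / 3350 controls).

# Known limitations

* Weights are consumed, never estimated: there is no penalised regression
  or genome-wide scoring.
* No linkage disequilibrium, imputation dosages, binary PLINK, or VCF
  input; allele matching is symbol-level (no strand flipping).
* The DeLong test assumes paired scores on identical samples; unpaired
  cohort comparisons are out of scope.
* Prevalence-adjusted predictive values and reclassification indices are
  not computed.
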