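# prspipe

Weighted polygenic risk score (PRS) modelling for case-control cohorts.

Genome-wide association studies of psoriasis have produced a compact panel
of susceptibility variants — a dozen small-effect SNPs plus one
large-effect HLA locus — and the practical question is whether those
variants, combined, can screen individuals by genetic risk. `prspipe` is
an R package for that analysis: it scores individuals by the weighted sum
of their risk-allele counts,

    PRS_j = sum_i  ln(OR_i) * g_ij ,      g_ij in {0, 1, 2},

with published per-allele odds ratios as weights (optionally extended by
an environmental ever-drinking term), and carries the score through the
full epidemiological workup:

* genotype QC — per-sample and per-SNP call rates, exact Hardy-Weinberg
  test in controls — and per-SNP allelic chi-square association with
  Woolf confidence intervals and design power;
* control-quartile risk groups with covariate-adjusted odds ratios per
  group (the classic four-row risk table);
* continuous-PRS logistic models with Nagelkerke pseudo-R²;
* ROC/AUC per score model with DeLong's paired test between models and a
  Youden operating point;
* age-of-onset analyses among cases: Kaplan-Meier curves, log-rank tests,
  Cox proportional-hazards models, onset ANOVA across risk groups;
* a calibrated synthetic cohort generator (retrospective case-control
  genotype sampling, proportional-hazards onset, family-history and
  drinking structure) so the whole pipeline is testable end to end
  without access to individual-level study data.

It is aimed at statistical geneticists and epidemiologists who want a
tested, scriptable reference implementation of this analysis for their
own panels, and at methodologists who want its pieces (exact HWE test,
DeLong comparison, retrospective genotype simulator) as building blocks.

Functions are tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` on fitted objects, `autoplot()` on every result type.

## Worked example

Simulate a cohort with the package's study-like defaults (14 SNPs, one
OR ≈ 8 HLA-like locus, drinking exposure, PRS-linked family history and
onset), score it, and walk the main analyses:

```r
library(prspipe)

panel  <- synthetic_panel()                       # 14-variant stand-in panel
cfg    <- sim_config(n_cases = 1200, n_controls = 1200, seed = 42)
cohort <- simulate_cohort(cfg)

prs    <- compute_prs(cohort, panel, model = "SNP_HLA",
                      missing_policy = "expected_dosage")
groups <- quartile_groups(prs)
group_or_table(groups, phenotypes(cohort))
#> # A tibble: 4 × 9
#>   group prs_range n_case n_control    or ci_lo ci_hi         p undefined
#>   <int> <chr>      <int>     <int> <dbl> <dbl> <dbl>     <dbl> <lgl>
#> 1     0 <= 1.65       31       300  1    NA    NA    NA        FALSE
#> 2     1 1.65-2.18     51       300  1.65  1.03  2.66  3.92e- 2 FALSE
#> 3     2 2.18-3.32    139       300  4.43  2.90  6.77  6.14e-12 FALSE
#> 4     3 > 3.32       979       300 33.4  22.5  49.6   1.37e-67 FALSE
```

Subjects in the top control-quartile of the score carry ~33-fold the odds
of disease of the bottom quartile (age/sex-adjusted), and 979 of 1200
cases sit in that top group — the single HLA-like locus dominates.

```r
r <- roc_auc(prs)
r
#> <ps_roc> AUC = 0.8633 (DeLong 95% CI 0.8488-0.8778) on 1200 cases / 1200 controls
sens_spec_at(r)
#> # A tibble: 1 × 4
#>   threshold sensitivity specificity youden
#>       <dbl>       <dbl>       <dbl>  <dbl>
#> 1      3.66       0.765       0.815   0.58
```

The full genetic model discriminates cases from controls with AUC ≈ 0.86;
at the Youden threshold it operates at ~77% sensitivity / ~82%
specificity.

```r
glance(continuous_prs_effect(prs, phenotypes(cohort)))
#> # A tibble: 1 × 6
#>   logLik null_logLik r2_nagelkerke    df     n converged
#>    <dbl>       <dbl>         <dbl> <int> <int> <lgl>
#> 1 -1071.      -1664.         0.520     4  2400 TRUE

od <- onset_data(cohort, groups)
od$prs <- prs$score[match(od$sample_id, prs$sample_id)]
tidy(cox_fit(od, ~ prs + sex))
#> # A tibble: 2 × 6
#>   term  estimate hazard_ratio std.error statistic  p.value
#>   <chr>    <dbl>        <dbl>     <dbl>     <dbl>    <dbl>
#> 1 prs    0.0666         1.07     0.0180     3.71  0.000208
#> 2 sex   -0.00985        0.990    0.0585    -0.168 0.866
```

Each unit of PRS raises the onset hazard by ~7% (true simulated value:
8%), i.e. high-score cases develop disease earlier. `run_full_analysis()`
chains every stage (QC → association → 4 score models → risk groups →
ROC/DeLong → onset) into one structured, JSON-serialisable report, and
`autoplot()` draws ROC curves, PRS densities, group-OR forests and
cumulative-onset curves.

## Package layout

| Where | What |
|---|---|
| `R/weights.R`, `R/cohort.R` | weight panels, PLINK text / TSV readers and writers, the cohort container |
| `R/simulate.R` | the synthetic cohort generator |
| `R/qc.R` | call-rate / HWE QC, allelic chi-square, power |
| `R/prs.R`, `R/logistic.R` | scoring, quartile groups, logistic risk models |
| `R/roc.R` | ROC/AUC, DeLong comparison, operating points |
| `R/onset.R` | Kaplan-Meier, log-rank, Cox, onset ANOVA |
| `R/pipeline.R` | `run_full_analysis()`, cohort summaries, JSON reports |
| `vignettes/prs-pipeline.Rmd` | the methods vignette: model, generator design, numerical choices |
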