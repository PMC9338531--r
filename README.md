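# concordmap

Analysis toolkit for matched proteome/transcriptome cohorts of ocular
adnexal B-cell lymphoma (OABL) and similar three-arm designs
(normal / inflammation / tumor). The clinical problem it serves is the
differential diagnosis and risk stratification of orbital lymphoma against
inflammatory mimics, using bulk proteomics and RNA-seq from the same
patients.

The package implements four connected analyses:

1. **Global protein–mRNA concordance.** For each sample, the Spearman
   correlation ρ between its protein and mRNA abundances over the matched
   pair set. Concordance is compared between groups (Mann–Whitney),
   correlated with clinical covariates and proliferation (Pearson), and
   tested against survival endpoints (median-split Kaplan–Meier + log-rank,
   and univariate Cox on continuous ρ). Tumor and control pair universes
   are built separately.
2. **Inflammation-independence trend signature.** Each protein's trajectory
   across normal → inflammation → tumor is classified into one of nine
   patterns by pairwise Welch tests (step gates: p < 0.05 and
   |log2 Δ| > log2(1.2)); in parallel, top-50%-MAD proteins are k-means
   clustered (k = 4) on z-scored profiles. Merging both yields five classes
   — MIMIC-UP, VAGUE-UP, SPECIFIC-UP, MIMIC-DOWN, SPECIFIC-DOWN — that
   separate tumor-specific from inflammation-mimicking dysregulation.
3. **Aberrant alternative-splicing landscape.** From per-sample inclusion
   levels (rMATS JC-format tables for A3/A5/MX/RI/SE), events with
   |ΔIncLevel| > 0.05 and BH-adjusted p < 0.01 are called aberrant;
   passing events are screened for progression association by univariate
   Cox, and candidate splicing regulators are ranked by the count of strong
   correlations (|r| > 0.6) between their protein abundance and event
   inclusion.
4. **Diagnostic biomarker funnel.** Differential proteins ∩ univariate
   logistic hits → repeated cross-validated lasso (selection frequency
   ≥ 0.5 over 200 iterations) → multiplicity-aware backward stepwise
   logistic refinement → final markers benchmarked by rank-based ROC AUC
   against reference markers.

A synthetic-cohort generator (`synth_config()` / `simulate_cohort()`)
produces cohorts with planted ground truth — per-sample-controllable
concordance via a Gaussian copula (ρ_S = 6/π·arcsin(r/2)), nine-pattern
trend genes, logit-scale splice events coupled to a driver regulator,
concordance- and inclusion-coupled survival, and one planted diagnostic
marker — so every stage is testable end to end.

## Worked example

```r
library(concordmap)

cfg <- synth_config(seed = 1)          # 3 arms x 20 samples, 3000 gene pairs
sim <- simulate_cohort(cfg)

prof <- compute_concordance(sim$cohort)
print(prof)
#> concordance_profile: 60 samples
#>   median rho [inflammation] = 0.238
#>   median rho [normal] = 0.139
#>   median rho [tumor] = 0.382
#>   pair universes: tumor 2871, control 2949

compare_groups(prof, prof$group == "tumor")
#> Mann-Whitney U: statistic = 780, estimate = 0.1923, p = 2.665e-09 (n = 60)

cs <- concordance_survival(prof, sim$cohort$meta, "DRFS")
print(cs$logrank)
#> log-rank: statistic = 16.5, estimate = NA, p = 4.862e-05 (n = 20)
```

The tumor arm's median concordance (0.38) sits well above the controls
(normal 0.14, inflammation 0.24), the Mann–Whitney test confirms the group
difference, and — because this cohort plants a distant-recurrence hazard of
2 per standard deviation of concordance — the median-split log-rank test
detects worse outcome in the high-concordance half. Ground truth for every
planted structure is in `sim$truth`.

Downstream stages follow the same pattern: `run_de()` +
`classify_concordance()` for cross-layer DE classes, `call_trend_patterns()`
+ `cluster_hvgs()` + `build_signature()` for the five-class signature,
`call_aase()` + `progression_aase()` + `sf_correlation_ranking()` for the
splicing landscape, and `run_funnel()` for the biomarker funnel. File-based
workflows go through `write_cohort()`, `read_omics_matrix()`,
`read_rmats_table()`, `read_gmt()` and `read_sf_list()`.

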