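---
title: "Methods: proteotranscriptomic concordance, splicing landscape and biomarker screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proteotranscriptomic concordance, splicing landscape and biomarker screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concordmap)
```

`concordmap` analyses matched proteome/transcriptome cohorts with a
three-arm design — normal tissue, inflammatory lesions (idiopathic orbital
inflammation and reactive lymphoid hyperplasia), and B-cell lymphoma — the
setting where distinguishing tumor-specific dysregulation from
inflammation-mimicking dysregulation is the central analytical problem.
This vignette explains each stage's model, its tunable parameters, the
numerical choices, and what the synthetic-data tests do and do not show.

## Per-sample protein–mRNA concordance

For sample $j$ with matched abundances $(p_{gj}, m_{gj})$ over the shared
gene set, the global concordance is the Spearman correlation
$\rho_j = \mathrm{cor}_S(p_{\cdot j}, m_{\cdot j})$. Because Spearman
correlation depends only on within-sample ranks, $\rho_j$ is invariant to
any per-sample monotone transform of either layer — the property that makes
it comparable across samples with different dynamic ranges, and the reason
per-sample gene-set scores used downstream must themselves be rank-based.

Design choices:

* **Scope-specific pair universes.** Tumor and control samples have
  different detection patterns, so the matched pair set is built separately
  within each scope: a gene enters a scope's universe when its protein value
  is observed in at least `min_obs_frac` (default 0.8) of that scope's
  samples. The two universes therefore differ in size.
* **Minimum pairs per sample** defaults to 100; below that a sample's rank
  correlation is too unstable to report and the sample is excluded with a
  warning.
* **Median split.** Tumor samples are split at the median $\rho$;
  ties at the median go to the low group (deterministic and documented
  rather than arbitrary).
* Group comparisons of $\rho$ use the Mann–Whitney U test (correlations are
  bounded, non-Gaussian quantities); correlations of $\rho$ with continuous
  covariates (proliferation marker abundance, gene-set scores) use Pearson's
  r within one group at a time. Survival association is reported both ways:
  median-split Kaplan–Meier with a log-rank test, and univariate Cox on
  continuous $\rho$.

## Differential expression and cross-layer classes

Both layers are analysed on the log2 scale (proteins: log2 abundance;
transcripts: log2(FPKM + 1)) after per-sample median centering. Per-gene
tests use limma's empirical-Bayes moderated t by default (variance
shrinkage matters at cohort sizes of tens of samples); a plain Welch t is
available by flag. Calls combine a raw-p gate (p < 0.05) with layer-specific
fold-change gates: |log2 FC| > log2(1.5) for transcripts and > log2(1.2)
for proteins — the proteome gate is smaller because isobaric-label
quantification compresses ratios. BH q-values are reported alongside but do
not drive the status call. Cross-layer classes are CO-UP / CO-DOWN
(significant in the same direction in both layers), DISCORDANT (significant
in opposite directions), NONE otherwise.

## The nine-pattern trend signature

Each protein's trajectory across normal → inflammation → tumor is reduced
to two steps. A step is `up`/`down` when its Welch test has p < 0.05 *and*
|log2 delta| > log2(1.2) (the proteome effect gate, reused for coherence
with the DE stage), else `flat`; the 3 × 3 step pairs give nine patterns.
In parallel, highly variable proteins (top 50% MAD by default) are z-scored
and clustered with k-means (k = 4, elbow curve exported for k = 2..10);
each cluster's trajectory is summarised by per-group means of per-sample
median z-scores with segmented-regression slopes between adjacent groups,
and the cluster is up/down-trending when |tumor − normal| exceeds 0.1 z.

The five-class signature merges the two views; a class is only assigned
when the gene's pattern and its cluster trend agree in direction:

| pattern | overall N→T call | cluster | class |
|---|---|---|---|
| (up, flat) | up | up | MIMIC-UP |
| (flat, up) | — | up | SPECIFIC-UP |
| (up, up) or (flat, flat) | up | up | VAGUE-UP |
| (down, flat) | down | down | MIMIC-DOWN |
| (flat, down) | — | down | SPECIFIC-DOWN |
| anything else (e.g. opposing steps) | | | NONE |

The vocabulary is deliberately asymmetric — there is no VAGUE-DOWN class —
so negating the data maps MIMIC/SPECIFIC classes to their mirror and sends
VAGUE-UP genes to NONE. MIMIC classes describe genes whose tumor state
cannot be discriminated from inflammation (the second step is flat);
SPECIFIC classes move only at the inflammation → tumor transition.

## Aberrant splicing events and regulator ranking

Inclusion levels (PSI) in [0, 1] per event and sample are compared between
tumor and pooled controls with a two-sided Mann–Whitney test (the package
works from inclusion levels, not read counts; when ingesting genuine rMATS
output its likelihood-test PValue/FDR columns can be reused via
`use_table_stats`). BH adjustment is applied once across all tested events
of all five types jointly, so q-values are comparable across types. An
event is an aberrant alternative-splicing event (AASE) when
|ΔIncLevel| > 0.05 *and* adjusted p < 0.01. Events with fewer than three
observed inclusion values in either group are skipped with a recorded
reason. Progression screening fits a univariate Cox model (Efron ties) per
passing event over tumor samples; raw p < 0.05 flags an event
progression-related, with BH-adjusted gating available by flag.

Splicing-factor ranking correlates each factor's protein abundance with
each passing event's inclusion across tumor samples (Pearson); a factor's
rank is its count of strong correlations (|r| > 0.6), mean |r| breaking
ties. Rankings are computed over all AASEs and over progression-related
AASEs; the "recurrent" set is the intersection of the two top-20 lists.

## Gene-set machinery

* **ORA** is the upper-tail hypergeometric test with BH across sets.
* **Preranked enrichment** uses the weighted Kolmogorov–Smirnov running sum
  (weight exponent 1); significance and NES come from gene-label
  permutation, with sign-matched normalization. FDR across a collection is
  BH over the permutation p-values — inputs here are ranked lists, so gene
  permutation (not phenotype permutation) is the appropriate null.
* **Per-sample scores** use the ssGSEA formulation (rank-weighted ECDF
  difference, exponent α = 0.25), rescaled per set across samples to
  [−1, 1]. This replaces kernel-based GSVA deliberately: downstream the
  scores are only correlated and ranked, which is stable under rank-based
  scoring, and rank-based scores inherit the monotone-transform invariance
  that licenses correlating them with $\rho$.

## The diagnostic biomarker funnel

Stage 1 runs proteome DE and a univariate logistic screen (Wald p < 0.05);
stage 2 intersects them; stage 3 repeats the 10-fold cross-validated lasso
(`lambda.1se`) `n_iterations` times with fresh fold splits and keeps
proteins selected in ≥ 50% of iterations; stage 4 refines by backward
stepwise logistic regression and the final set is benchmarked by rank-based
AUC against user-named reference markers.

Two properties of this funnel deserve emphasis:

* Because every iteration of the lasso refits the *same* samples (only the
  fold assignment changes), selection frequencies are close to 0/1 rather
  than graded: they measure stability to fold choice, not to sampling.
* A chance association that survives two marginal screens and the lasso is,
  *within the realized sample*, statistically indistinguishable from a true
  marker — no within-sample information criterion can remove it. AIC-based
  refinement therefore retains essentially every screen survivor. The
  default refinement instead applies a Bonferroni gate at level
  α / m, where m is the size of the originally screened protein universe,
  to each candidate's marginal likelihood-ratio p, then backward-eliminates
  among survivors with conditional LRTs at the same gate. This controls the
  family-wise probability that any screened null protein reaches the final
  set at α (default 0.05). Likelihood-ratio rather than Wald tests are used
  throughout because strong markers sit near separation, where Wald
  statistics collapse (the Hauck–Donner effect). Conditional tests are not
  used for the initial gate: a joint logistic model of a dozen co-selected
  candidates on a few dozen samples is anti-conservative. The
  spec-literal AIC behaviour remains available via `criterion = "aic"`.

## The synthetic cohort generator

The generator emulates the statistical structure every stage assumes, with
planted ground truth for recovery testing. It does **not** emulate reads or
spectra, batch effects, correlated gene modules, missing-not-at-random
dropout, or paired designs — so passing tests demonstrate that the
pipeline recovers the structures it models, not that it is robust to every
artefact of real data. In particular, real proteomes are strongly
co-expressed; the generator's independent noise makes some tasks (e.g.
unique-marker recovery) *harder* than in correlated data and others (e.g.
clustering) easier.

Key mechanisms and calibrations (defaults chosen once, from the field's
typical scales and from pre-implementation power analyses):

* **Rank coupling.** Per sample, the protein layer is generated from the
  gaussianized ranks of the mRNA column through a Gaussian copula whose
  latent correlation solves the bivariate-normal Spearman identity
  $\rho_S = \tfrac{6}{\pi}\arcsin(r/2)$, giving analytic control of the
  realized per-sample Spearman. Group targets default to the subgroup
  medians of the motivating cohort (normal 0.16, IOI 0.23, RLH 0.254,
  tumor 0.364) with per-sample jitter sd 0.06.
* **Noise scales.** Protein log2 noise sd 0.45 (TMT-style ratio
  compression); mRNA log2 noise sd 1.0; mRNA baselines N(4, 1.5) on the
  log2(FPKM+1) scale, floored at 0 (genes near the floor show attenuated
  fold changes, which is why the low-abundance filter precedes DE).
* **Trend genes** shift group means by ±1 log2 per step in both layers
  (concordant dysregulation), for each of the nine patterns.
* **Splice events** are simulated on the logit scale (noise sd 0.3) and
  squashed to (0, 1), which respects PSI bounds while keeping effect
  planting linear; aberrant events shift the tumor mean by ±0.2 *on the PSI
  scale* (the logit shift is solved per event). A designated driver
  regulator's standardized protein abundance enters coupled events' logit
  noise at correlation 0.8, mirroring a splicing program under one factor's
  control.
* **Survival** is exponential (baseline median 5 time units) with
  independent exponential censoring whose rate is solved numerically so the
  expected censoring fraction equals `censor_rate`. The distant-recurrence
  endpoint's log-hazard is `hazard_rho` × the *standardized* planted
  concordance — per standard deviation rather than per unit, so the planted
  prognostic strength does not silently depend on the concordance noise
  scale. Progression hazard is carried by planted events' inclusion levels
  (default 10 per PSI unit, i.e. HR ≈ e per 0.1 inclusion change, the
  order of magnitude reported for prognostic splice events); hazard events
  are chosen among events with mid-range baseline inclusion, because an
  event pinned near PSI 0 or 1 has no inclusion variance and cannot carry
  an identifiable per-sample hazard.
* **The diagnostic marker** is one protein shifted +1.5 log2 in tumors.
  Two reference markers are planted at +0.75 log2 with doubled noise,
  emulating membrane B-cell markers that stain inflammation too (AUC ≈
  0.7–0.85 rather than ≈ 0.97); marker-recovery studies switch them off so
  exactly one protein carries a diagnostic effect.
* **Missingness** is MCAR on the protein layer only (default 10%); the
  proliferation-proxy abundance lives in the metadata rather than the
  matrix so the rank coupling stays exact.

## Numerical choices and degenerate inputs

Exact small-sample rules make desk-scale results deterministic: exact
Spearman p for n ≤ 9 without ties, exact Mann–Whitney for min(n) ≤ 8
without ties (normal approximation with tie correction otherwise, p = 1
when everything ties), Welch t degenerating to p = 1 on constant equal
groups. Constant covariates are rejected by the Cox stage; monotone
likelihood is flagged. KNN imputation (k = 10) measures sample distance by
mean squared difference over jointly observed features and is idempotent;
features missing in > 20% of samples are dropped first. k-means is Lloyd's
algorithm, best of 10 seeded restarts. All stochastic routines take
explicit seeds, and rerunning any stage with the same configuration and
seed produces byte-identical output tables.

## Problem sizes used by the shipped studies

The test suite and `scripts/acceptance.R` run scaled-down cohorts chosen to
keep each study's Monte-Carlo error well inside its decision margin:
3000 protein–mRNA pairs × 20 samples/arm for concordance recovery (100
seeds); 400-gene cohorts at 30 tumors for survival coupling (100 power +
400 null seeds); 1000 genes × 10 samples/arm over 50 seeds for the trend
signature (planted genes ≈ 11% of the proteome, near the motivating
cohort's proportion); 750 events × 15/arm over 50 seeds for splicing
calls; 200 replicates × 10 planted hazard events at 40 tumors for Cox
recovery, simulated with inclusion noise sd 0.5 so that per-event Fisher
information, not the replicate budget, limits precision; and 20 funnel
runs at 1000 proteins × 30/arm with the full 200-iteration lasso.

## Known limitations

* The nine-pattern taxonomy and the five-class merge rule are this
  package's formalisation; the merge in particular is one of several
  defensible readings of an alluvial-style combination of clustering and
  pairwise testing.
* Event calling from inclusion levels ignores read-depth information; with
  real rMATS output, prefer `use_table_stats = TRUE`.
* The funnel's selection frequencies quantify fold-choice stability only;
  for sampling-stability estimates one would need subsampled refits.
* Survival modelling is exponential/proportional-hazards throughout; no
  competing risks, no time-varying effects.
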