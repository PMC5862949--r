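---
title: "Methods: set-activity Z-scores, signatures, and compound covariate classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: set-activity Z-scores, signatures, and compound covariate classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pagesig)
```

# The inference chain

`pagesig` implements a transcriptomic inference chain used to
characterize a regulator of the miRNA pathway — such as nc886, a Pol
III non-coding RNA induced by TGF-β in ovarian cancer — and to carry
the resulting expression signature into patient stratification:

1. **Differential expression.** Per-gene two-sample contrasts between
   conditions (e.g. TGF-β-treated vs control, nc886-expressing vs
   vector, nc886-knockdown vs control) on log2 intensities.
2. **Gene-set activity.** A parametric Z-score per gene set over
   MSigDB-style collections: miRNA-target sets (MIR), transcription
   factor target sets (TFT), pathway sets.
3. **Signature derivation.** Genes recurrently fold-changed in the
   nc886-high direction across experiments, plus unsupervised
   hierarchical clustering of divergent genes.
4. **Classification.** A Bayesian compound covariate predictor (BCCP)
   trained on the labelled experiments, cross-validated by
   leave-one-out, then applied to a patient cohort with tri-state
   (high / low / undetermined) calls.
5. **Clinical evaluation.** Kaplan–Meier curves, the log-rank test, a
   chi-square test of chemo response against the predicted subtype,
   and ROC/AUC for resistance prediction from the posterior.

Every stage is paired with a seeded synthetic generator so recovery of
planted structure can be scored against ground truth.

# Differential expression

The contrast statistic is the classical pooled-variance two-sample
Student *t* on log2 values, with `n1 + n2 - 2` degrees of freedom and a
two-sided p-value; the fold change is `mean(treatment) -
mean(reference)` in log2 units. The pooled-variance flavour was chosen
over moderated or random-variance alternatives because the analysis
this package reproduces describes plain Student's t-tests on
triplicates; Welch is available via `var_equal = FALSE`. No
multiple-testing correction is applied by default — selection uses raw
`p < 0.05` combined with a fold-change cutoff (`|log2 fc| >= 0.5`),
which is the filtering rule of the original analysis style.

Degenerate genes (zero pooled variance with unequal means, possible on
quantized data) are flagged and excluded from selection rather than
given infinite scores silently. Identical groups yield `t = 0, p = 1`.

Cross-contrast agreement is summarized by the Pearson correlation of
fold changes over genes with `p < 0.05` in *both* contrasts (no
fold-change cutoff), with significance from the F statistic of the
simple linear regression — identical to the two-sided correlation test.

# The set-activity Z-score

For a set with `m` members matched in the contrast (case-insensitive
symbol match), the activity score is

$$ z = \frac{(S_m - \mu)\sqrt{m}}{\sigma}, $$

where `S_m` is the mean fold change of the members, and `mu` and
`sigma` are the mean and standard deviation of all fold changes in the
contrast. This is the PAGE-style parametric statistic: under a null
contrast, the mean of `m` randomly chosen fold changes is approximately
normal with sd `sigma / sqrt(m)`, so `z` is approximately standard
normal — a property the test suite verifies by Monte Carlo (2,000
random 50-gene sets: sd within [0.95, 1.05]). The formula is isolated
behind `set_zscore()` so an alternative statistic (e.g. a mean
t-score) could be swapped without touching the profiling surface.

Interpretation contract for MIR collections: a positive `z` means the
miRNA's target genes are collectively elevated, i.e. the activity of
the corresponding miRNA is *low*. For a knockdown contrast the
orientation is reversed, which is why `rank_mirs()` takes an explicit
`orientations` vector (+1/-1 per profile) instead of hard-coding a
convention: the oriented score of a set is the sum of
`orientation_k * z_k` across experiments.

Choices worth noting:

* `min_set_size = 5` (default): the `sqrt(m)` scaling is unstable for
  tiny matched sets; skipped sets are reported.
* Sets with `z` exactly 0 are counted as neither depleted nor enriched
  in `rank_distribution()`; they are reported as `n_zero` rather than
  silently assigned to a side.
* Ties in sorting and ranking are broken by set name, making every
  ordering deterministic.

# Signature and clustering rules

Fold thresholds quoted as ratios (1.5 for divergence, 1.3 for the
signature) are applied on the log2 scale as `|log2 deviation| >=
log2(threshold)`, and all comparisons are inclusive; fixing
inclusivity one way avoids silent off-by-one-gene drift between runs.
The signature rule requires the oriented fold change to pass in at
least `min_experiments = 3` contrasts *with a consistent direction*
(switchable), reflecting the coherent up/down blocks such signatures
show in heat maps. The knockdown contrast is negated (orientation -1)
before the rule so all contrasts point toward the nc886-high state.

Clustering is the classic two-way agglomeration used by Cluster/
TreeView-style analyses: per-gene median centering, distance `1 -
Pearson correlation`, average linkage, genes and samples clustered
independently; the two-group sample partition cuts the sample
dendrogram at its last merge. The implementation delegates the
agglomeration to `stats::hclust` and is verified against a brute-force
O(n^3) oracle on small instances.

Candidate miRNA-target genes are those significantly *decreased* under
knockdown but *increased* under induction (the direction expected of
genes relieved from miRNA repression), intersected with the union of
the selected MIR sets' members. No fold-change magnitude cutoff is
applied beyond sign and `p < 0.05`, since none is part of the
described rule.

# The Bayesian compound covariate predictor

Training standardizes each signature gene across training samples,
weights it by its two-class pooled t statistic `t_i`, and forms the
per-sample compound covariate `c_j = sum_i t_i x_ij`. The two classes'
covariates are modelled as Gaussians with means `m_high`, `m_low` and a
single pooled within-class variance `s^2`; the posterior for a new
covariate follows from Bayes' rule and reduces to a logistic in `c`.
Three decisions the original description leaves open are made explicit
and configurable:

* **Priors** default to 0.5/0.5 rather than training proportions: the
  training set is a designed experiment panel, not a population
  sample.
* **Standardization of new cohorts** uses the cohort's own per-gene
  mean/sd ("internal"), the minimal calibration when training and test
  data come from different array platforms; within-platform use (e.g.
  LOOCV folds) reuses the training constants.
* **Variance** is pooled across classes; per-class variances are a
  straightforward extension but not the default.

LOOCV re-derives *everything* — weights, standardization, class
densities — inside each fold, the honest protocol for compound
covariate predictors; a fold that would lose a whole class is skipped
and reported. Cohort calls are tri-state: posterior above 0.7 is
high, below 0.3 low, otherwise undetermined; undetermined patients are
excluded from the contingency analysis, mirroring how such patients
are handled in clinical application of the classifier.

# Clinical evaluation

Kaplan–Meier estimation and the log-rank test delegate to the
`survival` package (`survfit`, `survdiff`) behind a plain-table
surface; events precede censorings at tied times, the standard
convention. The chi-square test is Pearson's without continuity
correction by default (`correct = TRUE` available); per-row
proportions are reported so statements like "15 of 18 resistant
patients were high" are reproducible from the table. The AUC is the
rank-based (Mann–Whitney) concordance with ties counted one half, and
its confidence interval is a percentile bootstrap over class-stratified
resamples (default 2,000), fully seeded. ROC scores are the BCCP
posterior oriented so that higher predicts resistance.

# What the synthetic generator emulates — and what it does not

`generate_experiment()` draws per-gene baselines from N(8, 2) on the
log2 scale (a typical array intensity range), adds a constant log2
shift `delta` to the member genes of planted sets in chosen conditions,
and homoscedastic N(0, noise_sd) noise per sample, with triplicates by
default. This makes the t-test's assumptions *exactly* satisfiable, so
calibration tests have sharp expectations. Defaults mirror the study
conditions the package is tested under: noise sd 0.5, planted shifts
0.5 on 50-gene sets, collections of ~200 sets over a 10,000-gene
universe, seven-experiment-style panels reduced to four two-condition
experiments (three toward nc886-high, one knockdown).

`generate_cohort()` draws a latent nc886-high subtype per patient
(Bernoulli, prevalence 0.5 by default over n = 285), shifts signature
genes by `delta_sig` (optionally signed per gene) in high patients,
and generates exponential survival with hazard `baseline_hazard *
hazard_ratio^{subtype}` (defaults 0.015/month and 3), independent
exponential censoring tuned to a 30% rate, and subtype-dependent
chemo-resistance probabilities (0.15 vs 0.02). Truth records retain
every latent label and planted gene, sufficient to score recovery.

Not emulated: probe-level artifacts, platform-specific intensity
distributions, batch effects, heteroscedastic (intensity-dependent)
noise, correlated genes within sets beyond the planted mean shift,
non-exponential hazards, and informative censoring. Passing the
recovery tests therefore shows the chain is correct under its own
assumptions, not that it is robust to every pathology of real arrays.

One structural point from the simulation design: when only 5 of 200
MIR sets are planted, the rank distribution of a single contrast is
close to balanced — randomly drawn sets contain planted genes at the
universe rate, so the unplanted sets' Z-scores centre near zero and
only the 5 planted sets tip the enriched/depleted balance. A heavily
one-sided rank distribution, as seen when a regulator suppresses the
majority of miRNAs at once, requires a majority of the collection to
be shifted; with 5 planted sets the enriched-majority event occurs in
roughly 60% of runs, which the acceptance checks report as measured.

# Problem sizes and numerical choices

The test suite runs at desk scale by design: null calibration uses
10,000 genes with 3-vs-3 replicates and 2,000 random sets;
planted-recovery checks use 100 seeded panels of four experiments
(200 sets x 50 genes over 10,000 genes); BCCP recovery uses 100
12-sample LOOCV runs and one n = 285 cohort; the clinical analogue
uses 100 cohorts for power/AUC and 500 for null calibration of the
log-rank test. All randomness flows from per-call seeds; generators
save and restore the caller's RNG state. Posterior computations are
done in log space; correlations of constant vectors, zero-variance
genes, empty collections, and zero-margin tables are rejected or
dropped with explicit messages rather than propagating NaN.

# Running the pipeline

```r
cfg <- default_config()   # every threshold is a key with its default
files <- run_pipeline(cfg, outdir = tempfile("pagesig_"))
```

The pipeline writes per-stage CSV/JSON artifacts plus a log of every
threshold and filter count, and identical configs (including the seed)
produce byte-identical outputs. See the README for a worked example
with the numbers it prints.

# Known limitations

* Symbol-level, case-insensitive matching is the only probe-to-gene
  mapping; platform annotation reconciliation is out of scope.
* The pipeline's training pool centers each experiment at its per-gene
  median before fitting the classifier; this removes experiment-level
  baselines but assumes roughly balanced designs within experiments.
* The chi-square test is asymptotic; for tables with small expected
  counts an exact test would be preferable (the zero-margin error
  message says as much).
* Reproducing the exact published gene counts or the 118-gene
  membership of any specific study requires the original deposited
  arrays and MSigDB release, which are deliberately not bundled;
  collections and cohorts are user-supplied or simulated.
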