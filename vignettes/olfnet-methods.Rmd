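---
title: "olfnet: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{olfnet: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`olfnet` links four data domains measured on humanized APOE mouse cohorts:
odor-guided behavior, diffusion-MRI structural connectomes, categorical AD
risk traits (APOE genotype, diet, sex, age group, NOS2 background), and
blood/brain transcriptomes. This vignette explains each model, the
parameters that matter, the synthetic-data generator behind the test
suite, and the choices made where the methodology was genuinely open.

## Behavioral indices

Investigation time is the seconds a mouse's nose spends within reach of an
odorized object. From the novel-odor time `No` and familiar-odor time `Fo`
we compute the recognition index `RI = No/(No+Fo)` (0.5 = chance, above
0.5 = memory of the familiar odor) and the dishabituation index
`DI = (No−Fo)/(No+Fo)`; the two are linked by `RI = (DI+1)/2` and the
package asserts this identity to machine precision. `DI` uses the trial-5
novel time against the trial-4 familiar time of the odor-switched object.
A pair with `No + Fo = 0` is an error, never silently 0: imputing 0 (or
0.5) would bias group means toward whichever convention was chosen.

The anhedonia index `(tracked − odor time)/tracked` is the fraction of
tracked time spent not engaging odorized objects; immobility is retained
because freezing itself can reflect reduced hedonic drive. Exploration AUC
integrates the response over the odor concentration series
(0, 0.001, 0.01, 0.1 v/v) by the trapezoid rule. Because the series starts
at a true zero concentration, a logarithmic abscissa is undefined; the
default abscissa is therefore the equally spaced concentration rank
(1..4), with the raw-value axis available via `abscissa = "value"`.

## Factorial effect sizes

`factorial_anova()` fits ordinary least squares with sum-to-zero contrasts
for every factor, so Type III sums of squares are well defined, and
reports per term the F statistic, partial `eta² = SS_eff/(SS_eff+SS_err)`
and Cohen's `f = sqrt(eta²/(1−eta²))`. Repeated measures (trials,
concentrations) are aggregated to one value per subject before fitting:
under balanced designs this preserves the fixed-effect estimates of the
corresponding random-intercept model while keeping the package free of a
mixed-model solver; the subject-level residual then absorbs the
between-animal variance. Effect-size confidence intervals use a
nonparametric bootstrap (default 1000 resamples) rather than noncentral-F
inversion — simpler, and consistent with the resampling used elsewhere in
the pipeline. Estimated marginal means average predicted cell means with
equal weights over non-focal factors (via emmeans); post hoc contrasts are
Tukey-adjusted for all-pairwise comparisons and Šidák-adjusted for planned
pairs. A degenerate all-equal outcome returns `F = 0` for every term, and
a rank-deficient design errors with the aliased terms named.

## Elastic Net edge selection

Connectomes are symmetric streamline-count matrices over a shared region
parcellation (332 labels by default). `vectorize_connectomes()` takes the
upper-triangle edges in row-major `(i, j), i < j` order, applies
`log(1+count)` to tame the heavy count tail, z-scores each edge, and drops
zero-variance edges with a report. The selection stage minimizes

```
(1/2n) ||Y − Xβ||² + λ (α ||β||₁ + (1−α)/2 ||β||²)
```

with `α = 0.5` and λ chosen by 10-fold cross-validated MSE, separately per
behavioral outcome; the selected edge set is the union of nonzero
coefficients across outcomes. The cross-validated path is fit with glmnet;
`elastic_net_coef()` additionally provides a plain cyclic coordinate
descent on exactly the loss above (no internal response rescaling), which
is what the oracle tests compare against dense grid search. Fold
assignment is seeded and returned, so selections are reproducible.

## SUMCOR MCCA

Given standardized domain matrices `X(k)` the model maximizes
`Σ_{i<j} corr(X(i)w(i), X(j)w(j))` subject to each canonical variate
having unit sample variance. This is the SUMCOR criterion, estimated by
Horst alternating updates: each `w(k)` is refit against the sum of the
other variates, then renormalized under its within-domain covariance.
Numerical choices:

- **Initialization** is deterministic — the leading right singular vector
  of each domain — so repeated runs are bit-identical.
- **Constraint solve**: the within-domain covariance gets a relative ridge
  (`1e-8` times its mean diagonal) purely for invertibility when features
  outnumber subjects; set `ridge = 0` for exact classical behavior on
  full-rank domains.
- **Convergence** at a summed-correlation change below `1e-8`, capped at
  500 iterations; non-convergence sets a flag instead of raising, since a
  near-stationary solution is still interpretable. The objective is
  asserted non-decreasing at every iteration.
- **Sign convention**: the global sign is flipped so the largest-magnitude
  weight of the first domain is positive; a global flip leaves every
  pairwise correlation unchanged.
- With two domains the fixed point coincides with the first classical CCA
  pair, which the tests verify against an eigen-solver oracle.

Only the first canonical dimension is estimated: the integration reports a
single weight per connection and a single summed correlation, and
deflation to further components is out of scope.

**Inference.** The bootstrap resamples subjects with replacement jointly
across domains and refits MCCA on the fixed selected-feature set (refitting
the selection per resample would change the hypothesis being interval-ed
and multiply the cost); the 95% CI is the percentile interval. The
permutation test shuffles the behavior domain's rows — breaking all of its
pairwise couplings symmetrically — with
`p = (1 + #{perm ≥ observed})/(P + 1)`. Note that refitted bootstrap
sumcors are optimistic when the subject count is small relative to the
selected edge count, so at toy sizes the interval can sit above the
observed value; the permutation test is the calibrated null reference.

**Back-projection.** Connectome-domain weights map back to region pairs.
Edges with `|w|` below `1e-3` are treated as zeroed by MCCA, and the final
subnetwork keeps `|w| ≥ 0.05`; the three stage counts (selected by Elastic
Net, nonzero after MCCA, post-threshold) are recorded. How exactly an MCCA
stage should "reduce" a feature set is not prescribed by the estimator —
the weight vector is generically dense — so the magnitude cutoff used here
is an explicit, configurable rule, and thresholds are applied to the
weights on their canonical-constraint scale (optionally unit-L2 or max
normalized).

## Eigengenes and the coupling grid

Expression counts are normalized by counts-per-million, `log2(x+1)`, and
gene-wise centering — a deliberately plain dialect, configurable in
principle, recorded in the output metadata. Eigengenes are SVD principal
components of the normalized matrix: scores standardized to unit variance,
unit-norm gene loadings ranked by absolute value for top-200 extraction,
and the sign fixed so each component's largest-magnitude loading is
positive. Blood uses K = 10 components; brain regions use K = 4. One blood
PCA is shared across all regions of the coupling grid (scores are not
recomputed per region subset), which keeps "eigengene 2" a single object
across the analysis.

The coupling grid forms every (region, metric, eigengene) combination — 8
a priori olfactory-memory regions × 10 blood eigengenes × 7
diffusion/propagator metrics = 560 models. Within each region both sides
are z-scored, so the regression slope of eigengene on metric equals the
Pearson correlation and `R² = r²` holds identically. The eigengene is the
response and the metric the predictor; this is irrelevant to `r` but fixes
the reported β. BH-FDR is applied jointly across the whole grid (not per
metric), and cells with fewer than four overlapping subjects are emitted
with missing statistics and an `incomplete` flag rather than dropped.
Missing subjects are handled by inner join with a logged count, never
imputation.

## Brain–blood coupling and enrichment

For each tissue pair, all PC pairs up to `top_k = 4` are correlated with
both Pearson and Spearman tests. The two test families are BH-adjusted
separately by default (a `pool_fdr` flag merges them), and a pair is
significant when its smaller adjusted p is below 0.05 — the combination
rule is explicit and configurable since running both tests does not by
itself define one. For significant pairs, the two top-200-|loading| gene
lists are intersected; intersections under five genes are skipped.
Over-representation uses the upper-tail hypergeometric test against GMT
gene-set collections, BH-adjusted across sets; PC-pair tests and
enrichment tests always form disjoint BH families.

## The synthetic-cohort generator

The generator is first-class, tested code. Its defaults encode the study
conditions: a 465-subject behavioral cohort reproducing the published
allocation table exactly (with proportional multinomial allocation when no
preset is given), a 175-subject imaging subset and a 130-subject blood
subset, 12/18-month age groups, the 0/0.001/0.01/0.1 v/v concentration
series, habituation decay 0.8 per trial with a trial-5 novelty bump,
planted APOE4 × HFD × age shifts on the recognition index, one shared
standard-normal latent factor loading on designated connectome edges
(loading 0.45), behavioral engagement and the composite risk contrast, a
planted eigengene–imaging correlation of −0.5 on the
subicular–hippocampal diffusivity cells, and a blood↔brain module
correlation of 0.7. Where the source reports no within-group variances,
noise scales are free parameters chosen once at values that give the
planted effects realistic detectability (behavioral noise SD 1 s;
negative-binomial dispersion 0.3; log-normal library sizes with CV 20% so
normalization genuinely matters); acceptance is therefore recovery-based,
not value-matching.

Determinism: every table is a pure function of the spec and master seed,
with per-table child seeds derived by fixed offsets and recorded in the
fixture manifest. Per-subject latent and module scores are keyed by
subject index, so the nested imaging/blood/brain sub-cohorts see the same
scores as the full cohort.

Expression matrices use block modules: consecutive gene blocks load on
per-subject module scores, with geometrically decaying module strength
(ratio 0.88) so successive PCA eigenvalues stay separated and component
order tracks module order. Module genes are kept a small share of the
library and a block of stable high-expression housekeeping genes anchors
it; this matters because CPM is compositional — if planted modules carry
too much of the library, normalization induces spurious negative coupling
between unrelated modules.

What the generator does **not** emulate: tract geometry (edges are
exchangeable given the latent structure), spatial correlation among
imaging metrics, gene–gene correlation beyond block modules, batch
effects, and count zero-inflation. Passing recovery tests therefore shows
the estimators work under clean planted structure of realistic size, not
that they are robust to every artifact of real acquisitions.

## Problem sizes in the test suite

The suite favors small, well-powered configurations: recovery tests run at
n = 500 subjects (n = 130 for blood–brain coupling, matching that cohort's
size), oracle comparisons use 2-feature toys where dense grid search at
0.5° angular resolution is exact enough to be a reference, null
calibrations use 200 seeds for the permutation p and 60 replicates of the
560-cell grid for FDR behavior, and the end-to-end pipeline test runs 36
subjects over a 10-region parcellation. These sizes were chosen so each
property is tested at meaningful power while the whole suite stays quick
to iterate on.

## Known limitations

- Single canonical dimension; no deflation.
- No mixed-model solver: repeated measures are aggregated, which loses
  within-subject covariance structure under imbalance.
- The Elastic-Net CV path uses glmnet's internal convergence behavior;
  exact-loss coordinate descent is exposed separately for fixed λ.
- Enrichment is plain over-representation against user-supplied GMT sets;
  no annotation-database mapping, no semantic grouping of terms.
- Bootstrap CIs for sumcor inherit refitting optimism at small n/p (see
  above); the permutation p-value is the preferred evidence measure.
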