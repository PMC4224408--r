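---
title: "Immune-focused survival analysis of ovarian cancer transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immune-focused survival analysis of ovarian cancer transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunoreact)
library(dplyr)
```

## The scientific problem

Bulk expression profiles of advanced serous ovarian cancers carry residual
RNA from tumour-infiltrating lymphocytes. Even without deconvolution, a
small panel of genes that are *a priori* lymphocyte-specific — antigen
presentation machinery (MHC class I and II), the T-cell receptor complex
(CD3), co-receptors (CD4, CD8) and co-regulatory surface molecules — can
therefore report on the tumour immune microenvironment. `immunoreact`
implements a complete analysis pipeline built on that idea:

1. **Survival screen** — a univariate Cox proportional-hazards score test
   per immune gene, with expected-false-positive accounting and
   discovery-to-validation reproduction.
2. **Subgroup discovery** — complete-linkage hierarchical clustering of
   patients over the validated genes, yielding an immunoreactive (IR)
   subgroup with concerted high expression and favourable prognosis, plus
   three poor-prognosis strata; labels transfer to validation cohorts by
   centroid-seeded k-means.
3. **Differential markers** — a volcano-style Welch t-test contrast of
   literature immunology markers between the IR subgroup and the rest.
4. **Graphical models** — shrinkage partial-correlation graphs over
   immune metagenes, estimated separately in good- and poor-prognosis
   subgroups and compared edge by edge.
5. **Hidden-node search** — a three-condition conditional-independence
   scan for latent mediator genes that explain an unexpected edge.
6. **CT antigen classifier** — BIC-stepwise logistic regression
   predicting IR membership from cancer-testis antigen expression, with a
   sensitivity/specificity-intersection call threshold and a three-way
   antigen partition (non-IR, IR, immune-stimulatory).

A synthetic multi-study cohort generator with planted ground truth makes
every stage testable at desk scale.

## Data model and normalisation

Expression tables are tibbles with a `gene` column and one numeric column
per sample (`expr_table()`). Probes are collapsed to official symbols
before analysis; by default multi-probe genes are **averaged**
(`collapse_probes(method = "mean")`), with the highest-mean-probe rule
available as an alternative — array platforms do not dictate a choice, so
both are exposed.

All downstream stages work in *relative expression*: each gene row is
z-scored by `scale_center()`. Because cohorts mix array platforms, the
default workflow scales **within study** before pooling; hazard ratios
and mean differences are then per 1 sd of expression, comparable across
genes and platforms. Constant rows cannot be scaled and are set to zero
(not dropped) so panel indexing stays stable; they are reported through a
warning and the `zeroed_genes` attribute.

One cohort-hygiene step mirrors a known array-series problem: a series
may bank several arrays per patient. `merge_replicates()` averages
columns whose Pearson correlation reaches 0.95 (by default) — and, when a
patient-id table is supplied, only columns declaring the same patient —
using connected components so triplets collapse correctly.

`quantile_rank()` supports the specificity check that immune markers sit
in the unexpressed background of pure tumour cell lines: it ranks a
gene's mean expression among all gene means (midranks for ties).

## The survival screen

Each panel gene is fit alone in a Cox model with no covariates and no
time truncation; significance comes from the partial-likelihood **score
test**, which is exact at the null and cheap over many genes. Ties use
the Efron approximation. The default screen level is `alpha = 0.05`,
configurable: validated genes in this setting have score p-values up to
about 0.04, so a conventional 5% cut is the natural default. Multiplicity
is summarised the simple way: under the global null a 64-gene screen at
5% expects `64 * 0.05 = 3.2` false positives, and the plug-in FDR
estimate divides that by the observed hit count
(`expected_false_positives()`). A gene is *reproduced* when it is
significant in discovery and validation with a concordant hazard-ratio
direction (`validate_hits()`).

Kaplan–Meier medians (`km_median()`) use log-log confidence intervals;
an undefined median (curve never crossing one half) is reported as `NA`
with an open upper bound rather than an error.

## Subgroup discovery and transfer

`cluster_subgroups()` clusters samples by complete-linkage agglomeration
under Euclidean distance over the chosen gene set and cuts the tree at
`k = 4`. Four groups is a judgement call, not a theorem; the
within/between sum-of-squares ratio (`wb_ss_ratio()`) is the supporting
diagnostic and can be computed for any `k`. Groups are numbered by
decreasing centre mean and given display aliases: `purple` (uniform high
expression — the IR subgroup), `yellow`, `green` (synonym `aqua`) and
`orange` (uniform low). The alias order is a display convention keyed to
centre means, not a biological claim about the middle two strata.

`transfer_subgroups()` runs Lloyd k-means on a validation cohort seeded
at the discovery centres (at most 300 iterations, centre-movement
tolerance 1e-6). Because the initialisation is fixed, the procedure is
deterministic, and each converged cluster inherits the alias of the
centre that seeded it — subgroup identity is carried across cohorts by
construction, never re-derived. A cluster left empty keeps its seeding
centre and is reported with a warning.

Survival differences across subgroups use a **study-stratified log-rank
test** (`stratified_logrank()`): observed-minus-expected event counts are
summed within each study so that between-study baseline differences
cannot masquerade as subgroup effects.

`cross_tabulate()` tests subgroup association with clinical covariates:
chi-square for categorical covariates with a Fisher fallback when any
expected cell is below 5, one-way ANOVA for numeric ones. Because
external class labels are missing for some samples, per-cell shares are
reported against **both** denominators — the full subgroup size and the
classified-only count. Published summaries of this kind use each
denominator in different places, so the table keeps both explicit rather
than choosing silently.

## Differential markers

`marker_volcano()` applies a Welch (unequal-variance) two-sample t-test
per marker — the conservative default when subgroup sizes and variances
differ — with Bonferroni correction over the marker set. A marker is
highlighted when its Bonferroni p is below 0.001 **and** its mean
difference is at least 0.5 sd in magnitude. The 0.5 sd fold cut is a
package default standing in for "biologically extreme"; it is a flag, is
recorded in the result's metadata, and the x-axis is scaled mean
difference (inputs are z-scores, so raw fold changes are not available).

## Partial-correlation graphs

Per-gene graphs are unstable at subgroup sizes of a few dozen samples,
so nodes are **metagenes**: unweighted per-sample means of the z-scored
members of each immune class (`metagene_average()`). Individual genes
(e.g. the RFX transcription factors) can be added as extra nodes.

`shrinkage_partial_correlation()` shrinks the sample correlation matrix
toward the identity, `R* = (1 - λ) R + λ I`, and converts its inverse to
partial correlations. With `lambda = "auto"` the intensity is the
analytic variance-minimising value for correlation shrinkage toward the
identity — the ratio of the summed estimated variances of the
off-diagonal correlations to their summed squares, clipped to [0, 1].
Any `λ > 0` guarantees positive definiteness; at `λ = 0` a pseudo-inverse
is used so that exactly singular fixtures are still handled. λ is always
reported.

Edge selection (`edge_select()`) converts each partial correlation to a
p-value via the t-approximation with `n - 2 - (p - 2)` degrees of
freedom, applies Benjamini–Hochberg across all node pairs, and keeps an
edge only when `q < fdr_level` (default 0.05) **and**
`|pcor| >= hard_threshold` (default 0.1). We use the deterministic
t/BH route rather than an empirical-null mixture fit deliberately: with
of order ten metagene nodes there are too few null edges to fit a
mixture stably, and a closed-form rule is reproducible and directly
testable against oracles. Both selection knobs are mandatory metadata on
every graph. `compare_graphs()` partitions the union of selected edges
into shared / good-only / poor-only with signs (positive vs inhibitory).

## The hidden-node search

An edge A–B that contradicts biology (e.g. a CD8 metagene coupled to
MHC class II) may be induced by a latent mediator X. A candidate X must
satisfy three conditions:

1. A ⟂ B given X — the partial correlation of A and B given X is *not*
   significant (`p > alpha_ci`, default 0.05);
2. A ⟂̸ X given the declared conditioning set;
3. B ⟂̸ X given the same set — both dependence tests Bonferroni-corrected
   over the candidate pool.

Each statement reduces to a residual-regression (added-variable) t-test
(`partial_cor_test()`), with collinear conditioning columns dropped by
the QR rank decision rather than failing. "Given all other genes" is
read as conditioning on the **graph's node set**, not the transcriptome:
at subgroup sizes near 55 samples, conditioning on thousands of genes
would leave negative degrees of freedom, so the graph nodes are the only
feasible conditioning set, and the choice is recorded in the scan's
metadata. Passing candidates are ranked by
`rank_score = p_ci - max(p_ax, p_bx)` — an invented but monotone score
favouring strong induced independence together with strong dependence on
both endpoints; the full candidate table is always returned so the
ranking is auditable.

## The CT antigen classifier

`ir_antigen_screen()` is the marginal screen (Welch t, Bonferroni over
the antigen count). `stepwise_bic_logistic()` builds the multivariate
model: starting from the intercept-only model it applies, at each step,
the single addition or removal that most lowers BIC, stopping when no
move lowers it, with ties broken by antigen name order so the procedure
is deterministic; the accepted-move trace (strictly decreasing in BIC)
is kept on the fit. Separation is flagged, not fatal. `tidy()` and
`glance()` give the regression table and fit summary.

The call threshold is tuned at the **sensitivity/specificity
intersection**: the sweep runs over observed predicted values, picks the
threshold minimising |sens − spec|, and breaks ties toward the lower
threshold. Pooling predictions across validation studies is the default
(per-study tuning is possible by calling `tune_threshold()` per stratum).
`predict_ir_and_hr()` reports the Cox hazard ratio of predicted-non-IR
versus predicted-IR patients.

`antigen_prognostic_partition()` reconstructs the three-class antigen
map. Within the IR subgroup, patients are labelled good/poor prognosis
by overall survival dichotomised at 33.5 months (an overall-population
median). Patients censored before the cutoff carry no information about
surviving past it and are **excluded** from the dichotomy by default;
`censored_good = TRUE` exposes the alternative. Over the union of
IR-screen hits and good/poor differential hits, an antigen is `non-IR`
when its mean is higher outside the IR subgroup, `immune-stimulatory`
when higher in IR *and* differential between good and poor prognosis
(Bonferroni t at a configurable α), and `IR` otherwise.

## The synthetic cohort generator

`simulate_cohort()` draws the structure every stage assumes:

* **Bimodal background** — gene means from a two-component mixture
  (an unexpressed noise peak near 4 and a signal peak near 8 on the
  log scale, weights 0.45/0.55), i.i.d. Gaussian noise around them.
* **Immune block** — 64 immune genes share an equicorrelated latent
  factor (`block_rho = 0.6`) and gain `ir_shift = 1.5` sd in IR samples.
* **IR membership** — antigens are drawn first and IR status is sampled
  from a logistic model on the active antigens
  (four negative effects, two positive, one twice the magnitude of the
  others: −1.2, −0.6, −0.6, −0.6, +0.6, +0.6 per sd), so the classifier
  stage has a recoverable truth. The intercept is solved numerically so
  the marginal IR rate equals `ir_fraction = 0.11`, matching an IR
  subgroup of roughly one patient in nine.
* **Poor-prognosis strata** — non-IR samples split into a heterogeneous
  stratum (a random half of the immune block at half the IR shift,
  56%), a uniformly intermediate stratum (35%) and a low stratum (9%).
* **Survival** — exponential with baseline median OS 44 months
  (PFS 18), hazard multiplied by `ir_hazard_ratio = 0.5` in IR samples,
  administrative censoring at 120 months. Exponential times make
  proportional hazards hold *exactly*, which is what lets the screen's
  type-I error be tested against the binomial law.
* **Mediator chains** — for each declared triple (A, X, B), X is the
  latent driver and A, B load on it (loading 0.8, unit variances), so A
  and B are marginally correlated at `loading²` but conditionally
  independent given X.
* **Multi-study structure** — additive per-study mean offsets; the
  default sizes 100/50/50/30 are a desk-scale echo of a 503-sample
  discovery cohort with three validation studies (503/240/260/134
  reachable by configuration).

What the generator does **not** emulate: platform-specific probe noise,
batch effects beyond mean offsets, non-proportional hazards, informative
censoring, or tumour-purity variation. Passing recovery tests on this
generator therefore demonstrates correctness of the estimators under the
stated model, not robustness to real-data violations of it.

`simulate_null_cohort()` zeroes every effect (expression shift, survival
benefit, antigen coefficients, mediator loadings) while still emitting
truth labels, giving exact null calibration targets.

## Numerical choices and problem sizes

Determinism: every simulation takes an integer seed; clustering is
deterministic given input order; k-means is seeded by discovery centres;
stepwise ties break by name order. Degenerate inputs are handled
explicitly (constant genes zeroed and flagged, empty clusters retained
with warnings, undefined KM medians open-ended, separation flagged,
collinear conditioning dropped).

The test and acceptance suites run at sizes chosen to make each check
sharp but quick: screen calibration on 1000 null genes at n = 300
(the exact binomial 99% band around 5% is then ±1.7 points), mediator
recovery over 50 planted and 50 null seeds at n = 500 with a 200-gene
pool, subgroup transfer over 20 discovery/validation blob pairs, and
classifier sign-recovery over 25 cohorts of n = 1000. The separable
four-blob fixture (centres 3 apart, within-cluster sd 0.1) is the
configuration under which exact partition recovery (ARI = 1) is the
correct expectation; at smaller separations exact recovery is not a
property any clustering method has.

## Known limitations

* The pipeline consumes pre-normalised expression; no array
  normalisation or download client is included.
* External molecular subtype labels are consumed as given, never
  re-derived.
* The hidden-node search considers one mediator per edge and makes no
  causal-direction claims.
* The antigen classifier is an unpenalised stepwise fit by design;
  penalised alternatives are out of scope.
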