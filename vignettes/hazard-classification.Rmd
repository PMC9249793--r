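---
title: "Multi-layer hazard classification of nanomaterials: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-layer hazard classification of nanomaterials: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`enmhazard` implements a layered procedure for grouping engineered
nanomaterials (ENMs) into ordered hazard classes and for discovering
compact multivariate biomarker models that predict those classes. This
vignette is the package's account of the underlying models, the tunable
parameters and their defaults, the numerical choices, and the places where
the design was genuinely open.

```{r setup, message = FALSE}
library(enmhazard)
```

## The study design being modelled

The unit of analysis is a panel of around 31 nanomaterials laid out on a
grid of core chemistries and surface modifications. Each material carries:

* several **omics layers** (mRNA, miRNA, proteomics from cell models;
  protein corona profiles) summarized as continuous per-feature values;
* **physicochemical properties** (a short, wide-format table);
* **in vitro assay readouts** — cytotoxicity in multiple cell models,
  genotoxicity, cytokine panels — on heterogeneous scales;
* **in vivo BAL neutrophil counts** from mouse exposures.

The pipeline never sees raw sequencing data; it operates on processed
expression summaries. Because the processed scale (log fold change versus
normalized intensity) is not fixed by the framework, all layers are
treated as continuous standardized summaries, and every model standardizes
features on training rows before fitting.

## Assay homogenization: the 1–6 ordinal score

Heterogeneous assays are made commensurable by a point-based rubric: per
endpoint, five strictly increasing bin edges map a readout to a score from
1 (no toxicity) to 6 (highest toxicity). Two conventions matter:

* **Boundary semantics.** Bins are half-open and lower-inclusive on the
  toxic side — a readout equal to an edge enters the more severe bin. This
  mirrors the only boundary rule the framework states elsewhere, the
  neutrophil rule `1 <= count < 10`.
* **Direction.** Endpoints where a *low* readout is adverse (e.g. viability)
  carry a `decreasing` flag; internally the readout and edges are negated.

The exact rubric cell values used in any given laboratory campaign are a
configuration artifact, not package code. `default_rubric()` estimates a
neutral default from a reference panel: the five interior sextile
quantiles of each endpoint, giving six equal-mass bins; tied quantiles are
separated by a vanishing increment to keep edges strictly monotone.
Missing readouts raise an error rather than defaulting to score 1, since a
silent "no toxicity" would bias grouping downward.

Whether cytokine panels should be aggregated before binning is not
prescribed anywhere; the package scores per endpoint and leaves
aggregation to the grouping stage, which accepts any list of score views.

## Grouping materials into hazard classes

Three labeling tasks produce a `hazard_labeling` (ordered classes
`NoL < M < H`):

* **NEU** (in vivo): thresholds on BAL neutrophil counts — `NoL` below 1,
  `M` in [1, 10), `H` at or above 10.
* **CYT**: k-means on the cytotoxicity score profiles.
* **INT**: similarity network fusion (SNF) of all assay score views,
  followed by spectral clustering.

Cluster identities from k-means or spectral clustering are arbitrary, so
`order_clusters_by_severity()` renames them: clusters are ranked by the
mean total toxicity score of their members, lowest becoming `NoL` and
highest `H`; ties break deterministically by cluster size, then cluster id.

### How many clusters? BIC with restart stability

`assess_k()` fits a spherical Gaussian mixture (each component covariance
σ²ₖI) for k = 2…6, restarting EM 250 times per k from random seeds, and
records the full distribution of BIC = −2 log L + m log n with
m = kd + k + (k − 1) free parameters. A wide BIC spread across restarts
signals sensitivity to initialization — the overfitting regime. The
selection rule, a reproducible operationalization of the qualitative
"trade off fit against stability" idea, is: *choose the smallest k whose
mean BIC is within one standard deviation of the best mean BIC and whose
BIC coefficient of variation is below 0.05* (`cv_cap`, configurable).

Numerical choices in the EM:

* convergence at relative log-likelihood change ≤ 1e-6, at most 500
  iterations;
* **k-means++ seeding** of the component means. Random-row initialization
  makes the restart distribution at the true k artificially bimodal (many
  restarts land in a merged/split local optimum), which defeats the whole
  point of using restart spread as a stability signal;
* **variance floor at 1% of the mean per-dimension variance** of the data
  (configurable via `var_floor`). Ordinal score tables contain duplicated
  rows; with a near-zero floor a component can collapse onto a duplicate
  set and drive σ² to the floor, producing an unbounded likelihood spike
  that makes large k look spuriously good and stable. A data-scaled floor
  removes the spikes without affecting genuine clusters, whose variances
  sit far above it;
* an empty component triggers an internal restart (budget 10), then an
  error.

### Similarity network fusion

`snf_fuse()` implements the cross-diffusion scheme for multi-view
integration. Per view: a scaled exponential kernel affinity with locally
adaptive bandwidth (α = 0.5; bandwidth from the mean distance to the k
nearest neighbors, k = max(3, ⌈n/10⌉)); a row-normalized *full* matrix
(off-diagonal mass 1/2, diagonal 1/2) and a kNN-sparsified row-normalized
*local* matrix. For T = 20 iterations each view's full matrix is replaced
by S · mean(other views' full matrices) · Sᵀ, renormalized and
symmetrized. The defaults follow the algorithm's source conventions and
are all configurable through `snf_config()`.

The output contract asks for a fused matrix that is simultaneously
symmetric and row-stochastic. After averaging the diffused views those two
properties conflict slightly, so the package's chosen output normalization
makes them exact: symmetric Sinkhorn scaling (iterated D^{-1/2} A D^{-1/2})
to a symmetric doubly stochastic matrix. Entries of the fused matrix are
strictly positive, so the scaling always converges.

Spectral clustering uses the symmetric normalized graph Laplacian: the
leading k eigenvectors of D^{-1/2} W D^{-1/2}, row-normalized, then seeded
k-means (25 starts). If the affinity graph is disconnected into at least
k components, the components themselves are returned as clusters.

## Marker selection

All selectors share one evaluation backbone (`split_scheme()`): five
stratified 70/30 train/test splits; all fitted quantities — including the
per-feature standardization — are learned on training rows only, and test
rows are touched solely for accuracy reporting. This is enforced by a test
that corrupts held-out rows and asserts the selected subsets are unchanged.
With ~31 materials in 3 classes, naive splits easily lose a class, so
stratified draws keep every class in every training split (non-stratified
draws are re-drawn, at most 100 times).

* **Univariate screen** — each feature alone predicts the class through a
  multinomial (softmax) logistic model. The multinomial formulation was an
  open choice; it gives a single coherent accuracy per feature for three
  classes instead of three one-vs-rest numbers. Features are ranked by mean
  test accuracy; intervals are 95% t-intervals with n−1 = 4 degrees of
  freedom, the honest small-sample convention for five repeats.
* **LR-PCA** — PCA on standardized training rows; the first two component
  scores feed a multinomial logistic classifier; rank-1 data falls back to
  one component (flagged). Since the "model" is a projection of the whole
  layer, it produces no feature subset; its stability is undefined and it
  is ranked by accuracy alone.
* **LASSO** — multinomial L1 path over a 20-point geometric grid spanning
  exactly [2⁻³, 2⁻¹] (the framework fixes the interval, not the grid
  density). Inner stratified 5-fold CV per split; chosen λ is the largest
  one with CV error within one standard deviation of the minimizer (the
  parsimony direction); the model is refitted on the whole training split
  and the subset is the union of nonzero coefficients across classes. An
  all-zero solution yields an empty, flagged subset — not an exception.
* **RF backward elimination** — drop the least important 20% of features
  per iteration (random-forest permutation importance), track OOB error,
  and return the smallest set within one binomial standard error of the
  minimum OOB error. Intended for the moderate-width layers
  (physicochemical, corona).
* **GARBO-style GA** — a genetic algorithm over feature subsets with a
  fuzzy fitness: min(increasing sigmoid of inner-CV random-forest
  accuracy, decreasing sigmoid of subset size). Defaults: accuracy sigmoid
  midpoint 0.7 (slope 10), size midpoint 20 features (slope 0.5),
  population 30, 25 generations, tournament selection (size 2), uniform
  crossover on the parents' union, mutation by swap/add/remove, elitism 2,
  hard size cap. Two deliberate design points:
  * the fitness is a *pure function of the subset* — the RF seed is derived
    from the subset's ids — so exhaustive-search comparisons of the GA are
    well-defined and the elite trace is exactly non-decreasing;
  * offspring whose subset has already been scored are nudged by extra
    mutation attempts toward unexplored neighbors. This novelty pressure
    prevents premature convergence and, on small instances, drives the
    memoized search to cover the whole subset space.
  The published algorithm's multi-niche archive and adaptive operators are
  intentionally not replicated; this is a documented approximation that
  preserves the accuracy/size trade-off objective.

A selector run returns one `biomarker_model`: the five per-repeat subsets,
per-repeat test accuracies, and a canonical subset. Which of the five
subsets "names" the model was an open choice; the package uses the subset
from the best-accuracy repeat (ties to the first), keeping all five for
stability scoring.

## Ranking and ensembling

Selection stability is the mean pairwise Dice–Sørensen index
2|A∩B|/(|A|+|B|) over the five per-repeat subsets, in [0, 1]. Degenerate
pairs are defined conservatively: two empty subsets count as identical
(1), an empty against a non-empty counts as 0. The composite rank is
`0.5·accuracy + 0.5·Dice` (weights configurable, must sum to 1); ties
break by smaller subset, then model id; the top 10 models are flagged.

`evaluate_model()` scores any fixed subset with a 500-tree random forest
(√p feature subsampling, seeded) — the framework names the classifier but
no settings, so the forest defaults are the library conventions.
Ensembling across data layers averages class-probability vectors without
weights (whether the original ensembles were rank-weighted is not stated;
unweighted is the default and configurable by the caller simply by
pre-weighting tables). Probability ties resolve toward the **less severe**
class and are flagged: a conservative hazard claim is surfaced rather than
silently inflated.

## Predicting external exposures

`fit_hazard_ensemble()` trains one forest per top-ranked subset on the
standardized full panel and stores the panel's center/scale.
`predict_external()` matches model features to external columns by exact
id; a model participates only if at least 80% of its features are present
(`min_coverage`), and missing features of participating models are imputed
with 0 — the training mean on the standardized scale. Both the threshold
and the fill value are configurable and recorded in the output
(`n_models_used`). Per-dose predictions of the same exposure are averaged
and renormalized. Per-exposure summaries over biological systems use the
median of the ordinal codes NoL = 1, M = 2, H = 3; half-integer medians
map to two intermediate levels, giving the five-level scale *low,
low-to-medium, medium, medium-to-high, high*. Distances between the
prediction tables of different cell models (mean absolute difference of
probability matrices) feed average-linkage hierarchical clustering,
serialized as a newick tree.

## Neutrophil-count regression

`fit_count_regression()` is ordinary least squares of log(count + offset)
on marker expression. The offset defaults to 1 because zero counts are
legitimate (they define the NoL class) and the bare log is undefined
there; the offset is recorded and predictions invert the transform.
Singular designs fail with the collinear columns named. Because in-sample
R² is optimistic at n ≈ 31, `crossfit_r2()` also reports out-of-sample R²
over repeated 70/30 splits; both are reported since the framework does not
say which convention its performance bound refers to.

## The synthetic study generator

`simulate_study()` emulates the study design, not transcriptome
distributions:

* 31 materials, 3 latent classes (configurable proportions, sum to 1
  within 1e-9);
* per layer, a configurable number of **planted features** whose
  class-conditional means shift by `effect_size` standard deviations
  between adjacent classes — the class-conditional Gaussian mean-shift
  model matches the standardize-then-model convention of the analysis
  stack. All other features are class-independent noise. An optional
  equicorrelated block (ρ, default 0) can emulate co-regulated
  transcripts; it is off by default so that closed-form oracles stay
  simple;
* assay readouts are monotone in the latent class (mean gap 1.5 per
  endpoint by default) plus Gaussian noise, so the rubric can bin them;
* BAL neutrophil counts are per-class log-normal with default locations
  log 0.3, log 3, log 30 (σ = 0.5), chosen so the class distributions
  straddle the 1 and 10 cut-points and threshold labeling recovers the
  truth with ≥ 90% agreement;
* one master seed feeds documented per-layer streams (R's Mersenne
  Twister), so a fixed seed reproduces the study bit for bit.

What the generator does **not** simulate: count-based marginals, dropout,
batch effects, platform differences, or realistic gene–gene correlation.
Passing tests therefore demonstrate that the pipeline recovers planted
structure under its own assumptions — a necessary condition, not evidence
about any particular real exposure campaign.

`simulate_external_exposure()` draws fresh profiles from one layer's
generative model for a chosen class at several doses, optionally retaining
only a fraction of feature ids to exercise the coverage/imputation logic
of external prediction.

## Validation problem sizes

The test suite and the end-to-end validation run at deliberately compact
sizes chosen as the package's own defaults for examples: 31 materials,
mRNA layers of 60–120 features with 5 planted features, effect size 2,
selectors LASSO and RF-backward, 200-tree forests, and external exposures
of three doses per class. The cluster-number analysis runs the full
k = 2…6 × 250 restarts protocol. The GA is validated against exhaustive
search on 10-feature instances with subsets of size ≤ 2, where the entire
search space can be enumerated.

## Known limitations

* With ~31 materials, test splits average ~9 rows; accuracies are coarse
  (multiples of 1/9) and the 95% t-intervals are wide. Overall accuracy is
  the only metric reported, by design; AUROC/F1 at these test sizes would
  suggest precision that is not there.
* The GA's operator suite is an approximation of the published wrapper
  (see above); it optimizes the same objective but will not reproduce that
  implementation's exact subsets.
* The default scoring rubric is estimated from the data it scores
  (sextile bins); laboratory campaigns with externally fixed rubric
  thresholds should supply them through `scoring_rubric()`.
* Cross-species or cross-platform feature-id harmonization is out of
  scope: external matrices must arrive with ids matching the training
  layer.
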