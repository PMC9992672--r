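---
title: "Discovering stage-discriminative expression features with stageminer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering stage-discriminative expression features with stageminer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stageminer)
```

## The problem

Bulk expression profiles (FPKM-scale mRNA transcripts, miRNA abundances) of
tumor samples labeled *early stage* (TNM stage I) or *late stage* (stages
II–IV) contain a handful of genuinely stage-associated features buried among
tens of thousands of uninformative ones. `stageminer` implements a
discovery pipeline for this setting: it selects a compact feature subset
whose expression discriminates the two stages, quantifies that
discrimination with a classifier suite under honest error estimation, and
then mines interpretable association rules that connect discretized
expression levels to the stage phenotype, ranking features by how often
they appear in stage-concluding rules.

The pipeline has five stages, applied to one expression matrix at a time:

1. nested cross-validation planning and normalization,
2. a univariate *filter* (t-test or ANOVA F),
3. a binary particle swarm optimization (BPSO) *wrapper*,
4. multi-classifier evaluation,
5. FP-Growth association rule mining.

## Nested cross-validation and normalization

Error estimation uses nested cross-validation: `build_fold_plan()` splits
samples into 10 outer test folds (default), and each outer-train set into 5
inner validation folds. Feature selection and tuning only ever see the
inner splits of one outer fold; the outer test fold measures generalization.
Folds are stratified so each fold's class ratio stays within one sample of
the global ratio — with near-balanced classes and AUC-driven selection,
unstratified small folds would inject avoidable variance.

Three preprocessing rules are applied per fold, always with statistics
computed on training samples only:

* **Constant cleaning.** A feature identical across all samples of an inner
  training set is removed; within one outer fold the removal mask is the
  union over that fold's inner training sets, so every inner fold of an
  outer fold searches the same candidate space.
* **z-score** (`fit_zscore()`/`apply_zscore()`), `y = (x - mu) / sigma`,
  used for filter scoring, the wrapper's SVM and the classifier suite. The
  *population* standard deviation (n denominator) is used; at these sample
  sizes the difference from the n−1 form is immaterial, but one convention
  must be fixed for reproducibility.
* **min–max** (`fit_minmax()`/`apply_minmax()`),
  `y = (x - Min) / (Max - Min)`, used for rule mining. Values outside the
  training range (possible on validation/test data) are clipped to
  `[0, 1]` so the discretization bins stay well defined.

Whether the original study normalized inside or outside the folds is not
stated; computing every statistic on training partitions only is the
standard leakage-free reading and is asserted by tests that perturb
non-training samples and demand identical parameters.

## Filter: univariate ranking, top 25 per inner fold

Each feature is scored on each inner training fold with either the Welch
two-sample t statistic,

$$t = \frac{\bar x_1 - \bar x_2}{\sqrt{S_1^2/n_1 + S_2^2/n_2}},$$

with sample variances and a two-sided p-value at Welch–Satterthwaite
degrees of freedom, or the one-way ANOVA F statistic `F = BMS / WMS`
(between/within mean squares, df `K - 1` and `N - K`). The unpooled
denominator above is literally the Welch statistic, which is why the Welch
form is used rather than the pooled t; for two groups the pooled-variance
identity `F = t²` is kept as a regression test. Which statistic applies to
which data kind is configuration — t-test is the conventional choice for
mRNA-style matrices and ANOVA for miRNA-style ones — and both consume the
same two-class input.

The 25 smallest p-values per inner fold are kept (`select_top_k()`; ties
break by ascending feature index so selection is deterministic), and the
per-fold lists are pooled by set union with per-feature selection counts
(`union_candidates()`). No multiple-testing correction is applied: the
filter is a ranking device, not an inference procedure.

## Wrapper: binary PSO minimizing an AUC-based fitness

Over one outer fold's pooled candidates, `run_bpso()` searches feature
subsets encoded as bit vectors. The fitness of a subset is

$$\mathrm{fitness} = \bigl(1 - \overline{\mathrm{AUC}}\bigr) + \mathrm{sd}(\mathrm{AUC}),$$

where the AUCs come from a radial-kernel SVM trained on each inner training
fold (restricted to the subset) and scored on the corresponding inner
validation fold. The dispersion term penalizes subsets whose performance is
unstable across folds. The standard deviation is the sample (n−1) form of
the per-fold AUCs — the only dispersion computable from a handful of scalar
AUCs. An empty subset is assigned fitness 2.0, worse than any attainable
value, so the search remains total.

The swarm follows the classic binary PSO update: velocities

$$v' = \theta v + \alpha\,\epsilon_1 (g^* - x) + \beta\,\epsilon_2 (x^* - x)$$

with inertia `theta = 0.9` and acceleration `alpha = beta = 2`, 35
particles and 100 iterations by default; `eps1`, `eps2` and the bit-redraw
uniforms are fresh per element, particle and iteration from one seeded
stream. Velocities are clamped to `[-6, 6]`: the sigmoid transfer
`S(v) = 1/(1 + e^{-v})` then stays within `(0.0025, 0.9975)`, so no bit is
ever frozen. Positions initialize i.i.d. Bernoulli(0.5) and velocities
uniform on `[-1, 1]` — standard practice where the source is silent.
Fitness evaluations are memoized by bit pattern, which matters once the
swarm starts revisiting good subsets.

BPSO runs once per outer fold (each outer fold has its own inner
validation folds, which is what the fitness consumes); the final feature
set is the union of the per-fold global bests, with each feature's
outer-fold frequency reported (`consolidate_selection()`). Union keeps
every feature any fold found useful; how the original study mapped ten
per-fold runs to a single list is not stated, and the resulting counts are
data-dependent either way.

## Classifier suite

`evaluate_suite()` measures the discrimination power of a feature set with
six built-in classifiers — radial SVM, random forest, 5-NN, naive Bayes,
logistic regression, XGBoost (50 rounds, binary logistic) — all at library
defaults otherwise, since no hyperparameters are printed for them.
A seventh slot is open: `register_classifier()` accepts any fit/predict
closure pair (this is where a deep self-organizing auto-encoder or any
other external scorer plugs in).

For every inner fold of every outer fold, each classifier is fitted on the
inner training split and evaluated on the train, validation and outer-test
splits with: accuracy (%), AUC-ROC (rank-sum estimator, ties at ½), F1 per
class, MCC, sensitivity and specificity (positive class = *late*). The MCC
is reported as 0 when a denominator factor vanishes — the standard
convention that keeps the report total. The table averages over all
inner-by-outer fits; the averaging axis is recorded in the report's
`averaged_over` attribute because reasonable alternatives (outer folds
only) exist.

## Association rule mining

The consolidated features are min–max scaled on the full labeled matrix and
discretized per feature into equal-frequency tertiles — `low`, `medium`,
`high` — with boundary ties falling to the lower bin (type-7 quantiles).
Equal-frequency binning is robust to the strong right skew of expression
data; the binning rule is configurable in spirit (any discretization
producing one level item per feature slot works) but tertiles are the
package's fixed default. Each sample becomes a transaction of
`feature=level` items plus one `stage=early|late` item. Rule mining runs
once on the full matrix rather than within folds, matching the pipeline's
step order in which mining follows selection.

`mine_frequent_itemsets()` is a from-scratch FP-Growth: items are ranked by
descending support (alphabetical tie-break), transactions insert into a
prefix-compressed FP-tree, and conditional pattern bases are mined
bottom-up. Output is exactly the itemsets with support ≥ `min_support`
(default 0.3; 0.2 is the conventional choice for the sparser mRNA-style
runs) and length ≤ `max_length` (default 4, which therefore bounds
`|A| + |C|` for every rule). The miner is validated against exhaustive
subset enumeration on hundreds of random transaction tables.

`generate_rules()` scores every split of a frequent itemset into nonempty
disjoint antecedent/consequent with support, confidence and lift
(`lift = confidence / support(C)`), keeping rules with lift ≥ 1.1 by
default. No minimum-confidence cut is applied — the mining thresholds are
support, length and lift only. Stage-consequent rules
(`filter_stage_rules()`: stage item in the consequent, none in the
antecedent) drive the ranking: `rank_repeat_counts()` counts, per feature,
the stage rules whose antecedent contains any of its level items (a
feature counts once per rule; low/medium/high variants aggregate because
the ranking is per feature, not per level). `anchor_feature_rules()`
builds the second-level feature–feature view around a chosen anchor, and
`export_rule_graph()` writes the tripartite phenotype/rule/feature edge
list that the rule-network figures draw.

## The synthetic generator

`generate_dataset()` emulates the shape of the real inputs without any
download: two near-balanced classes (the reference dimensions are
189/192 and 190/192 samples), many uninformative features, a small planted
set of differential features, ENSG-like or hsa-mir-like identifiers, and an
optional fraction of constant columns to exercise cleaning. Each feature is
log-normal with location drawn uniformly from `meanlog` range `[0, 4]` and
common `sdlog` 0.5, mimicking FPKM-like skew; informative features shift
the late-class location by `effect_size × sdlog` with alternating sign, so
the planted separation is exactly `effect_size` within-class SDs on the
log scale and the filter t statistic is directly controllable. The
log-normal is a stand-in for rank/variance structure, not a claim about any
real cohort; batch effects, library-size effects, count overdispersion and
miRNA–mRNA coupling are deliberately not modeled. Passing tests therefore
demonstrate correctness of the machinery and recoverability of planted
signal — not performance on TCGA-scale data, whose headline accuracies
depend on the real matrices.

## Numerical choices and degenerate inputs

* Population SD in the z-score; sample SD in the fitness dispersion (each
  per its defining context).
* Filter ties break by feature index; ranking ties by feature id; both make
  reruns bit-identical.
* Min–max values outside the training range clip to `[0, 1]`.
* Constant features: exact-equality test on the training set; z-score and
  min–max refuse zero-variance input and direct the caller to cleaning.
* MCC zero-denominator → 0; empty BPSO subset → fitness 2.0; features with
  fewer than three distinct values discretize through the same quantile
  thresholds.
* All stochastic stages (fold assignment, swarm, stochastic learners) are
  driven by one global seed fanned out deterministically per stage and
  fold; the run manifest records the derived seeds and output checksums,
  and rerunning a configuration reproduces the manifest byte for byte.

## Problem sizes in the shipped tests

The test suite exercises the pipeline at desk scale: fold-plan sweeps over
50 seeds; the default 35-particle/100-iteration swarm on a 100-sample,
50-candidate problem over 20 seeds; planted-recovery runs with 150
candidates and 10 planted features at 2 SD over 10 seeds using a reduced
(15 × 15) swarm over 3 outer folds; FP-Growth versus exhaustive enumeration
on 200 random tables of up to 12 items and 100 transactions; and
chance-level calibration of all six classifiers on pure noise over 10
seeds. These sizes were chosen so the full suite runs on a single CPU in
minutes while keeping every threshold at its stated value.

## Limitations

* The selection pipeline's outputs (candidate counts, selected-set sizes,
  rule counts) are data-dependent; on synthetic data they should not be
  compared to counts reported for real cohorts.
* BPSO is a stochastic heuristic: the union consolidation favors recall
  over sparsity, and with generous swarms the consolidated set can be
  large. Per-feature outer-fold frequency is reported precisely so users
  can tighten the selection.
* The deep auto-encoder classifier slot is an interface, not an
  implementation.
* FP-Growth's output size grows quickly at low support thresholds on
  correlated data; `max_length` is the practical guard.
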