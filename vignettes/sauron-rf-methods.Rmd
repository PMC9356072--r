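---
title: "Joint regression and classification forests for imbalanced drug response"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint regression and classification forests for imbalanced drug response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sauronrf)
```

## The modeling problem

Per-drug sensitivity models map a cell line's expression profile to its
ln(IC50). A drug-specific threshold `t` (supplied externally, e.g. from a
mixture-model calibration of the IC50 distribution) divides the panel into
sensitive (`y < t`) and resistant lines; values exactly at `t` are called
resistant, the conservative clinical default. Sensitive lines are the
minority, typically around 1:10. Two failure modes follow for off-the-shelf
learners: classifiers default to "resistant", and regression forests
average the minority's extreme responses away, so their errors concentrate
exactly on the clinically interesting lines.

`sauronrf` fits one weighted regression forest that also classifies. Its
assumptions are modest: a tabular samples-by-genes matrix on a roughly
log-scale, a continuous response whose class-conditional means differ, and
complete cases after aligning expression with response (unmatched samples
are dropped with a message, IDs are sorted so that seeds alone control all
randomness).

## Training and aggregation

Trees are grown on `N`-sized bootstraps. At a node `v` with bootstrap
members `δ(v)`, `mtry` genes are drawn without replacement and the split
maximizes the weighted-MSE improvement with per-node normalized sample
weights and weight-mass node factors. Internally the builder maximizes the
equivalent raw-weight SSE decrease — the two criteria differ by a positive
node-constant factor, which the test suite verifies against an exhaustive
split enumeration on a 12-sample fixture.

Initial weights implement the imbalance countermeasures (`uniform`,
`simple`, `linear`, `quadratic`), or the training set is rebalanced by
upsampling before growing the forest (`upsample`, `proportional`). Weights
and resampling are always computed from the training portion only.

Each leaf stores the weighted mean of its members' responses, the
unweighted mean (used by the classification-forest baseline's derived
continuous prediction), the per-class member counts and weight mass, and a
class label. Prediction combines the reached leaves under one of five tree
weightings (`uniform`, `binary`, `binary_sens`, `majority`,
`majority_sens`); the forest's class is the vote mode with ties resistant.

### Why leaf labels use weight mass

The open design point with the largest consequence is how a leaf acquires
its class label. Labeling by the raw member-count mode makes sample weights
invisible to the classification channel: weights then only relocate splits,
and in our synthetic experiments the vote-based sensitivity of a
simple-weights model stays at the level of the unweighted model. Labeling
by the weighted class mass makes a sensitive line count `N_res/N_sens`
times, exactly what duplicating minority rows does to the count mode — so
the two countermeasures the package offers (weights and upsampling) act
equivalently on classification, and the balanced-vote behavior that
motivates the method emerges. With uniform weights the weighted mode is the
plain count mode, so the heterogeneity-aware baseline is unaffected. The
package therefore labels leaves by weight mass, ties resistant.

Other deliberate choices:

* **Vote ties** (even `B`) predict resistant, consistent with the
  binarization tie rule.
* **Upsampled duplicates** are real rows with uniform weights; leaf means
  over them are plain averages.
* **Proportional upsampling** turns the doubled linear class weights into
  per-sample importances, multiplies by `N_res`, rounds half-to-even and
  repairs the total by largest remainder, so the classes balance exactly; a
  sample at the threshold can legitimately receive zero copies.
* **Split candidates** are midpoints between consecutive distinct values;
  gain ties (including distinct features inducing the same partition) are
  resolved toward the lower feature index, then the lower split value,
  inside a relative tolerance of `1e-9` of the node error so that
  floating-point summation order cannot flip a mathematical tie.
* **Degenerate nodes** (pure response, fewer than `2 * min_node` members,
  or no admissible split among the drawn genes) become leaves. The binary
  weighting's denominator cannot vanish because the forest class is the
  vote mode.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `trees` | 500 | ensemble size `B`; variance, not bias |
| `mtry` | `⌊P/3⌋` | genes per split, the regression-forest convention |
| `min_node` | 5 | minimum bootstrap members per leaf |
| `sample_weights` | `"uniform"` | imbalance countermeasure on the loss |
| `resampling` | `"none"` | imbalance countermeasure on the data |
| `tree_weighting` | `"binary_sens"` | aggregation scheme at prediction |
| `k` (mRMR) | grid 20–100 | input genes; selected by cross-validation |
| `n_bins` (MI) | 10 | quantile bins of the plug-in MI estimator |

Thresholds `t` are in ln(IC50) units; the package never estimates them.

## Feature selection

Greedy mRMR with a plug-in mutual-information estimator: each variable is
independently discretized into `n_bins` equal-frequency bins (variables
with at most `n_bins` distinct values keep their values as levels, so
binary labels behave sensibly), and MI is computed in nats on the resulting
table. The score is the MID difference form, relevance minus mean
redundancy with the already-selected genes; the MIQ quotient form is
available behind `score = "quotient"`. Argmax ties break lexicographically
by gene identifier. Selection is refit inside every cross-validation fold
and again on the full training set, so no information leaks from validation
folds. One estimator caveat worth knowing: after selecting a near-copy of
the response, relevance and redundancy of the remaining genes largely
cancel, so scores compress toward zero — an intrinsic property of the MID
score, not of this implementation.

## Evaluation workflow

`run_experiment()` draws a seeded 80/20 split without replacement (not
stratified; a minority class can by chance be absent from a fold, in which
case that grid point is marked failed, logged and skipped), runs 5-fold CV
per grid point, selects by mean validation MCC for classifying models and
mean validation MSE for the pure regression baseline (the selection metric
is configurable), refits on the full training set and reports test-set
MSE/median-SE overall and per true class, plus the confusion metrics with
MCC's zero-denominator convention of 0.

## The synthetic generator

`simulate_drug_data()` emulates the structure the method targets: ~800
lines, 300 log-scale expression features of which 20 carry signal, a latent
sensitive class drawn Bernoulli(0.09), and a bimodal response whose class
means are `effect_size = 3` apart with noise sd 1. Half of the separation
is a direct class effect, half is mediated linearly through the informative
genes (each shifted down by one unit in sensitive lines), so the genes
genuinely predict the response but no single gene separates the classes.
The threshold sits at the midpoint of the class means, and the stored
labels are always the thresholded response. Under the default noise about
8% of resistant lines fall below `t`, so the realized label imbalance
(~0.13–0.15 sensitive) is milder than the latent 0.09 — as with measured
IC50s, some labels are intrinsically noisy, which caps the attainable
sensitivity of any classifier. What the generator does **not** emulate:
gene–gene correlation beyond the shared class factor, batch structure,
heavy-tailed IC50 error, or realistic GDSC marginals. Passing tests
demonstrate the mechanics and the direction of the imbalance
countermeasures, not field performance on real panels.

Test and benchmark sizes are deliberately desk-scale: the directional
benchmark uses 20 generator seeds, 20 mRMR genes and 100-tree forests; the
exhaustive split oracle runs on a fixed 12×3 fixture; workflow tests use
120–150 samples and 15–25 genes.

## Limitations

Two classes only (the vote and the sensitive-only weightings have an
obvious multi-class generalization, but it is not implemented); expression
is the only omics layer; the splitting criterion remains pure regression —
class information enters through weights, leaf annotation and aggregation,
not through a combined impurity; thresholds must be supplied. Forests
serialize to JSON (`write_forest_json()`) with full double precision, so
predictions replay identically, but training data and bootstrap indices are
not stored.
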