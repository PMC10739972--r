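---
title: "Hybrid resampling and ensemble voting for heart-failure mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid resampling and ensemble voting for heart-failure mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(hfensemble)
```

## The problem

Heart-failure cohorts collected during clinical follow-up are small and
imbalanced: one outcome class (here, patients who died before the end of
follow-up, coded `death_event = 1`) heavily outnumbers the other. A
classifier trained on such a table drifts toward the majority class and
its headline accuracy hides poor minority detection. This package
implements a two-part answer for tables with the standard 12-predictor
heart-failure clinical schema (age, anaemia, high blood pressure,
creatinine phosphokinase, diabetes, ejection fraction, sex, platelets,
serum creatinine, serum sodium, smoking, follow-up time):

* a **hybrid resampler** (`boo_st()`) that concentrates emphasis on
  hard minority cases before oversampling, and cleans the result;
* a **hybrid classifier** (`fit_cbcec()`) that bags the empirically
  best conventional learner and soft-votes it with itself.

Around these sit min–max scaling, dual feature ranking, a multi-split
evaluation protocol with signed-rank comparisons, and partial-dependence
extraction of high-risk value ranges.

## The resampler

`boo_st()` composes three stages on a scaled training table.

**Stage 1 — boosting weights.** `boost_weights()` runs `T` rounds
(default 10) of AdaBoost-style reweighting with a depth-1 decision
stump as the weak learner. Starting from uniform weights `1/n`, each
round fits the stump on the current weights, computes the weighted
error `eps`, and multiplies the weights of misclassified cases by
`exp(lr * 0.5 * log((1 - eps)/eps))` before renormalising. Because the
minority class is misclassified most often, weight mass migrates to
minority cases. Degenerate rounds are handled explicitly: `eps = 0`
stops early (a separable table needs no emphasis), `eps >= 0.5` resets
that round to uniform and continues. The stump is the canonical weak
learner here; anything deeper would separate small tables outright and
return uniform weights.

**Stage 2 — weight-biased SMOTE.** `weighted_smote()` synthesises
`ceiling(target_ratio * n_majority) - n_minority` minority records
(default `target_ratio = 1`, full balance). Each record grows from a
seed row drawn from the minority class with probability proportional to
its boost weight — this is how the emphasis propagates — towards a
neighbor drawn uniformly from the seed's `k` nearest minority neighbors
(Euclidean, default `k = 5`), as `xs = xi + r * (xj - xi)` with `r`
uniform on (0, 1]. Binary flags cannot be interpolated, so they copy
the nearer endpoint (seed when `r` is at most 0.5, neighbor otherwise).
When the minority class has fewer than `k + 1` members, `k` is lowered
with a warning; a single-member minority is an error rather than a
silent duplication.

**Stage 3 — Tomek cleaning.** `find_tomek_links()` returns every
cross-class pair of mutual nearest neighbors in the augmented table
(original plus synthetic rows), and `remove_tomek_majority()` drops the
member belonging to the majority class *of the table before
oversampling* — after full balancing the counts are tied, and the
protected class must remain the original minority so that synthetic
rows are never deleted by the stage that was meant to clean around
them. Nearest-neighbor ties break by lowest row index for determinism.
The cleaning pass runs once by default; `iterate_tomek = TRUE` repeats
it to a fixpoint.

The report object reconciles every count exactly
(`after = before + synthesized - removed`, per class), and carries the
synthetic provenance (seed row, neighbor, interpolation fraction per
record) and the removed sample ids.

## The hybrid classifier

Four conventional families are supported behind one train/predict
contract: decision tree (rpart), gradient boosting (xgboost), SVM with
an RBF kernel (e1071) and extremely randomised trees (ranger with the
`extratrees` split rule). Their training internals are deliberately
delegated to those libraries; this package owns the combination logic.
SVM class probabilities come from a deterministic Platt-style logistic
calibration of the decision values, fitted on the training scores —
the library's built-in probability machinery uses an internal
cross-validation whose randomness cannot be fixed from R, which would
break the reproducibility contract every other learner honours.

`fit_cbcec()` then:

1. selects the best family by validation accuracy (`select_best()`,
   ties broken in the fixed order DT, GB, SVM, ET);
2. refits that family on the full training table;
3. bags it: `B` bootstrap resamples of size `n` (default `B = 10`),
   one member each, aggregated by the arithmetic mean of probability
   vectors; a resample missing a class is redrawn (at most 10 times);
4. combines the single fit and the bag by voting. Soft voting — the
   default — averages the two probability vectors and takes the argmax;
   hard voting keeps the agreed label and falls back to the single
   best classifier on disagreement; weighted voting takes a weighted
   average (default weights 0.5/0.5, since no principled asymmetry
   exists a priori).

Selecting the base family on the final test split would leak
information into model choice, so by default selection happens on an
internal stratified fold (20 % of the training table). The
`paper_faithful` flag scores selection on the supplied validation table
instead, for reproducing published protocols that select on the test
split. Both the selection winner and the bag are refit on the full
training table before voting.

`run_ablation()` exposes the three grids that matter for this
architecture — base family, random state, voting type — as one
factorial, crossed with feature sets, flagging the setting with the
best mean accuracy.

## Feature ranking

Two rankings, intentionally different in character:

* `rank_impurity_importance()` — mean impurity decrease from a random
  forest (default 500 trees), normalised to sum to one; deterministic
  under its seed.
* `rank_information_gain()` — `IG(D, f) = I(D) - sum_j (N_j/N) I(D_j)`
  with Shannon entropy in bits. Continuous features are discretised
  into 10 equal-frequency bins, which is robust to the heavy right
  tails of features like creatinine phosphokinase and platelets and
  makes the score invariant under monotone transformations; features
  with at most 10 distinct values are treated as categories directly.

Ranking ties break alphabetically. By default the pipeline ranks on the
scaled full table before resampling, so the ranking reflects the data
rather than the oversampler. `top_features()` cuts to the top 10, the
subset size used in the downstream three-way comparison (ALL vs FI vs
IG sets).

## Evaluation protocol

`make_splits()` implements the multi-split protocol: stratified splits
at 70, 80 and 90 % training fraction, with the test count
`round(n * (1 - fraction))` allocated across classes by largest
remainder (the split rule had to be pinned down somewhere; this one is
deterministic and keeps per-side class proportions within one sample of
the global ones). Metrics are the standard confusion-matrix quartet
plus AUC as the trapezoidal area under the threshold-swept ROC;
zero-denominator ratios return 0 with a warning rather than NaN.

`wsrt()` is the paired Wilcoxon signed-rank test with the conventions
fixed as: zeros dropped, midranks for ties, statistic
`TS = min(W+, W-)`, two-sided p-values. For up to 25 effective pairs
the p-value is exact, computed from the full null distribution of the
rank sum via its characteristic polynomial (midranks double to
integers, so the distribution lives on a half-integer grid and is
obtained by convolution rather than by enumerating all `2^n` sign
vectors); beyond that a normal approximation with continuity and tie
corrections takes over. `stats::wilcox.test` cannot serve here because
its exact path refuses ties, and the test suite instead uses it — plus
a literal sign-enumeration oracle — as independent cross-checks.
`compare_all_pairs()` applies the test to every unordered classifier
pair, per feature set.

## Explanations

`pdp()` computes true partial dependence: each grid value (20
equal-frequency quantiles for continuous features, both levels for
binary flags) is substituted into every row while the other features
keep their observed values, and the model's death probability is
averaged. `risk_ranges()` turns a curve into interpretable intervals:
contiguous grid runs where the dependence exceeds
`mean(pd) + 0.5 * sd(pd)`. Published analyses of this kind report such
ranges without stating a rule; this threshold is the package's own
operationalisation of "relatively high" and is configurable.

## The synthetic generator

`simulate_hf()` emulates the heart-failure clinical-records schema so
every stage is testable without external data. Features are drawn
within the schema's valid ranges: the right-skewed labs (creatinine
phosphokinase, platelets, serum creatinine) from range-truncated
log-normals, other non-binary features uniformly, binary flags from
Bernoulli draws at plausible prevalences. Labels come from a logistic
latent score over standardized signal features,

```
z = sum_j w_j x_j_std / (1 + overlap) + N(0, noise_sd)
```

with the intercept solved by bisection so the expected minority share
matches the configuration, then trimmed to the exact count by flipping
the most boundary-ambiguous records. The defaults are fixed once:
n = 299 records with 96 minority cases — note the minority class is the
*survivors*, matching the composition the package's reference protocol
assumes — and planted weights time −1.4, serum creatinine +1.0,
ejection fraction −0.8, age +0.6, mirroring the published importance
order with clinically sensible signs (early death means short
follow-up; high creatinine and age increase risk; high ejection
fraction is protective). `noise_sd = 1` leaves the classes genuinely
overlapping rather than separable.

What the generator does *not* emulate: feature–feature correlation
beyond the shared latent score, censoring structure in the follow-up
time, and site- or cohort-specific measurement artefacts. Tests passing
on this generator therefore demonstrate that the algorithms recover
planted structure under realistic marginals and imbalance — not that
any particular clinical accuracy will transfer to real cohorts.

## Numerical choices and degenerate inputs

* Zero-range columns min–max scale to 0, not NaN; unseen test values
  clip to [0, 1] so distance computations stay bounded.
* Scaling is fitted on the training side only by default; the
  `paper_faithful` pipeline flag fits on the full table before
  splitting and balances before splitting, reproducing the published
  order of operations at the cost of leakage.
* All nearest-neighbor ties break by lowest row index; ranking ties
  alphabetically; selection ties by the fixed family order.
* Every stochastic step (generation, splitting, SMOTE draws, bootstrap,
  forest fits) takes an explicit seed, and the pipeline's metrics JSON
  is byte-identical across reruns with the same configuration.

## Problem sizes in the test suite

The suite validates the geometric oracles (SMOTE interpolation, Tomek
mutual-NN, partial dependence) on hundreds of random tables of up to 60
rows, the statistical properties on 10–20 seeds at n = 150–1000, and
the signed-rank test's size on 20,000 null replicates of 12 pairs —
sizes chosen so each property is measured with comfortable Monte-Carlo
margins while the whole suite stays quick to run.

## Known limitations

* Binary targets only; no multiclass imbalance handling.
* The resampler assumes features on comparable scales and warns, but
  does not rescale, when given raw clinical units.
* Timing and memory figures in the profiling output are informational
  and hardware-dependent; no test asserts them.
* Reproduction of published accuracies on the real Kaggle
  heart-failure table requires downloading that table and the
  `paper_faithful` flags; results remain sensitive to hyperparameters
  the original protocol leaves unstated.
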