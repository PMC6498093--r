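---
title: "Compartment-resolved miRNA biomarker selection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compartment-resolved miRNA biomarker selection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compartmiR)
```

## The analytical problem

Circulating miRNAs can be profiled from whole plasma, from the extracellular
vesicle (EV) fraction, or from vesicle-depleted (EV-free) plasma, and the
three compartments need not carry the same diagnostic information. The
motivating application is distinguishing lung adenocarcinoma from granuloma —
a benign inflammatory lesion that is clinically confusable with cancer — from
small-RNA sequencing profiles of the three compartments in the same small
cohort (on the order of 10 cancer and 9 granuloma patients, ~1,500 miRNAs).

With far more features than samples, any sufficiently flexible model
separates the training data perfectly, so the pipeline is built around two
deliberately constrained components: a feature-ranking stage that aggregates
evidence over many small random models, and a rule learner whose output is a
short, clinically readable decision list. Everything downstream
(cross-validation, signature overlaps, clustering) quantifies how much signal
each compartment actually carries.

## Monte-Carlo feature selection

`run_mcfs()` repeatedly draws a random *projection* of `m` of the `d`
features and grows `t` binary decision trees per projection, each on its own
random train/test split of the samples. Feature `g` accumulates the relative
importance

$$
RI_g \;=\; \sum_{\tau=1}^{s\,t} (wAcc_\tau)^u
\sum_{n_g(\tau)} IG\!\left(n_g(\tau)\right)
\left( \frac{\text{no. in } n_g(\tau)}{\text{no. in } \tau} \right)^{v}
$$

where the inner sum runs over the nodes of tree $\tau$ that split on `g`,
$IG$ is the node's information gain in bits, the fraction is the node's share
of the tree's training samples, and $wAcc_\tau$ is the tree's weighted
accuracy (mean of per-class accuracies) on its held-out split. A feature
therefore scores highly when it is *repeatedly* chosen as a splitting
variable, near the root, in trees that generalize.

### The internal tree learner

The trees are plain information-gain trees over numeric features: candidate
thresholds sit midway between consecutive distinct observed values, samples
with `value <= threshold` go left, and the (feature, threshold) pair
maximizing the gain is chosen at every node. Nodes are split until pure,
smaller than 2 samples, or gain-free; there is no pruning — individual trees
are allowed to overfit because the ensemble score, not the tree, is the
product. Ties in the gain are resolved toward the first feature of the
projection and the lowest threshold, making every tree deterministic given
its inputs.

Per-tree weighted accuracy is computed on the held-out part of a stratified
train/test split (`train_fraction = 0.66`). Stratification keeps both classes
on both sides whenever a class has at least two members; if a class is absent
from the test split, the accuracy is averaged over the classes present.

### Parameter defaults

The reference description of the method leaves `m`, `s`, `t`, `u`, `v` and
the split fraction open. The package defaults are `u = 1`, `v = 1`
(importance proportional to tree quality and node coverage), `t = 5`,
`m = ceiling(0.05 d)`, and `s = ceiling(20 d / m)` so that each feature is
expected to enter at least ~20 projections — enough for the ranking to be
dominated by signal rather than sampling noise. All are exposed in
`mcfs_params()`. Each projection draws its randomness from a counter-based
substream of one seed, so a run split into batches (`projection_offset`)
reproduces the combined run exactly; this additivity is asserted in the test
suite.

Whether the `t` trees of one projection should share one train/test split or
draw `t` independent splits is ambiguous in the method's description; the
package draws independent splits, which lowers the variance of the
$wAcc$-weighting at no extra cost.

## RIPPER rule induction

`train_ripper()` is a from-scratch implementation of Repeated Incremental
Pruning to Produce Error Reduction, specialized to binary classes over
numeric features. Rules are learned for the minority class; the majority
class becomes the default (`"otherwise"`), which is exactly the shape of a
published compartment rule table: one threshold rule for granuloma, default
adenocarcinoma.

* **Growing** adds the condition (`feature <= v` or `feature >= v`, `v` an
  observed value in the grow set) with maximal FOIL gain
  $p \left(\log_2 \frac{p}{p+n} - \log_2 \frac{p_0}{p_0+n_0}\right)$
  until no negatives are covered or no condition has positive gain. Placing
  thresholds at observed data values is what makes a learned cutoff like
  `210.43` an actual measured expression value rather than an arbitrary
  midpoint. Ties are broken lexicographically by (feature, op, threshold).
* **Pruning** evaluates every final-segment deletion of the rule on a held
  out prune set (one third of the data, stratified) with the IREP* metric
  $(p-n)/(p+n)$, −1 for a rule covering nothing; the shortest prefix among
  the maxima is kept, so deletions that do not hurt are always taken.
* **Stopping** uses a minimum-description-length criterion: rule adding
  stops once the ruleset's total description length (theory bits for the
  conditions plus exception bits for the errors) exceeds the best length
  seen so far by more than `dl_slack = 64` bits.
* **Optimization** (2 passes) revisits each rule, grows a *replacement* and
  a *revision* on fresh splits of the data not covered by earlier rules, and
  keeps whichever of the three variants minimizes the total description
  length, followed by a mop-up round for still-uncovered positives.

### Small-cohort behavior

Two choices matter specifically because the cohorts are tiny. First,
`min_coverage = 2` is evaluated against the full training data, not the
residual set, so a final rule that covers a single *remaining* positive (but
several training samples overall) is still admissible. Second, with ~6
samples in a prune set it regularly happens that the prune split contains
none of the samples a consistent grown rule covers; strict IREP* would then
discard the rule and stop with positives uncovered. When that happens the
learner falls back to the unpruned grown rule, accepting it only if it covers
at least one new positive and misclassifies under half of what it covers on
the remaining training data, with the MDL stop still in force. This keeps the
learner exact on separable data for every seed while leaving its behavior on
realistic noisy data essentially unchanged.

`predict()` on a ruleset applies the first matching rule, else the default;
rulesets render as text (`format()`) and parse back losslessly
(`parse_ruleset()`), with thresholds printed in their shortest decimal form
that round-trips to the same double.

## Evaluation

`repeated_cv()` runs stratified `n_folds`-fold cross-validation `n_repeats`
times (defaults 10 × 3) and **pools counts** over all repeats rather than
averaging percentages — with 19 samples and 3 repeats the pooled confusion
matrix sums to 57, which is the denominator convention of the published
tables. Fold assignment deals each class round-robin onto the least-filled
folds, so fold sizes differ by at most one and per-fold class counts are
within one of proportionality; with 19 samples and 10 folds this forces nine
folds of two and one singleton.

Weighted accuracy is the mean of the two per-class accuracies, which a
constant classifier can never push beyond 50% regardless of the 10-vs-9
imbalance.

`feature_selection_scope` controls where MCFS runs. The default,
`"full_data"`, ranks features once on the complete dataset and then
cross-validates the RIPPER stage on the selected features — this mirrors the
historical protocol of the motivating study but lets feature selection see
the test folds, so its accuracies are optimistic. `"per_fold"` nests the
ranking inside every training fold and is the recommended setting for new
analyses; both are first-class code paths.

## Cross-compartment comparison

* `venn_overlaps()` intersects the k-prefixes of the per-compartment
  rankings (k = 10, 15, 20 by default in `run_study()`); intersection sizes
  are necessarily monotone in k.
* `class_means()` / `fold_change()` report per-class arithmetic means on the
  stored expression scale and the negative/positive ratio. When the
  positive-class mean is zero the ratio is flagged undefined and both means
  are reported instead — never an infinity.
* `ward_cluster()` clusters samples by Ward.D2 on Euclidean distances (the
  criterion whose Lance–Williams updates are consistent with squared
  Euclidean merge costs) and cuts the tree in two;
  `count_missclustered()` evaluates both cluster-to-class mappings and
  reports the smaller disagreement, making the count invariant to cluster
  relabeling. Clustering runs on the expression scale as stored by default;
  with presence/absence markers among high-abundance noise the Euclidean
  geometry is dominated by the abundant features, and the `scale_rows` flag
  (z-scoring features first) is the appropriate remedy — the package leaves
  this off by default because the original figures do not state any scaling.

## The synthetic-data generator

`generate_compartment_dataset()` produces studies with the cohort geometry
of the motivating data — 10 positive and 9 negative samples, 1,509 features —
and known planted truth, so every downstream stage is testable without any
download. The model, chosen to emulate small-RNA sequencing counts:

* feature baselines drawn log-normally (median `noise_mean = 50`,
  `baseline_sdlog = 1`) — small-RNA abundances span orders of magnitude;
* per-sample library factors with mean 1 and coefficient of variation
  `library_size_cv = 0.3` (gamma-distributed);
* negative-binomial counts (`noise_dispersion = 0.5`) with mean
  baseline × library factor; a log-normal alternative is provided for
  simulating directly on a normalized continuous scale;
* independent Bernoulli zero-masking with probability `sparsity = 0.6` —
  plasma miRNA tables are mostly zeros;
* markers: `on_off_positive` / `on_off_negative` features are exactly zero
  in the "off" class and drawn zero-truncated around `effect` in the "on"
  class (a presence/absence marker is *detected* in the class that carries
  it, which is what makes `<= 0` rules exact); `fold_shift` features
  multiply the negative-class mean by `effect`.

The cohort sizes and feature count reproduce the study conditions; sparsity
and dispersion are not reported for the real data, so their defaults are
plausible-scale placeholders, exposed in the config and never asserted by
tests. One global seed drives labels, baselines, library sizes, masks and
counts through fixed substream offsets, so each component and each
compartment is independently reproducible; `generate_study()` offsets each
compartment's substream so compartments differ under one seed.

What the generator does **not** emulate: correlation between miRNAs
(features are independent given the library factor), compartment-to-
compartment correlation of the same feature, batch structure, or any
parameter fitted to the real cohort. Passing the planted-truth tests
therefore demonstrates that the machinery recovers class-conditional
structure of the planted kinds at realistic sparsity and depth — not that it
would attain any particular accuracy on real cohort data.

## Numerical and reproducibility choices

* Entropies and information gains are in bits; pure nodes have entropy 0 by
  convention (no 0·log 0 artifacts).
* All tie-breaks (tree splits, FOIL gain, ranking) are lexicographic and
  documented, so identical inputs give identical outputs on any platform.
* Feature ranking breaks equal scores lexicographically by feature id in the
  C locale (`method = "radix"`).
* Every stochastic stage (projections, tree splits, grow/prune splits, fold
  assignment) derives from explicit integer seeds through fixed substream
  offsets; `run_compartment()`/`run_study()` spread one user seed across all
  stages and echo the full configuration into their report bundles.
* Degenerate inputs are hard errors, not silent fixes: all-zero sample
  columns in normalization (dropping a sample would change CV
  stratification), missing rule features at prediction time, single-class
  label vectors where both classes are required. The one deliberate
  exception: a single-class *training* input to tree building or RIPPER
  yields the trivial leaf/empty ruleset, since that legitimately occurs in
  resampling.

The test suite exercises the full 19 × 1,509 cohort geometry where the
contract is about that scale (planted-marker recovery across 100 seeds,
cross-compartment overlap recovery) and smaller instances (up to a few dozen
features, ≤ 12-sample oracles) where the contract is arithmetic equality
with brute-force reimplementations; these sizes keep the whole suite at a
few minutes on one core while still covering the regime the pipeline is
designed for.

## Known limitations

* Binary classes only; multi-class rule induction and nominal attributes are
  out of scope.
* The MCFS significance cutoff used by some implementations (permutation
  based "informative feature" thresholds) is not implemented; top-k
  selection is explicit.
* `feature_selection_scope = "full_data"` reproduces the historical
  protocol's optimism; treat its accuracies as upper bounds.
* The RI ranking among several equally perfect discriminators depends on
  projection sampling (they compete for the same tree roots), so the order
  *within* a set of equivalent markers is not meaningful — membership in the
  top-k is.
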