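---
title: "Methods: physicochemical encoding, redundancy-aware selection and forest classification of bacterial promoters"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: physicochemical encoding, redundancy-aware selection and forest classification of bacterial promoters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promforest)
```

promforest classifies fixed-length DNA windows as promoter or non-promoter.
This vignette explains the model behind each stage, the tunable parameters
and their defaults, the numerical choices made where the procedure was
genuinely open, what the simulator does and does not emulate, and the known
limitations.

## The statistical-parameter encoding

Promoter activity depends on how the double helix deforms and interacts
with RNA polymerase and sigma factors, which is captured at the dinucleotide
level by published physicochemical property collections: each of the 16
dinucleotides receives $K$ numeric descriptors (twist, rise, slide,
hydrophilicity, ...; $K = 90$ in the collection this package is designed
around). A window $s$ of length $L$ is read as its $L-1$ overlapping
dinucleotides $a_1 \dots a_{L-1}$, and each $a_i$ is replaced by five
statistical parameters of its property row:

$$a_i \mapsto (p_{\min}, p_{\max}, p_{\text{mean}}, p_{\text{var}}, p_{\text{sum}}),$$

concatenated position-major into a $5(L-1)$-dimensional vector — 400
features for the 81 bp windows used throughout. The encoding is a pure
positional lookup: at most 16 distinct 5-vectors can occur, and feature ids
(`pos017_var`) make the layout auditable.

Two choices here were open and are exposed as flags on `dinuc_stats()`:

* **Variance form.** "Variance" alone does not fix a denominator. The
  default is the population form (denominator $K$), the descriptive-
  statistics reading: it makes a constant property row have variance
  exactly 0, which the degenerate-input tests rely on. `variance =
  "sample"` switches to $K-1$ for sensitivity analysis.
* **Property standardization.** By default the statistics summarize the
  properties as distributed in the table, since the spread across
  dinucleotides is itself the signal. Because some distributed property
  tables ship pre-normalized, `standardize = TRUE` z-scores each property
  column across the 16 dinucleotides first.

## ANOVA F + first-level clustering selection

Neighbouring positions share a base, and many physicochemical properties
are mutually correlated, so the 400 features are heavily redundant.
Selection combines a relevance score with a redundancy structure:

1. **Relevance.** Each feature gets the two-group one-way ANOVA F value
   $F = MS_{\text{between}} / MS_{\text{within}}$ with df $(1, n-2)$.
   Degenerate features are handled explicitly: a feature constant across
   all samples gets $F = 0$ with a warning; a feature with zero
   within-class scatter but distinct class means gets $F = +\infty$, which
   outranks every finite value (two infinities tie). Zero is detected
   relative to the feature's mean square, since a column of identical
   values accumulates floating-point noise of order $10^{-16}$.
2. **Redundancy.** The feature columns are clustered agglomeratively. A
   *first-level pair* is a merge whose two children are both original
   features; every feature not in such a merge is a singleton. This
   structural reading — rather than cutting the dendrogram at a fixed
   cluster count — is what makes pairs and singletons partition the
   features and gives the invariant $|\text{retained}| = d - |\text{pairs}|$.
3. **Retention.** From each pair the larger-F member survives; exact ties
   are broken by a seeded uniform choice recorded in the result. Singletons
   are kept directly.

The clustering configuration was not fully determined by the procedure's
description, so all three axes are parameters with documented defaults:

* **Linkage and metric** default to Ward linkage (`hclust` method
  `ward.D2`) on Euclidean distance — the default of the common
  agglomerative-clustering implementations in this literature — with
  complete/average/single linkage and correlation distance available.
* **Feature scaling** before clustering defaults to ON (z-score each
  feature across samples). The five statistics live on wildly different
  scales — sums are roughly $K$ times means — so unscaled Euclidean
  distance would pair features almost exclusively by statistic type rather
  than by information content. This is the largest replication risk of the
  whole pipeline and is therefore recorded in every selection report;
  `scale_features = FALSE` disables it. Constant features are centred
  only, avoiding 0/0.

The full selection pipeline is cross-checked in the test suite against a
naive $O(d^3)$ Lance–Williams agglomerative oracle plus a textbook
per-column ANOVA, on random matrices up to $d = 12$.

## The forest and its search space

A random forest with Gini impurity splits fits the heterogeneous,
mixed-scale feature distributions without any further normalization. Five
hyperparameters are tuned by full factorial grid search — trees 80–150 in
steps of 5, depth 15–20, minimum terminal-node size 1–8, minimum split size
2–5, and the fraction of features tried per split 0.1–1 in steps of 0.1
(28,800 combinations) — each evaluated as the mean over stratified
five-fold cross-validation. Choices made where the procedure was open:

* **`max_features` as a fraction.** A sub-unit value conventionally means a
  fraction of the feature count; `mtry = ceiling(fraction * d)`.
* **Objective.** Accuracy (the headline metric of this literature) by
  default; MCC and AUC are selectable.
* **Tie-break.** Exact objective ties go to fewer trees, then shallower
  depth, then lexicographic order on the remaining axes — deterministic.
* **Seeding.** The forest engine is seeded, per-fold refits share the
  combination's seed, and the pipeline derives fixed per-stage sub-seeds
  from one master seed, so any run is reproducible end to end.
* **Scores.** A sample's score is the fraction of trees voting promoter
  (obtained from per-tree votes, not averaged leaf probabilities), and the
  label threshold is 0.5, so labels and scores are always consistent.

The engine is `ranger`, the only installed forest implementation exposing
all five axes (`num.trees`, `max.depth`, `min.bucket`, `min.node.size`,
`mtry`) with Gini splits and a seed.

## Evaluation protocol

From confusion counts (TP, FP, TN, FN): Sn = TP/(TP+FN), Sp = TN/(TN+FP),
Acc = (TP+TN)/n, and MCC with the usual four-margin denominator, defined as
0 (logged) when a margin is zero. Reports print the field's two-decimal
percentages — including MCC — while machine output keeps fractions. The ROC
curve sweeps a threshold across the unique scores; tied scores move the
curve diagonally, so the trapezoidal AUC equals the probabilistic
$P(\text{score}_+ > \text{score}_-) + \tfrac12 P(=)$, which the tests
verify against an exhaustive pairwise oracle. Cross-validation reports one
metric row per fold plus the arithmetic mean of folds (not the pooled
confusion matrix) as the summary row; because it is unspecified whether a
">95% AUC" style summary refers to per-fold or pooled curves, both per-fold
AUCs and the pooled-score AUC are emitted.

The train/independent split is stratified per class — the 8:2 split of a
1,000 + 1,000 benchmark yields 800 + 800 and 200 + 200, which a pooled
split would only match in expectation — with a fractional extra record
going to training.

## What the simulator emulates — and what it does not

`simulate_promoter_dataset()` emulates the promoter/background contrast:
negatives are i.i.d. draws from a background base distribution (uniform by
default; `cg_background()` gives a 53.8% G+C composition typical of the
*C. glutamicum* genome), and positives carry a planted consensus box
(default TATAAT, a canonical −10 element) at a fixed offset (default 66 in
an 81 bp window, i.e. near the 3' end where the transcription start would
sit), each motif base emitted with probability `match_prob` (default 0.95)
and otherwise replaced by one of the other three bases uniformly. Setting
`match_prob = 0.25` under a uniform background makes the planted positions
exactly background — a null dataset on which cross-validated accuracy sits
at chance, which the tests assert at 50% ± 5% on 400 samples.

Real promoters are not this: they mix several sigma-factor classes with
variable spacer lengths, positional jitter, a −35 element, UP elements and
genome-wide compositional structure, and real negatives are genomic
fragments with their own repeat and coding-sequence biases. Passing the
end-to-end tests therefore shows that the pipeline recovers a planted
positional signal under controlled conditions — not that it attains any
particular accuracy on real genomes. `simulate_property_table()` likewise
stands in for curated property collections with seeded Gaussian draws
(per-dinucleotide location ~ N(0, spread), values ~ N(location, scale)),
plus constant-row and duplicate-row pathological variants for encoder
tests; it reproduces the shape of such tables, not their measured values.

## Problem sizes and numerical notes

The shipped tests and the acceptance script run everything at desk scale,
chosen so the full suite completes in well under a minute: simulated sets
of 200 + 200 training samples (an 8:2 split of 250 + 250) with the full
$K = 90$ table for the end-to-end checks, and a reduced corner grid — the
extreme values of trees, depth and feature fraction with the smallest node
sizes — standing in for the 28,800-combination search, whose cardinality is
asserted separately. The full grid remains available behind
`rf_param_grid()` defaults and the CLI's `--full-grid`.

Other numerical details: property-table orientation is auto-detected by
locating the line or column containing at least 12 of the 16 dinucleotide
tokens, so transposed files parse identically; feature matrices are
validated for finite values and exact feature-id agreement before any
selection or prediction is applied (misaligned columns are an error, and
prediction realigns permuted columns by name); serialized models carry a
JSON sidecar with an order-sensitive hash of the training feature ids,
checked on load.

## Known limitations

* Exact bit-level replication of any externally published feature subset
  may require toggling the documented flags (variance form,
  standardization, linkage, metric, scaling), since those choices are not
  fixed by the method's description; the defaults are one documented
  reading.
* Only dinucleotide (k = 2) encodings are implemented; no pseudo-nucleotide
  composition variants, reverse-complement augmentation, or multi-class
  ANOVA.
* The selector removes at most one member per first-level pair; it never
  prunes recursively, so strongly correlated triples keep two members.
* Comparison classifiers (KNN, SVM, MLP) are out of scope; the package
  evaluates only the forest pipeline.
```{r example}
seqs  <- simulate_promoter_dataset(n_pos = 100, n_neg = 100, seed = 1)
props <- simulate_property_table(K = 90, seed = 2)
run <- run_promoter_pipeline(seqs, props,
  grid = rf_param_grid(c(80, 150), 15, 1, 2, 0.5), seed = 3)
glance(run)
```
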