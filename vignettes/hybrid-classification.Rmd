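---
title: "Hybrid cluster-routed classification of gene sequences: model, design decisions and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid cluster-routed classification of gene sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridseq)
```

## The model

`hybridseq` classifies nucleotide sequences whose classes are internally
heterogeneous — each class hides latent subgroups, and some subgroups'
sequence composition leans toward the other class. The motivating setting
is disease-gene classification, where a class such as "genes of conditions
co-occurring with an autoimmune disorder" aggregates genes of many distinct
diseases. The pipeline has five phases:

1. **Featurization.** Each sequence becomes its k-mer frequency vector
   (default k = 3, 64 features; stride-1 sliding window; windows containing
   symbols outside A/C/G/T are skipped rather than expanded or the
   sequence dropped, so partially ambiguous records keep their usable
   signal). Frequencies rather than raw counts are the default because
   sequences have unequal lengths. Reverse-complement (canonical)
   collapsing to 32 classes is available but off by default.
2. **Scaling and projection.** Min-max scaling to [0, 1] with training-set
   statistics; a test value outside the training range maps outside [0, 1]
   and is *not* clipped. A feature constant in training maps to 0,
   avoiding a zero denominator without dropping samples. Optionally, a
   Fisher linear discriminant projection to at most (classes − 1)
   dimensions follows. The scaling-then-projection order is one of two
   defensible orders; the Fisher criterion is invariant to per-feature
   affine rescaling, so the choice is benign, and both stages are
   independently togglable.
3. **Probability computation.** A weight-decay-regularised multinomial
   logistic model scores every training sample with a class-probability
   vector. The default scores the same rows the model was fitted on
   (`in_sample`), matching the sequential construction of the method;
   `out_of_fold` (5-fold cross-fitted) is available to avoid scoring seen
   rows.
4. **Clustering and label augmentation.** k-means partitions the
   probability vectors; the cluster count is chosen by maximising the mean
   silhouette width over a configurable range (default 2–8), ties going to
   the smaller count. Each training label is then refined to a composite
   (class, cluster) code — an invertible encoding, so the code
   simultaneously carries the class and the routing target.
5. **Bridge and per-cluster ensembles.** An SVM fitted on the composite
   codes predicts a code for each test sample; the code's cluster
   component routes the sample to that cluster's ensemble, where every
   learner of the chosen combination (subset of SVM, RF, LR, KNN, MLP)
   was fitted on the cluster's rows. The ensemble soft-votes: unweighted
   mean of per-learner class-probability vectors (learners that cannot
   emit probabilities contribute a one-hot vote), argmax with
   lowest-index tie-break. Majority (hard) voting is available as
   configuration.

The working hypothesis is that the probability vectors of a moderately
regularised classifier carry *within-class geometry*: samples of the same
latent subgroup receive similar probabilities, so clustering them exposes
the subgroups, and per-subgroup models are easier problems than the global
one. With `cluster_range = c(1, 1)` the whole construction collapses, by
design, to a plain soft-voting ensemble of the same combination — a
property the test suite checks exactly, and the natural baseline
(`fit_softvote()`) for every benchmark row.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k` | 3 | k-mer length (1, 2, 3, 5, 6 supported in the sweep) |
| `cluster_range` | [2, 8] | candidate cluster counts for silhouette selection |
| `min_cluster_size` | 5 | clusters smaller than this merge into the nearest centroid |
| `combination` | RF-LR-KNN-MLP | per-cluster base learners |
| `probability_source` | in_sample | Phase-2 scoring mode |
| `lr$decay` | 1e-4 | Phase-2 logistic weight decay (but see the study note below) |
| `voting` | soft | Phase-5 combiner |
| base learners | RBF SVM (C = 1), 100-tree RF, L2 LR, k = 5 KNN, 8-unit MLP | overridable per learner, or tuned |

Hold-out evaluation uses an unstratified random 60/40 split;
cross-validation uses 5 folds (sizes differing by at most one). Both are
deterministic given a seed, and every stochastic stage of a fit derives
its own stream from the single configuration seed, so a fit is exactly
reproducible.

## The synthetic generator

`synthetic_spec()` emulates a curated disease-gene dataset that cannot be
distributed: `n_classes` observed classes, each split into
`subgroups_per_class` latent subgroups, `samples_per_subgroup` i.i.d.
multinomial sequences per subgroup (defaults 2 × 2 × 60 sequences of
2 kb — a curated-gene-set scale). Subgroup base compositions sit at evenly
spaced positions on [−1, 1] along the composition direction
(+A, −C, +G, −T), scaled by `divergence`; consecutive positions alternate
classes. Consequences, all exercised by the tests:

* expected 3-mer profiles separate monotonically in `divergence`, and
  `divergence = 0` collapses every subgroup onto the base composition, so
  classifier accuracy falls to chance;
* classes interleave: each class has one subgroup on the other class's
  side of the axis, so no single linear boundary separates the classes —
  the "opposing within-class signal" regime the hybrid targets. A plain
  logistic ensemble stays near 0.5–0.7 accuracy on these data while the
  hybrid, routing each subgroup to its own (often single-class) cluster
  ensemble, reaches ≈ 1.0 at the default divergence.

What the generator does **not** emulate: codon and gene structure,
length variation, phylogenetic correlation between sequences, and
class-imbalance effects. Passing tests therefore demonstrate the
machinery's correctness and the claimed qualitative behaviour on
composition-structured data, not performance on real gene sets.

## Study conditions and two load-bearing numerical choices

The reference conditions for the subgroup study (`study_config()`,
`run_study()`) are the four-learner RF-LR-KNN-MLP combination on the
default generator, with two deliberate settings:

* **No discriminant projection** (`fit_hybrid(..., n_components = 0)`).
  A Fisher projection to (classes − 1) dimensions *minimises within-class
  scatter* — and the latent-subgroup signal **is** within-class scatter.
  Empirically, fitting the projection on the default generator compresses
  the within-class subgroup gaps to the noise floor (and, at k-mer
  dimensionalities comparable to the sample count, overfits: the training
  projection separates classes while the test projection does not), after
  which Phase 3 can only rediscover the classes themselves. The
  projection is therefore beneficial for between-class discrimination on
  homogeneous classes but structurally at odds with subgroup discovery;
  the subgroup study runs without it. This interaction is, to our
  knowledge, the main practical caveat of the five-phase design.
* **Phase-2 decay = 5.** With a weakly regularised logistic model on
  near-separable classes, the probability vectors saturate at 0 and 1 and
  the within-class clumps collapse against the rails, where silhouette
  selection sees only the two class blobs. Substantial weight decay keeps
  the logistic map in its graded regime, in which the probability clumps
  of the four planted subgroups stay evenly spread and silhouette
  selection recovers the planted count (4) in every seeded replicate.
  The package-wide default stays at 1e-4 (a probability model should
  saturate on genuinely separated data); the large decay is a property of
  the *study*, documented here, not a hidden global.

Problem sizes were likewise fixed once: 240 sequences of 2 kb give
per-feature multinomial noise small enough that adjacent subgroup clumps
are ≈ 4 standard deviations apart at the default divergence 0.3; the
study's conclusions are stable across seeds at this size.

## Numerical choices

* **Within-class scatter ridge.** k-mer frequency tables are exactly
  collinear (rows sum to 1), so the within-class scatter matrix can be
  singular; when its reciprocal condition number falls below 1e-12, a
  ridge `1e-6 · trace(Sw)/d` is added. Discriminant directions are
  normalised to unit length with the first nonzero coefficient positive,
  making the fit deterministic up to numerical noise.
* **Silhouette ties and argmax ties** resolve to the smaller cluster count
  and the lowest class index respectively — determinism over elegance.
* **k-means** uses 10 random restarts per candidate count under a derived
  seed. (A k-means++ initialisation would be a drop-in improvement; the
  restart scheme was chosen because it is what `stats::kmeans` provides
  and it selects the planted count reliably in the study conditions.)
* **0/0 metric denominators** (e.g. precision with no positive
  predictions) yield 0 with a warning rather than NaN, keeping benchmark
  tables stable.
* **Degenerate guards.** A single-class cluster gets a constant predictor
  with a one-hot vote; a single composite code makes the bridge a
  constant router; a sequence with zero valid k-mer windows gets a zero
  row with a warning rather than NaN.
* **Bayesian optimisation** uses a Gaussian-process surrogate with a
  squared-exponential kernel on unit-cube-encoded parameters (fixed
  lengthscale 0.25, small nugget) and expected-improvement acquisition
  over a 500-point random candidate pool, seeded Latin-hypercube initial
  design. The fixed-lengthscale surrogate avoids fitting GP
  hyperparameters inside the loop; with the budgets involved (default 25
  evaluations) this is accurate enough to land within 5% of a dense-grid
  optimum on smooth objectives, which the tests verify.

## Statistical comparison of classifiers

Two classifiers evaluated on the same test set of size n are compared by
the pooled two-proportion statistic
`Z = (a − b) / sqrt(2 p̄ (1 − p̄) / n)`, `p̄ = (a + b)/2`, two-sided, with
|Z| > 1.96 significant at the 95% level, and by the 2 × 2 χ² test on
correct/incorrect counts without continuity correction, df = 1, critical
value 3.841. These are the standard constructions consistent with those
critical values; both degrade gracefully (statistic 0) when the margins
are degenerate. The benchmark attaches, per combination arity, the tests
of every plain ensemble against the best hybrid of that arity. Note that
with a shared test set the two classifiers' errors are correlated, so the
two-proportion Z (which assumes independent samples) is conservative in
some regimes and anticonservative in others; McNemar's test on the
discordant pairs would be the sharper choice and is a natural extension.

## Known limitations

* The composite-label reading of "combining" original and cluster labels
  — bridge on (class, cluster) pairs, class re-predicted within the
  routed cluster — is one defensible interpretation; using the bridge's
  own class component as the final output, or feeding cluster ids as
  extra *features*, are plausible alternatives not implemented.
* Clustering is global over all training probability vectors, not
  within-class; with strongly imbalanced classes a global silhouette can
  hide small-class subgroups.
* The discriminant projection versus subgroup-discovery conflict above
  means the full default pipeline (with projection) should be preferred
  only when classes are believed homogeneous.
* `in_sample` probabilities leak training fit into Phase 3;
  `out_of_fold` mitigates this but makes the probability geometry
  noisier. Both are exposed; neither is uniformly better in the study
  conditions.
* Multi-class operation is supported throughout (one-vs-rest confusion
  matrices per designated positive class), but the study fixtures are
  binary; multi-class subgroup recovery is untested beyond unit level.
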