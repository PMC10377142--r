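---
title: "Triple-association tensor completion: models, protocol and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triple-association tensor completion: models, protocol and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tritensor)
```

## The problem

Drug repositioning asks which existing drugs might treat which diseases.
Because drugs act by binding gene products and diseases arise from gene
dysfunction, the drug–disease question is naturally mediated by genes.
`tritensor` models the three entity types jointly: a binary three-way
tensor `X` of shape drugs × genes × diseases has `x[i, j, k] = 1`
exactly when drug *i* treats disease *k*, drug *i* binds gene *j*, and
gene *j* is implicated in disease *k* — a closed triangle across the
three bipartite association networks.  Known triangles are vanishingly
sparse, so predicting new ones is a tensor completion problem, and the
latent factors learned along the way double as entity representations
for predicting the three pairwise association types.

## Scoring models

The classical CP decomposition approximates each cell by a sum of
rank-one terms, `x[i,j,k] ≈ Σ_r a[i,r] b[j,r] c[k,r]`.  The package's
generalized tensor decomposition (GTD) head keeps the element-wise
factor product but learns an output weight vector `h` and applies a
sigmoid:

    score(i, j, k) = σ( h' (a_i ⊙ b_j ⊙ c_k) )

Setting the activation to the identity and `h = 1` recovers CP exactly;
this degenerate case is pinned down by a test that reconstructs an
exact rank-8 synthetic tensor to `< 1e-6`.

The MLP path transforms each role's latent vector through its own tower
of fully connected layers (default widths `2r → r → r/2`, widest at the
bottom) before the same product-and-project head.  The ensemble keeps
separate embedding and fusion parameters per path and concatenates the
two interaction vectors — `a ⊙ b ⊙ c` from the GTD path, the product of
tower outputs from the MLP path — before a single output layer of
length `r + r/2`.  Concatenation (rather than averaging) preserves each
path's gradients and lets the output layer arbitrate between them.
Whether fusion layers could be shared between the paths is genuinely
open; they default to unshared because sharing couples the paths'
optimization in a way that is hard to reason about, and the ensemble
owns its output weights rather than reusing either path's.

Entity inputs fuse two feature sets: a learned ID embedding (dimension
`r` by default) and the entity's row of a fixed similarity matrix.  One
affine layer per role maps the concatenation to the shared latent size
`r`.  The similarity row is what rescues cold-start entities: a drug
with no training associations still has chemical/therapeutic neighbors,
and the fusion layer learns to construct its latent vector from them.
ID embeddings of cold entities are never updated by training and stay
at their small random initialization; this is inherent to the method,
not a defect, and is why informative side information matters.

## Similarity kernels

Two bespoke kernels provide the side information when precomputed
matrices are not supplied:

* **ATC similarity.**  WHO ATC codes have five cumulative levels
  (`N02BA01` → `N`, `N02`, `N02B`, `N02BA`, `N02BA01`).  For each level
  the kernel takes the Jaccard index of the two drugs' level-prefix
  sets (drugs may carry several codes) and averages over the five
  levels.  Sharing through level k therefore guarantees a similarity of
  at least `k/5` for single-code drugs.

* **Ontology semantic similarity.**  Terms of a DAG-structured ontology
  (Gene Ontology for genes, phenotype ontologies for diseases) get
  information content `IC = −log P`, where `P` is the fraction of
  annotated entities carrying the term after propagating annotations to
  all ancestors; the root always has `IC = 0`.  Term–term similarity is
  the IC-ratio over shared versus united ancestor sets; ancestor sets
  include the term itself, since otherwise a term would not be
  maximally similar to itself.  Entity–entity similarity is the
  best-match average over the two annotation sets.  The printed IC-ratio
  can be written with `log P` in numerator and denominator; the package
  sums `−log P` in both so each sum is non-negative — the signs cancel
  and the value is identical, and the natural log is used since the
  ratio is base-invariant.  Annotations with evidence code `IEA` or a
  `NOT` qualifier are dropped by default when those columns are
  present.  Gene similarity is conventionally computed on the
  biological-process and molecular-function sub-ontologies separately;
  `combine_subontology_similarities()` averages the per-sub-ontology
  scores for pairs defined in both, uses the defined one otherwise, and
  scores 0 when neither defines the pair — the combination rule is not
  canonical, and averaging was chosen as the symmetric option.
  Restricting a corpus to a sub-root (`roots =`) is also how phenotype
  similarity is limited to an abnormality subtree.  A pair whitelist
  (e.g. a protein-interaction edge set) restricts which gene pairs are
  computed; non-listed pairs are 0 rather than missing, which keeps the
  matrix a valid model input.

## Training protocol

The tensor's non-positive cells are unlabeled, not confirmed negatives.
The protocol samples `α` negatives per positive (default `α = 10`)
uniformly without replacement from the free cells, once per experiment:
re-sampling per epoch would make fold membership of a negative
ill-defined.  `α` is read as "negatives per positive" throughout; the
default of 10 is also where a sweep over `α` can be centred with
`sweep_hyperparameters()`.

Cross-validation is entity-wise on the chosen side (drugs or diseases):
entities are sorted by decreasing positive count and greedily assigned
to the currently lightest of 10 folds, which bounds the spread of
positives between folds by the largest single-entity count.  All of an
entity's triples — positive and negative — follow it, so a test fold's
entities contribute nothing to training: every evaluation is cold
start.  Fold *t* tests, fold *t*+1 (cyclically) provides the validation
set, and the remaining eight train.

Training minimizes binary cross-entropy (the natural likelihood for a
sigmoid output over binary labels) with full-batch Adam.  Defaults and
their reasons:

* `lr = 0.01`.  Full-batch gradients are low-variance; at `1e-3` the
  validation AUC is still climbing when the epoch cap is reached.
  At `0.1` optimization saturates the sigmoid and collapses.
* `max_epochs = 200`, `patience = 10` on validation AUC (the selection
  metric, not the loss), best-validation weights restored.
* `min_epochs = 100` burn-in before early stopping may fire.  Cold-start
  validation AUC transiently *dips* — often well below 0.5 — during the
  first tens of epochs while the ID embeddings overfit the training
  entities faster than the fusion layer learns the similarity mapping;
  without a burn-in, a lucky epoch-1 validation value gets frozen.
* Glorot-uniform weight initialization, ID embeddings uniform in
  (−0.05, 0.05), all seeded; a fixed seed reproduces folds, negatives,
  the loss trace and the final metrics bit-for-bit on a single thread.
* Hidden activations are leaky ReLU (slope 0.01) rather than plain
  ReLU, and rectified layers start with bias 0.1.  With plain ReLU at
  small ranks, an entire latent column can be inactive for every entity
  at initialization; the ReLU gate then zeroes its gradient exactly and
  the optimizer sits at a saddle forever (observed as a loss pinned at
  log 2).  The leaky slope removes the trap; the positive bias makes it
  rare to begin with.

## Ranking metrics

AUC uses the rank (Mann–Whitney) formulation with ties counted ½, and
the exported ROC points collapse tied scores into single steps so the
trapezoid over the curve equals the rank AUC to numerical precision.
NDCG@n discounts binary relevance by `1/log2(rank + 1)` and normalizes
by the ideal ordering; an all-irrelevant list scores 0 by convention.
Because the method's framing is "rank candidates for a new drug", NDCG
is computed per sided entity — each test drug's candidate triples form
one ranked list — and averaged over entities with at least one
positive; a single pooled list is available via `grouping = "global"`.
Ties in NDCG ranking are broken by stable order.

## Pairwise prediction

Latent vectors from triple training score pairs by inner products
(`pairwise_scores()`).  The raw product of two roles' latents, however,
ignores both the learned output weights `h` and the absent third role
entirely, and on the planted benchmark it performs at or below chance.
`predict_pairwise()` therefore defaults to a *marginal* weighting: the
first role's latents are scaled by `h ⊙ mean-latent-of-absent-role`
before the product.  This is exactly how a pair matrix is derived from
a CP decomposition — `A diag(λ) B'` with `λ` absorbing the third mode —
and it matches full marginalization of the model over the absent role
(mean predicted probability) to within a few AUC points while remaining
a pure inner product.  The raw product is kept under
`weighting = "none"`.  For the ensemble, both paths' latents are
concatenated by default, mirroring the ensemble's merge; one path can
be selected with `path =`.  Pairwise evaluation ranks *all* unknown
counterpart entities as negatives (no subsampling — the pair matrices
are small) for the cold-start entities of the chosen test folds.

## The synthetic benchmark

`generate_planted_tensor()` draws sparse non-negative CP factors, marks
the top-`n` CP-scoring cells positive (ties broken in lexicographic
(i, j, k) order, so the planted set is well-defined even for constant
tensors), and optionally replaces a fraction of positives with random
cells as label noise.  Side information is the cosine similarity of the
ground-truth factor rows, so the similarity matrices are informative
about the planted structure in the same way real chemical or phenotype
similarity is assumed to be informative about real associations;
`informative_sims = FALSE` provides the uninformative control for
ablations.  `generate_toy_ontology()` (complete tree plus random DAG
cross-edges, entities annotated to leaves) and `generate_toy_atc()`
(code families sharing prefixes through a controlled level) exercise
the similarity kernels, and the generators write the same TSV/OBO
dialects the readers parse, which is round-trip tested.

What the generator does *not* emulate: real association networks have
heavy-tailed degree distributions, correlated missingness, and
similarity matrices that are noisy and partially redundant with the
associations; identifiers, evidence codes and ontology scale are all
idealized.  Passing the recovery tests therefore shows the machinery is
correct and that the models exploit informative side information in
cold start — it does not certify accuracy figures on any real dataset.

## Problem sizes and runtimes

The recovery benchmark used by the tests and the acceptance script is a
50 × 80 × 40 tensor of planted rank 4 with 300 positives, `α = 10`,
noiseless, drug-side cold start on one test fold of ten, five (tests)
or three (script) replicate seeds — sizes chosen so the whole suite
runs in about a minute on one core while leaving the learning problem
non-trivial (the test fold's drugs are entirely unseen).  Statistical
claims are deliberately modest at this scale: each model's held-out AUC
must beat its permuted-label null on every replicate (sign test), the
ensemble's mean AUC must not trail either path by more than 0.02, and a
rank-1 model must underperform the rank-4 model on the rank-4 tensor.

## Known limitations

* Entities indexed internally by integer position (1-based, as is
  natural in R); external identifiers appear only at I/O boundaries.
* Gradient computation is hand-written; it is verified against central
  finite differences in the tests, but exotic activation choices
  supplied as raw functions have no analytic gradient and are rejected
  by training (they remain usable for forward scoring).
* The full-batch optimizer holds the feature matrix of every training
  triple in memory; at the scale of real pharmacological databases a
  mini-batch variant would be required.
* The optional gene-degree preprocessing filter (drop genes below a
  minimum association degree before triangle closure) defaults to off;
  whether such filtering precedes or follows triangle closure changes
  the tensor and should be an explicit analysis decision.
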