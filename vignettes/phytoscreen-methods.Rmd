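---
title: "phytoscreen: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{phytoscreen: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytoscreen)
```

## The screening problem

Natural compounds — phytochemicals, vitamins, secondary metabolites — are
annotated far more sparsely than approved drugs: targets are partially
known, structures are sometimes missing, and the literature is thin for
rare compounds. `phytoscreen` treats indication prediction as a set of
independent per-disease binary classification problems over a heterogeneous
686-column feature vector per compound, trained on drugs with verified
indications and applied to natural compounds. The underlying assumption is
transferability: a compound resembling indicated drugs across several
complementary information channels is more likely to share their effects,
and channels can compensate for each other where one is incomplete.

## Feature blocks

**Latent knowledge (300 columns).** Compound names are preprocessed
(lowercasing, Greek-letter transliteration such as α → alpha, splitting on
punctuation while preserving intra-word hyphens) and resolved against a
pre-built word-vector table in the word2vec text dialect. In-vocabulary
tokens use their stored vector; out-of-vocabulary tokens fall back to the
mean of their character *n*-gram vectors (range 3–6 with `<`/`>` boundary
markers, the sub-word embedding convention). Two deliberate choices differ
from the sum used at sub-word training time: n-gram vectors are *averaged*,
and multi-word names are *averaged* over word vectors. Averaging keeps the
vector norm comparable between in- and out-of-vocabulary names and across
name lengths, which matters because downstream layers see all compounds in
one batch; it also makes composition invariant to word order, which the
test suite asserts. Embedding quality can be profiled against the ATC
hierarchy (`atc_similarity_profile()`): within-group cosine similarity
should exceed a size-matched random baseline and increase with ATC depth.

**Molecular interaction (285 columns at full scale).** The restart walk

$$p_{t+1} = (1-r)\,W^{\top} p_t + r\,p_0$$

propagates a compound's target profile over the interaction network, with
`W` the column-normalized adjacency, restart probability `r = 0.7`, and L1
convergence tolerance `1e-8` (capped at 1000 iterations; the geometric
contraction factor `1 - r` makes convergence fast). Seeds are weighted 1.0
(direct binding) and 0.3 (indirect: expression changes, active-metabolite
effects) and then normalized to a probability vector — the walk formalism
requires one, and normalization preserves the 10:3 evidence ratio.
Zero-degree columns are left all-zero rather than teleported: the restart
term re-injects the lost mass and no artificial uniform jump is
introduced. The stationary vector is restricted to the disease-related
protein list and reduced by PCA, keeping the smallest component count
whose cumulative explained variance reaches 0.8. The reduction (like the
descriptor scaling below) is fitted on *training rows only* and applied to
held-out rows with the stored center and basis — at full data scale this
means fitting on drugs and projecting natural compounds — so no test-set
statistics leak into the features.

**Chemical properties (101 columns in the default schema).** Descriptor
columns are typed: physicochemical columns (molecular weight, heavy atoms,
fraction Csp3, rotatable bonds, H-bond acceptors/donors, molar
refractivity) are Z-scored with training-set mean and sample (n−1) SD;
log-scale predictions (log P estimators and their consensus, solubility
estimators, skin permeability, synthetic accessibility) pass through
unchanged; categorical pharmacokinetics, drug-likeness and
structural-alert descriptors are one-hot encoded over enumerated
categories. The exact category counts of the published 101-column layout
are not recoverable, so the default schema is configuration, not contract:
`descriptor_schema()` accepts any layout and the encoder derives its width
from the schema. Constant training columns are dropped with a warning
(they cannot be standardized); unseen categories at encoding time are
errors, because silently extending a one-hot basis would desynchronize the
model's input layout.

## The partially connected network

One model per disease. The first two hidden layers are *partially
connected*: the weight matrix is masked block-diagonally so a hidden unit
receives input only from its own feature block. Per-block first-layer
widths are 200/160/68 (latent/interaction/chemical) at full scale, giving
`300·200 + 285·160 + 101·68 = 112,468` trainable edges against
`686 · 428 = 293,608` for a dense layer — the partial structure trains
roughly 38% of the dense edge count, which is what makes the model fit
trainable from a few thousand drugs. The published width of the middle
dense comparison appears once as 190 and once as 160; the package adopts
160 for the masked layer and reports both partial and dense counts from
`count_partial_edges()` so the arithmetic is explicit. The second partial
layer reuses the per-block widths (unstated in the original description;
reuse keeps the parameterization minimal), after which block outputs are
concatenated and passed through two fully connected layers — 256 and 64 at
full scale, configurable, and 32/16 at fixture scale — and a sigmoid unit.

Numerical and training choices:

* **Initialization**: zero-mean Gaussian with SD `sqrt(2/n_l)` (He
  scaling for ReLU), where `n_l` counts the *unmasked* fan-in of each
  unit — a masked unit sees only its block, so its variance budget must be
  computed over that block.
* **Batch normalization** after each affine transform, before ReLU.
  Running statistics for inference are bias-corrected exponential moving
  averages (momentum 0.9, divided by `1 − 0.9^t`): with only a couple of
  minibatches per epoch at desk scale, a plain EMA initialized at (0, 1)
  produces meaningless validation losses in the first epochs, which can
  trip early stopping before training has started.
* **Loss**: class-weighted binary cross-entropy, summed form
  `−Σ [w₀ y log ŷ + w₁ (1−y) log(1−ŷ)]` with probabilities clipped at
  1e-7; class weights `N/(2·N_c)` are inversely proportional to class
  frequencies. The printed form of this loss pairs `w₀` with the positive
  term while the accompanying text labels `w₀`, `w₁` as weights "for class
  1 and 0"; the package follows that labelling (the positive class gets
  the larger weight, which is the entire point of imbalance correction)
  and exposes `swap_class_weights` for the reversed pairing.
* **Optimization**: Adam (lr 1e-4, β₁ 0.9, β₂ 0.999, ε 1e-8), batch size
  64, max 3000 epochs, early stopping on validation loss with patience 30
  and best-epoch restoration. Masks are re-applied to weights (and their
  gradients) after every update, so masked entries are *exactly* zero at
  every checkpoint — `mask_violation()` verifies this invariant.
* **Determinism**: a fixed `train_config(seed=)` drives initialization,
  the internal stratified split and batch shuffling, so training histories
  are bit-identical across reruns on one thread.

## Network-proximity baselines

Five shortest-path summaries between a compound's target set T and a
disease gene set G serve as non-learned baselines: closest (mean over T of
the distance to the nearest gene), shortest (mean over all pairs), kernel
(`−(1/|G|) Σ_g log[(1/|T|) Σ_t e^{−(d+1)}]`, downweighting long paths
exponentially), centre (mean distance to the disease gene with maximal
closeness centrality, ties broken lexicographically), and separation
(between-set nearest-neighbour mean minus the average of the two
within-set nearest-neighbour means, negative when the sets interpenetrate).
The formulas are frozen here because the originals are described only
verbally; they follow the established network-medicine proximity
literature. Unreachable pairs are excluded from means rather than imputed
(this only affects disconnected graphs; an error is raised when nothing is
reachable). For ranking, distances are negated so that "higher = stronger
prediction" holds for every method; all five agree with brute-force BFS
oracles on random graphs in the test suite.

## Evaluation and literature statistics

Splits are 6:2:2 train/validation/test (label-stratified by default, since
positives are rare) with k-fold cross-validation available; AUROC uses the
rank-based Mann-Whitney formulation with midranks, and accuracy thresholds
at 0.5. The literature validation takes the top-ranked 10%, bottom-ranked
10% and a size-matched random set of (compound, disease) cells (global
score ranking, ties broken by compound then disease id), then compares
document co-occurrence counts, Jaccard indices and one-sided Fisher's
exact enrichment p-values (hypergeometric tail; significance threshold
0.001) across the three sets, with two-sided Mann-Whitney U tests between
sets. The Mann-Whitney p-value is computed by exhaustive midrank
permutation enumeration when the pooled sample is below 20 (ties handled
exactly) and by the tie-corrected normal approximation with continuity
correction above. Term matching in the literature index is exact
contiguous-token matching after preprocessing; synonym expansion is out of
scope.

## What the synthetic generator emulates — and what it does not

The fixture study conditions (defaults of `fixture_config()`): a 300-node
preferential-attachment network (2 edges per new node) standing in for a
scale-free interaction network; 3 disease modules of 15 genes planted as
connected breadth-first balls; 150 compounds with 8 targets each, half of
them positives assigned round-robin to diseases. A positive draws half its
targets from its disease module itself and the rest uniformly — sampling
from the module rather than its distance-1 neighbourhood is deliberate,
because in a scale-free graph a module touching a hub has a neighbourhood
covering much of the network and the planted signal would wash out.
Descriptors get a class-conditional mean shift of 1 SD, embeddings cluster
around per-disease centroids (noise SD 0.4), and `noise_rate` flips label
cells symmetrically to dial difficulty (default 0). Every generator is a
pure function of the config seed.

The generator reproduces the *structure* of the real inputs (formats,
degree heterogeneity, module locality, class-conditional shifts), not
their hardness: real target annotation is biased and incomplete, real
disease modules are not clean BFS balls, and real embeddings encode far
more than group membership. Passing the planted-signal tests therefore
demonstrates that the pipeline is correctly wired and can recover a known
association — held-out AUROC reaches 1.0 at fixture scale while the
label-permutation control stays near 0.5 — not that real-data performance
reaches any particular level. The permutation null is averaged over 5
independent permutations because a single permutation's macro-AUROC over
three diseases with ~5 test positives each has a standard error around
0.08; averaging brings the control reliably into a tight band around 0.5
without touching the study conditions.

## Problem sizes

Desk-scale sizes were chosen to keep the full test suite in the
low minutes: the pipeline fixtures use the 300-node/150-compound defaults
(three seeds plus permutation controls), oracle equivalences run on 100
random graphs of up to 200 nodes (restart walk vs closed-form solve, 1e-6)
and up to 30 nodes (proximities vs BFS, 1e-10), Fisher's tail is checked
against explicit hypergeometric sums for every 2×2 table with total ≤ 60
(1e-10), and exact Mann-Whitney enumeration covers samples up to 7 per
group.

## Known limitations

* Per-disease models share no parameters; correlated indications (e.g.
  hypertension and heart failure) are learned independently.
* The default 101-column descriptor schema is a faithful *shape*, not a
  recovered byte-level layout; real SwissADME exports need a rename map
  and possibly adjusted category sets.
* The walk treats the interaction network as unweighted and undirected;
  edge confidence scores and directionality are ignored.
* Literature statistics use exact token-sequence matching only — no
  synonym or abbreviation expansion — so co-occurrence counts are a lower
  bound.
* Training is plain R matrix algebra: fine for hundreds of compounds and
  ~700 features, not for order-of-magnitude larger inputs.
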