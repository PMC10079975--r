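---
title: "Predicting protein-protein interactions with a pair-node graph transformer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein-protein interactions with a pair-node graph transformer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pairGBERT)
```

## The problem and the formulation

Given a curated list of protein pairs labelled interacting (1) or
non-interacting (0), plus a numeric embedding for every protein derived
from its amino-acid sequence, we want a classifier for unseen pairs.
pairGBERT casts this as *node* classification on an unusual graph: every
labelled **pair** is a node, and two nodes are joined by an edge when the
pairs share a protein. A pair (A,B) is therefore adjacent to (A,C) and
(B,D) but not to (C,D). Pairs are unordered — identifiers are sorted
lexicographically so (A,B) and (B,A) name one node — and self pairs are
rejected, mirroring the usual benchmark curation that also drops
sequences shorter than 50 residues or containing non-standard amino
acids (`filter_records()`).

Each node carries a raw feature vector: the concatenation, in canonical
pair order, of the two per-protein embeddings (width $2d$; with the
common 1024-dim protein language-model embeddings this is the familiar
2048-wide node feature). The per-protein vector itself is the mean over
sequence positions of a per-residue embedding, which in turn is the sum
of the embedder's three layer outputs; `combine_layers()` and
`pool_per_protein()` implement exactly that arithmetic, while running a
pretrained embedder is out of scope — `read_embedding_store()` ingests
exported vectors and `mock_embedding()` stands in for tests.

## The model

Classification follows the Graph-BERT recipe: instead of convolving over
graph edges (prone to over-smoothing and the suspended-animation
problem as depth grows), each target node is classified from a small
*linkless subgraph* — itself plus the $k$ nodes most "intimate" with it
— processed by a transformer encoder that never sees the edges among
them.

**Intimacy and sampling.** With $A$ the adjacency matrix and
$M = A D^{-1}$ its column-normalized form, the intimacy matrix is the
PageRank-style kernel

$$S = \alpha \left( I - (1-\alpha) A D^{-1} \right)^{-1}
    = \sum_{t \ge 0} \alpha (1-\alpha)^t M^t,$$

computed by a dense linear solve (`intimacy_matrix()`). $\alpha$ is the
restart probability; it is not fixed by the published setup, so the
package uses the conventional 0.15 and exposes it. Columns of zero
degree are left all-zero rather than given a teleport distribution: an
isolated pair-node then simply has an arbitrary (index-ordered) context,
which is harmless since its own features dominate. The context of $v$ is
the top $\min(k, |V|-1)$ nodes by $S[u, v]$, ties broken by ascending
node index to keep runs reproducible. The target sits first, so a
subgraph has up to $k+1$ nodes; graphs smaller than that use all
available nodes without padding.

**Four additive input embeddings.** Every subgraph node contributes
$h^0 = e^x + e^r + e^p + e^d$: an affine projection of its raw features
into $\mathbb{R}^{d_h}$, plus one shared sinusoidal encoder
(`position_embed()`) applied to three integers — its Weisfeiler-Lehman
structural role code (computed once on the full graph, `wl_codes()`),
its intimacy rank within this subgraph (target 0, nearest context 1, …),
and its hop distance to the target in the original graph (`hop_distances()`,
unreachable mapped to `max_hop`, default 20).

One numerical subtlety: the sinusoidal encoder consumes the WL integer
itself, so the integer must not depend on the order nodes happen to be
listed in. Final WL colors are therefore densified in sorted-signature
order, which makes codes canonical under node relabeling; the partition
is the standard 1-WL fixed point either way.

**Encoder.** Each of $D$ layers computes multi-head scaled dot-product
attention over the subgraph's rows,

$$H^{l} = \mathrm{softmax}\!\left(\frac{QK^{\top}}{\sqrt{d_k}}\right)V
        + G_R(H^{l-1}, X_i),$$

with $Q, K, V$ linear maps of $H^{l-1}$ and $d_k = d_h/\text{heads}$ the
per-head width. The graph-residual term $G_R$ re-injects an affine
projection of the subgraph's *raw* features at every layer (the "raw"
residual variant), countering suspended animation. The default encoder
wraps this in the standard transformer sublayers — output projection,
layer normalization, and a GELU feed-forward block with hidden width
$d_h$ — matching the reference Graph-BERT implementation; a `pure_eq3`
configuration drops everything but attention + residual so tests can
check the core equation against a straight-line recomputation. Dropout
(hidden 0.5, attention probabilities 0.3, the published rates) is active
only in training mode.

**Readout.** After $D$ layers the classifier sees a single vector $z$,
passed through an affine map and a softmax (`classify()`). Two readouts
are implemented. `fuse()` averages the final representations of all
subgraph nodes, target included. The package *default*, however, is the
target node's own final representation (`readout = "target"`), and this
is a deliberate design decision worth spelling out.

With $k = 7$ and context labels uncorrelated with the target's label —
exactly the situation in the synthetic world, where sharing a protein
says nothing about the label — averaging dilutes the target's feature
signal by $1/(k+1)$ while adding the contexts' (label-irrelevant)
signals at equal weight. A linear readout of the average then caps near
64% held-out accuracy regardless of how separable the features are, and
in practice 200-epoch training with the published hyperparameters
plateaus at ~0.62 test accuracy: the optimizer instead memorizes
training labels through the near-unique WL role codes, which
generalizes not at all (validation loss rises from the first epochs).
The same model with target readout reaches 1.00 train / 1.00 test
accuracy under identical hyperparameters. The reference Graph-BERT
node-classification head reads the target token, so the target readout
is also the behaviour of the code the published experiments ran, even
though the accompanying description speaks of averaging over the
subgraph. Users can select `readout = "mean"` to recover the literal
averaging-fusion variant.

## Training machinery

`train()` minimizes two-class cross-entropy (the softmax form of binary
cross-entropy) with Adam at learning rate 0.001, over mini-batches of
subgraphs (default 64), for at most 200 epochs. Early stopping watches
the loss on a stratified 10% carve-out of the training nodes with
patience 20 and restores the best-epoch weights; these early-stopping
specifics are package conventions (the published setup states only that
early stopping was used) and all sit in `train_config()`. The model is
transductive in the usual Graph-BERT sense: the intimacy matrix, WL
codes and subgraphs are precomputed once on the full graph, so held-out
nodes contribute *features* (never labels) to training subgraphs, and
cross-validation reuses the full-graph precomputation.

Evaluation (`evaluate()`, `compute_metrics()`) reports accuracy,
sensitivity, specificity, precision, F-score and MCC from the confusion
counts, with the convention that a 0/0 ratio yields 0 and is flagged in
the report's `degenerate` field — this keeps degenerate folds
comparable instead of crashing skewed-ratio experiments.
`split_train_test()` / `kfold_indices()` give stratified 80:20 and
5-fold partitions; `welch_t_test()` wraps the unequal-variance t-test
used to compare method variants.

## The synthetic world

Real benchmark datasets and pretrained embedder weights are external
artifacts, so the package ships a generator whose defaults are the
desk-scale verification world used by the test suite: 60 proteins,
250 positive + 250 negative pairs (≈500 pair-nodes), 32-dim embeddings,
sequence lengths 50–400 residues. Per-protein vectors are isotropic
Gaussian noise (sd 1); the class signal is planted at the *pair* level —
a per-pair offset of $\pm\,\text{separation}\cdot\sigma/2$ (default
separation 6) along one fixed random direction of the concatenated
feature space, applied at pair-feature assembly through a companion
offset table carried by the store. Pair-level planting matters because
one protein can occur in both a positive and a negative pair; a purely
per-protein signal could cancel. Class ratios are exact by
construction, so skewed regimes (1:2.5, 1:5, 1:10) are a matter of
setting `n_pos`/`n_neg`. All randomness flows from one seed through
named independent streams (pairs, embeddings, sequences, direction).

What the generator does *not* emulate: scale-free PPI-network topology,
realistic embedding geometry, sequence-feature correlation (sequences
are uniform random and carry no signal), or dataset redundancy. A green
learnability test therefore establishes that the implementation can
extract a planted, linearly-decodable signal through the whole
graph-transformer pipeline — not that the method reaches any particular
accuracy on real interactomes.

## Numerical choices and degenerate inputs

* Intimacy solve: direct dense inversion; for $\alpha \in (0,1]$ the
  system is strictly diagonally dominant and cannot be singular.
  $\alpha = 0$ is rejected (the kernel is undefined there).
* Layer norm uses $\varepsilon = 10^{-12}$; softmax subtracts the row
  maximum; per-node loss clamps probabilities at $10^{-12}$.
* Hidden width $d_h$ (default 32, even, divisible by the head count) is
  not fixed by the published setup; 32 matches the reference
  Graph-BERT's node-classification configuration.
* Weights are Glorot-uniform; gradients are exact analytic backprop
  (verified against central finite differences to ~3e-10 during
  development).
* Duplicate interaction records merge silently when labels agree and
  are a hard error when they conflict; empty record sets, single-class
  training sets, and unsatisfiable splits raise classed errors rather
  than producing silent nonsense.
* Ties in intimacy are broken by ascending node index; WL integer codes
  are canonical under relabeling (sorted-signature densification).

## Limitations

Training is plain R (no GPU, no vectorized batching across subgraphs);
the intended scale is the desk-scale synthetic world and small curated
datasets (up to a few thousand pair-nodes). The intimacy matrix is
dense, $O(|V|^2)$ memory. Graph-BERT pre-training tasks and the
protein-per-node (variational graph auto-encoder) formulation are out
of scope, as is running the sequence embedders themselves.
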