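---
title: "Reaction-enhanced molecular embeddings: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reaction-enhanced molecular embeddings: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reactembed)
```

## The problem

Chemical reactions encode relational knowledge that a molecule's own
structure does not: molecules that react together, or that can be
produced from one another, tend to be functionally related.
`reactembed` learns low-dimensional molecule embeddings that combine
both sources — intramolecular structure and reaction-level relations —
and models each reaction as a learned *translation* between its
reactant and product sides.  The embeddings support three downstream
uses: ranking candidate product sides for a reactant set (product
prediction), classifying reactions from concatenated side embeddings,
and exporting per-molecule features for property prediction.

## The model

**Molecular view.**  A molecule is an undirected graph of heavy atoms;
hydrogens are implicit and enter only as per-atom counts.  Each atom
starts as the concatenation of four one-hot blocks — element, formal
charge, aromaticity, hydrogen count (row sum exactly 4) — linearly
projected to width $d$.  $K$ message-passing layers follow, with one of
four interchangeable aggregation rules (GCN's symmetrically normalized
mean, GAT's learned attention, SAGE's self/neighbor-mean concatenation,
TAG's hop polynomial), each followed by a ReLU except the last, which
stays linear.  The molecule embedding $h^A$ is the *sum* of the final
atom states; sum pooling makes the encoder additive over disconnected
components, which the tests exploit as an invariant.

**Reaction view.**  The reaction-aware graph has one node per molecule
and one edge per (reactant, product) pair of every reaction, tagged
with the reaction that created it.  Node features start as the
molecule's 39-entry functional-group count vector (a sum of per-group
one-hots), projected to $d$.  One attention layer (default $L = 1$)
updates each node as
$m_i \leftarrow m_i + \sum_j \pi_{ij} m_j$
over a fixed-size sample of $Q$ incident edges, where the logit of
edge $(i, j)$ from reaction $x$ is $W_a (m_i \odot m_j \odot c_x)$ and
$c_x$ is the sum of the current states of all molecules in $x$.  The
context term lets the same neighbor contribute differently depending on
which reaction connects it.  The result is $h^X$.

**Fusion and relation memory.**  The final embedding is
$h = W_c [h^A \| h^X]$.  A reaction side is the sum of its members'
$h$; for a pair $(x_R, x_P)$ a memory network computes attention
$\mathrm{att}_n \propto \exp((x_R \odot x_P)^\top k_n)$ over $N$ key
rows and returns the relation vector $e = \sum_n \mathrm{att}_n m_n$, a
convex combination of memory rows.  The pair score is
$S = \lVert x_R + e - x_P \rVert^2$ (squared Euclidean by default; a
plain-norm variant is available and ranks identically).  With $N = 1$
the model degenerates exactly to a single global translation, the
classic TransE limit.

**Objectives.**  Training minimizes
$L = L_E + \alpha L_C + \lambda \lVert \Theta \rVert_F^2$:

* $L_E$: mean positive score plus the mean hinge
  $\max(\gamma - S(R_i, P_j), 0)$ over all *ordered* in-batch
  mismatches $(i, j)$, $i \ne j$ — a batch of $B$ reactions contributes
  exactly $B^2 - B$ hinge terms, and epoch-level reshuffling refreshes
  the negatives.
* $L_C$: InfoNCE between the two views of the same side (anchors in
  the atom view, candidates in the reaction view; cosine similarities
  at temperature $\tau$), summed over reactant-side and product-side
  versions.
* the $L_2$ penalty is applied analytically in the optimizer
  ($\lambda = 0$ by default; its reference value is unpublished).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `aggregator` | `gcn` | molecular-view message-passing rule |
| `layers` (K) | 2 | molecular-view depth |
| `rx_layers` (L) | 1 | reaction-view depth |
| `dim` (d) | 256 | embedding width of every layer |
| `Q` | 10 | sampled neighbors per reaction-graph node |
| `N` | 10 | memory slots of the relation network |
| `gamma` | 4 | margin of the hinge loss (score units) |
| `tau` | 0.1 | InfoNCE temperature (cosine units) |
| `alpha` | 1e-3 | weight of the cross-view loss |
| `epochs`, `batch_size`, `learning_rate` | 50, 1024, 1e-4 | Adam schedule |

The defaults mirror the reference setting for corpora of 10⁴–10⁵
reactions.  They do not transfer verbatim to small corpora: with a few
hundred reactions, a batch of 1024 collapses each epoch to a single
step and a learning rate of 1e-4 barely moves the parameters within 50
epochs.  All desk-scale work in this package (tests, the acceptance
script, the examples below) therefore uses `dim = 32`,
`batch_size = 32`, `learning_rate = 5e-3`, keeping every
model-structural hyperparameter ($\gamma, \tau, \alpha, Q, N, K, L$) at
its reference value.  These scale choices were fixed once, from the
ratio of corpus sizes, and the 200-reaction runs finish in roughly half
a minute on one CPU.

## What the synthetic corpora emulate

External reaction corpora are deliberately not required anywhere.  The
generator (`fixture_spec()`, `generate_molecule_universe()`,
`generate_reaction_set()`) builds molecules from a template grammar —
enumerated alkyl trees combined into alkanes, alcohols, carboxylic
acids, esters, terminal alkenes, cyclic ethers and diols — and
reactions from four families with family-constant bond- and ring-count
changes $(\Delta NB, \Delta NR)$: hydration $(+1, 0)$, ring opening
$(0, -1)$, esterification $(0, 0)$ and cyclization $(0, +1)$.
Transesterification companions reuse an existing ester product under a
different reactant pair, which is what creates second-order neighbors
(two reactant sets sharing a product) in the reaction-aware graph; the
`overlap_degree` field controls how many exist.  Three frozen corpora
(8, 200 and 2000 reactions) are byte-reproducible from their seeds and
checksummed in the test suite.

What the grammar does *not* emulate: stereochemistry, reagents and
catalysts, atom mapping, unbalanced or noisy reaction records,
multi-step transformations, and the long-tailed molecule-frequency
distribution of patent corpora.  Water, however, is ubiquitous here
exactly as in real condensation chemistry, so the reaction-aware graph
is *not* a disjoint union of per-reaction stars even without product
overlap — most reactions touch the water node.  Passing tests on these
corpora demonstrate that the machinery (featurization, dual-view
encoding, relation memory, objectives, ranking) is implemented
correctly and that the model can learn a small, clean reaction
distribution; they say nothing about accuracy on patent-scale data.

## Numerical choices

* **Gradients.**  All training gradients come from a small
  reverse-mode tape implemented in the package (`R/autodiff.R`) over
  dense/sparse matrix products, row gathers and scatters, grouped
  softmaxes and fused loss heads.  Every operation and the full
  objective are validated against central finite differences
  (tolerances 1e-6 and 1e-4).
* **Initialization.**  Glorot-uniform weights; key and memory matrices
  $\mathcal N(0, 1/\sqrt d)$ so slot logits start at order one.  All
  randomness (init, neighbor sampling, shuffling, splits) derives from
  one integer seed; two runs with equal seeds produce identical loss
  traces.
* **Sampling.**  Neighborhoods larger than $Q$ are subsampled without
  replacement; smaller ones are padded by sampling with replacement, so
  attention is always a proper distribution without masking logic.
  Samples are redrawn once per epoch.
* **Softmaxes** are max-shifted; a zero interaction vector or zero
  attention weights yield exactly uniform attention.  Cosine
  similarity on a zero-norm side embedding is an error, not a silent
  NaN.
* **Ties** in ranking are broken pessimistically (the true candidate
  ranks after equal-scored competitors), so reported MRR/Hit@1 are
  never flattered by degenerate scores.
* **Splits** use largest-remainder 8:1:1 apportionment with a floor of
  one record per part.
* **Checkpointing** keeps the parameters of the epoch with the best
  validation MRR, evaluated every epoch; ties keep the earliest such
  epoch (see the limitations below for why).

## Design decisions that were genuinely open

* **Attention context per edge.**  A node's neighbors span several
  reactions, while the attention formula is written for one reaction.
  Each edge therefore uses the context of the reaction stored on that
  edge, and parallel edges from different reactions are sampled as
  distinct.
* **$W_a$ shape.**  A per-layer $1 \times d$ row vector is the minimal
  shape that makes the attention logit scalar; adopted as such.
* **Squared vs plain norm.**  The score exponent is read as the
  squared norm (smoother gradients); both are exposed and rank
  identically, which a test asserts.
* **Ranking-time relation vectors** are recomputed per candidate pair:
  the memory network conditions on both sides, so each candidate gets
  its own translation.
* **Train-split graph.**  The reaction-aware graph uses training
  reactions only; molecules outside it fall back to their projected
  functional-group vector, preventing test-reaction leakage through
  graph edges.
* **Molecule-level property features** concatenate $h^A$ with the raw
  functional-group embedding sum rather than $h^X$, so they are defined
  for molecules that appear in no reaction.

## Worked example

```{r example, eval = FALSE}
rx <- golden_fixture("small")                  # 200 reactions, 4 families
cfg <- model_config(aggregator = "gcn", dim = 32, batch_size = 32,
                    learning_rate = 5e-3, epochs = 50, seed = 1)
model <- train_reaction_model(rx, cfg)
rank_products(model)          # test-split ranking: MRR 0.908, Hit@1 0.850
glance(model)                 # best validation MRR 0.975 at epoch 3
autoplot(model)               # loss components and validation MRR
```

## Known limitations

* **A random encoder is already far above chance.**  On the
  200-reaction corpus an *untrained* model reaches MRR ≈ 0.3–0.5
  against a random-ranking expectation of ≈ 0.18.  This is not a bug:
  reaction sides approximately conserve substructure content, and even
  random-weight message passing embeds structurally overlapping sets
  nearby, so $\lVert x_R - x_P \rVert$ is smaller for true pairs at
  initialization.  Untrained performance is therefore *not* a valid
  chance baseline for this architecture, and the corresponding
  distinguishability check in the acceptance suite fails by design of
  the architecture, not of the code.
* **The cross-view term does not help at desk scale.**  Removing the
  InfoNCE task ($\alpha = 0$) changes validation MRR by at most one
  rank step on the 200-reaction corpus — and on a majority of seeds
  that step is an improvement.  With 160 training reactions the two
  views align well without an explicit alignment loss; the cooperative
  effect reported at corpus scale should not be expected here.
* **Relation-memory degeneracy.**  With a free encoder and few
  distinct transformation types, the margin objective admits a
  degenerate optimum in which all pairs attend to one memory slot and
  the relation vector is a single global translation (the TransE
  limit).  Prolonged training converges there; early checkpoints
  (which best-validation selection naturally prefers, hence the
  earliest-epoch tie rule) retain a small but directionally consistent
  within-family excess in relation-vector cosine similarity.  Family
  structure in relation embeddings should be read as a direction, not
  an effect size, at this scale.
* **Chemistry scope.**  OpenBabel perception governs canonicalization,
  aromaticity and valence; stereochemistry is ignored throughout, and
  reagents between `>` tokens in extended reaction SMILES are not
  parsed.
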