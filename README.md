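# reactembed

Molecule representation learning from chemical reactions, in R.

Most molecular embedding methods look only inside the molecule.
`reactembed` also looks *between* molecules: it learns embeddings from
a corpus of reactions `reactants >> products`, combining two graph
views of every molecule and modeling each reaction as a learned
translation between its sides.  The embeddings serve chemists and
method developers who want reaction-aware molecule features for
product prediction, reaction classification, or property prediction —
without leaving R.

## The model

For each molecule two embeddings are learned and fused,
`h = Wc [hA || hX]`:

* **hA** — message passing over the molecular graph (atoms as nodes,
  bonds as edges; GCN / GAT / SAGE / TAG aggregation, K = 2 layers)
  followed by sum pooling over atoms.  Atom features are one-hot
  element, charge, aromaticity and hydrogen count.
* **hX** — attention-based propagation on the *reaction-aware graph*,
  whose nodes are molecules and whose edges connect every reactant of
  a reaction to every product of the same reaction.  Node features are
  39-dimensional functional-group counts; the attention logit of an
  edge is `Wa (mi ⊙ mj ⊙ c)` with `c` the summed states of that
  reaction's molecules.

A reaction side is the sum of its members' `h`.  A key/memory network
turns each pair `(xR, xP)` into a relation vector
`e = Σ_n att_n m_n`, `att = softmax((xR ⊙ xP) Kᵀ)`, and the pair is
scored by `S = ||xR + e − xP||²` — zero exactly when the translation
lands on the product side.  Training minimizes a margin loss over
in-batch mismatched pairs plus `α ·` a cross-view InfoNCE loss
aligning the two views of the same side.

At evaluation time, each test reaction's reactant side is scored
against every candidate product side (the relation vector is
recomputed per pair) and the rank of the true side yields MRR and
Hit@1.

## Worked example

```r
library(reactembed)

rx <- golden_fixture("small")      # frozen 200-reaction synthetic corpus
cfg <- model_config(aggregator = "gcn", dim = 32, batch_size = 32,
                    learning_rate = 5e-3, epochs = 50, seed = 1)
model <- train_reaction_model(rx, cfg)
model
#> <reaction embedding model>
#>   aggregator: gcn  d = 32  K = 2 molecular layers, L = 1 reaction layers
#>   trained 50 epochs; best validation MRR 0.975 at epoch 3

rank_products(model)               # rank true product sides on the test split
#> <product ranking>  20 reactions, 20 candidates
#>   MRR 0.9083   Hit@1 0.8500
```

MRR 0.908 means the true product side sits, on average, at the top of
the 20-candidate list (reciprocal rank near 1); Hit@1 0.85 means it is
ranked first for 17 of the 20 test reactions.  `tidy(model)` returns
the per-epoch loss trace, `glance(model)` a one-row fit summary, and
`autoplot(model)` plots both.  Downstream features come from
`reaction_features()` (classification) and `molecule_features()`
(property prediction); `relation_similarity_analysis()` tabulates
relation-vector cosine similarity against each reaction pair's bond-
and ring-count changes.

A thin command-line front end ships in `inst/exec/reactembed`
(`train`, `rank`, `embed`, `classify`, `analyze-relations`,
`make-fixtures`).

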