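# Model assembly: dataset constants, the joint batch objective on the
# autodiff tape, and inference-time embedding computation.

derive_seed <- function(seed, a = 0L, b = 0L) {
  as.integer((as.numeric(seed) + 104729 * a + 7919 * b) %% 2147483629)
}

side_members <- function(sides) strsplit(sides, ".", fixed = TRUE)

membership_matrix <- function(sides, mol_index) {
  mem <- side_members(sides)
  i <- rep(seq_along(mem), vapply(mem, length, integer(1)))
  j <- mol_index[unlist(mem)]
  Matrix::sparseMatrix(i = i, j = j, x = 1,
                       dims = c(length(mem), length(mol_index)))
}

# Precompute every constant structure the training loop needs:
# the stacked molecular graphs of all dataset molecules, the
# reaction-aware graph of the training split, the graph-to-dataset
# alignment for the reaction view's fallback, and the reaction side
# membership matrices.
model_data <- function(reactions, config, fg_patterns, vocab) {
  stopifnot("split" %in% names(reactions))
  all_smiles <- unique(unlist(side_members(c(reactions$reactants,
                                             reactions$products))))
  mols <- lapply(all_smiles, parse_molecule, fg_patterns = fg_patterns,
                 vocab = vocab)
  mol_index <- stats::setNames(seq_along(all_smiles), all_smiles)
  mgc <- molgraph_constants(mols, vocab = vocab, config = config)
  train <- reactions[reactions$split == "train", , drop = FALSE]
  graph <- build_reaction_aware_graph(train, fg_patterns = fg_patterns)
  # graph nodes -> dataset molecule rows
  node_rows <- mol_index[graph$nodes]
  P_in <- Matrix::sparseMatrix(i = node_rows, j = seq_along(node_rows),
                               x = 1,
                               dims = c(length(mols), length(node_rows)))
  FG_all <- do.call(rbind, lapply(mols, `[[`, "fg_vector"))
  FG_out <- FG_all
  FG_out[node_rows, ] <- 0      # molecules covered by the graph
  list(reactions = reactions, molecules = mols, mol_index = mol_index,
       smiles = all_smiles, mgc = mgc, graph = graph,
       S_rxn = reaction_membership_matrix(graph),
       P_in = P_in, FG_all = FG_all, FG_out = FG_out,
       S_R = membership_matrix(reactions$reactants, mol_index),
       S_P = membership_matrix(reactions$products, mol_index))
}

# Fused per-molecule embeddings for the whole dataset on a tape.
# Returns node ids for hA, hX and h (all n_molecules x d).
forward_all_molecules <- function(tp, pids, data, config, sample) {
  HA <- forward_molecular(tp, pids, data$mgc, config)
  Mgr <- forward_reaction_view(tp, pids, data$graph, sample, config,
                               S_rxn = data$S_rxn)
  HX <- ad_add(tp, ad_lmul(tp, data$P_in, Mgr),
               ad_lmul(tp, data$FG_out, pids$fg_proj))
  H <- ad_matmul(tp, ad_cbind(tp, HA, HX), pids$fuse_W)
  list(hA = HA, hX = HX, h = H)
}

# The full minibatch objective.  Returns the loss node ids and scalar
# component values.
batch_objective <- function(tp, pids, data, config, sample, batch) {
  emb <- forward_all_molecules(tp, pids, data, config, sample)
  S_Rb <- data$S_R[batch, , drop = FALSE]
  S_Pb <- data$S_P[batch, , drop = FALSE]
  xR <- ad_lmul(tp, S_Rb, emb$h)
  xP <- ad_lmul(tp, S_Pb, emb$h)
  b <- length(batch)
  S_pos <- forward_pair_scores(tp, xR, xP, seq_len(b), seq_len(b),
                               pids, config)
  LE <- ad_affine(tp, ad_sum(tp, S_pos), 1 / b)
  if (b > 1) {
    neg <- negative_pair_index(b)
    S_neg <- forward_pair_scores(tp, xR, xP, neg$i, neg$j, pids, config)
    hinge <- ad_relu(tp, ad_affine(tp, S_neg, -1, config$gamma))
    LE <- ad_add(tp, LE, ad_affine(tp, ad_sum(tp, hinge), 1 / (b^2 - b)))
  }
  LC <- ad_const(tp, matrix(0, 1, 1))
  if (b > 1) {
    sides <- list(list(S_Rb, emb$hA, emb$hX), list(S_Pb, emb$hA, emb$hX))
    parts <- lapply(sides, function(s) {
      vA <- ad_normalize_rows(tp, ad_lmul(tp, s[[1]], s[[2]]))
      vX <- ad_normalize_rows(tp, ad_lmul(tp, s[[1]], s[[3]]))
      ad_infonce(tp, ad_matmul_nt(tp, vA, vX), config$tau)
    })
    LC <- ad_add(tp, parts[[1]], parts[[2]])
  }
  loss <- ad_add(tp, LE, ad_affine(tp, LC, config$alpha))
  list(loss = loss, LE = as.numeric(ad_value(tp, LE)),
       LC = as.numeric(ad_value(tp, LC)))
}

# Inference: fused embeddings of arbitrary molecules under the trained
# parameters.  Molecules outside the training reaction-aware graph fall
# back to their projected functional-group vector for the reaction
# view; the `in_graph` flag records which rows fell back.
embed_molecules_impl <- function(params, graph, mols, config, vocab,
                                 sample_seed) {
  canon <- vapply(mols, `[[`, character(1), "canonical_smiles")
  mgc <- molgraph_constants(mols, vocab = vocab, config = config)
  tp <- ad_tape()
  pids <- push_params(tp, params, as_params = FALSE)
  hA <- ad_value(tp, forward_molecular(tp, pids, mgc, config))
  sample <- sample_all_edges(graph, config$Q, sample_seed)
  Mgr <- ad_value(tp, forward_reaction_view(tp, pids, graph, sample, config))
  node <- graph$node_index[canon]
  in_graph <- !is.na(node)
  FG <- do.call(rbind, lapply(mols, `[[`, "fg_vector"))
  hX <- FG %*% params$fg_proj
  if (any(in_graph)) hX[in_graph, ] <- Mgr[node[in_graph], , drop = FALSE]
  h <- cbind(hA, hX) %*% params$fuse_W
  rownames(hA) <- rownames(hX) <- rownames(h) <- canon
  list(hA = hA, hX = hX, h = h, in_graph = in_graph)
}

# Side embeddings (summed fused h, and per-view sums) for a reaction
# tibble under a trained model.  Reactions drawn entirely from the
# model's dataset reuse its precomputed graph constants.
reaction_side_embeddings <- function(model, reactions) {
  smiles <- unique(unlist(side_members(c(reactions$reactants,
                                         reactions$products))))
  if (all(smiles %in% names(model$data$mol_index))) {
    tp <- ad_tape()
    pids <- push_params(tp, model$params, as_params = FALSE)
    sample <- sample_all_edges(model$data$graph, model$config$Q,
                               model$config$seed)
    ids <- forward_all_molecules(tp, pids, model$data, model$config, sample)
    emb <- lapply(ids, function(i) {
      v <- ad_value(tp, i)
      rownames(v) <- model$data$smiles
      v
    })
    names(emb) <- c("hA", "hX", "h")
    mol_index <- model$data$mol_index
  } else {
    mols <- lapply(smiles, parse_molecule,
                   fg_patterns = model$fg_patterns, vocab = model$vocab)
    emb <- embed_molecules_impl(model$params, model$data$graph, mols,
                                model$config, model$vocab,
                                sample_seed = model$config$seed)
    mol_index <- stats::setNames(seq_along(smiles), smiles)
  }
  S_R <- membership_matrix(reactions$reactants, mol_index)
  S_P <- membership_matrix(reactions$products, mol_index)
  list(xR = as.matrix(S_R %*% emb$h), xP = as.matrix(S_P %*% emb$h),
       xR_A = as.matrix(S_R %*% emb$hA), xR_X = as.matrix(S_R %*% emb$hX),
       xP_A = as.matrix(S_P %*% emb$hA), xP_X = as.matrix(S_P %*% emb$hX),
       molecule_embeddings = emb)
}
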