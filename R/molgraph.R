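# Molecular-graph encoder: K rounds of message passing over atoms
# followed by sum pooling into the atom-level molecule embedding hA.
#
# Four aggregation rules are supported: GCN (symmetrically normalized
# mean including the self node), GAT (learned pairwise attention), SAGE
# (concatenation of self state and neighbor mean) and TAG (polynomial in
# the normalized adjacency).  Layers are ReLU-activated except the last,
# which stays linear; the one-hot atom features enter through a learned
# linear projection into d dimensions.

# Stack a list of molecules into one block-diagonal graph with constant
# structure matrices reused by every forward pass.
molgraph_constants <- function(molecules, vocab = feature_vocab(),
                               config = model_config()) {
  feats <- lapply(molecules, featurize_atoms, vocab = vocab)
  sizes <- vapply(feats, nrow, integer(1))
  offsets <- cumsum(c(0L, sizes[-length(sizes)]))
  n <- sum(sizes)
  X <- do.call(rbind, feats)
  e1 <- integer(0); e2 <- integer(0)
  for (i in seq_along(molecules)) {
    ed <- molecules[[i]]$graph$edges
    if (nrow(ed)) {
      e1 <- c(e1, ed[, 1] + offsets[i])
      e2 <- c(e2, ed[, 2] + offsets[i])
    }
  }
  A <- Matrix::sparseMatrix(i = c(e1, e2), j = c(e2, e1), x = 1,
                            dims = c(n, n))
  A_self <- A + Matrix::Diagonal(n)
  d_self <- Matrix::rowSums(A_self)
  Dm <- Matrix::Diagonal(n, 1 / sqrt(d_self))
  A_norm <- Dm %*% A_self %*% Dm
  deg <- Matrix::rowSums(A)
  A_mean <- Matrix::Diagonal(n, 1 / pmax(deg, 1)) %*% A
  dst <- c(e1, e2, seq_len(n))
  src <- c(e2, e1, seq_len(n))
  S_dst <- Matrix::sparseMatrix(i = dst, j = seq_along(dst), x = 1,
                                dims = c(n, length(dst)))
  pool <- Matrix::sparseMatrix(i = rep(seq_along(molecules), sizes),
                               j = seq_len(n), x = 1,
                               dims = c(length(molecules), n))
  list(X = X, n_atoms = n, A_norm = A_norm, A_mean = A_mean,
       gat_src = src, gat_dst = dst, S_dst = S_dst, pool = pool)
}

# One message-passing layer on the tape.  `weights` is a named list of
# node ids (W, and al/ar for GAT).  Returns the node id of the new
# atom-state matrix.
mol_layer_forward <- function(tp, H, consts, weights, config, last) {
  out <- switch(config$aggregator,
    gcn = ad_matmul(tp, ad_lmul(tp, consts$A_norm, H), weights$W),
    sage = {
      nb <- ad_lmul(tp, consts$A_mean, H)
      ad_matmul(tp, ad_cbind(tp, H, nb), weights$W)
    },
    tag = {
      hops <- list(H)
      for (h in seq_len(config$tag_hops)) {
        hops[[h + 1L]] <- ad_lmul(tp, consts$A_norm, hops[[h]])
      }
      stacked <- Reduce(function(a, b) ad_cbind(tp, a, b), hops)
      ad_matmul(tp, stacked, weights$W)
    },
    gat = {
      Wh <- ad_matmul(tp, H, weights$W)
      el <- ad_matmul(tp, Wh, weights$al)
      er <- ad_matmul(tp, Wh, weights$ar)
      logits <- ad_leaky_relu(tp,
        ad_add(tp, ad_gather(tp, el, consts$gat_dst),
               ad_gather(tp, er, consts$gat_src)),
        slope = config$leaky_slope)
      pi_ <- ad_group_softmax(tp, logits, consts$gat_dst)
      msg <- ad_scale_rows(tp, ad_gather(tp, Wh, consts$gat_src), pi_)
      ad_lmul(tp, consts$S_dst, msg)
    })
  if (last) out else ad_relu(tp, out)
}

`%otherwise%` <- function(a, b) if (is.null(a)) b else a

# Push all parameters onto a tape.  `as_params = TRUE` registers them
# for gradients; FALSE pushes constants (inference).
push_params <- function(tp, params, as_params = TRUE) {
  f <- if (as_params) function(x, nm) ad_param(tp, x, nm) else
    function(x, nm) ad_const(tp, x)
  stats::setNames(
    lapply(names(params), function(nm) f(params[[nm]], nm)),
    names(params))
}

layer_weight_ids <- function(pids, k) {
  list(W = pids[[paste0("enc", k, "_W")]],
       al = pids[[paste0("enc", k, "_al")]] %otherwise% NULL,
       ar = pids[[paste0("enc", k, "_ar")]] %otherwise% NULL)
}

# Full molecular-view forward: projected features -> K layers -> sum
# pooling.  Returns the node id of the molecule embedding matrix hA.
forward_molecular <- function(tp, pids, consts, config) {
  H <- ad_lmul(tp, consts$X, pids$atom_proj)
  for (k in seq_len(config$layers)) {
    H <- mol_layer_forward(tp, H, consts, layer_weight_ids(pids, k),
                           config, last = (k == config$layers))
  }
  ad_lmul(tp, consts$pool, H)
}

#' Apply one molecular-graph aggregation layer
#'
#' Exposes a single message-passing step as a plain matrix operation:
#' given per-atom states at layer k-1 it returns the states at layer k
#' (linear part only, no activation).  The neighborhood of an atom
#' always includes the atom itself: via the added self loop for GCN, GAT
#' and TAG, and via the concatenated self state for SAGE.  Atoms with no
#' neighbors aggregate only themselves.
#'
#' @param states numeric matrix, one row per atom.
#' @param molecule a molecule from [parse_molecule()].
#' @param weights named list with entry `W` (and `al`, `ar` column
#'   vectors for `"gat"`).
#' @param config a [model_config()]; only the aggregator settings are
#'   used.
#' @return numeric matrix of the same number of rows as `states`.
#' @export
aggregate_layer <- function(states, molecule, weights,
                            config = model_config()) {
  consts <- molgraph_constants(list(molecule), config = config)
  stopifnot(nrow(states) == consts$n_atoms)
  tp <- ad_tape()
  H <- ad_const(tp, states)
  wids <- lapply(weights, function(w) ad_const(tp, as.matrix(w)))
  out <- mol_layer_forward(tp, H, consts, wids, config, last = TRUE)
  ad_value(tp, out)
}

#' Encode a molecule into its atom-level embedding hA
#'
#' Runs the full molecular-graph encoder (input projection, K
#' aggregation layers, sum pooling over atoms) for a single molecule.
#'
#' @inheritParams aggregate_layer
#' @param params parameter list from the trained model (or
#'   `init_params()`-style); needs `atom_proj` and the per-layer
#'   encoder weights.
#' @param vocab atom feature vocabulary the parameters were built for.
#' @return a numeric vector of length `config$dim`.
#' @export
encode_molecule <- function(molecule, params, config = model_config(),
                            vocab = feature_vocab()) {
  consts <- molgraph_constants(list(molecule), vocab = vocab,
                               config = config)
  tp <- ad_tape()
  pids <- push_params(tp, params, as_params = FALSE)
  hA <- forward_molecular(tp, pids, consts, config)
  as.vector(ad_value(tp, hA))
}
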