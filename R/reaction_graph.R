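# Reaction-aware graph: molecules are nodes; every (reactant, product)
# pair of every reaction contributes one edge tagged with its reaction.
# Message passing uses reaction-context attention: the attention logit
# of edge (i, j) from reaction x is Wa . (m_i * m_j * c_x), with c_x the
# sum of the current states of all molecules in x, and the update is the
# residual m_i + sum_j pi_ij m_j.  Neighborhoods are subsampled to a
# fixed size Q (without replacement when the degree allows it, with
# replacement otherwise), so the attention weights always form a proper
# distribution.

#' Build the reaction-aware graph
#'
#' Nodes are the unique molecules (by canonical SMILES) of all supplied
#' reactions; each reaction contributes one edge per (reactant, product)
#' pair, tagged with the reaction id.  Edges are traversed undirected
#' during aggregation — products inform reactants and vice versa — and
#' multiple reactions connecting the same pair keep distinct edges.
#'
#' @param reactions a reaction tibble (see [read_reaction_file()]).
#' @param fg_patterns functional-group catalog used for the initial node
#'   features.
#' @return an object of class `re_rxgraph`: node table, edge table
#'   (`reactant_node`, `product_node`, `reaction_id`), per-node incident
#'   edge lists, per-reaction member lists, and the node
#'   functional-group count matrix.
#' @export
build_reaction_aware_graph <- function(reactions,
                                       fg_patterns = read_fg_patterns()) {
  if (nrow(reactions) == 0) stop_input("no reactions supplied")
  r_sides <- strsplit(reactions$reactants, ".", fixed = TRUE)
  p_sides <- strsplit(reactions$products, ".", fixed = TRUE)
  nodes <- unique(c(unlist(r_sides), unlist(p_sides)))
  node_index <- stats::setNames(seq_along(nodes), nodes)
  rid <- if ("id" %in% names(reactions)) reactions$id else seq_len(nrow(reactions))
  edges <- dplyr::bind_rows(lapply(seq_len(nrow(reactions)), function(k) {
    expand.grid(reactant_node = node_index[r_sides[[k]]],
                product_node = node_index[p_sides[[k]]],
                KEEP.OUT.ATTRS = FALSE) |>
      tibble::as_tibble() |>
      dplyr::mutate(reaction_id = rid[k])
  }))
  members <- lapply(seq_len(nrow(reactions)), function(k) {
    unique(c(node_index[r_sides[[k]]], node_index[p_sides[[k]]]))
  })
  # incident (undirected) edge list per node: columns neighbor, reaction
  incident <- vector("list", length(nodes))
  for (i in seq_along(nodes)) incident[[i]] <- list(nb = integer(), rx = integer())
  for (k in seq_len(nrow(edges))) {
    a <- edges$reactant_node[k]; b <- edges$product_node[k]
    r <- match(edges$reaction_id[k], rid)
    incident[[a]]$nb <- c(incident[[a]]$nb, b)
    incident[[a]]$rx <- c(incident[[a]]$rx, r)
    if (b != a) {
      incident[[b]]$nb <- c(incident[[b]]$nb, a)
      incident[[b]]$rx <- c(incident[[b]]$rx, r)
    }
  }
  mols <- lapply(nodes, parse_molecule, fg_patterns = fg_patterns)
  FG <- do.call(rbind, lapply(mols, `[[`, "fg_vector"))
  structure(list(nodes = nodes, node_index = node_index,
                 edges = edges, reaction_ids = rid,
                 members = members, incident = incident,
                 FG = FG, molecules = mols),
            class = "re_rxgraph")
}

#' @export
print.re_rxgraph <- function(x, ...) {
  cat("<reaction-aware graph> ", length(x$nodes), " molecules, ",
      nrow(x$edges), " reactant-product edges from ",
      length(x$members), " reactions\n", sep = "")
  invisible(x)
}

#' Sample a fixed-size neighborhood of a molecule
#'
#' Uniform sample of `Q` incident edges: without replacement when the
#' degree is at least `Q`, with replacement (padding) otherwise.  A node
#' of degree zero yields an empty sample.
#'
#' @param graph an [build_reaction_aware_graph()] object.
#' @param node a node index or canonical SMILES.
#' @param Q sample size.
#' @param seed integer seed; the same seed reproduces the sample.
#' @return a tibble with columns `neighbor` (node index) and
#'   `reaction` (position of the tagging reaction).
#' @export
sample_neighbors <- function(graph, node, Q = 10, seed = 1) {
  if (is.character(node)) node <- graph$node_index[[node]]
  inc <- graph$incident[[node]]
  deg <- length(inc$nb)
  if (deg == 0) {
    return(tibble::tibble(neighbor = integer(), reaction = integer()))
  }
  pick <- with_seed(seed, sample.int(deg, Q, replace = deg < Q))
  tibble::tibble(neighbor = inc$nb[pick], reaction = inc$rx[pick])
}

# One joint sample over all nodes: index vectors over sampled edges plus
# the scatter matrix back to nodes.  Deterministic given the seed.
sample_all_edges <- function(graph, Q, seed) {
  n <- length(graph$nodes)
  picks <- with_seed(seed, lapply(seq_len(n), function(i) {
    deg <- length(graph$incident[[i]]$nb)
    if (deg == 0) integer() else sample.int(deg, Q, replace = deg < Q)
  }))
  i_idx <- rep(seq_len(n), vapply(picks, length, integer(1)))
  j_idx <- unlist(lapply(seq_len(n), function(i) graph$incident[[i]]$nb[picks[[i]]]))
  r_idx <- unlist(lapply(seq_len(n), function(i) graph$incident[[i]]$rx[picks[[i]]]))
  S_target <- Matrix::sparseMatrix(i = i_idx, j = seq_along(i_idx), x = 1,
                                   dims = c(n, length(i_idx)))
  list(i = i_idx, j = as.integer(j_idx), r = as.integer(r_idx),
       S_target = S_target)
}

reaction_membership_matrix <- function(graph) {
  i <- rep(seq_along(graph$members),
           vapply(graph$members, length, integer(1)))
  Matrix::sparseMatrix(i = i, j = unlist(graph$members), x = 1,
                       dims = c(length(graph$members), length(graph$nodes)))
}

# Reaction-view forward on the tape: L attention layers over the
# sampled reaction-aware graph.  Returns the node id of the final
# node-state matrix (one row per graph molecule).
forward_reaction_view <- function(tp, pids, graph, sample, config,
                                  S_rxn = reaction_membership_matrix(graph)) {
  M <- ad_lmul(tp, graph$FG, pids$fg_proj)
  for (l in seq_len(config$rx_layers)) {
    Wa <- pids[[paste0("rx", l, "_Wa")]]
    if (length(sample$i)) {
      C <- ad_lmul(tp, S_rxn, M)
      t1 <- ad_emul(tp, ad_gather(tp, M, sample$i),
                    ad_gather(tp, M, sample$j))
      t2 <- ad_emul(tp, t1, ad_gather(tp, C, sample$r))
      logits <- ad_matmul_nt(tp, t2, Wa)
      pi_ <- ad_group_softmax(tp, logits, sample$i)
      msg <- ad_scale_rows(tp, ad_gather(tp, M, sample$j), pi_)
      M <- ad_add(tp, M, ad_lmul(tp, sample$S_target, msg))
    }
  }
  M
}

#' Reaction-context attention weights
#'
#' Softmax over a molecule's sampled neighbors of the logits
#' `Wa . (m_i * m_j * c)`, where `*` is the elementwise product and `c`
#' is the reaction context vector.  An empty neighborhood returns an
#' empty vector (no normalization is attempted).
#'
#' @param m_i state vector of the center molecule (length d).
#' @param neighbors matrix of neighbor state vectors, one per row.
#' @param context reaction context vector (length d).
#' @param Wa attention weight row vector (length d).
#' @return a probability vector with one entry per neighbor row.
#' @export
attention_scores <- function(m_i, neighbors, context, Wa) {
  if (is.null(dim(neighbors))) neighbors <- matrix(neighbors, nrow = 1)
  if (nrow(neighbors) == 0) return(numeric(0))
  logits <- as.vector(neighbors %*% (as.vector(Wa) * as.vector(m_i) *
                                       as.vector(context)))
  e <- exp(logits - max(logits))
  e / sum(e)
}

#' Apply one reaction-aware aggregation layer
#'
#' Computes `m_i + sum_j pi_ij m_j` for every graph molecule, with the
#' attention of each sampled edge conditioned on the context of the
#' reaction that created the edge (the sum of the current states of that
#' reaction's molecules).  Isolated molecules keep their state.
#'
#' @param graph an [build_reaction_aware_graph()] object.
#' @param states numeric matrix of current node states (nodes x d).
#' @param Wa attention weight row vector (length d).
#' @param Q neighbor sample size.
#' @param seed sampling seed.
#' @return the updated node-state matrix.
#' @export
aggregate_reaction_layer <- function(graph, states, Wa, Q = 10, seed = 1) {
  sample <- sample_all_edges(graph, Q, seed)
  n <- length(graph$nodes)
  if (!length(sample$i)) return(states)
  C <- as.matrix(reaction_membership_matrix(graph) %*% states)
  logits <- rowSums(states[sample$i, , drop = FALSE] *
                    states[sample$j, , drop = FALSE] *
                    C[sample$r, , drop = FALSE] *
                    matrix(as.vector(Wa), length(sample$i), ncol(states),
                           byrow = TRUE))
  pi_ <- numeric(length(logits))
  for (grp in split(seq_along(logits), sample$i)) {
    e <- exp(logits[grp] - max(logits[grp]))
    pi_[grp] <- e / sum(e)
  }
  agg <- as.matrix(sample$S_target %*%
                     (states[sample$j, , drop = FALSE] * pi_))
  states + agg
}

#' Reaction-level molecule embeddings hX
#'
#' Stacks `config$rx_layers` attention layers on the reaction-aware
#' graph, starting from the projected functional-group count vectors,
#' and returns the final states.
#'
#' @inheritParams aggregate_reaction_layer
#' @param params model parameter list (`fg_proj` and per-layer `rx*_Wa`).
#' @param config a [model_config()].
#' @param seed sampling seed.
#' @return a numeric matrix with one row per graph molecule.
#' @export
encode_reaction_view <- function(graph, params, config = model_config(),
                                 seed = config$seed) {
  sample <- sample_all_edges(graph, config$Q, seed)
  tp <- ad_tape()
  pids <- push_params(tp, params, as_params = FALSE)
  M <- forward_reaction_view(tp, pids, graph, sample, config)
  out <- ad_value(tp, M)
  rownames(out) <- graph$nodes
  out
}
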