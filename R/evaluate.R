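# Downstream evaluation: product-prediction ranking, reaction
# classification features, property-prediction features, and the
# relation-embedding diagnostics.

# Pessimistic ranks from a score matrix: S[i, j] is the score of
# candidate product side j for test reaction i (lower = better, true
# candidate on the diagonal); ties rank the true candidate last.
ranks_from_scores <- function(S) {
  vapply(seq_len(nrow(S)), function(i) {
    1L + sum(S[i, -i] < S[i, i]) + sum(S[i, -i] == S[i, i])
  }, integer(1))
}

#' Rank candidate product sides for each test reaction
#'
#' The candidate pool is the set of product sides of the supplied
#' reactions.  Every (reactant side, candidate product side) pair is
#' scored with the translation score — the relation vector is recomputed
#' for each candidate through the memory network — and candidates are
#' sorted ascending (lower score = better).  Ties are broken
#' pessimistically: the true candidate ranks after equal-scored
#' competitors.  Duplicate candidate sides are kept as distinct
#' candidates; their count is reported in a message.
#'
#' @param model a trained [train_reaction_model()] object.
#' @param reactions reactions to evaluate; defaults to the model's test
#'   split.
#' @return an object of class `re_ranking`: a per-reaction tibble
#'   (`id`, `rank`, `reciprocal_rank`, `n_candidates`) plus fields
#'   `mrr` and `hit1`.
#' @export
rank_products <- function(model, reactions = NULL) {
  if (is.null(reactions)) {
    reactions <- model$data$reactions
    reactions <- reactions[reactions$split == "test", , drop = FALSE]
  }
  n <- nrow(reactions)
  if (n == 0) stop_input("no reactions to rank")
  emb <- reaction_side_embeddings(model, reactions)
  dup <- sum(duplicated(reactions$products))
  if (dup > 0) {
    message(dup, " duplicate candidate product side(s) kept as distinct",
            " candidates")
  }
  K <- model$params$mem_K; M <- model$params$mem_M
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    XR <- emb$xR[rep(i, n), , drop = FALSE]
    S[i, ] <- score_pairs(XR, emb$xP, K, M, model$config$score_norm)$score
  }
  ranks <- ranks_from_scores(S)
  out <- list(
    reactions = tibble::tibble(id = reactions$id %||% seq_len(n),
                               rank = ranks,
                               reciprocal_rank = 1 / ranks,
                               n_candidates = n),
    mrr = mean(1 / ranks),
    hit1 = mean(ranks == 1L),
    n_candidates = n)
  class(out) <- "re_ranking"
  out
}

#' @export
print.re_ranking <- function(x, ...) {
  cat(sprintf("<product ranking>  %d reactions, %d candidates\n  MRR %.4f   Hit@1 %.4f\n",
              nrow(x$reactions), x$n_candidates, x$mrr, x$hit1))
  invisible(x)
}

#' Reaction features for classification
#'
#' Concatenates each reaction's summed reactant and product embeddings
#' into one feature vector of width 2d, suitable for an external
#' classifier such as an MLP decoder.
#'
#' @inheritParams rank_products
#' @param reactions a reaction tibble.
#' @return a tibble with `id`, `label` and a `feature` matrix-column of
#'   width `2 * config$dim`.
#' @export
reaction_features <- function(model, reactions) {
  emb <- reaction_side_embeddings(model, reactions)
  feat <- cbind(emb$xR, emb$xP)
  colnames(feat) <- paste0("f", seq_len(ncol(feat)))
  tibble::tibble(id = reactions$id %||% seq_len(nrow(reactions)),
                 label = reactions$label %||% NA_integer_,
                 feature = feat)
}

#' Molecule features for property prediction
#'
#' The transfer recipe for molecules outside any reaction: the
#' atom-level embedding hA concatenated with the summed functional-group
#' embedding (the projected 39-entry count vector).  The reaction-aware
#' view is deliberately not used, so the features are defined for any
#' parseable molecule.
#'
#' @param model a trained model.
#' @param smiles character vector of molecule SMILES.
#' @return a tibble with `smiles`, `canonical_smiles` and a `feature`
#'   matrix-column of width `2 * config$dim`.
#' @export
molecule_features <- function(model, smiles) {
  mols <- lapply(smiles, parse_molecule, fg_patterns = model$fg_patterns,
                 vocab = model$vocab)
  mgc <- molgraph_constants(mols, vocab = model$vocab,
                            config = model$config)
  tp <- ad_tape()
  pids <- push_params(tp, model$params, as_params = FALSE)
  hA <- ad_value(tp, forward_molecular(tp, pids, mgc, model$config))
  FG <- do.call(rbind, lapply(mols, `[[`, "fg_vector"))
  fg_emb <- FG %*% model$params$fg_proj
  feat <- cbind(hA, fg_emb)
  colnames(feat) <- paste0("f", seq_len(ncol(feat)))
  tibble::tibble(smiles = smiles,
                 canonical_smiles = vapply(mols, `[[`, character(1),
                                           "canonical_smiles"),
                 feature = feat)
}

#' Classify reactions with an MLP decoder
#'
#' Trains a single-hidden-layer perceptron (via \pkg{nnet}) on the
#' concatenated reaction features and reports test accuracy together
#' with macro- and micro-averaged recall.
#'
#' @param model a trained embedding model.
#' @param train_reactions,test_reactions labeled reaction tibbles.
#' @param hidden hidden-layer width.
#' @param seed seed for the decoder's weight initialization.
#' @return a list with `accuracy`, `recall_macro`, `recall_micro` and
#'   the per-reaction `predictions` tibble.
#' @export
classify_reactions <- function(model, train_reactions, test_reactions,
                               hidden = 32, seed = 1) {
  if (!requireNamespace("nnet", quietly = TRUE)) {
    stop_input("package 'nnet' is required for the MLP decoder")
  }
  tr <- reaction_features(model, train_reactions)
  te <- reaction_features(model, test_reactions)
  labels <- factor(train_reactions$label)
  fit <- with_seed(seed,
    nnet::nnet(x = tr$feature, y = nnet::class.ind(labels),
               size = hidden, softmax = TRUE, maxit = 200,
               MaxNWts = 1e6, trace = FALSE))
  pred <- factor(levels(labels)[max.col(stats::predict(fit, te$feature))],
                 levels = levels(labels))
  truth <- factor(test_reactions$label, levels = levels(labels))
  per_class <- vapply(levels(labels), function(cl) {
    pos <- truth == cl
    if (!any(pos)) return(NA_real_)
    mean(pred[pos] == cl)
  }, numeric(1))
  list(accuracy = mean(pred == truth),
       recall_macro = mean(per_class, na.rm = TRUE),
       recall_micro = mean(pred == truth),
       predictions = tibble::tibble(id = te$id, truth = truth, pred = pred))
}

#' Evaluate molecule features with logistic regression
#'
#' The property-prediction harness: fits `glm(label ~ features,
#' binomial)` on the training portion and reports the test AUC.
#'
#' @param model a trained embedding model.
#' @param data a tibble with columns `smiles` and binary `label`,
#'   optionally a `split` column (otherwise an 8:1:1 split is drawn).
#' @param seed split seed when `data` has no `split` column.
#' @return a list with `auc` and the per-molecule `predictions` tibble.
#' @export
evaluate_property <- function(model, data, seed = 1) {
  if (!"split" %in% names(data)) data <- split_dataset(data, seed = seed)
  feats <- molecule_features(model, data$smiles)
  x <- feats$feature
  tr <- data$split == "train"
  te <- data$split == "test"
  df <- data.frame(label = data$label, x)
  fit <- suppressWarnings(stats::glm(label ~ ., data = df[tr, ],
                                     family = stats::binomial()))
  p <- suppressWarnings(stats::predict(fit, df[te, ], type = "response"))
  auc <- if (requireNamespace("pROC", quietly = TRUE) &&
             length(unique(data$label[te])) == 2) {
    as.numeric(pROC::auc(pROC::roc(data$label[te], p, quiet = TRUE)))
  } else NA_real_
  list(auc = auc,
       predictions = tibble::tibble(smiles = data$smiles[te],
                                    label = data$label[te], score = p))
}

#' Relation-embedding diagnostics against bond and ring changes
#'
#' Each reaction's relation vector e is recovered from the trained
#' memory network, and each reaction is characterized by its bond-count
#' change (sum of product-side heavy-atom bonds minus reactant-side
#' bonds) and ring-count change.  For every reaction pair the cosine
#' similarity of the relation vectors is tabulated against the absolute
#' differences of those changes, plus a binned summary (mean change
#' difference per cosine interval).
#'
#' @inheritParams rank_products
#' @param reactions reactions to analyze; defaults to the test split.
#' @param breaks cosine-similarity bin edges for the summary.
#' @return an object of class `re_relation_analysis`: tibbles `reactions`
#'   (`id`, `delta_bonds`, `delta_rings`), `pairs` (`cosine`,
#'   `d_bond_change`, `d_ring_change`) and `summary` (binned means).
#' @export
relation_similarity_analysis <- function(model, reactions = NULL,
                                         breaks = seq(-1, 1, by = 0.25)) {
  if (is.null(reactions)) {
    reactions <- model$data$reactions
    reactions <- reactions[reactions$split == "test", , drop = FALSE]
  }
  emb <- reaction_side_embeddings(model, reactions)
  rel <- score_pairs(emb$xR, emb$xP, model$params$mem_K,
                     model$params$mem_M,
                     model$config$score_norm)$relation
  delta <- side_change_counts(reactions, model$fg_patterns, model$vocab)
  n <- nrow(reactions)
  rn <- sqrt(rowSums(rel^2))
  cosine <- (rel %*% t(rel)) / outer(rn, rn)
  ut <- which(upper.tri(cosine), arr.ind = TRUE)
  pairs <- tibble::tibble(
    i = ut[, 1], j = ut[, 2],
    cosine = cosine[ut],
    d_bond_change = abs(delta$delta_bonds[ut[, 1]] - delta$delta_bonds[ut[, 2]]),
    d_ring_change = abs(delta$delta_rings[ut[, 1]] - delta$delta_rings[ut[, 2]]))
  pairs$bin <- cut(pairs$cosine, breaks = breaks, include.lowest = TRUE)
  summary <- pairs |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(n_pairs = dplyr::n(),
                     mean_d_bond_change = mean(.data$d_bond_change),
                     mean_d_ring_change = mean(.data$d_ring_change),
                     .groups = "drop")
  out <- list(reactions = tibble::tibble(id = reactions$id %||% seq_len(n),
                                         label = reactions$label %||% NA_integer_,
                                         delta_bonds = delta$delta_bonds,
                                         delta_rings = delta$delta_rings),
              relations = rel, pairs = pairs, summary = summary)
  class(out) <- "re_relation_analysis"
  out
}

# Per-reaction bond- and ring-count changes (product side minus
# reactant side, summed over deduplicated side members).
side_change_counts <- function(reactions, fg_patterns = read_fg_patterns(),
                               vocab = feature_vocab()) {
  count_side <- function(sides, what) {
    vapply(side_members(sides), function(ms) {
      sum(vapply(ms, function(s) {
        parse_molecule(s, fg_patterns = fg_patterns, vocab = vocab)[[what]]
      }, numeric(1)))
    }, numeric(1))
  }
  list(delta_bonds = count_side(reactions$products, "bond_count") -
         count_side(reactions$reactants, "bond_count"),
       delta_rings = count_side(reactions$products, "ring_count") -
         count_side(reactions$reactants, "ring_count"))
}
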