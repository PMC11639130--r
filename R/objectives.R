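# Training objectives: margin-based relation loss over in-batch
# negatives, cross-view InfoNCE, and their weighted combination.
#
# Negative pairs are exactly the ordered mismatches (i, j), i != j,
# within a minibatch — both directions — so a batch of B reactions
# contributes B positives and B^2 - B hinge terms.  Negatives refresh
# every epoch through reshuffling of the training reactions.

#' Margin-based relation loss
#'
#' Mean positive score plus the mean hinge `max(gamma - S_neg, 0)` over
#' all ordered mismatched pairs of the batch.  A batch of one reaction
#' has no negatives and the second term is zero.  Pairs whose product
#' sides coincide as sets are still treated as negatives (no
#' deduplication); their count is reported in
#' `attr(, "negative_collisions")` when side identities are supplied.
#'
#' @param pos_scores numeric vector of matched-pair scores S(Ri, Pi).
#' @param neg_scores numeric vector of mismatched-pair scores S(Ri, Pj),
#'   i != j; must have length `B^2 - B`.
#' @param gamma positive margin.
#' @param product_sides optional character vector of the batch's product
#'   side identities, used only to count negative collisions.
#' @return scalar loss.
#' @export
margin_loss <- function(pos_scores, neg_scores = numeric(0), gamma = 4,
                        product_sides = NULL) {
  b <- length(pos_scores)
  stopifnot(b >= 1, gamma > 0)
  expected <- b^2 - b
  if (length(neg_scores) != expected) {
    stop_input("expected ", expected, " negative scores (ordered in-batch ",
               "mismatches), got ", length(neg_scores))
  }
  out <- mean(pos_scores)
  if (expected > 0) out <- out + mean(pmax(gamma - neg_scores, 0))
  if (!is.null(product_sides)) {
    pairs <- negative_pair_index(b)
    attr(out, "negative_collisions") <-
      sum(product_sides[pairs$i] == product_sides[pairs$j])
  }
  out
}

# ordered mismatched pairs (i, j), i != j, of a batch of size b
negative_pair_index <- function(b) {
  g <- expand.grid(i = seq_len(b), j = seq_len(b))
  g <- g[g$i != g$j, , drop = FALSE]
  list(i = g$i, j = g$j)
}

#' Per-view side embeddings of a reaction
#'
#' Sums each side's members separately in the atom-level (hA) and
#' reaction-level (hX) embedding tables — the inputs of the cross-view
#' contrastive loss.
#'
#' @param reactants,products character vectors of member molecule keys.
#' @param hA_table,hX_table embedding matrices with molecule rownames.
#' @return a list with `xR_A`, `xR_X`, `xP_A`, `xP_X`.
#' @export
view_side_embeddings <- function(reactants, products, hA_table, hX_table) {
  list(xR_A = side_embedding(reactants, hA_table),
       xR_X = side_embedding(reactants, hX_table),
       xP_A = side_embedding(products, hA_table),
       xP_X = side_embedding(products, hX_table))
}

#' Cross-view InfoNCE loss
#'
#' For each batch row the anchor is the atom-view side embedding and the
#' positive is the same reaction's reaction-view side embedding; the
#' other rows' reaction-view embeddings are negatives.  Computed as
#' `sum_i -log softmax(c(x_i^A, x_j^X) / tau)[j = i]` with cosine
#' similarity `c`.  A batch of one gives exactly zero.
#'
#' @param view_A,view_X numeric matrices (batch x d) of side embeddings
#'   from the two views, aligned by row.  Zero rows are an error:
#'   cosine similarity is undefined.
#' @param tau positive temperature.
#' @return scalar loss (non-negative).
#' @export
infonce_loss <- function(view_A, view_X, tau = 0.1) {
  stopifnot(nrow(view_A) == nrow(view_X), tau > 0)
  na <- sqrt(rowSums(view_A^2)); nx <- sqrt(rowSums(view_X^2))
  if (any(na == 0) || any(nx == 0)) {
    stop_input("zero-norm embedding: cosine similarity undefined")
  }
  sim <- (view_A / na) %*% t(view_X / nx) / tau
  m <- apply(sim, 1, max)
  lse <- m + log(rowSums(exp(sim - m)))
  sum(lse - diag(sim))
}

#' Total training objective
#'
#' `L = LE + alpha * LC + lambda * ||theta||_F^2`, where the last term
#' sums the squared Frobenius norms of all learnable parameter matrices.
#'
#' @param LE margin relation loss.
#' @param LC combined cross-view loss (reactant side + product side).
#' @param params named list of parameter matrices (may be empty).
#' @param alpha contrastive weight.
#' @param lambda L2 weight.
#' @return scalar loss.
#' @export
total_loss <- function(LE, LC, params = list(), alpha = 1e-3, lambda = 0) {
  reg <- if (lambda > 0) {
    lambda * sum(vapply(params, function(p) sum(p^2), numeric(1)))
  } else 0
  as.numeric(LE) + alpha * as.numeric(LC) + reg
}
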