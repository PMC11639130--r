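# Dual-view fusion and the key/memory relation network.
#
# A reaction side is embedded as the sum of its member molecules' fused
# embeddings.  For a reactant-product pair (xR, xP) the network attends
# over N memory slots with logits (xR * xP)' k_n against the key matrix
# K, and returns the relation vector e as the attention-weighted
# combination of the memory rows of M — a learned translation such that
# xR + e should approximate xP.  The pair score is the (squared)
# Euclidean distance between xR + e and xP; lower is better.

#' Fuse the two molecule views
#'
#' `h = Wc (hA || hX)`: a learned linear map of the concatenated
#' atom-level and reaction-level embeddings back to width d.  `Wc` is
#' stored as a (2d x d) matrix applied on the right of the row vector.
#'
#' @param hA,hX numeric vectors of length d (or matrices with matching
#'   rows).
#' @param Wc fusion weight matrix, 2d x d.
#' @return the fused embedding (vector, or matrix if the inputs were
#'   matrices).
#' @export
fuse <- function(hA, hX, Wc) {
  vec <- is.null(dim(hA))
  if (vec) { hA <- matrix(hA, 1); hX <- matrix(hX, 1) }
  if (ncol(hA) != ncol(hX)) stop_input("hA and hX must have equal width")
  if (nrow(Wc) != ncol(hA) + ncol(hX)) {
    stop_input("Wc must have ", ncol(hA) + ncol(hX), " rows")
  }
  out <- cbind(hA, hX) %*% Wc
  if (vec) as.vector(out) else out
}

#' Sum-pool a reaction side
#'
#' The embedding of a reactant or product side is the sum of its member
#' molecules' embeddings — order-independent, and additive over members.
#'
#' @param members character vector of member molecule keys.
#' @param h_table numeric matrix of molecule embeddings with rownames
#'   covering `members`.
#' @return a numeric vector.
#' @export
side_embedding <- function(members, h_table) {
  if (length(members) == 0) stop_input("a reaction side cannot be empty")
  missing <- setdiff(members, rownames(h_table))
  if (length(missing)) {
    stop_input("no embedding for molecule(s): ",
               paste(missing, collapse = ", "))
  }
  colSums(h_table[members, , drop = FALSE])
}

#' Memory-slot attention for a reactant-product pair
#'
#' `att_n = softmax_n((xR * xP)' k_n)` over the N rows of the key
#' matrix.  If `xR * xP` is the zero vector, or all key rows coincide,
#' the attention is uniform.
#'
#' @param xR,xP side embedding vectors of length d.
#' @param K key matrix, N x d.
#' @return a probability vector of length N.
#' @export
memory_attention <- function(xR, xP, K) {
  logits <- as.vector(K %*% (as.vector(xR) * as.vector(xP)))
  e <- exp(logits - max(logits))
  e / sum(e)
}

#' Relation vector from memory attention
#'
#' `e = sum_n att_n m_n`: a convex combination of the memory rows, so
#' each component of `e` lies between the componentwise extrema of `M`.
#'
#' @param att probability vector of length N.
#' @param M memory matrix, N x d.
#' @return a numeric vector of length d.
#' @export
relation_vector <- function(att, M) {
  as.vector(crossprod(M, att))
}

#' Translation score of a reactant-product pair
#'
#' `S = || xR + e - xP ||^2` (default) or the plain Euclidean norm with
#' `norm = "l2"`.  Zero iff `xP = xR + e` exactly; both conventions rank
#' candidate pairs identically.
#'
#' @param xR,xP,e numeric vectors of length d.
#' @param norm `"squared"` or `"l2"`.
#' @return a non-negative scalar.
#' @export
reaction_score <- function(xR, xP, e, norm = c("squared", "l2")) {
  norm <- match.arg(norm)
  s <- sum((as.vector(xR) + as.vector(e) - as.vector(xP))^2)
  if (norm == "l2") sqrt(s) else s
}

# Vectorized pair scoring: XR and XP hold one pair per row; the relation
# vector is recomputed for every pair.  Returns scores, attention and
# relation matrices.
score_pairs <- function(XR, XP, K, M, norm = "squared") {
  att <- row_softmax((XR * XP) %*% t(K))
  E <- att %*% M
  s <- rowSums((XR + E - XP)^2)
  if (norm == "l2") s <- sqrt(s)
  list(score = s, att = att, relation = E)
}

# Tape version used inside the training objective; `pi`/`pj` index the
# (reactant, product) pairs into the batch side-embedding matrices.
forward_pair_scores <- function(tp, xR, xP, pi_, pj, pids, config) {
  XRp <- ad_gather(tp, xR, pi_)
  XPp <- ad_gather(tp, xP, pj)
  att <- ad_softmax_rows(tp, ad_matmul_nt(tp, ad_emul(tp, XRp, XPp),
                                          pids$mem_K))
  E <- ad_matmul(tp, att, pids$mem_M)
  D <- ad_sub(tp, ad_add(tp, XRp, E), XPp)
  S <- ad_rowsums(tp, ad_emul(tp, D, D))
  if (config$score_norm == "l2") S <- ad_sqrt(tp, S)
  S
}
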