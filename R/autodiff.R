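# Minimal reverse-mode automatic differentiation on matrices.
#
# The model is a composition of (sparse) matrix products, row gathers /
# scatters, elementwise products, grouped softmaxes and a handful of
# fused loss heads.  A tape records each operation eagerly with a
# closure computing the vector-Jacobian product; ad_backward() walks the
# tape in reverse, accumulating gradients only along paths that reach a
# parameter.  Analytic gradients are validated against central finite
# differences in the test suite.
#
# Node-id arguments are force()d on entry: `tp$vals[[a]]` must not
# extract the value list before a nested operation (still an unforced
# promise) has pushed its node.
#
# Values are plain numeric matrices; constant structure matrices
# (adjacency, incidence, gather/scatter maps) enter as `Matrix` sparse
# matrices on the constant side of ad_lmul()/ad_rmul() and never receive
# gradients.

ad_tape <- function() {
  tp <- new.env(parent = emptyenv())
  tp$vals <- list()
  tp$parents <- list()
  tp$backs <- list()
  tp$n <- 0L
  tp$param_ids <- integer()
  tp$param_names <- character()
  tp
}

ad_push <- function(tp, val, parents = integer(), back = NULL) {
  i <- tp$n + 1L
  tp$n <- i
  tp$vals[[i]] <- val
  tp$parents[[i]] <- parents
  tp$backs[[i]] <- back
  i
}

ad_const <- function(tp, x) ad_push(tp, x)

ad_param <- function(tp, x, name) {
  id <- ad_push(tp, x)
  tp$param_ids <- c(tp$param_ids, id)
  tp$param_names <- c(tp$param_names, name)
  id
}

ad_value <- function(tp, id) {
  force(id)
  tp$vals[[id]]
}

ad_add <- function(tp, a, b) {
  force(a); force(b)
  ad_push(tp, tp$vals[[a]] + tp$vals[[b]], c(a, b),
          function(g) list(g, g))
}

ad_sub <- function(tp, a, b) {
  force(a); force(b)
  ad_push(tp, tp$vals[[a]] - tp$vals[[b]], c(a, b),
          function(g) list(g, -g))
}

ad_emul <- function(tp, a, b) {
  force(a); force(b)
  va <- tp$vals[[a]]; vb <- tp$vals[[b]]
  ad_push(tp, va * vb, c(a, b),
          function(g) list(g * vb, g * va))
}

# mult * a + shift, with numeric scalars mult/shift
ad_affine <- function(tp, a, mult = 1, shift = 0) {
  force(a)
  ad_push(tp, mult * tp$vals[[a]] + shift, a,
          function(g) list(mult * g))
}

ad_matmul <- function(tp, a, b) {
  force(a); force(b)
  va <- tp$vals[[a]]; vb <- tp$vals[[b]]
  ad_push(tp, va %*% vb, c(a, b),
          function(g) list(g %*% t(vb), t(va) %*% g))
}

# a %*% t(b)
ad_matmul_nt <- function(tp, a, b) {
  force(a); force(b)
  va <- tp$vals[[a]]; vb <- tp$vals[[b]]
  ad_push(tp, va %*% t(vb), c(a, b),
          function(g) list(g %*% vb, t(g) %*% va))
}

# A %*% b with constant (possibly sparse) A
ad_lmul <- function(tp, A, b) {
  force(b)
  ad_push(tp, as.matrix(A %*% tp$vals[[b]]), b,
          function(g) list(as.matrix(Matrix::crossprod(A, g))))
}

# a %*% B with constant B
ad_rmul <- function(tp, a, B) {
  force(a)
  ad_push(tp, as.matrix(tp$vals[[a]] %*% B), a,
          function(g) list(as.matrix(Matrix::tcrossprod(g, B))))
}

ad_gather <- function(tp, a, idx) {
  force(a)
  va <- tp$vals[[a]]
  nr <- nrow(va)
  ad_push(tp, va[idx, , drop = FALSE], a, function(g) {
    acc <- matrix(0, nr, ncol(g))
    rs <- rowsum(g, group = idx)
    acc[as.integer(rownames(rs)), ] <- rs
    list(acc)
  })
}

# rows of a scaled by the column vector s (node, n x 1)
ad_scale_rows <- function(tp, a, s) {
  force(a); force(s)
  va <- tp$vals[[a]]; vs <- as.vector(tp$vals[[s]])
  ad_push(tp, va * vs, c(a, s), function(g) {
    list(g * vs, matrix(rowSums(g * va), ncol = 1))
  })
}

ad_relu <- function(tp, a) {
  force(a)
  va <- tp$vals[[a]]
  ad_push(tp, pmax(va, 0), a, function(g) list(g * (va > 0)))
}

ad_leaky_relu <- function(tp, a, slope = 0.2) {
  force(a)
  va <- tp$vals[[a]]
  ad_push(tp, ifelse(va > 0, va, slope * va), a,
          function(g) list(g * ifelse(va > 0, 1, slope)))
}

ad_sqrt <- function(tp, a, eps = 1e-12) {
  force(a)
  v <- sqrt(pmax(tp$vals[[a]], 0))
  ad_push(tp, v, a, function(g) list(g / (2 * pmax(v, eps))))
}

ad_rowsums <- function(tp, a) {
  force(a)
  va <- tp$vals[[a]]
  ad_push(tp, matrix(rowSums(va), ncol = 1), a,
          function(g) list(matrix(as.vector(g), nrow(va), ncol(va))))
}

ad_sum <- function(tp, a) {
  force(a)
  va <- tp$vals[[a]]
  ad_push(tp, matrix(sum(va), 1, 1), a,
          function(g) list(matrix(as.vector(g), nrow(va), ncol(va))))
}

ad_cbind <- function(tp, a, b) {
  force(a); force(b)
  va <- tp$vals[[a]]; vb <- tp$vals[[b]]
  na <- ncol(va)
  ad_push(tp, cbind(va, vb), c(a, b), function(g) {
    list(g[, seq_len(na), drop = FALSE],
         g[, na + seq_len(ncol(vb)), drop = FALSE])
  })
}

# softmax within each row
ad_softmax_rows <- function(tp, a) {
  force(a)
  p <- row_softmax(tp$vals[[a]])
  ad_push(tp, p, a, function(g) {
    list(p * (g - rowSums(p * g)))
  })
}

# softmax of a column vector of logits within groups
ad_group_softmax <- function(tp, a, groups) {
  force(a)
  v <- as.vector(tp$vals[[a]])
  p <- numeric(length(v))
  for (grp in split(seq_along(v), groups)) {
    e <- exp(v[grp] - max(v[grp]))
    p[grp] <- e / sum(e)
  }
  pm <- matrix(p, ncol = 1)
  ad_push(tp, pm, a, function(g) {
    gv <- as.vector(g)
    dot <- rowsum(gv * p, groups)
    key <- match(as.character(groups), rownames(dot))
    list(matrix(p * (gv - dot[key]), ncol = 1))
  })
}

# rows normalized to unit L2 norm; errors on zero rows (cosine undefined)
ad_normalize_rows <- function(tp, a) {
  force(a)
  va <- tp$vals[[a]]
  nr <- sqrt(rowSums(va^2))
  if (any(nr == 0)) stop_input("zero-norm embedding: cosine similarity undefined")
  v <- va / nr
  ad_push(tp, v, a, function(g) {
    list((g - v * rowSums(g * v)) / nr)
  })
}

# InfoNCE head: given an n x n similarity matrix with positives on the
# diagonal, returns sum_i -log softmax(sim[i, ] / tau)[i]
ad_infonce <- function(tp, sim, tau) {
  force(sim)
  s <- tp$vals[[sim]] / tau
  m <- apply(s, 1, max)
  lse <- m + log(rowSums(exp(s - m)))
  val <- sum(lse - diag(s))
  p <- exp(s - lse)           # row softmax
  ad_push(tp, matrix(val, 1, 1), sim, function(g) {
    list(as.vector(g) * (p - diag(nrow(p))) / tau)
  })
}

ad_backward <- function(tp, loss_id) {
  grads <- vector("list", tp$n)
  grads[[loss_id]] <- matrix(1, 1, 1)
  needed <- logical(tp$n)
  needed[tp$param_ids] <- TRUE
  for (i in seq_len(tp$n)) {
    ps <- tp$parents[[i]]
    if (length(ps) && any(needed[ps])) needed[i] <- TRUE
  }
  for (i in tp$n:1) {
    g <- grads[[i]]
    if (is.null(g) || is.null(tp$backs[[i]])) next
    pg <- tp$backs[[i]](g)
    ps <- tp$parents[[i]]
    for (k in seq_along(ps)) {
      p <- ps[k]
      if (!needed[p] || is.null(pg[[k]])) next
      grads[[p]] <- if (is.null(grads[[p]])) pg[[k]] else grads[[p]] + pg[[k]]
    }
    grads[i] <- list(NULL)   # free as we go; keep list indices aligned
  }
  stats::setNames(lapply(tp$param_ids, function(i) grads[[i]]),
                  tp$param_names)
}
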