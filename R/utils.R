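# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG state, restoring the caller's state.
# RNG kind is pinned so seeded results do not drift across R versions.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed) %% .Machine$integer.max,
           kind = "Mersenne-Twister", sample.kind = "Rejection")
  expr
}

# sample() without the length-1 surprise
sample_safe <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# named-vector lookup with a zero default
qget <- function(q, nm) if (nm %in% names(q)) q[[nm]] else 0L

stop_input <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 1 && x == floor(x)

# Connected components of an undirected graph given as a 2-column edge
# matrix over nodes 1..n (union-find).
graph_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (length(edges)) {
    for (k in seq_len(nrow(edges))) {
      a <- find(edges[k, 1]); b <- find(edges[k, 2])
      if (a != b) parent[a] <- b
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

row_softmax <- function(x) {
  m <- apply(x, 1, max)
  e <- exp(x - m)
  e / rowSums(e)
}
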