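# Shared test objects.  Everything is generated in code; expensive
# pieces are built once per test run and memoized here.

.test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.test_cache[[key]])) .test_cache[[key]] <- force(expr)
  .test_cache[[key]]
}

# small, frequently reused parsed molecules
tmol <- function(smiles) {
  cached(paste0("mol:", smiles), parse_molecule(smiles))
}

# a tiny labeled reaction corpus (8 reactions, 4 families)
tiny_corpus <- function() cached("tiny", golden_fixture("tiny"))

small_corpus <- function() cached("small", golden_fixture("small"))

# desk-scale training configuration: paper-default model hyperparameters
# (gamma 4, tau 0.1, alpha 1e-3, Q 10, N 10, K 2, L 1) with width,
# batch size and learning rate rescaled for a 200-reaction corpus
desk_config <- function(seed = 1, epochs = 50, ...) {
  defaults <- list(aggregator = "gcn", layers = 2L, dim = 32L,
                   rx_layers = 1L, Q = 10L, N = 10L, gamma = 4, tau = 0.1,
                   alpha = 1e-3, batch_size = 32L, learning_rate = 5e-3,
                   epochs = epochs, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(model_config, args)
}

# central finite-difference gradient of f (scalar-valued) w.r.t. a
# named list of parameter matrices
fd_gradients <- function(f, params, h = 1e-5) {
  lapply(params, function(p) p)  # shape template
  out <- params
  for (nm in names(params)) {
    g <- params[[nm]] * 0
    for (i in seq_along(params[[nm]])) {
      up <- params; up[[nm]][i] <- up[[nm]][i] + h
      dn <- params; dn[[nm]][i] <- dn[[nm]][i] - h
      g[i] <- (f(up) - f(dn)) / (2 * h)
    }
    out[[nm]] <- g
  }
  out
}

expect_near <- function(a, b, tol = 1e-8) {
  expect_lt(max(abs(a - b)), tol)
}
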