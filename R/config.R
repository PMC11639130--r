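# Model and training configuration.

#' Model configuration
#'
#' Collects every tunable of the embedding model and its training loop.
#' Defaults follow the reference setting for large reaction corpora
#' (d = 256, 2 molecular-graph layers, 1 reaction-graph layer, Q = 10
#' sampled neighbors, N = 10 memory slots, margin 4, temperature 0.1,
#' contrastive weight 1e-3, Adam at 1e-4 for 50 epochs with batches of
#' 1024).  For small corpora, scale `dim`, `batch_size` and
#' `learning_rate` down together; see the package vignette.
#'
#' @param aggregator molecular-graph message-passing rule: `"gcn"`
#'   (symmetrically normalized mean), `"gat"` (learned attention),
#'   `"sage"` (self/neighbor-mean concatenation) or `"tag"`
#'   (k-hop polynomial).
#' @param layers number of molecular-graph layers K.
#' @param dim embedding width d of every layer.
#' @param rx_layers number of reaction-aware graph layers L.
#' @param Q neighbor sample size in the reaction-aware graph.
#' @param N memory slot count of the relation network.
#' @param gamma margin of the relation ranking loss.
#' @param tau temperature of the cross-view InfoNCE loss.
#' @param alpha weight of the cross-view loss in the total objective.
#' @param l2 L2 penalty weight on all parameters (0 = off).
#' @param score_norm `"squared"` (default) scores a pair by the squared
#'   Euclidean distance between translated reactant and product
#'   embeddings; `"l2"` uses the plain distance.  Rankings agree.
#' @param tag_hops hop count of the TAG aggregator.
#' @param leaky_slope negative slope of the GAT attention nonlinearity.
#' @param epochs,batch_size,learning_rate Adam training schedule;
#'   `epochs = 0` returns the initialized (untrained) model, e.g. as a
#'   random baseline.
#' @param seed master seed: parameter init, neighbor sampling and batch
#'   shuffling all derive from it, so runs are reproducible.
#' @return a list of class `re_config`.
#' @export
model_config <- function(aggregator = c("gcn", "gat", "sage", "tag"),
                         layers = 2L, dim = 256L, rx_layers = 1L,
                         Q = 10L, N = 10L,
                         gamma = 4, tau = 0.1, alpha = 1e-3, l2 = 0,
                         score_norm = c("squared", "l2"),
                         tag_hops = 2L, leaky_slope = 0.2,
                         epochs = 50L, batch_size = 1024L,
                         learning_rate = 1e-4, seed = 1L) {
  aggregator <- match.arg(aggregator)
  score_norm <- match.arg(score_norm)
  stopifnot(is_count(layers), is_count(dim), is_count(rx_layers),
            is_count(Q), is_count(N), gamma > 0, tau > 0, alpha >= 0,
            l2 >= 0, epochs >= 0, epochs == floor(epochs),
            is_count(batch_size), learning_rate > 0)
  structure(list(aggregator = aggregator, layers = as.integer(layers),
                 dim = as.integer(dim), rx_layers = as.integer(rx_layers),
                 Q = as.integer(Q), N = as.integer(N), gamma = gamma,
                 tau = tau, alpha = alpha, l2 = l2, score_norm = score_norm,
                 tag_hops = as.integer(tag_hops), leaky_slope = leaky_slope,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, seed = as.integer(seed)),
            class = "re_config")
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

# Parameter set for a given feature width F0 and fg catalog size.
# Glorot-uniform weights; key/memory matrices are N(0, 1/d) so that
# attention logits start at O(1).
init_params <- function(config, f0, n_fg = 39L) {
  d <- config$dim
  with_seed(config$seed, {
    p <- list(atom_proj = glorot(f0, d))
    for (k in seq_len(config$layers)) {
      nm <- function(s) paste0("enc", k, "_", s)
      p[[nm("W")]] <- switch(config$aggregator,
        gcn = glorot(d, d),
        gat = glorot(d, d),
        sage = glorot(2L * d, d),
        tag = glorot((config$tag_hops + 1L) * d, d))
      if (config$aggregator == "gat") {
        p[[nm("al")]] <- glorot(d, 1L)
        p[[nm("ar")]] <- glorot(d, 1L)
      }
    }
    p$fg_proj <- glorot(n_fg, d)
    for (l in seq_len(config$rx_layers)) {
      p[[paste0("rx", l, "_Wa")]] <- glorot(1L, d)
    }
    p$fuse_W <- glorot(2L * d, d)
    p$mem_K <- matrix(stats::rnorm(config$N * d, sd = 1 / sqrt(d)),
                      config$N, d)
    p$mem_M <- matrix(stats::rnorm(config$N * d, sd = 1 / sqrt(d)),
                      config$N, d)
    p
  })
}
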