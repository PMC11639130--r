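# Training loop: Adam over the joint objective, epoch-level shuffling
# (which also refreshes the in-batch negatives), per-epoch validation
# ranking, and checkpointing on the best validation MRR.

adam_state <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, l2 = 0) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (l2 > 0) g <- g + 2 * l2 * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Train a reaction-enhanced embedding model
#'
#' Fits the dual-view embedding model: molecular-graph encoder,
#' reaction-aware graph encoder (built from the training split only),
#' fusion, and the key/memory relation network, by minimizing the
#' margin relation loss plus `alpha` times the cross-view InfoNCE loss
#' (plus an optional L2 penalty) with Adam.  Negatives are the in-batch
#' mismatched pairs and refresh every epoch through reshuffling.  After
#' each epoch the validation reactions are ranked and the parameters
#' with the best validation MRR are kept.
#'
#' @param reactions a reaction tibble (see [read_reaction_file()]); if
#'   it has no `split` column an 8:1:1 split is drawn from
#'   `config$seed`.
#' @param config a [model_config()].
#' @param fg_patterns functional-group catalog.
#' @param vocab atom feature vocabulary.
#' @param verbose print per-epoch progress.
#' @return an object of class `re_model` with elements `params` (best
#'   checkpoint), `final_params`, `trace` (per-epoch tibble with
#'   `epoch`, `LE`, `LC`, `loss`, `val_mrr`), `best_epoch`, `config`,
#'   and the dataset constants under `data`.
#' @export
train_reaction_model <- function(reactions, config = model_config(),
                                 fg_patterns = read_fg_patterns(),
                                 vocab = feature_vocab(),
                                 verbose = FALSE) {
  if (!"split" %in% names(reactions)) {
    reactions <- split_dataset(reactions, seed = config$seed)
  }
  data <- model_data(reactions, config, fg_patterns, vocab)
  params <- init_params(config, f0 = vocab$dim, n_fg = nrow(fg_patterns))
  state <- adam_state(params)
  train_ids <- which(reactions$split == "train")
  valid <- reactions[reactions$split == "valid", , drop = FALSE]
  trace <- vector("list", config$epochs)
  best <- list(mrr = -Inf, params = params, epoch = 0L)
  model_stub <- function(p) {
    structure(list(params = p, config = config, vocab = vocab,
                   fg_patterns = fg_patterns, data = data),
              class = "re_model")
  }
  for (epoch in seq_len(config$epochs)) {
    order <- with_seed(derive_seed(config$seed, 1L, epoch),
                       sample(train_ids))
    sample <- sample_all_edges(data$graph, config$Q,
                               derive_seed(config$seed, 2L, epoch))
    batches <- split(order, ceiling(seq_along(order) / config$batch_size))
    ep <- c(LE = 0, LC = 0, loss = 0)
    for (bi in seq_along(batches)) {
      tp <- ad_tape()
      pids <- push_params(tp, params)
      obj <- batch_objective(tp, pids, data, config, sample, batches[[bi]])
      lval <- as.numeric(ad_value(tp, obj$loss)) +
        if (config$l2 > 0) config$l2 * sum(vapply(params, function(p)
          sum(p^2), numeric(1))) else 0
      if (!is.finite(lval)) {
        stop_input("non-finite loss in epoch ", epoch, ", batch ", bi,
                   " (reactions ", paste(utils::head(batches[[bi]], 5),
                                         collapse = ", "), " ...)")
      }
      grads <- ad_backward(tp, obj$loss)
      upd <- adam_step(params, grads, state, config$learning_rate,
                       l2 = config$l2)
      params <- upd$params
      state <- upd$state
      w <- length(batches[[bi]]) / length(train_ids)
      ep <- ep + w * c(obj$LE, obj$LC, lval)
    }
    val_mrr <- NA_real_
    if (nrow(valid) > 0) {
      rk <- rank_products(model_stub(params), valid)
      val_mrr <- rk$mrr
      if (val_mrr > best$mrr) {
        best <- list(mrr = val_mrr, params = params, epoch = epoch)
      }
    }
    trace[[epoch]] <- tibble::tibble(epoch = epoch, LE = ep[["LE"]],
                                     LC = ep[["LC"]], loss = ep[["loss"]],
                                     val_mrr = val_mrr)
    if (verbose) {
      message(sprintf("epoch %3d  loss %.4f  LE %.4f  LC %.4f  val MRR %s",
                      epoch, ep[["loss"]], ep[["LE"]], ep[["LC"]],
                      ifelse(is.na(val_mrr), "-", sprintf("%.3f", val_mrr))))
    }
  }
  if (!is.finite(best$mrr)) best <- list(mrr = NA_real_, params = params,
                                         epoch = config$epochs)
  structure(list(params = best$params, final_params = params,
                 best_epoch = best$epoch, best_val_mrr = best$mrr,
                 trace = dplyr::bind_rows(trace), config = config,
                 vocab = vocab, fg_patterns = fg_patterns, data = data),
            class = "re_model")
}

#' @export
print.re_model <- function(x, ...) {
  cat("<reaction embedding model>\n",
      "  aggregator: ", x$config$aggregator,
      "  d = ", x$config$dim,
      "  K = ", x$config$layers, " molecular layers, L = ",
      x$config$rx_layers, " reaction layers\n",
      "  trained ", nrow(x$trace), " epochs; best validation MRR ",
      sprintf("%.3f", x$best_val_mrr), " at epoch ", x$best_epoch, "\n",
      sep = "")
  invisible(x)
}
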