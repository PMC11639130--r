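# broom-style tidiers and ggplot2 autoplot methods.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a trained embedding model
#'
#' @param x an `re_model`.
#' @param ... unused.
#' @return the per-epoch training trace as a tibble (`epoch`, `LE`,
#'   `LC`, `loss`, `val_mrr`).
#' @export
tidy.re_model <- function(x, ...) x$trace

#' @rdname tidy.re_model
#' @return for `glance()`: a one-row tibble summarizing the fit.
#' @export
glance.re_model <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$trace),
                 best_epoch = x$best_epoch,
                 best_val_mrr = x$best_val_mrr,
                 final_loss = x$trace$loss[nrow(x$trace)],
                 aggregator = x$config$aggregator,
                 dim = x$config$dim,
                 n_parameters = sum(vapply(x$params, length, integer(1))))
}

#' @export
tidy.re_ranking <- function(x, ...) x$reactions

#' @export
glance.re_ranking <- function(x, ...) {
  tibble::tibble(n_reactions = nrow(x$reactions),
                 n_candidates = x$n_candidates,
                 mrr = x$mrr, hit1 = x$hit1)
}

#' @export
tidy.re_relation_analysis <- function(x, ...) x$pairs

#' @export
glance.re_relation_analysis <- function(x, ...) {
  tibble::tibble(n_reactions = nrow(x$reactions),
                 n_pairs = nrow(x$pairs),
                 cor_bond = stats::cor(x$pairs$cosine, x$pairs$d_bond_change),
                 cor_ring = stats::cor(x$pairs$cosine, x$pairs$d_ring_change))
}

#' Plot the training trace
#'
#' Loss components and validation MRR per epoch.
#'
#' @param object an `re_model`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.re_model <- function(object, ...) {
  long <- tidyr::pivot_longer(object$trace,
                              cols = c("loss", "LE", "LC", "val_mrr"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, title = "training trace")
}

#' @export
autoplot.re_ranking <- function(object, ...) {
  ggplot2::ggplot(object$reactions, ggplot2::aes(x = .data$rank)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "rank of true product side", y = "reactions",
                  title = sprintf("MRR %.3f, Hit@1 %.3f",
                                  object$mrr, object$hit1))
}

#' @export
autoplot.re_relation_analysis <- function(object, ...) {
  long <- tidyr::pivot_longer(object$summary,
                              cols = c("mean_d_bond_change",
                                       "mean_d_ring_change"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$bin, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "relation-vector cosine similarity",
                  y = "mean absolute change difference")
}
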