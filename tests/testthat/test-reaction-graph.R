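# Reaction-aware graph construction, neighbor sampling and
# context-conditioned attention aggregation.

ns <- asNamespace("reactembed")

graph_from_lines <- function(lines) {
  build_reaction_aware_graph(reaction_table(lines))
}

test_that("one reaction wires each reactant to every product", {
  # A -> {F, G, H}: a 4-node star with 3 edges, A adjacent to all three
  g <- graph_from_lines("CCO>>CC=O.CC(C)O.CCC")
  expect_equal(length(g$nodes), 4L)
  expect_equal(nrow(g$edges), 3L)
  a <- g$node_index[[tmol("CCO")$canonical_smiles]]
  expect_setequal(g$incident[[a]]$nb, setdiff(seq_len(4), a))
})

test_that("shared products create second-order neighbors", {
  # A -> F and B -> F: A and B are not adjacent but meet through F
  g <- graph_from_lines(c("CCO>>CC=O", "CCCO>>CC=O"))
  a <- g$node_index[[tmol("CCO")$canonical_smiles]]
  b <- g$node_index[[tmol("CCCO")$canonical_smiles]]
  f <- g$node_index[[tmol("CC=O")$canonical_smiles]]
  expect_false(b %in% g$incident[[a]]$nb)
  expect_setequal(g$incident[[a]]$nb, f)
  expect_setequal(g$incident[[b]]$nb, f)
  expect_setequal(g$incident[[f]]$nb, c(a, b))
})

test_that("a reaction with sides of sizes a and b contributes a*b edges", {
  g <- graph_from_lines("CCO.CC(=O)O>>CCOC(C)=O.O")
  expect_equal(nrow(g$edges), 4L)
  # and over a generated corpus the total is the sum of per-reaction a*b
  rx <- tiny_corpus()
  gg <- build_reaction_aware_graph(rx)
  expect_equal(nrow(gg$edges), sum(rx$n_reactants * rx$n_products))
})

test_that("graph construction is order-invariant", {
  rx <- tiny_corpus()
  g1 <- build_reaction_aware_graph(rx)
  g2 <- build_reaction_aware_graph(rx[rev(seq_len(nrow(rx))), ])
  expect_setequal(g1$nodes, g2$nodes)
  canon_edges <- function(g) {
    e <- g$edges
    sort(paste(g$nodes[e$reactant_node], g$nodes[e$product_node],
               e$reaction_id))
  }
  expect_identical(canon_edges(g1), canon_edges(g2))
})

test_that("neighbor sampling pads, subsamples and is seed-deterministic", {
  g <- graph_from_lines("CCO>>CC=O.CC(C)O.CCC")
  a <- g$node_index[[tmol("CCO")$canonical_smiles]]
  s <- sample_neighbors(g, a, Q = 10, seed = 4)
  expect_equal(nrow(s), 10L)                       # padded with replacement
  expect_setequal(unique(s$neighbor), g$incident[[a]]$nb)
  expect_identical(s, sample_neighbors(g, a, Q = 10, seed = 4))
  # high-degree node: distinct draws
  lines <- paste0("CCO>>", vapply(3:25, function(k)
    paste(rep("C", k), collapse = ""), character(1)))
  gh <- graph_from_lines(lines)
  hub <- gh$node_index[[tmol("CCO")$canonical_smiles]]
  sh <- sample_neighbors(gh, hub, Q = 10, seed = 1)
  expect_equal(nrow(sh), 10L)
  expect_equal(anyDuplicated(sh$neighbor), 0L)
  # degree-zero node: empty sample, no error
  lone <- structure(list(incident = list(list(nb = integer(),
                                              rx = integer())),
                         node_index = c(x = 1L)), class = "re_rxgraph")
  expect_equal(nrow(sample_neighbors(lone, 1, Q = 5, seed = 1)), 0L)
})

test_that("attention scores are the softmax of Wa.(mi*mj*c)", {
  # identical neighbors and zero context both give uniform attention
  m_i <- c(1, 2)
  nb <- rbind(c(3, 1), c(3, 1))
  expect_equal(attention_scores(m_i, nb, c(1, 1), c(1, 1)), c(0.5, 0.5))
  nb2 <- rbind(c(1, 0), c(0, 1))
  expect_equal(attention_scores(m_i, nb2, c(0, 0), c(2, -1)), c(0.5, 0.5))
  # hand-computed: logits (1, 2)
  pi_ <- attention_scores(m_i, nb2, c(1, 1), c(1, 1))
  expect_near(pi_, c(exp(1), exp(2)) / (exp(1) + exp(2)), 1e-12)
  expect_equal(attention_scores(m_i, nb2[0, , drop = FALSE], c(1, 1),
                                c(1, 1)), numeric(0))
  # normalization holds for random inputs
  set.seed(8)
  for (k in 1:20) {
    p <- attention_scores(rnorm(4), matrix(rnorm(12), 3), rnorm(4), rnorm(4))
    expect_near(sum(p), 1, 1e-6)
  }
})

test_that("one aggregation layer matches hand computation", {
  g <- graph_from_lines("CCO>>CC=O.CC(C)O")
  n <- length(g$nodes)
  d <- 2
  set.seed(5)
  states <- matrix(rnorm(n * d), n, d)
  Wa <- c(0.5, -1)
  out <- aggregate_reaction_layer(g, states, Wa, Q = 4, seed = 9)
  # replicate with the same internal sample and scalar arithmetic
  smp <- ns$sample_all_edges(g, 4, 9)
  want <- states
  ctx <- colSums(states)                    # single reaction, all members
  for (i in unique(smp$i)) {
    sel <- smp$i == i
    pi_ <- attention_scores(states[i, ],
                            states[smp$j[sel], , drop = FALSE], ctx, Wa)
    want[i, ] <- states[i, ] +
      colSums(pi_ * states[smp$j[sel], , drop = FALSE])
  }
  expect_near(out, want, 1e-10)
})

test_that("single-neighbor and isolated nodes reduce as expected", {
  g <- graph_from_lines("CCO>>CC=O")
  set.seed(1)
  states <- matrix(rnorm(4), 2, 2)
  out <- aggregate_reaction_layer(g, states, Wa = c(1, 1), Q = 3, seed = 2)
  # softmax over copies of the single neighbor is 1: residual + neighbor
  expect_near(out[1, ], states[1, ] + states[2, ], 1e-12)
  expect_near(out[2, ], states[2, ] + states[1, ], 1e-12)
})

test_that("encode_reaction_view returns projected fg counts for isolated nodes", {
  rx <- reaction_table(c("CCO>>CC=O", "CCCCO>>CCC=O"))
  g <- build_reaction_aware_graph(rx)
  cfg <- model_config(dim = 6, rx_layers = 1)
  p <- ns$init_params(cfg, f0 = feature_vocab()$dim)
  hx <- encode_reaction_view(g, p, cfg, seed = 3)
  expect_equal(dim(hx), c(length(g$nodes), 6L))
  # with zero attention weights the layer is mean-style aggregation
  p0 <- p
  p0$rx1_Wa <- matrix(0, 1, 6)
  hx0 <- encode_reaction_view(g, p0, cfg, seed = 3)
  m0 <- g$FG %*% p0$fg_proj
  smp <- ns$sample_all_edges(g, cfg$Q, 3)
  for (i in seq_along(g$nodes)) {
    sel <- smp$i == i
    want <- m0[i, ] + if (any(sel))
      colMeans(m0[smp$j[sel], , drop = FALSE]) else 0
    expect_near(hx0[i, ], want, 1e-9)
  }
})
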