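# Margin relation loss, cross-view InfoNCE and the combined objective.

ns <- asNamespace("reactembed")

test_that("margin loss averages positives and in-batch hinge negatives", {
  # a batch of one has no negatives
  expect_equal(margin_loss(0.5, numeric(0), gamma = 4), 0.5)
  # two reactions, all scores zero: both ordered negatives hit the
  # margin fully, so the loss is 0 + gamma
  expect_equal(margin_loss(c(0, 0), c(0, 0), gamma = 4), 4)
  # saturated negatives contribute nothing
  expect_equal(margin_loss(c(1, 2), c(5, 7), gamma = 4), 1.5)
  # mixed case by hand: mean(pos) + mean(max(gamma - neg, 0))
  expect_equal(margin_loss(c(1, 3), c(1, 6), gamma = 4), 2 + (3 + 0) / 2)
  # the negative count must be exactly B^2 - B (ordered mismatches)
  expect_error(margin_loss(c(1, 2), c(1, 2, 3), gamma = 4), "negative scores")
  # product-side collisions are counted, not deduplicated
  l <- margin_loss(c(0, 0), c(0, 0), gamma = 4,
                   product_sides = c("X", "X"))
  expect_equal(attr(l, "negative_collisions"), 2L)
})

test_that("per-view side embeddings sum members order-independently", {
  hA <- rbind(a = c(1, 0), b = c(2, 2), c = c(0, 3))
  hX <- -hA
  v <- view_side_embeddings("a", c("b", "c"), hA, hX)
  expect_equal(v$xR_A, c(1, 0))
  expect_equal(v$xR_X, c(-1, 0))
  expect_equal(v$xP_A, c(2, 5))
  v2 <- view_side_embeddings("a", c("c", "b"), hA, hX)
  expect_equal(v, v2)
  expect_error(view_side_embeddings(character(), "a", hA, hX), "empty")
})

test_that("InfoNCE matches hand values and the brute-force cross-entropy", {
  # singleton batch: numerator equals denominator
  expect_equal(infonce_loss(matrix(c(1, 2), 1), matrix(c(1, 2), 1),
                            tau = 1), 0)
  # identical positives, orthogonal cross pairs, tau = 1:
  # each anchor contributes -log(e / (e + 1))
  A <- rbind(c(1, 0), c(0, 1))
  expect_near(infonce_loss(A, A, tau = 1), -2 * log(exp(1) / (exp(1) + 1)),
              1e-12)
  # brute-force oracle: cross-entropy of the row-softmaxed cosine
  # similarity matrix against the identity labeling
  set.seed(9)
  for (r in 1:5) {
    VA <- matrix(rnorm(4 * 6), 4, 6)
    VX <- matrix(rnorm(4 * 6), 4, 6)
    tau <- runif(1, 0.05, 1)
    sim <- matrix(0, 4, 4)
    for (i in 1:4) for (j in 1:4) {
      sim[i, j] <- sum(VA[i, ] * VX[j, ]) /
        sqrt(sum(VA[i, ]^2) * sum(VX[j, ]^2)) / tau
    }
    ce <- 0
    for (i in 1:4) {
      p <- exp(sim[i, ]) / sum(exp(sim[i, ]))
      ce <- ce - log(p[i])
    }
    expect_near(infonce_loss(VA, VX, tau), ce, 1e-6)
  }
  expect_error(infonce_loss(rbind(c(0, 0)), rbind(c(1, 1)), 0.1),
               "zero-norm")
})

test_that("InfoNCE is non-negative and sharpens as tau decreases", {
  set.seed(10)
  VA <- matrix(rnorm(5 * 8), 5, 8)
  VX <- VA + 0.1 * matrix(rnorm(5 * 8), 5, 8)  # positives dominate
  taus <- c(1, 0.5, 0.2, 0.1, 0.05)
  losses <- vapply(taus, function(t) infonce_loss(VA, VX, t), numeric(1))
  expect_true(all(losses >= 0))
  expect_true(all(diff(losses) <= 1e-10))
})

test_that("the total objective combines terms and the L2 penalty", {
  expect_equal(total_loss(3, 7, alpha = 0, lambda = 0), 3)
  expect_equal(total_loss(1, 2, params = list(W = matrix(0, 2, 2)),
                          alpha = 1e-3, lambda = 1), 1.002)
  # hand arithmetic: 1 + 0.001 * 2 + 0.01 * 100 = 2.002
  expect_equal(total_loss(1, 2, params = list(W = matrix(10, 1, 1)),
                          alpha = 1e-3, lambda = 0.01), 2.002)
})

test_that("in-batch negatives are exactly the ordered mismatches", {
  for (b in c(2, 3, 5)) {
    idx <- ns$negative_pair_index(b)
    expect_equal(length(idx$i), b^2 - b)
    expect_true(all(idx$i != idx$j))
    expect_equal(nrow(unique(cbind(idx$i, idx$j))), b^2 - b)
  }
})

test_that("the full minibatch objective matches its scalar components", {
  # the tape objective on a tiny corpus equals margin_loss/infonce_loss
  # computed from the same embeddings
  rx <- tiny_corpus()
  cfg <- desk_config(dim = 6, epochs = 0, seed = 2)
  m <- train_reaction_model(rx, cfg)
  data <- m$data
  batch <- which(data$reactions$split == "train")
  tp <- ns$ad_tape()
  pids <- ns$push_params(tp, m$params)
  smp <- ns$sample_all_edges(data$graph, cfg$Q, 77)
  obj <- ns$batch_objective(tp, pids, data, cfg, smp, batch)

  tp2 <- ns$ad_tape()
  pids2 <- ns$push_params(tp2, m$params, FALSE)
  emb <- ns$forward_all_molecules(tp2, pids2, data, cfg, smp)
  h <- ns$ad_value(tp2, emb$h)
  hA <- ns$ad_value(tp2, emb$hA)
  hX <- ns$ad_value(tp2, emb$hX)
  xR <- as.matrix(data$S_R[batch, ] %*% h)
  xP <- as.matrix(data$S_P[batch, ] %*% h)
  pos <- ns$score_pairs(xR, xP, m$params$mem_K, m$params$mem_M)$score
  neg_idx <- ns$negative_pair_index(length(batch))
  neg <- ns$score_pairs(xR[neg_idx$i, ], xP[neg_idx$j, ],
                        m$params$mem_K, m$params$mem_M)$score
  LE <- margin_loss(pos, neg, gamma = cfg$gamma)
  LC <- infonce_loss(as.matrix(data$S_R[batch, ] %*% hA),
                     as.matrix(data$S_R[batch, ] %*% hX), cfg$tau) +
    infonce_loss(as.matrix(data$S_P[batch, ] %*% hA),
                 as.matrix(data$S_P[batch, ] %*% hX), cfg$tau)
  expect_near(obj$LE, LE, 1e-8)
  expect_near(obj$LC, LC, 1e-8)
  expect_near(as.numeric(ns$ad_value(tp, obj$loss)),
              total_loss(LE, LC, alpha = cfg$alpha), 1e-8)
})
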