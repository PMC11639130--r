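# Training loop, ranking protocol and downstream feature export.
# Training here runs on a deliberately small corpus; the full
# study-condition runs live in test-acceptance.R.

ns <- asNamespace("reactembed")

train_corpus <- function() {
  cached("train60", {
    sp <- fixture_spec(n_molecules = 60, n_reactions = 60,
                       family_count = 4, seed = 17)
    generate_reaction_set(sp)
  })
}

quick_model <- function(epochs = 8, seed = 1, ...) {
  cached(paste0("qm", epochs, "s", seed, paste(c(...), collapse = "_")), {
    train_reaction_model(train_corpus(),
                         desk_config(seed = seed, epochs = epochs, ...))
  })
}

test_that("training is deterministic and reduces the loss", {
  m1 <- quick_model()
  m2 <- train_reaction_model(train_corpus(), desk_config(epochs = 8))
  expect_identical(m1$trace, m2$trace)
  expect_identical(m1$params, m2$params)
  expect_lt(m1$trace$loss[nrow(m1$trace)], m1$trace$loss[1])
  expect_true(all(is.finite(m1$trace$loss)))
})

test_that("a zero learning rate leaves parameters untouched", {
  cfg <- desk_config(epochs = 1)
  cfg$learning_rate <- 1e-30           # Adam step of (numerically) zero
  m <- train_reaction_model(train_corpus(), cfg)
  init <- ns$init_params(cfg, f0 = feature_vocab()$dim)
  for (nm in names(init)) {
    expect_near(m$final_params[[nm]], init[[nm]], 1e-12)
  }
})

test_that("ranks follow the pessimistic tie rule and MRR arithmetic", {
  # scores engineered so the true candidates rank 1, 2, 2, 4:
  # reaction 2 loses one candidate, reaction 3 ties one competitor
  S <- rbind(c(0.0, 9, 9, 9),
             c(5.0, 6, 9, 9),
             c(9, 9, 2.0, 2.0),
             c(1, 1, 1, 3.0))
  ranks <- ns$ranks_from_scores(S)
  expect_equal(ranks, c(1L, 2L, 2L, 4L))
  expect_equal(mean(1 / ranks), 0.5625)
})

test_that("product ranking reports MRR and Hit@1 consistently", {
  m <- quick_model()
  rk <- rank_products(m)
  expect_s3_class(tidy(rk), "tbl_df")
  expect_equal(nrow(tidy(rk)), sum(train_corpus()$id %in%
    m$data$reactions$id[m$data$reactions$split == "test"]))
  expect_true(all(tidy(rk)$rank >= 1))
  expect_lte(rk$hit1, rk$mrr)
  expect_lte(rk$mrr, 1)
  expect_equal(rk$mrr, mean(tidy(rk)$reciprocal_rank))
  # a single test reaction always ranks first
  one <- m$data$reactions[m$data$reactions$split == "test", ][1, ]
  rk1 <- rank_products(m, one)
  expect_equal(rk1$mrr, 1)
  expect_equal(rk1$hit1, 1)
})

test_that("ranking is invariant to candidate order up to the tie rule", {
  m <- quick_model()
  test_rx <- m$data$reactions[m$data$reactions$split == "test", ]
  rk <- rank_products(m, test_rx)
  perm <- rev(seq_len(nrow(test_rx)))
  rk_perm <- rank_products(m, test_rx[perm, ])
  expect_equal(tidy(rk_perm)$rank[order(tidy(rk_perm)$id)],
               tidy(rk)$rank[order(tidy(rk)$id)])
})

test_that("reaction features concatenate both sides in order", {
  m <- quick_model()
  rx <- train_corpus()[1:4, ]
  ft <- reaction_features(m, rx)
  d <- m$config$dim
  expect_equal(ncol(ft$feature), 2L * d)
  ft2 <- reaction_features(m, rx)
  expect_equal(ft$feature, ft2$feature)          # deterministic
  # swapping sides permutes the two blocks
  swapped <- rx
  swapped$reactants <- rx$products
  swapped$products <- rx$reactants
  fs <- suppressWarnings(reaction_features(m, swapped))
  expect_equal(unname(fs$feature[, 1:d]), unname(ft$feature[, d + 1:d]))
  expect_false(isTRUE(all.equal(ft$feature, fs$feature)))
})

test_that("molecule features work for molecules outside any reaction", {
  m <- quick_model()
  ft <- molecule_features(m, c("CCO", "c1ccccc1", "CC"))
  expect_equal(ncol(ft$feature), 2L * m$config$dim)
  expect_equal(ft$feature, molecule_features(m, c("CCO", "c1ccccc1",
                                                  "CC"))$feature)
  # a molecule with no functional groups has a zero fg-embedding block
  d <- m$config$dim
  ch4 <- molecule_features(m, "C")
  expect_equal(unname(ch4$feature[1, d + 1:d]), rep(0, d))
})

test_that("relation analysis tabulates cosines against bond/ring changes", {
  m <- quick_model()
  rx <- m$data$reactions[m$data$reactions$split == "test", ]
  ra <- relation_similarity_analysis(m, rx)
  expect_equal(nrow(ra$pairs), choose(nrow(rx), 2))
  expect_true(all(abs(ra$pairs$cosine) <= 1 + 1e-9))
  expect_true(all(ra$pairs$d_bond_change >= 0))
  # a reaction duplicated in the input is a perfect pair
  ra2 <- relation_similarity_analysis(m, rx[c(1, 1), ])
  expect_near(ra2$pairs$cosine, 1, 1e-9)
  expect_equal(ra2$pairs$d_bond_change, 0)
  expect_equal(ra2$pairs$d_ring_change, 0)
  # reactions of the same family always have zero change differences
  same_fam <- which(rx$label == rx$label[1])
  if (length(same_fam) >= 2) {
    pr <- ra$pairs[ra$pairs$i == same_fam[1] & ra$pairs$j == same_fam[2], ]
    expect_equal(pr$d_bond_change, 0)
    expect_equal(pr$d_ring_change, 0)
  }
})

test_that("the MLP decoder classifies reaction families on seen data", {
  skip_if_not_installed("nnet")
  m <- quick_model()
  rx <- m$data$reactions
  res <- classify_reactions(m, rx[rx$split == "train", ],
                            rx[rx$split != "train", ], hidden = 16)
  expect_gte(res$accuracy, 0.5)       # four classes, chance = 0.25
  expect_true(res$recall_macro >= 0 && res$recall_macro <= 1)
  expect_equal(nrow(res$predictions), sum(rx$split != "train"))
})

test_that("the logistic-regression harness scores exported features", {
  skip_if_not_installed("pROC")
  m <- quick_model()
  u <- generate_molecule_universe(fixture_spec(n_molecules = 60,
                                               n_reactions = 20, seed = 2))
  # hydroxyl-bearing roles are trivially separable from the exported
  # features, which embed functional-group counts directly
  d <- tibble::tibble(smiles = u$smiles,
                      label = as.integer(u$role %in% c("alcohol", "acid")))
  res <- evaluate_property(m, d, seed = 1)
  expect_gte(res$auc, 0.9)
  expect_true(all(res$predictions$score >= 0 & res$predictions$score <= 1))
})

test_that("tidiers and glance summarize models and rankings", {
  m <- quick_model()
  tr <- tidy(m)
  expect_equal(names(tr), c("epoch", "LE", "LC", "loss", "val_mrr"))
  g <- glance(m)
  expect_equal(g$epochs, 8L)
  expect_equal(g$dim, 32L)
  expect_s3_class(autoplot(m), "ggplot")
  expect_s3_class(autoplot(rank_products(m)), "ggplot")
  ra <- relation_similarity_analysis(m)
  expect_s3_class(autoplot(ra), "ggplot")
  expect_true(is.finite(glance(ra)$n_pairs))
})
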