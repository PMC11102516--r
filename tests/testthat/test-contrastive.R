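test_that("target grouping relations follow the declared set semantics", {
  expect_true(same_target_group(c("EGFR"), c("EGFR", "ERBB2"), "any_shared"))
  expect_false(same_target_group(c("EGFR"), c("TOP1"), "any_shared"))
  expect_false(same_target_group(c("EGFR"), c("TOP1"), "exact"))
  expect_true(same_target_group(c("EGFR"), c("EGFR"), "exact"))
  expect_false(same_target_group(c("EGFR"), c("EGFR", "ERBB2"), "exact"))
  expect_true(same_target_group(c("A", "B"), c("A", "B", "C"), "jaccard",
                                jaccard_t = 0.5))
  expect_false(same_target_group(c("A"), c("A", "B", "C"), "jaccard",
                                 jaccard_t = 0.5))
  expect_warning(g <- group_by_targets(list(a = "EGFR", b = character(0),
                                            c = "TOP1")),
                 "no reported gene target")
  expect_equal(g$ids, c("a", "c"))
})

test_that("pair sampling honors balance, forbids self-pairs, is seeded", {
  groups <- stats::setNames(rep(c("g1", "g2"), each = 3L), paste0("e", 1:6))
  gr <- group_by_key(groups)
  pairs <- make_group_pairs(gr, 100L, balance = 0.5, seed = 4L)
  expect_equal(nrow(pairs), 100L)
  expect_true(all(pairs$id_a != pairs$id_b))
  same_frac <- mean(pairs$y == 0L)
  expect_gt(same_frac, 0.35)    # binomial noise around 0.5
  expect_lt(same_frac, 0.65)
  # y agrees with the grouping
  expect_true(all((groups[pairs$id_a] == groups[pairs$id_b]) == (pairs$y == 0L)))
  expect_identical(make_group_pairs(gr, 100L, seed = 4L), pairs)
  expect_false(identical(make_group_pairs(gr, 100L, seed = 5L), pairs))

  expect_error(make_group_pairs(group_by_key(stats::setNames(rep("g", 4),
                                                             paste0("e", 1:4))),
                                10L),
               "one group")
  lonely <- group_by_key(stats::setNames(c("a", "a", "b"), paste0("e", 1:3)))
  expect_warning(p2 <- make_group_pairs(lonely, 50L, seed = 1L), "size 1")
  expect_true(all(p2$id_a != p2$id_b))
})

test_that("twin forward pass is a sigmoid of embedding distance", {
  ec <- small_enc_cfg(6L)
  enc <- init_encoder(ec, seed = 2L)
  x <- rnorm(6)
  expect_equal(snn_forward(enc, x, x), 0.5, tolerance = 1e-12)  # d = 0 at init
  set.seed(8)
  for (i in 1:20) {
    p <- snn_forward(enc, rnorm(6), rnorm(6))
    expect_gt(p, 0)
    expect_lt(p, 1)
    expect_gte(p, 0.5)  # w = 1, b = 0: distance is nonnegative
  }
  expect_error(snn_forward(enc, rnorm(5), rnorm(6)), "dimension")
})

test_that("twin output is strictly increasing in distance at frozen scale", {
  ec <- encoder_config(input_dim = 3L, hidden_dims = 4L, embedding_dim = 2L,
                       dropout = 0, distance_scale_learnable = FALSE,
                       normalize = FALSE)
  enc <- init_encoder(ec, seed = 3L)
  base <- rnorm(3)
  probe <- t(vapply(seq(0, 2, by = 0.25), function(eps) {
    E <- as.matrix(embed_entities(enc, rbind(a = base, b = base + eps)))
    c(d = sqrt(sum((E[1, ] - E[2, ])^2)),
      p = snn_forward(enc, base, base + eps))
  }, numeric(2)))
  ord <- order(probe[, "d"])
  expect_true(all(diff(probe[ord, "p"]) >= 0))
  expect_gt(probe[which.max(probe[, "d"]), "p"],
            probe[which.min(probe[, "d"]), "p"])
})

test_that("contrastive training reduces validation loss on separable groups", {
  fx <- two_group_features(seed = 21L)
  enc <- train_encoder(fx$features, group_by_key(fx$groups),
                       small_enc_cfg(ncol(fx$features)),
                       fast_train_cfg(seed = 3L, epochs = 25L))
  expect_lt(enc$best_val_loss, enc$log$val_loss[1L])
  expect_lt(enc$best_val_loss, 0.5)   # well below the ln(2) chance level
  # best state is never worse than any logged epoch
  expect_lte(enc$best_val_loss, min(enc$log$val_loss))
})

test_that("early stopping halts on a plateau and training is deterministic", {
  # uninformative features: the loss plateaus at chance almost immediately
  flat <- matrix(0, 12L, 6L, dimnames = list(sprintf("e%02d", 1:12), NULL))
  groups <- stats::setNames(rep(c("A", "B"), each = 6L), rownames(flat))
  tc <- train_config(max_epochs = 60L, patience = 3L, pairs_per_epoch = 64L,
                     seed = 9L)
  enc_flat <- train_encoder(flat, group_by_key(groups),
                            small_enc_cfg(ncol(flat)), tc)
  expect_lt(nrow(enc_flat$log), 60L)
  expect_lte(enc_flat$best_val_loss, min(enc_flat$log$val_loss))

  fx <- two_group_features(seed = 22L)
  enc1 <- train_encoder(fx$features, group_by_key(fx$groups),
                        small_enc_cfg(ncol(fx$features)), tc)
  enc2 <- train_encoder(fx$features, group_by_key(fx$groups),
                        small_enc_cfg(ncol(fx$features)), tc)
  expect_identical(enc1$net$W, enc2$net$W)
  expect_identical(enc1$w, enc2$w)
  expect_identical(enc1$log, enc2$log)
})

test_that("embedding produces one finite unit row per entity, novel entities included", {
  fx <- two_group_features(seed = 23L)
  enc <- train_encoder(fx$features, group_by_key(fx$groups),
                       small_enc_cfg(ncol(fx$features)),
                       fast_train_cfg(seed = 2L, epochs = 4L))
  emb <- embed_entities(enc, fx$features)
  expect_equal(dim(as.matrix(emb)), c(nrow(fx$features), 4L))
  expect_true(all(is.finite(as.matrix(emb))))
  expect_equal(unname(sqrt(rowSums(as.matrix(emb)^2))),
               rep(1, nrow(fx$features)), tolerance = 1e-9)
  # duplicated entity -> identical rows; unseen entity embeds fine
  set.seed(1)
  novel <- matrix(rnorm(2 * ncol(fx$features)), 2,
                  dimnames = list(c("new1", "new1b"), NULL))
  novel[2, ] <- novel[1, ]
  E <- as.matrix(embed_entities(enc, novel))
  expect_equal(E[1, ], E[2, ], ignore_attr = TRUE)
})

test_that("autoencoder baseline reconstructs, embeds, and is seeded", {
  fx <- two_group_features(seed = 24L)
  ae1 <- train_autoencoder_baseline(fx$features, small_enc_cfg(ncol(fx$features)),
                                    fast_train_cfg(seed = 6L, epochs = 20L))
  expect_lt(ae1$best_val_loss, ae1$log$val_loss[1L])  # reconstruction improves
  emb <- embed_entities(ae1, fx$features)
  expect_equal(ncol(as.matrix(emb)), 4L)
  ae2 <- train_autoencoder_baseline(fx$features, small_enc_cfg(ncol(fx$features)),
                                    fast_train_cfg(seed = 6L, epochs = 20L))
  expect_identical(ae1$net$W, ae2$net$W)
})

test_that("wide linear autoencoder approaches the identity-map limit", {
  set.seed(30)
  X <- matrix(rnorm(20 * 4), 20, dimnames = list(sprintf("e%02d", 1:20), NULL))
  ec <- encoder_config(input_dim = 4L, hidden_dims = 8L, embedding_dim = 4L,
                       dropout = 0, activation = "linear",
                       output_activation = "linear", standardize = FALSE)
  ae <- train_autoencoder_baseline(X, ec,
                                   train_config(learning_rate = 5e-3,
                                                max_epochs = 400L,
                                                patience = 60L,
                                                batch_size = 10L, seed = 2L))
  expect_lt(ae$best_val_loss, 0.05)
})
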