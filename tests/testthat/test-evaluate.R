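mk_result <- function(cell, ids, scores = NULL) {
  if (is.null(scores)) scores <- seq(1, 0.1, length.out = length(ids))
  prioritization_result(cell, ids, scores)
}

test_that("precision at k counts top-k intersection and validates k", {
  res <- mk_result("C1", paste0("D", 1:5))
  expect_equal(precision_at_k_cell(res, paste0("D", 1:3), 3L), 1.0)
  expect_equal(precision_at_k_cell(res, c("D2", "D5"), 5L), 0.4)
  expect_equal(precision_at_k_cell(res, character(0), 3L), 0.0)
  expect_error(precision_at_k_cell(res, "D1", 6L), "pool size")
  expect_error(precision_at_k_cell(res, "D1", 0L), ">= 1")
})

test_that("precision at k equals brute-force set intersection on random instances", {
  set.seed(123)
  for (i in 1:60) {
    ids <- sprintf("D%02d", sample(99, 30))
    res <- mk_result("C1", ids)
    eff <- sample(ids, sample(0:30, 1))
    for (k in sample(30, 6)) {
      brute <- length(intersect(ids[1:k], eff)) / k
      expect_identical(precision_at_k_cell(res, eff, k), brute)
    }
    # k = pool size identity
    expect_equal(precision_at_k_cell(res, eff, 30L), length(eff) / 30)
  }
})

test_that("cancer-level precision mean-pools cells and ignores cell order", {
  per_cell <- c(C1 = 1.0, C2 = 0.5, C3 = 0.25, C4 = 0.75)
  cancer_of <- c(C1 = "Lung", C2 = "Lung", C3 = "Skin", C4 = "Skin")
  out <- precision_at_k_cancer(per_cell, cancer_of)
  expect_equal(out[["Lung"]], 0.75)
  expect_equal(out[["Skin"]], 0.5)
  shuffled <- precision_at_k_cancer(per_cell[c(3, 1, 4, 2)], cancer_of)
  expect_equal(shuffled[names(out)], out)
  single <- precision_at_k_cancer(c(C9 = 0.2), c(C9 = "Bone"))
  expect_equal(single[["Bone"]], 0.2)
  expect_error(precision_at_k_cancer(per_cell, cancer_of[-1]), "C1")
})

test_that("evaluation report aggregates per-cell and per-cancer tables consistently", {
  results <- list(mk_result("C1", paste0("D", 1:6)),
                  mk_result("C2", paste0("D", c(4, 1, 6, 2, 3, 5))),
                  mk_result("C3", paste0("D", 6:1)))
  eff <- list(C1 = c("D1", "D2"), C2 = c("D4"), C3 = c("D1"))
  cancer_of <- c(C1 = "Lung", C2 = "Lung", C3 = "Skin")
  rep <- evaluate_prioritizations(results, eff, cancer_of,
                                  k_cell = c(1L, 2L), k_cancer = 1L)
  expect_equal(rep$per_cell["C1", "k1"], 1.0)
  expect_equal(rep$per_cell["C2", "k1"], 1.0)
  expect_equal(rep$per_cell["C3", "k1"], 0.0)
  expect_equal(rep$per_cancer["Lung", "k1"],
               mean(c(rep$per_cell["C1", "k1"], rep$per_cell["C2", "k1"])))
  expect_equal(rep$n_effective, c(C1 = 2L, C2 = 1L, C3 = 1L))
})

test_that("group similarity matches hand-computed cosines and guards degeneracy", {
  emb <- rbind(a1 = c(1, 0), a2 = c(1, 0), b1 = c(0.6, 0.8), b2 = c(0.6, 0.8))
  groups <- c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  rep <- group_similarity(emb, groups)
  expect_equal(rep$per_group$intra, c(1, 1), tolerance = 1e-12)
  expect_equal(rep$per_group$inter, c(0.6, 0.6), tolerance = 1e-12)
  expect_equal(rep$mean_separability, 1 / 0.6, tolerance = 1e-12)

  # uniform positive rescaling leaves every cosine unchanged
  rep2 <- group_similarity(emb * 7.3, groups)
  expect_equal(rep2$per_group, rep$per_group, tolerance = 1e-12)

  # orthogonal groups: inter at zero triggers the cap guard for each group
  orth <- rbind(a1 = c(1, 0), a2 = c(1, 0), b1 = c(0, 1), b2 = c(0, 1))
  w <- testthat::capture_warnings(rep3 <- group_similarity(orth, groups, cap = 50))
  expect_true(all(grepl("capped", w)))
  expect_equal(rep3$per_group$separability, c(50, 50))

  expect_error(group_similarity(rbind(a1 = c(0, 0), b1 = c(1, 0)),
                                c(a1 = "A", b1 = "B")),
               "zero-norm")
  w2 <- testthat::capture_warnings(
    group_similarity(rbind(a1 = c(1, 0), b1 = c(0, 1), b2 = c(0, 1)),
                     c(a1 = "A", b1 = "B", b2 = "B")))
  expect_true(any(grepl("single member", w2)))
})

test_that("identical embeddings give intra and separability exactly one", {
  emb <- matrix(rep(c(0.3, -0.2, 0.9), each = 6), 6,
                dimnames = list(paste0("e", 1:6), NULL))
  groups <- stats::setNames(rep(c("A", "B", "C"), each = 2), paste0("e", 1:6))
  rep <- group_similarity(emb, groups)
  expect_equal(rep$mean_intra, 1, tolerance = 1e-12)
  expect_equal(rep$mean_inter, 1, tolerance = 1e-12)
  expect_equal(rep$mean_separability, 1, tolerance = 1e-12)
})

test_that("coefficient stability compares variance against magnitude", {
  same <- matrix(rep(c(0.4, -0.3, 0.2), 4), 4, byrow = TRUE)
  st <- coefficient_stability(same)
  expect_equal(st$mean_variance, 0)
  expect_true(st$stable)

  flip <- rbind(c(1, -1), c(-1, 1))
  expect_false(coefficient_stability(flip)$stable)

  # variance two orders below magnitude is stable
  set.seed(2)
  base <- runif(10, 0.2, 0.6)
  folds <- t(replicate(5, base + rnorm(10, sd = 0.02)))
  st3 <- coefficient_stability(folds)
  expect_true(st3$stable)
  expect_lt(st3$mean_variance, st3$mean_abs_coef / 50)

  expect_error(coefficient_stability(matrix(1, 1, 3)), "folds")
})

test_that("feature importance tags sources and finds planted signal", {
  set.seed(31)
  n <- 300L
  x <- cbind(signal = rnorm(n), matrix(rnorm(3 * n), n,
                                       dimnames = list(NULL, paste0("noise", 1:3))))
  y <- as.integer(x[, "signal"] + rnorm(n, sd = 0.4) > 0)
  asm <- feature_assembly("fingerprint", "expression", "concat", 1L, 3L)

  rf <- train_classifier(x, y, classifier_spec("random_forest", seed = 2L))
  imp <- feature_importance(rf, asm)
  expect_equal(sum(imp$raw), 1, tolerance = 1e-9)   # native importances normalized
  expect_equal(imp$source, c("drug", rep("cell", 3)))
  expect_equal(which.max(imp$scaled), 1L)
  expect_true(all(imp$scaled >= 0 & imp$scaled <= 1))

  lr <- train_classifier(x, y, classifier_spec("logistic", seed = 2L))
  imp_lr <- feature_importance(lr, asm)
  expect_equal(which.max(imp_lr$scaled), 1L)
  expect_warning(feature_importance(lr, asm,
                                    fold_coefs = rbind(c(1, -1, 0, 0),
                                                       c(-1, 1, 0, 0))),
                 "unstable")

  dn <- train_classifier(x, y, classifier_spec("dense_network", seed = 2L))
  imp_dn <- feature_importance(dn, asm, x = x, y = y, seed = 5L)
  expect_equal(which.max(imp_dn$scaled), 1L)
  expect_error(feature_importance(dn, asm), "needs training")
})

test_that("model comparison reproduces the textbook pooled t-test", {
  out <- compare_models(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$t, -3.674, tolerance = 1e-3)
  expect_lt(abs(out$p_raw - 0.0214), 2e-3)
  expect_equal(out$p_raw, 2 * pt(out$t, df = 4), tolerance = 1e-9)

  capped <- compare_models(c(1, 2, 3), c(1.1, 2.2, 2.9), n_comparisons = 4L)
  expect_equal(capped$p_corrected, min(1, capped$p_raw * 4))
  expect_lte(capped$p_corrected, 1)

  same <- compare_models(c(2, 2), c(2, 2))
  expect_equal(same$p_raw, 1)
  expect_equal(same$tier, "ns")

  tiers <- compare_models(rnorm(5), rnorm(5) + 100, n_comparisons = 1L)
  expect_equal(tiers$tier, "****")
  expect_error(compare_models(1, c(1, 2)), "folds")
})
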