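# Ranking metrics, embedding-expressiveness statistics, feature importance
# and model-comparison significance tests.

#' Precision at k for one cell line
#'
#' Fraction of the cell's top-`k` prioritized drugs that belong to its
#' effective set: `|top_k(D) n E| / k`.
#'
#' @param result A [prioritization_result()].
#' @param effective_set Character vector of effective drug ids for the cell.
#' @param k Cutoff, `1 <= k <=` pool size.
#' @return A number in `[0, 1]`.
#' @export
precision_at_k_cell <- function(result, effective_set, k) {
  n <- nrow(result$ranked)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k > n) stop("k (", k, ") exceeds pool size (", n, ")", call. = FALSE)
  top <- result$ranked$drug_id[seq_len(k)]
  sum(top %in% effective_set) / k
}

#' Precision at k mean-pooled by cancer type
#'
#' Unweighted mean of per-cell precision over each cancer's cells, which
#' damps the influence of outlier cell lines.
#'
#' @param per_cell Named numeric vector: cell id -> precision at k.
#' @param cancer_of Named character vector: cell id -> cancer type.
#' @return Named numeric vector: cancer -> mean precision.
#' @export
precision_at_k_cancer <- function(per_cell, cancer_of) {
  cells <- names(per_cell)
  missing <- cells[!cells %in% names(cancer_of)]
  if (length(missing)) stop("no cancer label for cell(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  tapply(per_cell, cancer_of[cells], mean)
}

#' Evaluate prioritizations at several cutoffs
#'
#' @param results List of [prioritization_result()]s (one per cell).
#' @param effective_sets Named list: cell id -> character vector of
#'   effective drug ids.
#' @param cancer_of Named character vector: cell id -> cancer type.
#' @param k_cell Cutoffs for the per-cell table (default `c(1:5, 10)`).
#' @param k_cancer Cutoffs for the per-cancer table (default `1:5`).
#' @return An `eval_report`: `per_cell` (cell x k data frame), `per_cancer`
#'   (cancer x k data frame), `n_effective` per cell, cell counts per
#'   cancer.
#' @export
evaluate_prioritizations <- function(results, effective_sets, cancer_of,
                                     k_cell = c(1:5, 10L), k_cancer = 1:5) {
  cell_ids <- vapply(results, function(r) r$cell_id, character(1))
  names(results) <- cell_ids
  pool_min <- min(vapply(results, function(r) nrow(r$ranked), integer(1)))
  k_cell <- k_cell[k_cell <= pool_min]
  k_cancer <- k_cancer[k_cancer <= pool_min]
  per_cell <- sapply(k_cell, function(k) {
    vapply(cell_ids, function(cid) {
      precision_at_k_cell(results[[cid]], effective_sets[[cid]], k)
    }, numeric(1))
  })
  per_cell <- matrix(per_cell, nrow = length(cell_ids),
                     dimnames = list(cell_ids, paste0("k", k_cell)))
  per_cancer <- sapply(k_cancer, function(k) {
    pc <- per_cell[, paste0("k", k)]
    precision_at_k_cancer(stats::setNames(pc, cell_ids), cancer_of)
  })
  cancers <- sort(unique(cancer_of[cell_ids]))
  per_cancer <- matrix(per_cancer, nrow = length(cancers),
                       dimnames = list(cancers, paste0("k", k_cancer)))
  structure(list(
    per_cell = as.data.frame(per_cell),
    per_cancer = as.data.frame(per_cancer),
    k_cell = k_cell, k_cancer = k_cancer,
    n_effective = vapply(cell_ids, function(cid) length(effective_sets[[cid]]),
                         integer(1)),
    cells_per_cancer = table(cancer_of[cell_ids])
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\nmean per-cell precision:\n")
  print(colMeans(x$per_cell))
  cat("mean per-cancer precision:\n")
  print(colMeans(x$per_cancer))
  invisible(x)
}

#' Write an evaluation report
#'
#' Writes `<path>` (per-cell table) and `<path>` with suffix `.cancer.csv`
#' (per-cancer table).
#'
#' @param report An `eval_report`.
#' @param path Output CSV path for the per-cell table.
#' @export
write_eval_report <- function(report, path) {
  utils::write.csv(cbind(cell_id = rownames(report$per_cell), report$per_cell),
                   path, row.names = FALSE, quote = FALSE)
  utils::write.csv(cbind(cancer = rownames(report$per_cancer), report$per_cancer),
                   sub("\\.csv$", ".cancer.csv", path), row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Intra-/inter-group cosine similarity and separability of embeddings
#'
#' For each group: intra-group similarity is the mean pairwise cosine
#' similarity over unordered within-group pairs; inter-group similarity is
#' the mean cosine similarity of each member to all non-members; their
#' ratio is the group's separability. A separability of 1 means members
#' resemble non-members as much as each other (groups indistinguishable);
#' larger values mean tighter, better-separated groups. Group means weight
#' groups equally.
#'
#' @param embeddings An [embedding_set()] or a matrix with ids as row names.
#' @param groups Named character vector: id -> group label.
#' @param cap Separability cap applied when a group's inter similarity is
#'   at or below `1e-9` (ratio unstable); default 100.
#' @return A `separability_report`: per-group data frame (`group`, `n`,
#'   `intra`, `inter`, `separability`) plus `mean_intra`, `mean_inter`,
#'   `mean_separability`.
#' @export
group_similarity <- function(embeddings, groups, cap = 100) {
  V <- if (inherits(embeddings, "embedding_set")) embeddings$vectors
       else as.matrix(embeddings)
  ids <- rownames(V)
  ids <- ids[ids %in% names(groups)]
  V <- V[ids, , drop = FALSE]
  g <- groups[ids]
  if (length(unique(g)) < 2L) stop("need >= 2 groups", call. = FALSE)
  nrm <- sqrt(rowSums(V^2))
  if (any(nrm == 0)) stop("zero-norm embedding vector(s): ",
                          paste(ids[nrm == 0], collapse = ", "), call. = FALSE)
  U <- V / nrm
  C <- tcrossprod(U)
  rows <- lapply(sort(unique(g)), function(grp) {
    m <- which(g == grp)
    o <- which(g != grp)
    intra <- if (length(m) >= 2L) {
      Cm <- C[m, m, drop = FALSE]
      mean(Cm[upper.tri(Cm)])
    } else {
      warning("group '", grp, "' has a single member; intra similarity ",
              "undefined, group skipped", call. = FALSE)
      NA_real_
    }
    inter <- mean(C[m, o])
    sep <- if (is.na(intra)) NA_real_
           else if (inter <= 1e-9) {
             warning("group '", grp, "' inter similarity <= 1e-9; separability ",
                     "capped at ", cap, call. = FALSE)
             cap
           } else min(intra / inter, cap)
    data.frame(group = grp, n = length(m), intra = intra, inter = inter,
               separability = sep, stringsAsFactors = FALSE)
  })
  per_group <- do.call(rbind, rows)
  structure(list(per_group = per_group,
                 mean_intra = mean(per_group$intra, na.rm = TRUE),
                 mean_inter = mean(per_group$inter),
                 mean_separability = mean(per_group$separability, na.rm = TRUE),
                 cap = cap),
            class = "separability_report")
}

#' @export
print.separability_report <- function(x, ...) {
  cat(sprintf("<separability_report: mean intra %.3f, inter %.3f, separability %.3f>\n",
              x$mean_intra, x$mean_inter, x$mean_separability))
  print(x$per_group)
  invisible(x)
}

#' Write a separability report to CSV
#'
#' @param report A `separability_report`.
#' @param path Output CSV path.
#' @export
write_separability_report <- function(report, path) {
  utils::write.csv(report$per_group, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Stability of logistic coefficients across training folds
#'
#' Coefficients are a trustworthy importance signal only when they vary
#' little across folds relative to their magnitude.
#'
#' @param coef_matrix Numeric matrix, folds x features.
#' @param stability_ratio Stability bound: stable iff mean per-feature
#'   variance `<= stability_ratio *` mean `|coefficient|` (default 0.1).
#' @return List with `mean_abs_coef`, `mean_variance`, `stable`.
#' @export
coefficient_stability <- function(coef_matrix, stability_ratio = 0.1) {
  coef_matrix <- as.matrix(coef_matrix)
  if (nrow(coef_matrix) < 2L) stop("need >= 2 folds", call. = FALSE)
  mean_abs <- mean(abs(coef_matrix))
  mean_var <- mean(apply(coef_matrix, 2L, stats::var))
  list(mean_abs_coef = mean_abs, mean_variance = mean_var,
       stable = mean_var <= stability_ratio * mean_abs)
}

#' Feature importance for a trained end classifier
#'
#' Random forests use their native impurity importances (normalized to sum
#' to 1). Logistic models use absolute coefficients; if per-fold
#' coefficients are supplied their stability is checked first and a
#' warning is raised when unstable. Dense networks use seeded permutation
#' importance (mean log-loss increase when a feature is permuted) over at
#' most `n_sample` sampled training rows. All importances are min-max
#' scaled to `[0, 1]` and each feature is tagged `drug` or `cell` by its
#' block position in the assembly.
#'
#' @param model A `cdr_classifier`.
#' @param assembly The [feature_assembly()] used for training.
#' @param x,y Training features/labels (required for `dense_network`).
#' @param n_sample Row-sample cap for permutation importance (default 5000).
#' @param seed Seed for sampling/permutation.
#' @param fold_coefs Optional folds x features coefficient matrix for the
#'   logistic stability check.
#' @return An `importance_report` data frame (`feature_index`, `feature`,
#'   `source`, `raw`, `scaled`) with per-source means as attributes.
#' @export
feature_importance <- function(model, assembly, x = NULL, y = NULL,
                               n_sample = 5000L, seed = 1L, fold_coefs = NULL) {
  p <- model$n_features
  raw <- switch(model$kind,
    random_forest = {
      imp <- model$fit$variable.importance
      imp <- pmax(imp, 0)
      imp / sum(imp)
    },
    logistic = {
      if (!is.null(fold_coefs)) {
        st <- coefficient_stability(fold_coefs)
        if (!st$stable) {
          warning("logistic coefficients are unstable across folds; ",
                  "importances may be unreliable", call. = FALSE)
        }
      }
      cf <- as.numeric(stats::coef(model$fit))[-1L]  # drop intercept
      abs(cf)
    },
    dense_network = {
      if (is.null(x) || is.null(y)) {
        stop("dense_network importance needs training x and y", call. = FALSE)
      }
      .permutation_importance(model, as.matrix(x), as.integer(y),
                              n_sample = n_sample, seed = seed)
    })
  if (length(raw) != p) stop("importance length mismatch", call. = FALSE)
  rng <- range(raw)
  scaled <- if (diff(rng) < 1e-15) rep(1, p) else (raw - rng[1L]) / diff(rng)
  source <- rep("cell", p)
  if (assembly$combine == "concat") {
    source[seq_len(assembly$drug_block_len)] <- "drug"
  } else {
    source <- rep("drug_x_cell", p)
  }
  out <- data.frame(feature_index = seq_len(p),
                    feature = model$feature_names %||% paste0("f", seq_len(p)),
                    source = source, raw = as.numeric(raw),
                    scaled = scaled, stringsAsFactors = FALSE)
  attr(out, "per_source_mean") <- tapply(out$scaled, out$source, mean)
  class(out) <- c("importance_report", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.permutation_importance <- function(model, x, y, n_sample = 5000L, seed = 1L) {
  set.seed(seed)
  n <- nrow(x)
  idx <- if (n > n_sample) sample.int(n, n_sample) else seq_len(n)
  xs <- x[idx, , drop = FALSE]
  ys <- y[idx]
  base <- .bce(predict_scores(model, xs), ys)
  vapply(seq_len(ncol(xs)), function(j) {
    xp <- xs
    xp[, j] <- xp[sample.int(nrow(xs)), j]
    max(0, .bce(predict_scores(model, xp), ys) - base)
  }, numeric(1))
}

#' Write an importance report to CSV
#'
#' @param report An `importance_report`.
#' @param path Output CSV path.
#' @export
write_importance_report <- function(report, path) {
  utils::write.csv(as.data.frame(report), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Compare two models' per-fold metrics
#'
#' Two-sample, two-tailed, independent t-test (pooled variance by default,
#' Welch optionally) with Bonferroni correction over `n_comparisons`
#' hypotheses. Significance tiers follow the star convention:
#' `*` at alpha <= 0.1, `**` 0.05, `***` 0.01, `****` 0.001, `ns`
#' otherwise. Two constant samples with equal means give p = 1 by
#' convention.
#'
#' @param metric_a,metric_b Numeric vectors of per-fold metrics (>= 2 each).
#' @param n_comparisons Number of hypotheses in the family (default 1).
#' @param var_equal Pooled-variance t-test if `TRUE` (default), Welch
#'   otherwise.
#' @return List with `t`, `p_raw`, `p_corrected`, `tier`.
#' @export
compare_models <- function(metric_a, metric_b, n_comparisons = 1L,
                           var_equal = TRUE) {
  if (length(metric_a) < 2L || length(metric_b) < 2L) {
    stop("need >= 2 folds per model", call. = FALSE)
  }
  if (stats::sd(metric_a) == 0 && stats::sd(metric_b) == 0) {
    if (mean(metric_a) == mean(metric_b)) {
      t_stat <- 0; p <- 1
    } else {
      t_stat <- sign(mean(metric_a) - mean(metric_b)) * Inf; p <- 0
    }
  } else {
    tt <- stats::t.test(metric_a, metric_b, var.equal = var_equal)
    t_stat <- unname(tt$statistic)
    p <- tt$p.value
  }
  p_corr <- min(1, p * n_comparisons)
  tier <- if (p_corr <= 0.001) "****" else if (p_corr <= 0.01) "***"
          else if (p_corr <= 0.05) "**" else if (p_corr <= 0.1) "*" else "ns"
  list(t = t_stat, p_raw = p, p_corrected = p_corr, tier = tier)
}
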