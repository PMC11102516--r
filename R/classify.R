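# End classifiers: a drug representation and a cell-line representation are
# combined (concatenation by default, drug block first) and a classifier is
# trained on the binary effectiveness labels. Prediction scores order each
# cell line's candidate drugs.

#' Describe how drug and cell features are combined
#'
#' @param drug_repr `"fingerprint"` or `"embedding"` (metadata only).
#' @param cell_repr `"expression"` or `"embedding"` (metadata only).
#' @param combine `"concat"` (drug block first) or `"hadamard"`
#'   (elementwise product; requires equal block lengths).
#' @param drug_block_len,cell_block_len Feature block lengths, recorded so
#'   importance attribution can tag each feature's source.
#' @return A `feature_assembly` list.
#' @export
feature_assembly <- function(drug_repr = c("fingerprint", "embedding"),
                             cell_repr = c("expression", "embedding"),
                             combine = c("concat", "hadamard"),
                             drug_block_len, cell_block_len) {
  drug_repr <- match.arg(drug_repr)
  cell_repr <- match.arg(cell_repr)
  combine <- match.arg(combine)
  if (combine == "hadamard" && drug_block_len != cell_block_len) {
    stop("hadamard combination requires equal block lengths", call. = FALSE)
  }
  structure(list(drug_repr = drug_repr, cell_repr = cell_repr,
                 combine = combine,
                 drug_block_len = as.integer(drug_block_len),
                 cell_block_len = as.integer(cell_block_len)),
            class = "feature_assembly")
}

#' Combine one drug vector and one cell vector into a feature vector
#'
#' @param drug_vec,cell_vec Numeric vectors matching the assembly's block
#'   lengths.
#' @param assembly A [feature_assembly()].
#' @return Numeric feature vector: `[drug | cell]` for `concat`, the
#'   elementwise product for `hadamard`.
#' @export
assemble_features <- function(drug_vec, cell_vec, assembly) {
  if (length(drug_vec) != assembly$drug_block_len ||
      length(cell_vec) != assembly$cell_block_len) {
    stop("vector lengths do not match assembly block lengths", call. = FALSE)
  }
  switch(assembly$combine,
         concat = c(drug_vec, cell_vec),
         hadamard = drug_vec * cell_vec)
}

#' Build the feature matrix for a set of drug-cell pairs
#'
#' @param pairs Data frame with `drug_id` and `cell_id` columns.
#' @param drug_mat Numeric matrix of drug representations (rows = drug ids).
#' @param cell_mat Numeric matrix of cell representations (rows = cell ids).
#' @param assembly A [feature_assembly()].
#' @return Numeric matrix, one row per pair.
#' @export
assemble_pair_matrix <- function(pairs, drug_mat, cell_mat, assembly) {
  missing_d <- setdiff(unique(pairs$drug_id), rownames(drug_mat))
  missing_c <- setdiff(unique(pairs$cell_id), rownames(cell_mat))
  if (length(missing_d)) stop("no drug representation for: ",
                              paste(utils::head(missing_d, 5), collapse = ", "),
                              call. = FALSE)
  if (length(missing_c)) stop("no cell representation for: ",
                              paste(utils::head(missing_c, 5), collapse = ", "),
                              call. = FALSE)
  D <- drug_mat[pairs$drug_id, , drop = FALSE]
  C <- cell_mat[pairs$cell_id, , drop = FALSE]
  X <- switch(assembly$combine, concat = cbind(D, C), hadamard = D * C)
  colnames(X) <- switch(assembly$combine,
    concat = c(paste0("drug_", seq_len(ncol(D))), paste0("cell_", seq_len(ncol(C)))),
    hadamard = paste0("dc_", seq_len(ncol(X))))
  rownames(X) <- NULL
  X
}

#' Specify an end classifier
#'
#' @param kind `"logistic"` (ridge-penalized), `"random_forest"` or
#'   `"dense_network"`.
#' @param hyperparameters Named list. Logistic: `lambda` (ridge penalty,
#'   default 1e-4). Random forest: `num_trees` (default 500),
#'   `min_node_size` (default 10), `mtry` (default sqrt(p)). Dense network:
#'   `hidden_dims` (default `c(64, 32)`), `dropout` (default 0.2), plus any
#'   [train_config()] fields.
#' @param seed Integer seed (forest bootstrap / network initialization).
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(kind = c("logistic", "random_forest", "dense_network"),
                            hyperparameters = list(), seed = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, hyperparameters = hyperparameters,
                 seed = as.integer(seed)),
            class = "classifier_spec")
}

.hp <- function(spec, name, default) {
  if (!is.null(spec$hyperparameters[[name]])) spec$hyperparameters[[name]] else default
}

#' Train an end classifier on labeled pair features
#'
#' @param x Numeric feature matrix (one row per drug-cell pair).
#' @param y 0/1 labels; both classes must be present.
#' @param spec A [classifier_spec()].
#' @return A `cdr_classifier` exposing [predict_scores()].
#' @export
train_classifier <- function(x, y, spec = classifier_spec()) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- as.integer(y)
  if (length(unique(y)) < 2L) stop("labels contain a single class", call. = FALSE)
  if (nrow(x) != length(y)) stop("nrow(x) != length(y)", call. = FALSE)
  fit <- switch(spec$kind,
    logistic = {
      lambda <- .hp(spec, "lambda", 1e-4)
      glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                     lambda = lambda, standardize = .hp(spec, "standardize", TRUE))
    },
    random_forest = {
      ranger::ranger(
        x = x, y = factor(y, levels = c(0L, 1L)),
        num.trees = .hp(spec, "num_trees", 500L),
        min.node.size = .hp(spec, "min_node_size", 10L),
        mtry = .hp(spec, "mtry", max(1L, floor(sqrt(ncol(x))))),
        probability = TRUE, importance = "impurity",
        seed = spec$seed, num.threads = 1L,
        class.weights = if (isTRUE(.hp(spec, "balanced", FALSE))) {
          n <- table(factor(y, levels = c(0L, 1L)))
          stats::setNames(as.numeric(sum(n) / (2 * n)), names(n))
        } else NULL)
    },
    dense_network = .train_dense_classifier(x, y, spec)
  )
  structure(list(kind = spec$kind, fit = fit, spec = spec,
                 n_features = ncol(x), feature_names = colnames(x)),
            class = "cdr_classifier")
}

.train_dense_classifier <- function(x, y, spec) {
  tc <- train_config(
    learning_rate = .hp(spec, "learning_rate", 1e-3),
    lr_decay = .hp(spec, "lr_decay", 0.99),
    max_epochs = .hp(spec, "max_epochs", 100L),
    patience = .hp(spec, "patience", 10L),
    batch_size = .hp(spec, "batch_size", 64L),
    validation_fraction = .hp(spec, "validation_fraction", 0.15),
    seed = spec$seed)
  dropout <- .hp(spec, "dropout", 0.2)
  hidden <- .hp(spec, "hidden_dims", c(64L, 32L))
  scaler <- .fit_scaler(x)
  Xs <- .apply_scaler(x, scaler)
  n <- nrow(Xs)
  set.seed(tc$seed)
  n_val <- max(2L, round(tc$validation_fraction * n))
  val_idx <- sample.int(n, n_val)
  # guarantee both classes in training split
  train_idx <- setdiff(seq_len(n), val_idx)
  if (length(unique(y[train_idx])) < 2L) {
    train_idx <- seq_len(n)
    val_idx <- sample.int(n, n_val)
  }
  net <- .mlp_init(c(ncol(Xs), hidden, 1L), "relu", "sigmoid")
  adam <- .adam_init(net)
  val_loss_of <- function(net) .bce(drop(.mlp_forward(net, Xs[val_idx, , drop = FALSE])$out),
                                    y[val_idx])
  best <- list(net = net, loss = val_loss_of(net))
  wait <- 0L
  log_rows <- list()
  for (epoch in seq_len(tc$max_epochs)) {
    lr <- tc$learning_rate * tc$lr_decay^(epoch - 1L)
    set.seed(tc$seed + 4000L + epoch)
    perm <- sample(train_idx)
    epoch_loss <- 0
    for (s in seq(1L, length(perm), by = tc$batch_size)) {
      bi <- perm[s:min(s + tc$batch_size - 1L, length(perm))]
      cache <- .mlp_forward(net, Xs[bi, , drop = FALSE], dropout = dropout,
                            training = TRUE)
      p <- drop(cache$out)
      loss <- .bce(p, y[bi])
      if (!is.finite(loss)) stop("non-finite loss at epoch ", epoch, call. = FALSE)
      epoch_loss <- epoch_loss + loss * length(bi)
      # dBCE/dz with sigmoid output folds to (p - y)/m; divide out sigmoid'
      p_c <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      dOut <- matrix((p_c - y[bi]) / (length(bi) * p_c * (1 - p_c)), ncol = 1L)
      grads <- .mlp_backward(net, cache, dOut)
      upd <- .adam_step(net, grads, adam, lr)
      net <- upd$net; adam <- upd$state
    }
    vl <- val_loss_of(net)
    log_rows[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                    train_loss = epoch_loss / length(perm),
                                    val_loss = vl)
    if (vl < best$loss - 1e-6) {
      best <- list(net = net, loss = vl)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= tc$patience) break
    }
  }
  list(net = best$net, scaler = scaler, log = do.call(rbind, log_rows),
       best_val_loss = best$loss)
}

#' Predict effectiveness scores
#'
#' One score per feature row, each in `[0, 1]`: the predicted probability
#' that the drug is effective against the cell line.
#'
#' @param model A `cdr_classifier`.
#' @param x Feature matrix with the training feature width.
#' @return Numeric vector of scores in `[0, 1]`.
#' @export
predict_scores <- function(model, x) {
  x <- as.matrix(x)
  if (ncol(x) != model$n_features) {
    stop("feature width mismatch: model expects ", model$n_features,
         ", got ", ncol(x), call. = FALSE)
  }
  switch(model$kind,
    logistic = drop(stats::predict(model$fit, newx = x, type = "response")),
    random_forest = {
      colnames(x) <- model$feature_names
      stats::predict(model$fit, data = as.data.frame(x),
                     num.threads = 1L)$predictions[, "1"]
    },
    dense_network = {
      p <- drop(.mlp_forward(model$fit$net,
                             .apply_scaler(x, model$fit$scaler))$out)
      pmin(pmax(p, 0), 1)
    })
}

#' Rank a drug pool for one cell line
#'
#' Scores every drug in the pool against the cell and sorts in descending
#' score order; exact ties are broken by ascending drug id, so the ranking
#' is a deterministic permutation of the pool.
#'
#' @param model A `cdr_classifier`.
#' @param cell_vec The cell line's representation (vector).
#' @param drug_mat Matrix of drug representations, rows named by drug id.
#' @param assembly The [feature_assembly()] the model was trained under.
#' @param cell_id Cell id recorded on the result.
#' @return A [prioritization_result()].
#' @export
prioritize <- function(model, cell_vec, drug_mat, assembly, cell_id = "cell") {
  if (is.null(drug_mat) || nrow(drug_mat) == 0L) {
    stop("empty drug pool", call. = FALSE)
  }
  pairs <- data.frame(drug_id = rownames(drug_mat),
                      cell_id = "query", stringsAsFactors = FALSE)
  cmat <- matrix(cell_vec, nrow = 1L, dimnames = list("query", NULL))
  X <- assemble_pair_matrix(pairs, drug_mat, cmat, assembly)
  scores <- predict_scores(model, X)
  ord <- order(-scores, pairs$drug_id, method = "radix")
  prioritization_result(cell_id, pairs$drug_id[ord], scores[ord])
}
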