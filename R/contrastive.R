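# Siamese (twin shared-weight) contrastive pretraining. Two inputs are
# pushed through one encoder; a sigmoid of an affine function of the
# Euclidean distance between the two embeddings gives the probability that
# the inputs belong to *different* groups, and binary cross-entropy on
# known group labels is minimized. Same-group pairs are pulled together,
# different-group pairs pushed apart.

#' Grouping by explicit keys
#'
#' Entities are same-group iff their keys are equal (cell lines grouped by
#' cancer type use this).
#'
#' @param keys Named character vector: entity id -> group key.
#' @return A grouping object usable by [make_group_pairs()].
#' @export
group_by_key <- function(keys) {
  if (is.null(names(keys))) stop("keys must be named by entity id", call. = FALSE)
  structure(list(kind = "key", keys = keys, ids = names(keys)),
            class = "entity_grouping")
}

#' Grouping by gene-target sets
#'
#' Drugs are grouped by their gene targets. The default relation
#' (`any_shared`) calls two drugs same-group iff their target sets
#' intersect — the weakest reading of target-based grouping; `exact`
#' requires identical sets and `jaccard` requires Jaccard similarity at
#' least `jaccard_t`. Note `any_shared` and `jaccard` are pairwise
#' relations, not partitions. Entities with empty target sets are excluded
#' with a warning: they carry no grouping signal.
#'
#' @param targets Named list of character vectors (entity id -> gene set).
#' @param mode `"any_shared"`, `"exact"` or `"jaccard"`.
#' @param jaccard_t Jaccard threshold for `mode = "jaccard"`.
#' @return A grouping object usable by [make_group_pairs()].
#' @export
group_by_targets <- function(targets, mode = c("any_shared", "exact", "jaccard"),
                             jaccard_t = 0.5) {
  mode <- match.arg(mode)
  if (is.null(names(targets))) stop("targets must be named by entity id", call. = FALSE)
  empty <- lengths(targets) == 0L
  if (any(empty)) {
    warning(sum(empty), " entit(ies) with no reported gene target excluded ",
            "from grouping", call. = FALSE)
    targets <- targets[!empty]
  }
  if (length(targets) == 0L) stop("no entities with gene targets", call. = FALSE)
  structure(list(kind = "targets", targets = targets, mode = mode,
                 jaccard_t = jaccard_t, ids = names(targets)),
            class = "entity_grouping")
}

#' Are two target sets in the same group?
#'
#' @param a,b Character vectors of gene symbols.
#' @inheritParams group_by_targets
#' @return Logical scalar.
#' @export
same_target_group <- function(a, b, mode = c("any_shared", "exact", "jaccard"),
                              jaccard_t = 0.5) {
  mode <- match.arg(mode)
  switch(mode,
    any_shared = length(intersect(a, b)) > 0L,
    exact = setequal(a, b),
    jaccard = length(intersect(a, b)) / length(union(a, b)) >= jaccard_t
  )
}

# n x n logical same-group matrix (diagonal FALSE).
.same_matrix <- function(grouping) {
  ids <- grouping$ids
  n <- length(ids)
  if (grouping$kind == "key") {
    k <- grouping$keys[ids]
    S <- outer(k, k, `==`)
  } else {
    S <- matrix(FALSE, n, n)
    tg <- grouping$targets
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (j > i) S[i, j] <- same_target_group(tg[[i]], tg[[j]],
                                                grouping$mode, grouping$jaccard_t)
      }
    }
    S <- S | t(S)
  }
  diag(S) <- FALSE
  dimnames(S) <- list(ids, ids)
  S
}

#' Sample labeled training pairs from grouped entities
#'
#' Samples `n_pairs` entity pairs with replacement; an expected fraction
#' `balance` are same-group (label `y = 0`), the rest different-group
#' (`y = 1`, matching the convention that the twin network predicts the
#' probability of *different* groups). No self-pairs. Deterministic under
#' `seed`.
#'
#' @param grouping A grouping from [group_by_key()] or [group_by_targets()].
#' @param n_pairs Number of pairs to draw.
#' @param balance Expected same-group fraction (default 0.5).
#' @param seed Integer seed.
#' @return Data frame with columns `id_a`, `id_b`, `y`.
#' @export
make_group_pairs <- function(grouping, n_pairs, balance = 0.5, seed = 1L) {
  S <- .same_matrix(grouping)
  ids <- rownames(S)
  n <- length(ids)
  if (n < 2L) stop("need at least two entities", call. = FALSE)
  if (!any(!S[upper.tri(S)])) stop("all entities share one group; need >= 2 groups",
                                   call. = FALSE)
  has_same <- rowSums(S) > 0L
  if (!any(has_same)) {
    stop("no same-group pair exists under this grouping", call. = FALSE)
  }
  if (any(!has_same)) {
    warning(sum(!has_same), " entit(ies) belong to group(s) of size 1; ",
            "same-group draws resampled from other groups", call. = FALSE)
  }
  set.seed(seed)
  want_same <- stats::runif(n_pairs) < balance
  id_a <- character(n_pairs)
  id_b <- character(n_pairs)
  same_pool <- which(has_same)
  diff_pool <- which((n - 1L - rowSums(S)) > 0L)
  for (p in seq_len(n_pairs)) {
    if (want_same[p]) {
      a <- same_pool[sample.int(length(same_pool), 1L)]
      partners <- which(S[a, ])
    } else {
      a <- diff_pool[sample.int(length(diff_pool), 1L)]
      partners <- which(!S[a, ] & seq_len(n) != a)
    }
    b <- partners[sample.int(length(partners), 1L)]
    id_a[p] <- ids[a]
    id_b[p] <- ids[b]
  }
  data.frame(id_a = id_a, id_b = id_b, y = as.integer(!want_same),
             stringsAsFactors = FALSE)
}

#' Encoder architecture configuration
#'
#' @param input_dim Input feature dimension.
#' @param hidden_dims Hidden layer widths (default `c(128, 64)`).
#' @param embedding_dim Embedding dimension (>= 2).
#' @param dropout Dropout rate on hidden layers, in `[0, 1)`.
#' @param activation Hidden activation (`"relu"`, `"tanh"`).
#' @param output_activation Activation on the embedding layer. The default
#'   `"softplus"` keeps embeddings strictly inside the positive orthant, so
#'   pairwise cosine similarities are positive and no entity can collapse
#'   to a zero-norm vector; `"linear"` and `"relu"` are available.
#' @param distance_scale_learnable If `TRUE` (default) a learnable positive
#'   scale and offset `(w, b)` act on the twin distance before the sigmoid;
#'   frozen at `(1, 0)` otherwise, which recovers a plain sigmoid of
#'   distance (whose output can never drop below 0.5).
#' @param normalize If `TRUE` (default) embeddings are L2-normalized onto
#'   the unit sphere as the encoder's final operation, so the contrastive
#'   training distance maps monotonically onto cosine similarity — the
#'   geometry in which embedding expressiveness is measured.
#' @param standardize Feature-wise center/scale inputs before encoding.
#' @return An `encoder_config` list.
#' @export
encoder_config <- function(input_dim, hidden_dims = c(128L, 64L),
                           embedding_dim = 32L, dropout = 0.2,
                           activation = "relu", output_activation = "softplus",
                           distance_scale_learnable = TRUE,
                           normalize = TRUE, standardize = TRUE) {
  stopifnot(input_dim >= 1L, all(hidden_dims >= 1L), embedding_dim >= 2L,
            dropout >= 0, dropout < 1)
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dims = as.integer(hidden_dims),
                 embedding_dim = as.integer(embedding_dim),
                 dropout = dropout, activation = activation,
                 output_activation = output_activation,
                 distance_scale_learnable = distance_scale_learnable,
                 normalize = normalize, standardize = standardize),
            class = "encoder_config")
}

.normalize_rows <- function(E) {
  nrm <- pmax(sqrt(rowSums(E^2)), 1e-12)
  list(U = E / nrm, nrm = nrm)
}

# gradient of L wrt raw E given gradient wrt unit rows U
.normalize_backward <- function(dU, U, nrm) {
  (dU - rowSums(dU * U) * U) / nrm
}

#' Training configuration for the gradient-trained models
#'
#' Adam optimizer with per-epoch exponential learning-rate decay, dropout
#' and early stopping on a frozen validation set.
#'
#' @param learning_rate Initial Adam learning rate.
#' @param lr_decay Multiplicative decay per epoch, in `(0, 1]`.
#' @param max_epochs Maximum epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param pairs_per_epoch Training pairs resampled each epoch (Siamese
#'   training) or examples per epoch cap (ignored by the other trainers).
#' @param batch_size Minibatch size.
#' @param validation_fraction Fraction of the pair/example budget held out.
#' @param seed Integer seed governing sampling, initialization and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-3, lr_decay = 0.99,
                         max_epochs = 100L, patience = 10L,
                         pairs_per_epoch = 2048L, batch_size = 64L,
                         validation_fraction = 0.2, seed = 1L) {
  stopifnot(learning_rate > 0, lr_decay > 0, lr_decay <= 1, max_epochs >= 1L,
            patience >= 1L, pairs_per_epoch >= 2L, batch_size >= 1L,
            validation_fraction > 0, validation_fraction < 1)
  structure(list(learning_rate = learning_rate, lr_decay = lr_decay,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 pairs_per_epoch = as.integer(pairs_per_epoch),
                 batch_size = as.integer(batch_size),
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed)),
            class = "train_config")
}

# distance + sigmoid head shared by snn_forward and the trainer
.snn_head <- function(Ea, Eb, w, b) {
  diff <- Ea - Eb
  d <- sqrt(rowSums(diff^2))
  list(d = d, p = .sigmoid(w * d + b), diff = diff)
}

#' Twin-network forward pass
#'
#' Encodes both inputs with the shared-weight encoder and returns
#' `sigmoid(w * d + b)` where `d` is the Euclidean distance between the two
#' embeddings: the predicted probability that the inputs are from
#' different groups. At initialization (`w = 1`, `b = 0`) identical inputs
#' give exactly 0.5.
#'
#' @param encoder A trained or initialized `snn_encoder`.
#' @param x_a,x_b Numeric vectors (or matrices with matching rows) of the
#'   encoder's input dimension.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
snn_forward <- function(encoder, x_a, x_b) {
  if (is.vector(x_a)) x_a <- matrix(x_a, nrow = 1L)
  if (is.vector(x_b)) x_b <- matrix(x_b, nrow = 1L)
  if (ncol(x_a) != encoder$net$dims[1L] || ncol(x_b) != encoder$net$dims[1L]) {
    stop("input dimension mismatch: encoder expects ", encoder$net$dims[1L],
         call. = FALSE)
  }
  Xa <- .apply_scaler(x_a, encoder$scaler)
  Xb <- .apply_scaler(x_b, encoder$scaler)
  Ea <- .mlp_forward(encoder$net, Xa)$out
  Eb <- .mlp_forward(encoder$net, Xb)$out
  if (isTRUE(encoder$cfg$normalize)) {
    Ea <- .normalize_rows(Ea)$U
    Eb <- .normalize_rows(Eb)$U
  }
  .snn_head(Ea, Eb, encoder$w, encoder$b)$p
}

#' Initialize an untrained twin-network encoder
#'
#' @param enc_cfg An [encoder_config()].
#' @param seed Integer seed for weight initialization.
#' @param kind Entity kind the encoder embeds.
#' @return An `snn_encoder` with `w = 1`, `b = 0`.
#' @export
init_encoder <- function(enc_cfg, seed = 1L, kind = "generic") {
  set.seed(seed)
  dims <- c(enc_cfg$input_dim, enc_cfg$hidden_dims, enc_cfg$embedding_dim)
  net <- .mlp_init(dims, enc_cfg$activation, enc_cfg$output_activation)
  structure(list(net = net, w = 1, b = 0, cfg = enc_cfg, scaler = NULL,
                 kind = kind, log = NULL, seed = as.integer(seed)),
            class = "snn_encoder")
}

#' Pretrain an encoder with twin-network contrastive loss
#'
#' Trains a shared-weight encoder so that same-group entities embed close
#' together and different-group entities far apart. Validation pairs are
#' drawn once and frozen; training pairs are resampled every epoch. Early
#' stopping returns the best-validation-loss state. Fully deterministic
#' under the training seed.
#'
#' @param features Numeric matrix, rows named by entity id.
#' @param grouping Grouping from [group_by_key()] or [group_by_targets()].
#' @param enc_cfg An [encoder_config()]; `input_dim` may be omitted by
#'   passing `NULL` (taken from `features`).
#' @param train_cfg A [train_config()].
#' @param kind Entity kind (`"drug"`, `"cell"`, ...), recorded on the
#'   encoder.
#' @return An `snn_encoder` with a per-epoch `log` data frame
#'   (`epoch`, `lr`, `train_loss`, `val_loss`).
#' @export
train_encoder <- function(features, grouping, enc_cfg = NULL,
                          train_cfg = train_config(), kind = "generic") {
  ids <- intersect(rownames(features), grouping$ids)
  if (length(ids) < 2L) stop("need >= 2 grouped entities with features", call. = FALSE)
  grouping$ids <- ids
  if (grouping$kind == "key") grouping$keys <- grouping$keys[ids]
  if (grouping$kind == "targets") grouping$targets <- grouping$targets[ids]
  X <- features[ids, , drop = FALSE]
  if (is.null(enc_cfg)) enc_cfg <- encoder_config(input_dim = ncol(X))
  if (enc_cfg$input_dim != ncol(X)) stop("enc_cfg$input_dim != ncol(features)",
                                         call. = FALSE)

  scaler <- if (enc_cfg$standardize) .fit_scaler(X) else NULL
  Xs <- .apply_scaler(X, scaler)

  n_val <- max(16L, ceiling(train_cfg$validation_fraction * train_cfg$pairs_per_epoch))
  val <- make_group_pairs(grouping, n_val, balance = 0.5,
                          seed = train_cfg$seed + 1L)

  set.seed(train_cfg$seed)
  dims <- c(enc_cfg$input_dim, enc_cfg$hidden_dims, enc_cfg$embedding_dim)
  net <- .mlp_init(dims, enc_cfg$activation, enc_cfg$output_activation)
  w <- 1; b <- 0
  mwb <- c(0, 0); vwb <- c(0, 0)  # Adam state for (w, b)
  adam <- .adam_init(net)

  val_loss_of <- function(net, w, b) {
    Ea <- .mlp_forward(net, Xs[val$id_a, , drop = FALSE])$out
    Eb <- .mlp_forward(net, Xs[val$id_b, , drop = FALSE])$out
    if (enc_cfg$normalize) {
      Ea <- .normalize_rows(Ea)$U
      Eb <- .normalize_rows(Eb)$U
    }
    .bce(.snn_head(Ea, Eb, w, b)$p, val$y)
  }

  best <- list(net = net, w = w, b = b, loss = val_loss_of(net, w, b))
  wait <- 0L
  log_rows <- vector("list", train_cfg$max_epochs)
  for (epoch in seq_len(train_cfg$max_epochs)) {
    lr <- train_cfg$learning_rate * train_cfg$lr_decay^(epoch - 1L)
    pairs <- make_group_pairs(grouping, train_cfg$pairs_per_epoch, balance = 0.5,
                              seed = train_cfg$seed + 1000L + epoch)
    set.seed(train_cfg$seed + 2000L + epoch)  # dropout stream for this epoch
    perm <- sample.int(nrow(pairs))
    pairs <- pairs[perm, , drop = FALSE]
    batch_starts <- seq(1L, nrow(pairs), by = train_cfg$batch_size)
    epoch_loss <- 0
    for (s in batch_starts) {
      bi <- s:min(s + train_cfg$batch_size - 1L, nrow(pairs))
      Xa <- Xs[pairs$id_a[bi], , drop = FALSE]
      Xb <- Xs[pairs$id_b[bi], , drop = FALSE]
      y <- pairs$y[bi]
      ca <- .mlp_forward(net, Xa, dropout = enc_cfg$dropout, training = TRUE)
      cb <- .mlp_forward(net, Xb, dropout = enc_cfg$dropout, training = TRUE)
      if (enc_cfg$normalize) {
        na_ <- .normalize_rows(ca$out)
        nb_ <- .normalize_rows(cb$out)
        h <- .snn_head(na_$U, nb_$U, w, b)
      } else {
        h <- .snn_head(ca$out, cb$out, w, b)
      }
      m <- length(bi)
      loss <- .bce(h$p, y)
      if (!is.finite(loss)) stop("non-finite contrastive loss at epoch ", epoch,
                                 call. = FALSE)
      epoch_loss <- epoch_loss + loss * m
      dz <- (h$p - y) / m                   # d BCE / d (w*d + b)
      d_safe <- pmax(h$d, 1e-12)
      dd <- dz * w
      dEa <- h$diff * (dd / d_safe)
      dEb <- -dEa
      if (enc_cfg$normalize) {
        dEa <- .normalize_backward(dEa, na_$U, na_$nrm)
        dEb <- .normalize_backward(dEb, nb_$U, nb_$nrm)
      }
      ga <- .mlp_backward(net, ca, dEa)
      gb <- .mlp_backward(net, cb, dEb)
      grads <- list(dW = Map(`+`, ga$dW, gb$dW), db = Map(`+`, ga$db, gb$db))
      upd <- .adam_step(net, grads, adam, lr)
      net <- upd$net; adam <- upd$state
      if (enc_cfg$distance_scale_learnable) {
        gwb <- c(sum(dz * h$d), sum(dz))
        mwb <- 0.9 * mwb + 0.1 * gwb
        vwb <- 0.999 * vwb + 0.001 * gwb^2
        t <- adam$t
        step <- lr * (mwb / (1 - 0.9^t)) / (sqrt(vwb / (1 - 0.999^t)) + 1e-8)
        w <- max(w - step[1L], 1e-6)        # keep the distance scale positive
        b <- b - step[2L]
      }
    }
    train_loss <- epoch_loss / nrow(pairs)
    vl <- val_loss_of(net, w, b)
    log_rows[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                    train_loss = train_loss, val_loss = vl)
    if (vl < best$loss - 1e-6) {
      best <- list(net = net, w = w, b = b, loss = vl)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= train_cfg$patience) break
    }
  }
  structure(list(net = best$net, w = best$w, b = best$b, cfg = enc_cfg,
                 scaler = scaler, kind = kind,
                 log = do.call(rbind, log_rows[!vapply(log_rows, is.null, TRUE)]),
                 best_val_loss = best$loss, seed = train_cfg$seed),
            class = "snn_encoder")
}

#' Embed entities with a trained encoder
#'
#' Inference-mode forward pass (dropout disabled); one embedding row per
#' input row. Works for unseen entities with valid features.
#'
#' @param encoder An `snn_encoder` or `ae_embedder`.
#' @param features Numeric matrix with entity ids as row names.
#' @return An [embedding_set()].
#' @export
embed_entities <- function(encoder, features) {
  if (ncol(features) != encoder$net$dims[1L]) {
    stop("input dimension mismatch: encoder expects ", encoder$net$dims[1L],
         " features, got ", ncol(features), call. = FALSE)
  }
  Xs <- .apply_scaler(features, encoder$scaler)
  E <- .mlp_forward(encoder$net, Xs)$out
  if (inherits(encoder, "snn_encoder") && isTRUE(encoder$cfg$normalize)) {
    E <- .normalize_rows(E)$U
  }
  kind <- if (encoder$kind %in% c("drug", "cell")) encoder$kind else "generic"
  embedding_set(E, ids = rownames(features), entity_kind = kind)
}

#' Train a reconstruction-autoencoder baseline embedder
#'
#' Symmetric encoder-decoder trained to minimize mean-squared
#' reconstruction error; [embed_entities()] applies the encoder half. This
#' is the representation-learning baseline against which the contrastive
#' encoder is compared: its bottleneck is optimized for reconstruction,
#' not for group structure.
#'
#' @inheritParams train_encoder
#' @return An `ae_embedder` with a per-epoch loss `log`.
#' @export
train_autoencoder_baseline <- function(features, enc_cfg = NULL,
                                       train_cfg = train_config(),
                                       kind = "generic") {
  X <- as.matrix(features)
  if (is.null(rownames(X))) stop("features must have entity row names", call. = FALSE)
  if (is.null(enc_cfg)) enc_cfg <- encoder_config(input_dim = ncol(X))
  scaler <- if (enc_cfg$standardize) .fit_scaler(X) else NULL
  Xs <- .apply_scaler(X, scaler)
  n <- nrow(Xs)

  set.seed(train_cfg$seed)
  n_val <- max(2L, round(train_cfg$validation_fraction * n))
  val_idx <- sample.int(n, n_val)
  train_idx <- setdiff(seq_len(n), val_idx)
  if (length(train_idx) < 1L) stop("too few examples to train", call. = FALSE)

  enc_dims <- c(enc_cfg$input_dim, enc_cfg$hidden_dims, enc_cfg$embedding_dim)
  dims <- c(enc_dims, rev(enc_cfg$hidden_dims), enc_cfg$input_dim)
  net <- .mlp_init(dims, enc_cfg$activation, "linear")
  n_enc_layers <- length(enc_dims) - 1L
  # bottleneck activation: same as the encoder output activation
  mid_act <- enc_cfg$output_activation
  adam <- .adam_init(net)

  fwd <- function(net, X, training = FALSE) {
    # run full net but force the bottleneck activation at layer n_enc_layers
    full <- net
    cache <- .mlp_forward_ae(full, X, n_enc_layers, mid_act,
                             dropout = if (training) enc_cfg$dropout else 0,
                             training = training)
    cache
  }
  mse_of <- function(net, X) {
    out <- fwd(net, X)$out
    mean((out - X)^2)
  }
  best <- list(net = net, loss = mse_of(net, Xs[val_idx, , drop = FALSE]))
  wait <- 0L
  log_rows <- vector("list", train_cfg$max_epochs)
  for (epoch in seq_len(train_cfg$max_epochs)) {
    lr <- train_cfg$learning_rate * train_cfg$lr_decay^(epoch - 1L)
    set.seed(train_cfg$seed + 3000L + epoch)
    perm <- sample(train_idx)
    batch_starts <- seq(1L, length(perm), by = train_cfg$batch_size)
    epoch_loss <- 0
    for (s in batch_starts) {
      bi <- perm[s:min(s + train_cfg$batch_size - 1L, length(perm))]
      Xb <- Xs[bi, , drop = FALSE]
      cache <- fwd(net, Xb, training = TRUE)
      err <- cache$out - Xb
      loss <- mean(err^2)
      if (!is.finite(loss)) stop("non-finite reconstruction loss at epoch ",
                                 epoch, call. = FALSE)
      epoch_loss <- epoch_loss + loss * length(bi)
      dOut <- 2 * err / length(err)
      grads <- .mlp_backward_ae(net, cache, dOut, n_enc_layers, mid_act)
      upd <- .adam_step(net, grads, adam, lr)
      net <- upd$net; adam <- upd$state
    }
    vl <- mse_of(net, Xs[val_idx, , drop = FALSE])
    log_rows[[epoch]] <- data.frame(epoch = epoch, lr = lr,
                                    train_loss = epoch_loss / length(perm),
                                    val_loss = vl)
    if (vl < best$loss - 1e-8) {
      best <- list(net = net, loss = vl)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= train_cfg$patience) break
    }
  }
  enc_net <- list(W = best$net$W[seq_len(n_enc_layers)],
                  b = best$net$b[seq_len(n_enc_layers)],
                  dims = enc_dims, activation = enc_cfg$activation,
                  output_activation = mid_act)
  structure(list(net = enc_net, full_net = best$net, cfg = enc_cfg,
                 scaler = scaler, kind = kind,
                 log = do.call(rbind, log_rows[!vapply(log_rows, is.null, TRUE)]),
                 best_val_loss = best$loss, seed = train_cfg$seed),
            class = "ae_embedder")
}

# Autoencoder forward/backward: like .mlp_forward/.mlp_backward but with the
# configured activation at the bottleneck layer (index `mid`) and the
# hidden activation elsewhere; final layer linear.
.mlp_forward_ae <- function(net, X, mid, mid_act_name, dropout = 0,
                            training = FALSE) {
  n_layers <- length(net$W)
  act <- .act_fun(net$activation)
  mid_act <- .act_fun(mid_act_name)
  A <- list(X); Z <- vector("list", n_layers); M <- vector("list", n_layers)
  H <- X
  for (i in seq_len(n_layers)) {
    Z[[i]] <- sweep(H %*% net$W[[i]], 2L, net$b[[i]], `+`)
    H <- if (i == n_layers) Z[[i]]
         else if (i == mid) mid_act$f(Z[[i]])
         else act$f(Z[[i]])
    if (training && dropout > 0 && i < n_layers && i != mid) {
      M[[i]] <- matrix(stats::runif(length(H)) >= dropout, nrow(H), ncol(H)) /
        (1 - dropout)
      H <- H * M[[i]]
    }
    A[[i + 1L]] <- H
  }
  list(out = H, A = A, Z = Z, M = M)
}

.mlp_backward_ae <- function(net, cache, dOut, mid, mid_act_name) {
  n_layers <- length(net$W)
  act <- .act_fun(net$activation)
  mid_act <- .act_fun(mid_act_name)
  dW <- vector("list", n_layers); db <- vector("list", n_layers)
  delta <- dOut
  for (i in rev(seq_len(n_layers))) {
    if (!is.null(cache$M[[i]])) delta <- delta * cache$M[[i]]
    z <- cache$Z[[i]]
    if (i < n_layers) {
      afun <- if (i == mid) mid_act else act
      delta <- delta * afun$df(z, afun$f(z))
    }
    dW[[i]] <- crossprod(cache$A[[i]], delta)
    db[[i]] <- colSums(delta)
    if (i > 1L) delta <- tcrossprod(delta, net$W[[i]])
  }
  list(dW = dW, db = db)
}
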