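# Minimal feed-forward engine: dense layers, ReLU/tanh/sigmoid/linear
# activations, inverted dropout, Adam updates. All state is plain R
# matrices so training is exactly reproducible under set.seed().

.act_fun <- function(name) {
  switch(name,
    relu = list(f = function(z) pmax(z, 0), df = function(z, a) (z > 0) * 1),
    tanh = list(f = tanh, df = function(z, a) 1 - a^2),
    sigmoid = list(f = function(z) 1 / (1 + exp(-z)), df = function(z, a) a * (1 - a)),
    softplus = list(f = function(z) ifelse(z > 30, z, log1p(exp(pmin(z, 30)))),
                    df = function(z, a) 1 / (1 + exp(-z))),
    linear = list(f = identity, df = function(z, a) 1),
    stop("unknown activation: ", name, call. = FALSE)
  )
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

# layer_dims: c(input, hidden..., output); activation applies to hidden
# layers, output_activation to the last layer.
.mlp_init <- function(layer_dims, activation = "relu", output_activation = "linear") {
  n <- length(layer_dims) - 1L
  W <- vector("list", n)
  b <- vector("list", n)
  for (i in seq_len(n)) {
    fan_in <- layer_dims[i]
    sd <- sqrt(2 / fan_in)
    W[[i]] <- matrix(stats::rnorm(fan_in * layer_dims[i + 1L], sd = sd),
                     fan_in, layer_dims[i + 1L])
    b[[i]] <- rep(0, layer_dims[i + 1L])
  }
  list(W = W, b = b, dims = layer_dims,
       activation = activation, output_activation = output_activation)
}

# Forward pass on matrix X (rows = examples). During training, inverted
# dropout with rate `dropout` is applied to hidden activations; masks are
# drawn here so the caller controls the RNG stream.
.mlp_forward <- function(net, X, dropout = 0, training = FALSE) {
  n_layers <- length(net$W)
  act <- .act_fun(net$activation)
  out_act <- .act_fun(net$output_activation)
  A <- list(X)       # A[[i]]   = input to layer i
  Z <- vector("list", n_layers)
  M <- vector("list", n_layers)  # dropout masks on layer outputs (hidden only)
  H <- X
  for (i in seq_len(n_layers)) {
    Z[[i]] <- sweep(H %*% net$W[[i]], 2L, net$b[[i]], `+`)
    H <- if (i < n_layers) act$f(Z[[i]]) else out_act$f(Z[[i]])
    if (training && dropout > 0 && i < n_layers) {
      M[[i]] <- matrix(stats::runif(length(H)) >= dropout, nrow(H), ncol(H)) /
        (1 - dropout)
      H <- H * M[[i]]
    }
    A[[i + 1L]] <- H
  }
  list(out = H, A = A, Z = Z, M = M)
}

# Backward pass. dOut = dLoss/dOutput (same shape as forward output).
.mlp_backward <- function(net, cache, dOut) {
  n_layers <- length(net$W)
  act <- .act_fun(net$activation)
  out_act <- .act_fun(net$output_activation)
  dW <- vector("list", n_layers)
  db <- vector("list", n_layers)
  delta <- dOut
  for (i in rev(seq_len(n_layers))) {
    if (!is.null(cache$M[[i]])) delta <- delta * cache$M[[i]]
    a_i <- cache$A[[i + 1L]]
    dfun <- if (i < n_layers) act$df else out_act$df
    # recover pre-dropout activation for the derivative where needed
    z <- cache$Z[[i]]
    delta <- delta * dfun(z, if (i < n_layers) act$f(z) else out_act$f(z))
    dW[[i]] <- crossprod(cache$A[[i]], delta)
    db[[i]] <- colSums(delta)
    if (i > 1L) delta <- tcrossprod(delta, net$W[[i]])
  }
  list(dW = dW, db = db)
}

.adam_init <- function(net) {
  zero_like <- function(p) {
    if (is.matrix(p)) matrix(0, nrow(p), ncol(p)) else rep(0, length(p))
  }
  list(mW = lapply(net$W, zero_like), vW = lapply(net$W, zero_like),
       mb = lapply(net$b, zero_like), vb = lapply(net$b, zero_like),
       t = 0L)
}

.adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(net$W)) {
    state$mW[[i]] <- beta1 * state$mW[[i]] + (1 - beta1) * grads$dW[[i]]
    state$vW[[i]] <- beta2 * state$vW[[i]] + (1 - beta2) * grads$dW[[i]]^2
    net$W[[i]] <- net$W[[i]] - lr * (state$mW[[i]] / bc1) /
      (sqrt(state$vW[[i]] / bc2) + eps)
    state$mb[[i]] <- beta1 * state$mb[[i]] + (1 - beta1) * grads$db[[i]]
    state$vb[[i]] <- beta2 * state$vb[[i]] + (1 - beta2) * grads$db[[i]]^2
    net$b[[i]] <- net$b[[i]] - lr * (state$mb[[i]] / bc1) /
      (sqrt(state$vb[[i]] / bc2) + eps)
  }
  list(net = net, state = state)
}

.bce <- function(p, y, eps = 1e-12) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Feature-wise standardization helpers; sd floor avoids division blowups on
# near-constant features (e.g. never-set fingerprint bits).
.fit_scaler <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[!is.finite(sd) | sd < 1e-8] <- 1
  list(center = mu, scale = sd)
}

.apply_scaler <- function(X, scaler) {
  if (is.null(scaler)) return(X)
  sweep(sweep(X, 2L, scaler$center, `-`), 2L, scaler$scale, `/`)
}
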