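# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the unit suite stays fast.

# a tiny but complete synthetic study
tiny_sim <- function(seed = 1L, ...) {
  sim_config(n_drugs = 24L, n_moas = 3L, n_cells = 30L, n_cancers = 3L,
             n_genes = 40L, n_unknown_cells = 1L, seed = seed, ...)
}

tiny_study <- function(seed = 1L, ...) {
  cfg <- tiny_sim(seed = seed, ...)
  drugs <- gen_drugs(cfg)
  cells <- gen_cells(cfg)
  dr <- gen_dose_response(drugs, cells, cfg)
  list(cfg = cfg, drugs = drugs, cells = cells, dr = dr)
}

# well-separated two-group features for encoder smoke tests
two_group_features <- function(n_per_group = 10L, dim = 12L, gap = 4, seed = 1L) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n_per_group * dim), n_per_group),
             matrix(stats::rnorm(n_per_group * dim, mean = gap), n_per_group))
  rownames(X) <- sprintf("e%02d", seq_len(2L * n_per_group))
  groups <- stats::setNames(rep(c("A", "B"), each = n_per_group), rownames(X))
  list(features = X, groups = groups)
}

fast_train_cfg <- function(seed = 1L, epochs = 8L) {
  train_config(max_epochs = epochs, patience = 4L, pairs_per_epoch = 128L,
               batch_size = 32L, seed = seed)
}

small_enc_cfg <- function(input_dim, embedding_dim = 4L) {
  encoder_config(input_dim = input_dim, hidden_dims = c(16L, 8L),
                 embedding_dim = embedding_dim, dropout = 0.1)
}

# linearly separable toy classification set
toy_separable <- function(n = 40L, seed = 1L) {
  set.seed(seed)
  x <- cbind(a = c(stats::rnorm(n / 2, -2), stats::rnorm(n / 2, 2)),
             b = stats::rnorm(n))
  list(x = x, y = rep(c(0L, 1L), each = n / 2))
}

write_temp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
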