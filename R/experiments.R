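# Benchmark-style experiments on synthetic studies. These are the
# package-level analogues of the representation-expressiveness and
# drug-prioritization analyses: self-contained, seeded, and sized to run
# on one CPU in minutes.

#' Embedding-expressiveness experiment
#'
#' Generates a synthetic study, then measures mean inter-group
#' separability (intra/inter cosine ratio, equal group weights) of three
#' representations for drugs (grouped by MOA) and cell lines (grouped by
#' cancer type): the raw features (fingerprint / expression), the
#' bottleneck of a reconstruction autoencoder, and the contrastively
#' pretrained twin-network encoder. The contrastive encoder is expected to
#' separate groups far better than either baseline, mirroring the
#' expressiveness gap between task-aware and reconstruction-driven
#' representations.
#'
#' @param seed Integer seed; governs data generation and all training.
#' @param cfg A [sim_config()]; defaults to the standard study
#'   (4 MOAs x 25 drugs with 6-bit fingerprint noise, 4 cancers x 30 cells
#'   with expression signal-to-noise 6:1).
#' @param entities Which entity kinds to evaluate.
#' @param train_cfg Optional [train_config()] overrides (seed is always
#'   derived from `seed`).
#' @return Data frame with columns `entity`, `representation`
#'   (`raw`, `autoencoder`, `contrastive`), `mean_intra`, `mean_inter`,
#'   `mean_separability`.
#' @export
separability_experiment <- function(seed = 1L, cfg = NULL,
                                    entities = c("drug", "cell"),
                                    train_cfg = NULL) {
  if (is.null(cfg)) cfg <- sim_config(seed = .derive_seed(seed, "sim"))
  rows <- list()
  add <- function(entity, representation, rep_obj) {
    rows[[length(rows) + 1L]] <<- data.frame(
      entity = entity, representation = representation,
      mean_intra = rep_obj$mean_intra, mean_inter = rep_obj$mean_inter,
      mean_separability = rep_obj$mean_separability,
      stringsAsFactors = FALSE)
  }
  measure <- function(entity, features, grouping_obj, groups, edim) {
    tc <- train_cfg
    if (is.null(tc)) tc <- train_config()
    tc$seed <- .derive_seed(seed, paste0("enc_", entity))
    enc_cfg <- encoder_config(input_dim = ncol(features), embedding_dim = edim)
    add(entity, "raw", suppressWarnings(group_similarity(features, groups)))
    ae <- train_autoencoder_baseline(features, enc_cfg, tc, kind = entity)
    add(entity, "autoencoder",
        suppressWarnings(group_similarity(embed_entities(ae, features), groups)))
    enc <- train_encoder(features, grouping_obj, enc_cfg, tc, kind = entity)
    add(entity, "contrastive",
        suppressWarnings(group_similarity(embed_entities(enc, features), groups)))
  }
  if ("drug" %in% entities) {
    drugs <- gen_drugs(cfg)
    targets <- parse_gene_targets(drugs$table$gene_targets, drugs$table$drug_id)
    measure("drug", drugs$fingerprints, group_by_targets(targets),
            stats::setNames(drugs$table$moa, drugs$table$drug_id), 64L)
  }
  if ("cell" %in% entities) {
    cells <- gen_cells(cfg)
    keys <- stats::setNames(cells$table$cancer_type, cells$table$cell_id)
    keys <- keys[!keys %in% c("Unknown", "")]
    measure("cell", cells$expression[names(keys), , drop = FALSE],
            group_by_key(keys), keys, 32L)
  }
  do.call(rbind, rows)
}

#' Study configuration for the signal-recovery experiment
#'
#' Ten MOAs of ten drugs each over four cancers. Under the `"strong"`
#' condition exactly one MOA is matched to each cancer, so the planted
#' matched block covers 10% of each cell's drugs — the same fraction the
#' top-decile labeling rule marks effective — and with boost well above
#' the pair-level noise the effective set is essentially the matched set.
#' Under `"null"` the match matrix is zero and labels are pure noise.
#'
#' @param signal `"strong"` or `"null"`.
#' @param seed Integer seed.
#' @param n_cells Number of cell lines (default 240).
#' @param boost Sensitivity boost of matched (MOA, cancer) blocks.
#' @return A [sim_config()].
#' @export
signal_recovery_config <- function(signal = c("strong", "null"), seed = 1L,
                                   n_cells = 240L, boost = 4) {
  signal <- match.arg(signal)
  n_moas <- 10L
  n_cancers <- 4L
  M <- matrix(0, n_moas, n_cancers)
  if (signal == "strong") {
    M[cbind(seq_len(n_cancers), seq_len(n_cancers))] <- boost
  }
  sim_config(n_drugs = 100L, n_moas = n_moas, n_cells = n_cells,
             n_cancers = n_cancers, match_matrix = M, seed = seed)
}

#' End-to-end signal-recovery experiment
#'
#' Runs the full pipeline on a synthetic study: score and label the
#' dose-response table, split cells with a cancer-stratified plan, train a
#' random-forest end classifier on the training folds' pairs
#' (fingerprint + expression features), prioritize the full non-withdrawn
#' drug pool for each trained-on test cell, and measure mean precision at
#' 1 against the held-out effective sets. With a strong planted mechanism
#' the top-ranked drug should almost always be effective; with no
#' mechanism precision collapses to the label prevalence.
#'
#' @param seed Integer seed.
#' @param signal `"strong"` or `"null"` (see [signal_recovery_config()]).
#' @param num_trees Trees in the random forest (default 250).
#' @param n_cells Cells in the study (default 240).
#' @return List: `mean_p_at_1`, `prevalence` (label rate among test-cell
#'   pairs), `n_test_cells`, `per_cell` (named vector).
#' @export
signal_recovery_experiment <- function(seed = 1L,
                                       signal = c("strong", "null"),
                                       num_trees = 250L, n_cells = 240L) {
  signal <- match.arg(signal)
  cfg <- signal_recovery_config(signal, seed = .derive_seed(seed, "sim"),
                                n_cells = n_cells)
  drugs <- gen_drugs(cfg)
  cells <- gen_cells(cfg)
  dr <- gen_dose_response(drugs, cells, cfg)
  sc <- score_pairs(dr$records, drugs$table, cells$table, cells$expression)
  pairs <- sc$pairs
  cells_known <- cells$table[cells$table$cell_id %in% unique(pairs$cell_id), ,
                             drop = FALSE]
  plan <- make_split(cells_known, seed = .derive_seed(seed, "split"))
  tr <- pairs[pairs$cell_id %in% training_cells(plan), , drop = FALSE]
  te_cells <- plan$trained_on_test
  asm <- feature_assembly("fingerprint", "expression", "concat",
                          drug_block_len = ncol(drugs$fingerprints),
                          cell_block_len = ncol(cells$expression))
  X <- assemble_pair_matrix(tr, drugs$fingerprints, cells$expression, asm)
  mdl <- train_classifier(X, tr$label,
                          classifier_spec("random_forest",
                                          list(num_trees = num_trees),
                                          seed = .derive_seed(seed, "rf")))
  eff <- split(pairs$drug_id[pairs$label == 1L], pairs$cell_id[pairs$label == 1L])
  pool <- drugs$fingerprints[!drugs$table$withdrawn, , drop = FALSE]
  per_cell <- vapply(te_cells, function(cid) {
    res <- prioritize(mdl, cells$expression[cid, ], pool, asm, cell_id = cid)
    precision_at_k_cell(res, eff[[cid]], 1L)
  }, numeric(1))
  list(mean_p_at_1 = mean(per_cell),
       prevalence = mean(pairs$label[pairs$cell_id %in% te_cells]),
       n_test_cells = length(te_cells),
       per_cell = per_cell)
}
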