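# Synthetic study generator. Plants mechanism-of-action (MOA) structure in
# drug fingerprints and gene-target sets, cancer-type structure in
# expression, and a drug-group -> cancer-group effectiveness mechanism in
# the dose-response parameters, so every pipeline stage can be exercised
# and checked offline against closed-form expectations.

#' Configuration for the synthetic study generator
#'
#' The latent sensitivity of a (drug, cell) pair is
#' `s = base_sensitivity + match_matrix[moa, cancer] + N(0, sensitivity_noise_sd)`;
#' the fitted-curve parameters are fixed strictly decreasing transforms of
#' `s` (`auc = 1/(1+exp(s))`, `lower_limit = 0.01 + 0.99/(1+exp(s))`,
#' `ic50 = exp(-s)`), so the effective score is strictly increasing in `s`
#' and closed-form oracles exist for every expectation.
#'
#' Fingerprints are generated directly as bit vectors: each MOA gets a
#' prototype sharing `fp_shared_bits` scaffold bits with every other MOA
#' (drug libraries share common substructure bits) plus MOA-specific bits up
#' to `fp_on_bits`; each drug flips `fp_noise_bits` random bits of its
#' prototype. Expression is a shared per-gene baseline (log2-TPM-like,
#' `N(6, 2)`) plus a cancer-specific shift `N(0, expr_signal)` on a quarter
#' of the genes, plus `N(0, expr_noise_sd)` cell-level noise.
#'
#' @param n_drugs,n_moas Drug count and number of MOA groups.
#' @param targets_per_moa Gene targets per MOA (disjoint across MOAs).
#' @param n_bits Fingerprint length.
#' @param fp_on_bits Bits set in each MOA prototype.
#' @param fp_shared_bits Scaffold bits shared by all prototypes.
#' @param fp_noise_bits Random bit flips per drug.
#' @param withdrawn_frac Fraction of drugs flagged withdrawn.
#' @param n_cells,n_cancers Cell count and number of cancer types.
#' @param n_unknown_cells Extra cells labeled `"Unknown"` cancer.
#' @param n_genes Gene-panel length (default 463).
#' @param expr_signal SD of the cancer-specific mean shift.
#' @param expr_noise_sd SD of per-cell expression noise.
#' @param match_matrix Optional `n_moas x n_cancers` sensitivity-boost
#'   matrix; by default MOA `m` boosts cancer `((m-1) mod n_cancers) + 1`
#'   by `match_boost`.
#' @param match_boost Default boost magnitude (0 removes all signal).
#' @param base_sensitivity Baseline latent sensitivity.
#' @param sensitivity_noise_sd SD of pair-level sensitivity noise.
#' @param r2_low_frac Fraction of records given a poor curve fit (r2 < 0.7).
#' @param missing_frac Fraction of records with one curve parameter missing.
#' @param neg_lower_frac Fraction of records given a negative lower limit.
#' @param dup_frac Fraction of pairs duplicated under a secondary screen id.
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_drugs = 100L, n_moas = 4L, targets_per_moa = 3L,
                       n_bits = 256L, fp_on_bits = 48L, fp_shared_bits = 24L,
                       fp_noise_bits = 6L, withdrawn_frac = 0.05,
                       n_cells = 120L, n_cancers = 4L, n_unknown_cells = 2L,
                       n_genes = 463L, expr_signal = 3, expr_noise_sd = 0.5,
                       match_matrix = NULL, match_boost = 4,
                       base_sensitivity = -2, sensitivity_noise_sd = 1,
                       r2_low_frac = 0.05, missing_frac = 0.01,
                       neg_lower_frac = 0.01, dup_frac = 0.02, seed = 1L) {
  cfg <- list(n_drugs = as.integer(n_drugs), n_moas = as.integer(n_moas),
              targets_per_moa = as.integer(targets_per_moa),
              n_bits = as.integer(n_bits), fp_on_bits = as.integer(fp_on_bits),
              fp_shared_bits = as.integer(fp_shared_bits),
              fp_noise_bits = as.integer(fp_noise_bits),
              withdrawn_frac = withdrawn_frac,
              n_cells = as.integer(n_cells), n_cancers = as.integer(n_cancers),
              n_unknown_cells = as.integer(n_unknown_cells),
              n_genes = as.integer(n_genes), expr_signal = expr_signal,
              expr_noise_sd = expr_noise_sd, match_matrix = match_matrix,
              match_boost = match_boost, base_sensitivity = base_sensitivity,
              sensitivity_noise_sd = sensitivity_noise_sd,
              r2_low_frac = r2_low_frac, missing_frac = missing_frac,
              neg_lower_frac = neg_lower_frac, dup_frac = dup_frac,
              seed = as.integer(seed))
  stopifnot(cfg$n_drugs >= cfg$n_moas, cfg$n_moas >= 1L,
            cfg$fp_noise_bits < cfg$n_bits,
            cfg$fp_shared_bits <= cfg$fp_on_bits,
            cfg$fp_on_bits <= cfg$n_bits,
            all(c(cfg$r2_low_frac, cfg$missing_frac, cfg$neg_lower_frac,
                  cfg$dup_frac, cfg$withdrawn_frac) >= 0))
  structure(cfg, class = "sim_config")
}

.derive_seed <- function(seed, name) {
  (as.integer(seed) * 7919L + sum(utf8ToInt(name))) %% 2147483629L
}

.moa_match_matrix <- function(cfg) {
  if (!is.null(cfg$match_matrix)) {
    M <- cfg$match_matrix
    stopifnot(nrow(M) == cfg$n_moas, ncol(M) == cfg$n_cancers)
    return(M)
  }
  M <- matrix(0, cfg$n_moas, cfg$n_cancers)
  for (m in seq_len(cfg$n_moas)) {
    M[m, ((m - 1L) %% cfg$n_cancers) + 1L] <- cfg$match_boost
  }
  M
}

#' Generate the synthetic drug table and fingerprints
#'
#' @param cfg A [sim_config()].
#' @return List: `table` (drug_id, moa, gene_targets, withdrawn, smiles=NA)
#'   and `fingerprints` (0/1 matrix, rows = drug ids).
#' @export
gen_drugs <- function(cfg) {
  if (cfg$fp_noise_bits >= cfg$n_bits) stop("fp_noise_bits >= n_bits", call. = FALSE)
  set.seed(.derive_seed(cfg$seed, "drugs"))
  moas <- paste0("MOA_", seq_len(cfg$n_moas))
  shared <- sample.int(cfg$n_bits, cfg$fp_shared_bits)
  protos <- lapply(seq_len(cfg$n_moas), function(m) {
    own <- sample(setdiff(seq_len(cfg$n_bits), shared),
                  cfg$fp_on_bits - cfg$fp_shared_bits)
    v <- integer(cfg$n_bits)
    v[c(shared, own)] <- 1L
    v
  })
  moa_of <- rep(moas, length.out = cfg$n_drugs)
  ids <- sprintf("DRUG_%03d", seq_len(cfg$n_drugs))
  fp <- t(vapply(seq_len(cfg$n_drugs), function(i) {
    v <- protos[[match(moa_of[i], moas)]]
    if (cfg$fp_noise_bits > 0L) {
      flip <- sample.int(cfg$n_bits, cfg$fp_noise_bits)
      v[flip] <- 1L - v[flip]
    }
    v
  }, integer(cfg$n_bits)))
  rownames(fp) <- ids
  colnames(fp) <- paste0("b", seq_len(cfg$n_bits) - 1L)
  targets <- vapply(moa_of, function(m) {
    mi <- match(m, moas)
    paste0("TG", mi, "_", seq_len(cfg$targets_per_moa), collapse = ";")
  }, character(1))
  n_withdrawn <- round(cfg$withdrawn_frac * cfg$n_drugs)
  withdrawn <- rep(FALSE, cfg$n_drugs)
  if (n_withdrawn > 0L) withdrawn[sample.int(cfg$n_drugs, n_withdrawn)] <- TRUE
  list(table = data.frame(drug_id = ids, smiles = NA_character_, moa = moa_of,
                          gene_targets = targets, withdrawn = withdrawn,
                          stringsAsFactors = FALSE),
       fingerprints = fp)
}

#' Generate the synthetic cell-line table and expression matrix
#'
#' @param cfg A [sim_config()].
#' @return List: `table` (cell_id, cancer_type) and `expression` (matrix,
#'   rows = cell ids, columns = the gene panel).
#' @export
gen_cells <- function(cfg) {
  if (cfg$n_cancers > cfg$n_cells) stop("n_cancers > n_cells", call. = FALSE)
  set.seed(.derive_seed(cfg$seed, "cells"))
  cancers <- paste0("CANCER_", seq_len(cfg$n_cancers))
  genes <- sprintf("GENE%04d", seq_len(cfg$n_genes))
  baseline <- stats::rnorm(cfg$n_genes, mean = 6, sd = 2)
  n_shift <- max(1L, floor(cfg$n_genes / 4))
  shift <- sapply(seq_len(cfg$n_cancers), function(cc) {
    v <- numeric(cfg$n_genes)
    on <- sample.int(cfg$n_genes, n_shift)
    v[on] <- stats::rnorm(n_shift, sd = cfg$expr_signal)
    v
  })
  n_total <- cfg$n_cells + cfg$n_unknown_cells
  cancer_of <- c(rep(cancers, length.out = cfg$n_cells),
                 rep("Unknown", cfg$n_unknown_cells))
  hidden <- c(match(cancer_of[seq_len(cfg$n_cells)], cancers),
              sample.int(cfg$n_cancers, cfg$n_unknown_cells, replace = TRUE))
  ids <- sprintf("CELL_%03d", seq_len(n_total))
  expr <- t(vapply(seq_len(n_total), function(i) {
    baseline + shift[, hidden[i]] + stats::rnorm(cfg$n_genes, sd = cfg$expr_noise_sd)
  }, numeric(cfg$n_genes)))
  rownames(expr) <- ids
  colnames(expr) <- genes
  list(table = data.frame(cell_id = ids, cancer_type = cancer_of,
                          stringsAsFactors = FALSE),
       expression = expr)
}

#' Generate the synthetic dose-response table
#'
#' Also returns the latent per-pair sensitivities so monotonicity oracles
#' can be checked; corrupt rows (missing values, negative lower limits,
#' duplicate screens, poor fits) are injected to exercise the filter
#' cascade.
#'
#' @param drugs Output of [gen_drugs()].
#' @param cells Output of [gen_cells()].
#' @param cfg A [sim_config()].
#' @return List: `records` (a dose-response data frame) and `sensitivity`
#'   (clean per-pair latent values, named `drug\rcell`).
#' @export
gen_dose_response <- function(drugs, cells, cfg) {
  set.seed(.derive_seed(cfg$seed, "dose_response"))
  M <- .moa_match_matrix(cfg)
  cancers <- paste0("CANCER_", seq_len(cfg$n_cancers))
  moas <- paste0("MOA_", seq_len(cfg$n_moas))
  grid <- expand.grid(drug_id = drugs$table$drug_id,
                      cell_id = cells$table$cell_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mi <- match(drugs$table$moa[match(grid$drug_id, drugs$table$drug_id)], moas)
  ci <- match(cells$table$cancer_type[match(grid$cell_id, cells$table$cell_id)],
              cancers)
  boost <- ifelse(is.na(ci), 0, M[cbind(mi, ifelse(is.na(ci), 1L, ci))])
  s <- cfg$base_sensitivity + boost +
    stats::rnorm(nrow(grid), sd = cfg$sensitivity_noise_sd)
  auc <- 1 / (1 + exp(s))
  lower_limit <- 0.01 + 0.99 / (1 + exp(s))
  ic50 <- exp(-s)
  n <- nrow(grid)
  r2 <- stats::runif(n, 0.75, 0.995)
  n_low <- round(cfg$r2_low_frac * n)
  if (n_low > 0L) r2[sample.int(n, n_low)] <- stats::runif(n_low, 0.3, 0.69)
  rec <- data.frame(drug_id = grid$drug_id, cell_id = grid$cell_id,
                    auc = auc, lower_limit = lower_limit, ic50 = ic50,
                    r2 = r2, screen_id = "MTS010", stringsAsFactors = FALSE)
  n_miss <- round(cfg$missing_frac * n)
  if (n_miss > 0L) {
    rows <- sample.int(n, n_miss)
    col <- sample(c("auc", "lower_limit", "ic50"), n_miss, replace = TRUE)
    for (i in seq_len(n_miss)) rec[rows[i], col[i]] <- NA_real_
  }
  n_neg <- round(cfg$neg_lower_frac * n)
  if (n_neg > 0L) {
    rows <- sample.int(n, n_neg)
    rec$lower_limit[rows] <- -stats::runif(n_neg, 0.01, 0.2)
  }
  n_dup <- round(cfg$dup_frac * n)
  if (n_dup > 0L) {
    rows <- sample.int(n, n_dup)
    dup <- rec[rows, , drop = FALSE]
    dup$screen_id <- sample(c("MTS005", "MTS006"), n_dup, replace = TRUE)
    dup$r2 <- pmax(0.05, dup$r2 - stats::runif(n_dup, 0, 0.2))
    rec <- rbind(rec, dup)
  }
  rownames(rec) <- NULL
  list(records = rec,
       sensitivity = stats::setNames(s, paste(grid$drug_id, grid$cell_id,
                                              sep = "\r")))
}

#' Generate and write a complete synthetic study
#'
#' Writes `drugs.csv`, `fingerprints.csv`, `cells.csv`, `expression.csv`,
#' `gene_panel.txt`, `dose_response.csv` and a `manifest.json` recording
#' the configuration, into `outdir`.
#'
#' @param cfg A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the list of generated objects.
#' @export
simulate_study <- function(cfg, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  drugs <- gen_drugs(cfg)
  cells <- gen_cells(cfg)
  dr <- gen_dose_response(drugs, cells, cfg)
  .write_csv(drugs$table, file.path(outdir, "drugs.csv"))
  write_fingerprints(drugs$fingerprints, file.path(outdir, "fingerprints.csv"))
  .write_csv(cells$table, file.path(outdir, "cells.csv"))
  write_expression(cells$expression, file.path(outdir, "expression.csv"))
  writeLines(colnames(cells$expression), file.path(outdir, "gene_panel.txt"))
  write_dose_response(dr$records, file.path(outdir, "dose_response.csv"))
  manifest <- unclass(cfg)
  manifest$match_matrix <- .moa_match_matrix(cfg)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(list(drugs = drugs, cells = cells, dose_response = dr))
}
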