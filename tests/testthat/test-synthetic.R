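test_that("drug generator plants MOA structure and respects the noise knob", {
  cfg <- tiny_sim(2L, fp_noise_bits = 0L)
  drugs <- gen_drugs(cfg)
  # zero noise: all drugs of an MOA share the prototype fingerprint
  for (m in unique(drugs$table$moa)) {
    fp <- drugs$fingerprints[drugs$table$drug_id[drugs$table$moa == m], ,
                             drop = FALSE]
    expect_true(all(apply(fp, 2L, function(col) length(unique(col)) == 1L)))
  }
  # disjoint target sets: target grouping recovers exactly the MOA partition
  tg <- parse_gene_targets(drugs$table$gene_targets, drugs$table$drug_id)
  gr <- group_by_targets(tg)
  S <- siamdr:::.same_matrix(gr)
  moa <- drugs$table$moa[match(rownames(S), drugs$table$drug_id)]
  expect_identical(unname(S), unname(outer(moa, moa, `==`) & !diag(nrow(S))))
  expect_identical(gen_drugs(cfg), drugs)                # seeded
  expect_false(identical(gen_drugs(tiny_sim(3L)), drugs))
  expect_error(gen_drugs(tiny_sim(2L, fp_noise_bits = 300L)), "fp_noise_bits")
})

test_that("cell generator plants cancer structure with controllable noise", {
  quiet <- tiny_sim(4L, expr_noise_sd = 0)
  cells <- gen_cells(quiet)
  known <- cells$table[cells$table$cancer_type != "Unknown", ]
  for (ca in unique(known$cancer_type)) {
    expr <- cells$expression[known$cell_id[known$cancer_type == ca], ,
                             drop = FALSE]
    expect_lt(max(apply(expr, 2L, sd)), 1e-12)   # zero noise: identical cells
  }
  expect_equal(sum(cells$table$cancer_type == "Unknown"), 1L)
  expect_identical(gen_cells(quiet), cells)
  expect_error(gen_cells(sim_config(n_drugs = 24L, n_moas = 3L, n_cells = 2L,
                                    n_cancers = 3L, n_genes = 40L, seed = 1L)),
               "n_cancers")
})

test_that("dose-response sensitivities map monotonically to the effective score", {
  cfg <- tiny_sim(6L, missing_frac = 0, neg_lower_frac = 0, dup_frac = 0,
                  r2_low_frac = 0)
  study <- tiny_study(6L, missing_frac = 0, neg_lower_frac = 0, dup_frac = 0,
                      r2_low_frac = 0)
  rec <- study$dr$records
  s <- study$dr$sensitivity[paste(rec$drug_id, rec$cell_id, sep = "\r")]
  ces <- compute_ces(rec$auc, rec$lower_limit, rec$ic50)
  ord <- order(s)
  expect_true(all(diff(ces[ord]) > 0))          # strictly increasing in s
  expect_gt(cor(s, ces, method = "spearman"), 0.9999)
})

test_that("matched MOA-cancer pairs dominate the top-decile labels under strong signal", {
  study <- tiny_study(8L, match_boost = 6, sensitivity_noise_sd = 0.2)
  res <- score_pairs(study$dr$records, study$drugs$table, study$cells$table,
                     study$cells$expression)
  pairs <- res$pairs
  moa_i <- match(study$drugs$table$moa[match(pairs$drug_id,
                                             study$drugs$table$drug_id)],
                 paste0("MOA_", seq_len(study$cfg$n_moas)))
  can_i <- match(study$cells$table$cancer_type[match(pairs$cell_id,
                                                     study$cells$table$cell_id)],
                 paste0("CANCER_", seq_len(study$cfg$n_cancers)))
  M <- siamdr:::.moa_match_matrix(study$cfg)
  matched <- M[cbind(moa_i, can_i)] > 0
  expect_gt(mean(matched[pairs$label == 1L]), 0.95)
})

test_that("the poor-fit fraction lands near its binomial expectation", {
  cfg <- tiny_sim(9L, r2_low_frac = 0.1, missing_frac = 0, neg_lower_frac = 0,
                  dup_frac = 0)
  study <- tiny_study(9L, r2_low_frac = 0.1, missing_frac = 0,
                      neg_lower_frac = 0, dup_frac = 0)
  n <- nrow(study$dr$records)
  frac_low <- mean(study$dr$records$r2 < 0.7)
  expect_equal(frac_low, 0.1, tolerance = 0.03)
})

test_that("generated tables round-trip through every reader", {
  outdir <- file.path(tempdir(), "simcheck")
  on.exit(unlink(outdir, recursive = TRUE))
  cfg <- tiny_sim(10L)
  obj <- simulate_study(cfg, outdir)
  drugs <- read_drugs(file.path(outdir, "drugs.csv"))
  expect_equal(drugs$drug_id, obj$drugs$table$drug_id)
  expect_equal(drugs$withdrawn, obj$drugs$table$withdrawn)
  fp <- read_fingerprints(file.path(outdir, "fingerprints.csv"))
  expect_identical(unname(fp), unname(obj$drugs$fingerprints))
  panel <- read_gene_panel(file.path(outdir, "gene_panel.txt"))
  expr <- read_expression(file.path(outdir, "expression.csv"), panel)
  expect_equal(unname(expr), unname(obj$cells$expression), tolerance = 1e-12)
  rec <- read_dose_response(file.path(outdir, "dose_response.csv"))
  expect_equal(nrow(rec), nrow(obj$dose_response$records))
  cells <- read_cells(file.path(outdir, "cells.csv"))
  expect_equal(cells$cancer_type, obj$cells$table$cancer_type)
})

test_that("simulation is fully deterministic under its seed", {
  d1 <- file.path(tempdir(), "simA")
  d2 <- file.path(tempdir(), "simB")
  on.exit(unlink(c(d1, d2), recursive = TRUE))
  simulate_study(tiny_sim(12L), d1)
  simulate_study(tiny_sim(12L), d2)
  for (f in c("drugs.csv", "fingerprints.csv", "cells.csv", "expression.csv",
              "dose_response.csv", "gene_panel.txt")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
})
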