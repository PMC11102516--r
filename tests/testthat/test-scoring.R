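test_that("effective score matches hand-evaluated values and rejects bad domains", {
  expect_equal(compute_ces(1, 1, 1), log(3 / 2), tolerance = 1e-12)
  expect_equal(compute_ces(0.5, 0.1, 1), log(16), tolerance = 1e-12)
  expect_error(compute_ces(1, 0, 1), "lower_limit")
  expect_error(compute_ces(-1, 1, 1), "auc")
  expect_equal(compute_ces(0.5, 0.1, 1, base = 10), log10(16), tolerance = 1e-12)
})

test_that("effective score is symmetric and strictly decreasing in each argument", {
  set.seed(71)
  for (i in 1:200) {
    x <- exp(runif(3, -4, 4))
    v <- compute_ces(x[1], x[2], x[3])
    expect_equal(compute_ces(x[2], x[3], x[1]), v, tolerance = 1e-12)
    expect_equal(compute_ces(x[3], x[1], x[2]), v, tolerance = 1e-12)
    bump <- x[1] * 1.05
    expect_lt(compute_ces(bump, x[2], x[3]), v)
    expect_lt(compute_ces(x[1], x[2] * 1.05, x[3]), v)
  }
})

test_that("binarization thresholds follow the quantile and normal rules", {
  b <- binarize_scores(1:10)
  expect_equal(b$rule$threshold, 9.1)            # type-7 quantile by hand
  expect_equal(sum(b$labels), 1L)
  expect_equal(b$labels[10], 1L)

  x <- c(0, 1, 2, 3, 100)
  bn <- binarize_scores(x, method = "normal_approx")
  expect_equal(bn$rule$threshold, mean(x) + 1.28 * sd(x), tolerance = 1e-12)

  expect_warning(bc <- binarize_scores(rep(2, 5)), "all")
  expect_equal(bc$labels, rep(1L, 5))
  expect_error(binarize_scores(3), "finite")
})

test_that("empirical label fraction tracks 1 - quantile for distinct values", {
  set.seed(9)
  for (n in c(20L, 57L, 400L)) {
    x <- rnorm(n)
    lab <- binarize_scores(x)$labels
    expect_lte(abs(mean(lab) - 0.1), 1 / n + 1e-12)
  }
})

test_that("quality filter drops stages in order with telescoping counts", {
  rec <- data.frame(
    drug_id = paste0("D", 1:6), cell_id = "C1",
    auc = c(0.5, NA, 0.5, 0.5, 0.5, 0.5),
    lower_limit = c(0.1, 0.1, -0.1, 0, 0.1, 0.1),
    ic50 = c(1, 1, 1, 1, 1, 1),
    r2 = c(0.9, 0.9, 0.9, 0.9, 0.65, 0.9),
    screen_id = "MTS010", stringsAsFactors = FALSE)
  out <- filter_records(rec)
  expect_equal(out$records$drug_id, c("D1", "D6"))
  st <- out$report$stages
  expect_equal(st$n_in[-1], st$n_out[-length(st$n_out)])   # telescoping
  expect_equal(st$n_out[st$stage == "missing_values"], 5L)
  expect_equal(st$n_out[st$stage == "negative_lower_limit"], 4L)
  expect_equal(st$n_out[st$stage == "nonpositive_parameter"], 3L)
  expect_equal(st$n_out[st$stage == "low_r2"], 2L)
  expect_equal(out$report$dropped$stage[out$report$dropped$drug_id == "D5"],
               "low_r2")
  # idempotence
  again <- filter_records(out$records)
  expect_equal(again$records, out$records)
})

test_that("duplicate resolution prefers the designated screen then highest r2", {
  rec <- data.frame(
    drug_id = c("D1", "D1", "D2", "D2", "D3"),
    cell_id = "C1",
    auc = 0.5, lower_limit = 0.1, ic50 = 1,
    r2 = c(0.8, 0.95, 0.71, 0.93, 0.9),
    screen_id = c("MTS010", "MTS005", "MTS005", "MTS006", "MTS010"),
    stringsAsFactors = FALSE)
  out <- resolve_duplicates(rec)
  expect_equal(nrow(out), 3L)
  expect_equal(out$screen_id[out$drug_id == "D1"], "MTS010")  # preferred wins
  expect_equal(out$r2[out$drug_id == "D2"], 0.93)             # else best fit
  expect_equal(out$drug_id[3], "D3")                          # singleton kept

  tie <- data.frame(drug_id = "D1", cell_id = "C1", auc = 0.5,
                    lower_limit = 0.1, ic50 = 1, r2 = c(0.9, 0.9),
                    screen_id = c("MTS005", "MTS006"), stringsAsFactors = FALSE)
  expect_equal(resolve_duplicates(tie)$screen_id, "MTS005")   # first occurrence
})

test_that("entity exclusion removes withdrawn drugs and uninformative cells", {
  pairs <- rbind(
    data.frame(drug_id = "DW", cell_id = "C1", ces = 1, label = 1L),
    data.frame(drug_id = paste0("D", 1:3), cell_id = "C1", ces = 1,
               label = c(1L, 0L, 0L)),
    data.frame(drug_id = paste0("D", 1:3), cell_id = "C2", ces = 0, label = 0L),
    data.frame(drug_id = paste0("D", 1:3), cell_id = "C3", ces = 1,
               label = c(1L, 0L, 0L)),
    data.frame(drug_id = paste0("D", 1:3), cell_id = "C4", ces = 1,
               label = c(1L, 0L, 0L)))
  drugs <- data.frame(drug_id = c("DW", "D1", "D2", "D3"),
                      withdrawn = c(TRUE, FALSE, FALSE, FALSE))
  cells <- data.frame(cell_id = paste0("C", 1:4),
                      cancer_type = c("Lung", "Lung", "Unknown", "Lung"))
  expr <- matrix(0, 3, 2, dimnames = list(c("C1", "C2", "C3"), NULL))
  out <- exclude_entities(pairs, drugs, cells, expression = expr)
  expect_false("DW" %in% out$pairs$drug_id)     # withdrawn drug removed
  expect_false("C2" %in% out$pairs$cell_id)     # 0% effective cell removed
  expect_false("C3" %in% out$pairs$cell_id)     # unknown cancer removed
  expect_false("C4" %in% out$pairs$cell_id)     # no expression profile
  expect_equal(sort(unique(out$pairs$cell_id)), "C1")
  st <- out$report$stages
  expect_equal(st$n_in[-1], st$n_out[-length(st$n_out)])
})

test_that("full scoring cascade labels ~10% of surviving synthetic pairs", {
  study <- tiny_study(11L)
  res <- score_pairs(study$dr$records, study$drugs$table, study$cells$table,
                     study$cells$expression)
  expect_gt(nrow(res$pairs), 300L)
  expect_lt(abs(mean(res$pairs$label) - 0.1), 0.05)
  expect_true(all(is.finite(res$pairs$ces)))
  expect_equal(res$rule$method, "empirical_quantile")
})
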