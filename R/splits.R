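# Cancer-stratified partitioning. Cancers with too few cell lines are held
# out entirely ("novel" cancers, testing generalization to unseen cancer
# types); each remaining cancer contributes 15% of its cells to a
# trained-on test set and deals the rest round-robin into k folds.

#' Cancer-stratified train/test/novel split
#'
#' Cancers with fewer than `novel_min` cell lines send *all* their cells to
#' the novel-cancer test set. For each remaining cancer,
#' `round(test_frac * n)` cells (half away from zero, minimum 1) are
#' sampled into the trained-on test set; the rest are shuffled and dealt
#' round-robin into `k` folds, so every fold is stratified by cancer even
#' when counts do not divide evenly. Splits operate on cell lines: all of a
#' cell's drug pairs follow it, so no pair-level leakage is possible.
#'
#' @param cells Data frame with `cell_id` and `cancer_type` columns.
#' @param test_frac Per-cancer trained-on test fraction (default 0.15).
#' @param novel_min Minimum cell count for a cancer to be trainable
#'   (default 15).
#' @param k Number of cross-validation folds (default 5).
#' @param seed Integer seed.
#' @return A `split_plan`: `novel_test`, `trained_on_test` (character
#'   vectors of cell ids), `folds` (list of `k` id vectors), `seed`,
#'   `params`.
#' @export
make_split <- function(cells, test_frac = 0.15, novel_min = 15L, k = 5L,
                       seed = 1L) {
  stopifnot(all(c("cell_id", "cancer_type") %in% names(cells)))
  if (any(is.na(cells$cancer_type) | !nzchar(cells$cancer_type))) {
    stop("every cell needs a cancer label", call. = FALSE)
  }
  counts <- table(cells$cancer_type)
  trainable <- names(counts)[counts >= novel_min]
  if (length(trainable) == 0L) {
    stop("no cancer has >= ", novel_min, " cell lines; nothing to train on",
         call. = FALSE)
  }
  novel <- cells$cell_id[!cells$cancer_type %in% trainable]
  set.seed(seed)
  test <- character(0)
  folds <- rep(list(character(0)), k)
  for (cancer in sort(trainable)) {
    ids <- sort(cells$cell_id[cells$cancer_type == cancer])
    n <- length(ids)
    n_test <- max(1L, as.integer(floor(test_frac * n + 0.5)))  # half away from 0
    ids <- ids[sample.int(n)]
    test <- c(test, ids[seq_len(n_test)])
    rest <- ids[-seq_len(n_test)]
    if (length(rest) > 0L) {
      assign_to <- ((seq_along(rest) - 1L) %% k) + 1L
      for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], rest[assign_to == f])
    }
  }
  if (any(lengths(folds) == 0L)) {
    stop("a fold is empty; too few cells for k = ", k, call. = FALSE)
  }
  structure(list(novel_test = novel, trained_on_test = test, folds = folds,
                 seed = as.integer(seed),
                 params = list(test_frac = test_frac,
                               novel_min = as.integer(novel_min),
                               k = as.integer(k))),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan: %d novel-test, %d trained-on-test, folds %s>\n",
              length(x$novel_test), length(x$trained_on_test),
              paste(lengths(x$folds), collapse = "/")))
  invisible(x)
}

#' All training-compartment cell ids of a split plan
#'
#' @param plan A `split_plan`.
#' @return Character vector (union of all folds).
#' @export
training_cells <- function(plan) unlist(plan$folds, use.names = FALSE)

#' Write a split plan to CSV
#'
#' Columns `cell_id`, `compartment` (`novel_test`, `trained_on_test`,
#' `fold`), `fold` (number, NA outside folds).
#'
#' @param plan A `split_plan`.
#' @param path Output CSV path.
#' @export
write_split_plan <- function(plan, path) {
  block <- function(ids, compartment, fold = NA_integer_) {
    data.frame(cell_id = ids,
               compartment = rep(compartment, length(ids)),
               fold = rep(fold, length(ids)), stringsAsFactors = FALSE)
  }
  rows <- rbind(
    block(plan$novel_test, "novel_test"),
    block(plan$trained_on_test, "trained_on_test"),
    do.call(rbind, lapply(seq_along(plan$folds), function(f) {
      block(plan$folds[[f]], "fold", f)
    }))
  )
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a split plan written by [write_split_plan()]
#'
#' @param path CSV path.
#' @param k Number of folds recorded in the file (inferred if `NULL`).
#' @return A `split_plan` (params carry only `k`).
#' @export
read_split_plan <- function(path, k = NULL) {
  df <- .read_csv(path)
  if (is.null(k)) k <- max(df$fold, na.rm = TRUE)
  folds <- lapply(seq_len(k), function(f) {
    df$cell_id[df$compartment == "fold" & !is.na(df$fold) & df$fold == f]
  })
  structure(list(novel_test = df$cell_id[df$compartment == "novel_test"],
                 trained_on_test = df$cell_id[df$compartment == "trained_on_test"],
                 folds = folds, seed = NA_integer_,
                 params = list(k = as.integer(k))),
            class = "split_plan")
}
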