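#' @keywords internal
"_PACKAGE"

# CSV dialect used throughout: comma-delimited, UTF-8, header required,
# "." decimal; "NA" or the empty string denote missing values.
.na_strings <- c("NA", "")

.read_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (length(readLines(path, n = 1L, warn = FALSE)) == 0L) {
    stop("format error: file is empty: ", path, call. = FALSE)
  }
  utils::read.csv(path, stringsAsFactors = FALSE, na.strings = .na_strings,
                  check.names = FALSE, fileEncoding = "UTF-8")
}

.require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop("format error in ", path, ": missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

.as_num <- function(x) suppressWarnings(as.numeric(x))

#' Read a dose-response parameter table
#'
#' Reads fitted dose-response curve parameters for screened drug-cell line
#' pairs. The table must carry columns `drug_id`, `cell_id`, `auc`,
#' `lower_limit`, `ic50`, `r2` and `screen_id`; extra columns are ignored.
#' Unparseable numeric cells become `NA` (a missing flag), never silent
#' zeros. Row order is preserved.
#'
#' @param path Path to a CSV file.
#' @return A data frame with one row per screened pair, the numeric columns
#'   coerced to double with `NA` marking missing values.
#' @export
read_dose_response <- function(path) {
  df <- .read_csv(path)
  cols <- c("drug_id", "cell_id", "auc", "lower_limit", "ic50", "r2", "screen_id")
  .require_columns(df, cols, path)
  out <- data.frame(
    drug_id = as.character(df$drug_id),
    cell_id = as.character(df$cell_id),
    auc = .as_num(df$auc),
    lower_limit = .as_num(df$lower_limit),
    ic50 = .as_num(df$ic50),
    r2 = .as_num(df$r2),
    screen_id = as.character(df$screen_id),
    stringsAsFactors = FALSE
  )
  key <- paste(out$drug_id, out$cell_id, out$screen_id, sep = "\r")
  if (anyDuplicated(key)) {
    stop("format error in ", path,
         ": duplicate (drug_id, cell_id, screen_id) rows", call. = FALSE)
  }
  out
}

#' Write a dose-response parameter table
#'
#' @param records Data frame as returned by [read_dose_response()].
#' @param path Output CSV path.
#' @export
write_dose_response <- function(records, path) {
  .write_csv(records, path)
}

.write_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) {
    ifelse(is.na(x), NA, format(x, digits = 15, trim = TRUE, scientific = FALSE))
  })
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a gene panel
#'
#' One gene symbol per line; blank lines and surrounding whitespace ignored.
#'
#' @param path Path to a plain-text panel file.
#' @return Character vector of gene symbols.
#' @export
read_gene_panel <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x)]
}

#' Read a cell line by gene expression matrix
#'
#' Expects the DepMap orientation: rows are cell lines (first column the cell
#' id), columns are gene symbols. Output columns are restricted to
#' `gene_panel` in panel order.
#'
#' @param path Path to a CSV file.
#' @param gene_panel Character vector of gene symbols to retain, in order.
#' @param transpose If `TRUE`, the file is genes x cells and is transposed
#'   after reading.
#' @return Numeric matrix, rows named by cell id, columns by panel gene.
#' @export
read_expression <- function(path, gene_panel, transpose = FALSE) {
  df <- .read_csv(path)
  ids <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  if (transpose) mat <- t(mat)
  absent <- setdiff(gene_panel, colnames(mat))
  if (length(absent) > 0L) {
    stop("panel gene(s) absent from expression file: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(rownames(mat))) {
    stop("duplicate cell id rows in expression file: ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "),
         call. = FALSE)
  }
  mat <- mat[, gene_panel, drop = FALSE]
  bad <- rownames(mat)[!stats::complete.cases(mat) | !apply(is.finite(mat), 1L, all)]
  if (length(bad) > 0L) {
    stop("cell(s) missing panel gene expression: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  mat
}

#' Write an expression matrix
#'
#' @param mat Numeric matrix, rows cells, columns genes.
#' @param path Output CSV path.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(cell_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .write_csv(df, path)
}

#' Read drug metadata
#'
#' Columns: `drug_id`, `smiles`, `moa`, `gene_targets` (";"-joined symbols,
#' empty for none), `withdrawn` (logical or 0/1).
#'
#' @param path Path to a CSV file.
#' @return Data frame; `gene_targets` stays a ";"-joined string (see
#'   [parse_gene_targets()]), `withdrawn` is logical.
#' @export
read_drugs <- function(path) {
  df <- .read_csv(path)
  .require_columns(df, c("drug_id", "gene_targets", "withdrawn"), path)
  if (anyDuplicated(df$drug_id)) stop("duplicate drug_id rows in ", path, call. = FALSE)
  data.frame(
    drug_id = as.character(df$drug_id),
    smiles = if ("smiles" %in% names(df)) as.character(df$smiles) else NA_character_,
    moa = if ("moa" %in% names(df)) as.character(df$moa) else NA_character_,
    gene_targets = ifelse(is.na(df$gene_targets), "", as.character(df$gene_targets)),
    withdrawn = as.logical(df$withdrawn) %in% TRUE,
    stringsAsFactors = FALSE
  )
}

#' Split ";"-joined gene target strings into sets
#'
#' @param gene_targets Character vector of ";"-joined symbols ("" = none).
#' @param ids Optional names for the result.
#' @return Named list of character vectors (possibly empty).
#' @export
parse_gene_targets <- function(gene_targets, ids = names(gene_targets)) {
  out <- lapply(strsplit(gene_targets, ";", fixed = TRUE), function(x) {
    x <- trimws(x)
    x[nzchar(x)]
  })
  names(out) <- ids
  out
}

#' Read cell-line metadata
#'
#' Columns: `cell_id`, `cancer_type`.
#'
#' @param path Path to a CSV file.
#' @return Data frame with character columns.
#' @export
read_cells <- function(path) {
  df <- .read_csv(path)
  .require_columns(df, c("cell_id", "cancer_type"), path)
  if (anyDuplicated(df$cell_id)) stop("duplicate cell_id rows in ", path, call. = FALSE)
  data.frame(cell_id = as.character(df$cell_id),
             cancer_type = ifelse(is.na(df$cancer_type), "Unknown",
                                  as.character(df$cancer_type)),
             stringsAsFactors = FALSE)
}

#' Read a fingerprint matrix
#'
#' CSV with a `drug_id` column followed by one 0/1 column per bit.
#'
#' @param path Path to a CSV file.
#' @return Integer 0/1 matrix, rows named by drug id.
#' @export
read_fingerprints <- function(path) {
  df <- .read_csv(path)
  ids <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "integer"
  if (!all(mat %in% c(0L, 1L))) stop("fingerprint bits must be 0/1: ", path, call. = FALSE)
  rownames(mat) <- ids
  mat
}

#' Write a fingerprint matrix
#'
#' @param mat 0/1 matrix with drug ids as row names.
#' @param path Output CSV path.
#' @export
write_fingerprints <- function(mat, path) {
  df <- data.frame(drug_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct an embedding set
#'
#' A matrix of learned (or raw) entity vectors keyed by id.
#'
#' @param vectors Numeric matrix, one row per entity.
#' @param ids Entity ids (defaults to row names).
#' @param entity_kind `"drug"`, `"cell"` or `"generic"`.
#' @return An object of class `embedding_set`.
#' @export
embedding_set <- function(vectors, ids = rownames(vectors),
                          entity_kind = c("generic", "drug", "cell")) {
  entity_kind <- match.arg(entity_kind)
  vectors <- as.matrix(vectors)
  if (is.null(ids)) stop("embedding_set requires entity ids", call. = FALSE)
  if (length(ids) != nrow(vectors)) stop("id count must equal row count", call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicate entity ids in embedding set", call. = FALSE)
  if (!all(is.finite(vectors))) stop("embedding vectors must be finite", call. = FALSE)
  rownames(vectors) <- ids
  structure(list(entity_kind = entity_kind, ids = as.character(ids),
                 vectors = vectors),
            class = "embedding_set")
}

#' @export
as.matrix.embedding_set <- function(x, ...) x$vectors

#' @export
print.embedding_set <- function(x, ...) {
  cat(sprintf("<embedding_set: %d %s entities x %d dims>\n",
              length(x$ids), x$entity_kind, ncol(x$vectors)))
  invisible(x)
}

#' Write an embedding set to CSV
#'
#' Columns: `id`, then `dim_0` .. `dim_{d-1}`.
#'
#' @param emb An `embedding_set`.
#' @param path Output CSV path.
#' @export
write_embeddings <- function(emb, path) {
  v <- emb$vectors
  colnames(v) <- paste0("dim_", seq_len(ncol(v)) - 1L)
  df <- data.frame(id = emb$ids, v, check.names = FALSE, stringsAsFactors = FALSE)
  .write_csv(df, path)
}

#' Read an embedding set from CSV
#'
#' @param path CSV written by [write_embeddings()].
#' @param entity_kind Entity kind to record.
#' @return An `embedding_set`.
#' @export
read_embeddings <- function(path, entity_kind = "generic") {
  df <- .read_csv(path)
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  embedding_set(mat, ids = as.character(df[[1L]]), entity_kind = entity_kind)
}

#' Construct a prioritization result
#'
#' @param cell_id Cell line id.
#' @param drug_id Drug ids in rank order.
#' @param score Predicted effectiveness scores, non-increasing.
#' @return An object of class `prioritization` with a `ranked` data frame
#'   (`rank`, `drug_id`, `score`).
#' @export
prioritization_result <- function(cell_id, drug_id, score) {
  stopifnot(length(drug_id) == length(score))
  if (length(score) > 1L && any(diff(score) > 1e-12)) {
    stop("prioritization scores must be non-increasing with rank", call. = FALSE)
  }
  structure(list(
    cell_id = as.character(cell_id),
    ranked = data.frame(rank = seq_along(drug_id),
                        drug_id = as.character(drug_id),
                        score = as.numeric(score),
                        stringsAsFactors = FALSE)
  ), class = "prioritization")
}

#' @export
print.prioritization <- function(x, n = 5L, ...) {
  cat(sprintf("<prioritization for cell %s: %d drugs>\n", x$cell_id, nrow(x$ranked)))
  print(utils::head(x$ranked, n))
  invisible(x)
}

#' Write a per-cell drug prioritization to CSV
#'
#' Columns `cell_id`, `rank`, `drug_id`, `score`; scores are written with
#' enough digits to round-trip.
#'
#' @param result A `prioritization` object.
#' @param path Output CSV path.
#' @export
write_prioritization <- function(result, path) {
  df <- data.frame(cell_id = rep(result$cell_id, nrow(result$ranked)),
                   result$ranked[, c("rank", "drug_id", "score")],
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    df <- data.frame(cell_id = character(), rank = integer(),
                     drug_id = character(), score = numeric())
  }
  df$score <- format(df$score, digits = 15, trim = TRUE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a prioritization written by [write_prioritization()]
#'
#' @param path CSV path.
#' @return A `prioritization` object (or a list of them if the file holds
#'   several cells).
#' @export
read_prioritization <- function(path) {
  df <- .read_csv(path)
  .require_columns(df, c("cell_id", "rank", "drug_id", "score"), path)
  cells <- unique(df$cell_id)
  out <- lapply(cells, function(cid) {
    sub <- df[df$cell_id == cid, , drop = FALSE]
    sub <- sub[order(sub$rank), , drop = FALSE]
    prioritization_result(cid, sub$drug_id, as.numeric(sub$score))
  })
  if (length(out) == 1L) out[[1L]] else out
}
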