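# Continuous effective score (CES) and the record-filtering cascade that
# turns raw fitted-curve tables into labeled drug-cell pairs.

#' Continuous effective score for a fitted dose-response curve
#'
#' Combines the three curve parameters that jointly describe how effective a
#' drug is against a cell line: the area under the viability curve (AUC,
#' lower = more sensitive), the curve's attainable lower viability limit, and
#' the half-maximal inhibitory concentration (IC50). The score is
#'
#' \deqn{CES = \log\frac{a + l + c}{2\,a\,l\,c}}
#'
#' with `a` = AUC, `l` = lower limit, `c` = IC50. It is symmetric in its
#' three arguments and strictly decreasing in each over the positive reals,
#' so smaller AUC / lower limit / IC50 (all signs of a potent, efficacious
#' drug) give a larger score. Vectorized over its arguments.
#'
#' @param auc Area under the viability curve (> 0).
#' @param lower_limit Minimum attainable viability fraction (> 0).
#' @param ic50 Half-maximal inhibitory concentration (> 0, native units).
#' @param base Logarithm base; natural log by default.
#' @param eps Positivity floor: arguments must exceed `eps`.
#' @return Numeric vector of scores; higher means more effective.
#' @export
compute_ces <- function(auc, lower_limit, ic50, base = exp(1), eps = 1e-12) {
  args <- list(auc = auc, lower_limit = lower_limit, ic50 = ic50)
  for (nm in names(args)) {
    v <- args[[nm]]
    if (any(!is.finite(v))) stop("non-finite ", nm, call. = FALSE)
    if (any(v <= eps)) {
      stop("domain error: ", nm, " must be > ", format(eps),
           " (got ", format(min(v)), ")", call. = FALSE)
    }
  }
  log((auc + lower_limit + ic50) / (2 * auc * lower_limit * ic50), base = base)
}

#' Binarize effective scores into drug-response labels
#'
#' Pairs whose score lands in the top decile of the score distribution are
#' labeled effective (1), the rest 0. Two threshold rules are available:
#' the empirical 90th-percentile quantile (linear interpolation; the
#' operative "top 10%" definition, and the default), or a normal
#' approximation `mu + z sigma` with `z = 1.28` so that ~10% of a normal
#' score distribution exceeds it. Scores equal to the threshold are labeled
#' effective (the threshold is closed on the effective side).
#'
#' @param ces Numeric vector of effective scores (>= 2 finite values).
#' @param method `"empirical_quantile"` or `"normal_approx"`.
#' @param quantile Quantile defining the label boundary (default 0.90).
#' @param z Normal multiplier used by `normal_approx` (default 1.28).
#' @return A list with `labels` (integer 0/1 vector) and `rule`, a
#'   `binarization_rule` carrying `mu`, `sigma`, `z`, `threshold`, `method`
#'   and `quantile`.
#' @export
binarize_scores <- function(ces, method = c("empirical_quantile", "normal_approx"),
                            quantile = 0.90, z = 1.28) {
  method <- match.arg(method)
  if (sum(is.finite(ces)) < 2L) stop("need >= 2 finite scores", call. = FALSE)
  if (any(!is.finite(ces))) stop("non-finite scores in input", call. = FALSE)
  mu <- mean(ces)
  sigma <- stats::sd(ces)
  threshold <- switch(method,
    empirical_quantile = stats::quantile(ces, probs = quantile, names = FALSE, type = 7),
    normal_approx = mu + z * sigma
  )
  labels <- as.integer(ces >= threshold)
  if (all(labels == 1L)) {
    warning("all scores at or above threshold; every pair labeled effective",
            call. = FALSE)
  }
  rule <- structure(list(mu = mu, sigma = sigma, z = z, threshold = threshold,
                         method = method, quantile = quantile),
                    class = "binarization_rule")
  list(labels = labels, rule = rule)
}

#' @export
print.binarization_rule <- function(x, ...) {
  cat(sprintf("<binarization_rule %s: threshold %.4f (mu %.4f, sigma %.4f)>\n",
              x$method, x$threshold, x$mu, x$sigma))
  invisible(x)
}

.filter_report <- function(stages, dropped) {
  structure(list(stages = stages, dropped = dropped), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report>\n")
  print(x$stages)
  invisible(x)
}

#' Write a filter report
#'
#' Stage counts go to `<path>` as CSV (`stage`, `n_in`, `n_out`); the
#' dropped-record log goes to `<path>.dropped.json`.
#'
#' @param report A `filter_report`.
#' @param path Output CSV path.
#' @export
write_filter_report <- function(report, path) {
  utils::write.csv(report$stages, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(report$dropped, paste0(path, ".dropped.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(path)
}

#' Quality-filter dose-response records
#'
#' Drops records, in order: (1) any of AUC / lower limit / IC50 missing;
#' (2) fitted lower limit below zero (a viability fraction cannot be
#' negative); (3) any score argument at or below the positivity floor,
#' where the effective score is undefined; (4) curve fit quality
#' `r2 < r2_min`. Stage counts telescope; the cascade is idempotent.
#'
#' @param records Data frame from [read_dose_response()].
#' @param r2_min Minimum curve-fit R-squared retained (default 0.7).
#' @param eps Positivity floor for score arguments.
#' @return List with `records` (retained rows, input order preserved) and
#'   `report` (a `filter_report`).
#' @export
filter_records <- function(records, r2_min = 0.7, eps = 1e-12) {
  drop_stage <- function(df, flag, stage, reason) {
    kept <- df[!flag, , drop = FALSE]
    dropped <- df[flag, c("drug_id", "cell_id", "screen_id"), drop = FALSE]
    if (nrow(dropped) > 0L) {
      dropped$stage <- stage
      dropped$reason <- reason
    } else {
      dropped$stage <- character(0)
      dropped$reason <- character(0)
    }
    list(kept = kept, dropped = dropped)
  }
  stages <- c("missing_values", "negative_lower_limit",
              "nonpositive_parameter", "low_r2")
  cur <- records
  stage_rows <- vector("list", length(stages))
  dropped_all <- vector("list", length(stages))
  for (i in seq_along(stages)) {
    flag <- switch(stages[i],
      missing_values = is.na(cur$auc) | is.na(cur$lower_limit) | is.na(cur$ic50),
      negative_lower_limit = cur$lower_limit < 0,
      nonpositive_parameter = cur$auc <= eps | cur$lower_limit <= eps | cur$ic50 <= eps,
      low_r2 = is.na(cur$r2) | cur$r2 < r2_min
    )
    res <- drop_stage(cur, flag, stages[i], switch(stages[i],
      missing_values = "missing AUC/lower limit/IC50",
      negative_lower_limit = "lower limit < 0",
      nonpositive_parameter = "score argument <= positivity floor",
      low_r2 = paste0("r2 < ", r2_min)))
    stage_rows[[i]] <- data.frame(stage = stages[i], n_in = nrow(cur),
                                  n_out = nrow(res$kept), stringsAsFactors = FALSE)
    dropped_all[[i]] <- res$dropped
    cur <- res$kept
  }
  list(records = cur,
       report = .filter_report(do.call(rbind, stage_rows),
                               do.call(rbind, dropped_all)))
}

#' Resolve duplicate screens of the same drug-cell pair
#'
#' When a (drug, cell) pair was screened more than once, keep the row from
#' the preferred screen if one exists (these screens are higher quality);
#' otherwise keep the duplicate with the highest curve-fit R-squared, ties
#' broken by first occurrence. Output preserves the original order of the
#' retained rows.
#'
#' @param records Data frame from [read_dose_response()].
#' @param preferred_screen Screen id retained outright (default `"MTS010"`).
#' @return Data frame with one row per (drug, cell) pair.
#' @export
resolve_duplicates <- function(records, preferred_screen = "MTS010") {
  if (nrow(records) == 0L) return(records)
  key <- paste(records$drug_id, records$cell_id, sep = "\r")
  pref <- records$screen_id == preferred_screen
  idx <- seq_len(nrow(records))
  r2 <- ifelse(is.na(records$r2), -Inf, records$r2)
  ord <- order(key, !pref, -r2, idx)
  keep_sorted <- !duplicated(key[ord])
  keep <- sort(idx[ord][keep_sorted])
  records[keep, , drop = FALSE]
}

#' Exclude withdrawn drugs and uninformative cell lines from labeled pairs
#'
#' After labeling, removes (1) all pairs of previously withdrawn drugs, and
#' all pairs of any cell line that (2) has fewer than `min_effective_frac`
#' of its screened drugs labeled effective, (3) has an unknown cancer type,
#' or (4) lacks an expression profile. The label threshold is *not*
#' recomputed afterwards.
#'
#' @param pairs Data frame with columns `drug_id`, `cell_id`, `ces`, `label`.
#' @param drugs Drug metadata data frame ([read_drugs()]).
#' @param cells Cell metadata data frame ([read_cells()]).
#' @param expression Expression matrix with cell ids as row names (used only
#'   to check profile availability); `NULL` skips the check.
#' @param min_effective_frac Minimum fraction of a cell's pairs labeled
#'   effective (default 0.01).
#' @return List with `pairs` (retained rows) and `report` (`filter_report`).
#' @export
exclude_entities <- function(pairs, drugs, cells, expression = NULL,
                             min_effective_frac = 0.01) {
  stages <- list()
  dropped <- list()
  log_stage <- function(df, flag, stage, reason) {
    d <- df[flag, c("drug_id", "cell_id"), drop = FALSE]
    if (nrow(d) > 0L) {
      d$stage <- stage
      d$reason <- reason
    } else {
      d$stage <- character(0)
      d$reason <- character(0)
    }
    stages[[length(stages) + 1L]] <<- data.frame(
      stage = stage, n_in = nrow(df), n_out = sum(!flag), stringsAsFactors = FALSE)
    dropped[[length(dropped) + 1L]] <<- d
    df[!flag, , drop = FALSE]
  }

  withdrawn_ids <- drugs$drug_id[drugs$withdrawn]
  cur <- log_stage(pairs, pairs$drug_id %in% withdrawn_ids,
                   "withdrawn_drugs", "drug previously withdrawn")

  eff <- tapply(cur$label, cur$cell_id, mean)
  low_cells <- names(eff)[eff < min_effective_frac]
  cur <- log_stage(cur, cur$cell_id %in% low_cells, "low_effective_cells",
                   paste0("cell effective fraction < ", min_effective_frac))

  unknown <- cells$cell_id[is.na(cells$cancer_type) |
                             cells$cancer_type %in% c("", "Unknown")]
  known_ids <- setdiff(cells$cell_id, unknown)
  cur <- log_stage(cur, !(cur$cell_id %in% known_ids), "unknown_cancer_cells",
                   "cancer type unknown or unlisted")

  if (!is.null(expression)) {
    cur <- log_stage(cur, !(cur$cell_id %in% rownames(expression)),
                     "no_expression_cells", "no expression profile")
  }
  list(pairs = cur,
       report = .filter_report(do.call(rbind, stages), do.call(rbind, dropped)))
}

#' Score, label and filter a raw dose-response table end to end
#'
#' Runs the full cascade: quality filters, duplicate resolution, effective
#' scoring, top-decile labeling, then entity exclusion. The label threshold
#' is computed on the pairs surviving the quality filters and is not
#' recomputed after entity exclusion.
#'
#' @inheritParams filter_records
#' @inheritParams exclude_entities
#' @inheritParams binarize_scores
#' @inheritParams resolve_duplicates
#' @param log_base Logarithm base for the effective score.
#' @return List with `pairs` (drug_id, cell_id, ces, label), `rule`
#'   (the `binarization_rule`), and `reports` (named list of
#'   `filter_report`s).
#' @export
score_pairs <- function(records, drugs, cells, expression = NULL,
                        r2_min = 0.7, preferred_screen = "MTS010",
                        method = "empirical_quantile", quantile = 0.90,
                        log_base = exp(1), min_effective_frac = 0.01) {
  filt <- filter_records(records, r2_min = r2_min)
  uniq <- resolve_duplicates(filt$records, preferred_screen = preferred_screen)
  ces <- compute_ces(uniq$auc, uniq$lower_limit, uniq$ic50, base = log_base)
  bin <- binarize_scores(ces, method = method, quantile = quantile)
  pairs <- data.frame(drug_id = uniq$drug_id, cell_id = uniq$cell_id,
                      ces = ces, label = bin$labels, stringsAsFactors = FALSE)
  excl <- exclude_entities(pairs, drugs, cells, expression = expression,
                           min_effective_frac = min_effective_frac)
  list(pairs = excl$pairs, rule = bin$rule,
       reports = list(quality = filt$report, exclusion = excl$report))
}
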