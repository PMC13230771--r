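#' Dataset completeness
#'
#' Fraction of possible single-amino-acid substitutions reported in a score
#' set: `completeness = reported variants / (scanned residues x 20)`, where
#' a scanned residue is a position with at least one reported variant and
#' the per-residue denominator 20 counts the 19 missense substitutions plus
#' Ter (the wild-type residue is excluded). Synonymous records do not count
#' toward the numerator; nonsense (Ter) records do. Values above 1 (e.g.
#' duplicate-heavy inputs) are reported raw and clamped only for bin
#' assignment.
#'
#' Datasets are assigned to one of eleven bins: ten half-open intervals
#' `[0.0, 0.1), ..., [0.9, 1.0)` plus a closed top bin for exactly complete
#' datasets (`completeness = 1`).
#'
#' @param score_set a `dms_score_set`.
#' @return Object of class `dms_completeness`: list with `n_variants`,
#'   `n_residues`, `completeness`, `bin` (label), `bin_lo`, `bin_hi`.
#' @export
completeness <- function(score_set) {
  rec <- score_set$records
  rec <- rec[rec$type != "synonymous", , drop = FALSE]
  scanned <- unique(score_set$records$position)
  if (!length(scanned)) stop("no scanned residues in score set")
  n_var <- nrow(unique(rec[, c("position", "wt_aa", "var_aa")]))
  comp <- n_var / (length(scanned) * 20)
  bin <- completeness_bin(comp)
  structure(
    list(n_variants = n_var, n_residues = length(scanned),
         completeness = comp, bin = bin$label, bin_lo = bin$lo,
         bin_hi = bin$hi),
    class = "dms_completeness"
  )
}

# eleven bins over [0, 1]: [0,0.1), ..., [0.9,1), and {1} for exactly
# complete maps; completeness > 1 is clamped into the top bin
completeness_bin <- function(comp) {
  c_clamped <- min(max(comp, 0), 1)
  if (c_clamped >= 1) {
    return(list(label = "[1.0,1.0]", lo = 1, hi = 1))
  }
  lo <- floor(c_clamped * 10) / 10
  hi <- lo + 0.1
  list(label = sprintf("[%.1f,%.1f)", lo, hi), lo = lo, hi = hi)
}

#' @export
print.dms_completeness <- function(x, ...) {
  cat(sprintf(
    "completeness: %.4f (%d variants over %d scanned residues; bin %s)\n",
    x$completeness, x$n_variants, x$n_residues, x$bin))
  invisible(x)
}

fixed_test_rows <- function(rec, holdout, seed) {
  n_test <- max(1L, round(holdout * nrow(rec)))
  n_test <- min(n_test, nrow(rec) - 1L)
  with_seed(seed, sort(sample.int(nrow(rec), n_test)))
}

#' Imputation accuracy as a function of dataset completeness
#'
#' For each score set, 10% of missense variants are held out once as a fixed
#' test set (identical across fractions and imputers for a given seed); the
#' remaining variants are subsampled at each training fraction, every
#' imputer is refitted on the subsample -- positional means and any other
#' data-derived features are recomputed from the subsample only -- and the
#' Pearson correlation on the fixed test set is recorded. The summary
#' statistic is the median across score sets.
#'
#' @param score_sets list of normalized `dms_score_set` objects.
#' @param imputers named list of imputer factories (see
#'   [imputer_factories]).
#' @param fractions training fractions in (0, 1] (default 0.1 to 0.9).
#' @param holdout fixed test fraction (default 0.10).
#' @param seed master seed; per-(dataset, fraction) subsampling seeds are
#'   derived from it.
#' @param provider embedding provider forwarded to model imputers.
#' @return List with `per_dataset` (model, fraction, protein, pearson, n)
#'   and `summary` (model, fraction, median_pearson).
#' @export
subsampling_curve <- function(score_sets, imputers,
                              fractions = seq(0.1, 0.9, by = 0.1),
                              holdout = 0.10, seed = 1L, provider = NULL) {
  stopifnot(all(fractions > 0), all(fractions <= 1),
            length(names(imputers)) == length(imputers))
  if (inherits(score_sets, "dms_score_set")) score_sets <- list(score_sets)
  rows <- list()
  for (si in seq_along(score_sets)) {
    set <- score_sets[[si]]
    rec <- model_records(set)
    test_rows <- fixed_test_rows(rec, holdout, derive_seed(seed, si))
    pool <- setdiff(seq_len(nrow(rec)), test_rows)
    test_rec <- rec[test_rows, , drop = FALSE]
    for (fi in seq_along(fractions)) {
      f <- fractions[fi]
      n_train <- round(f * length(pool))
      if (n_train < 1L) {
        warning("fraction ", f, " yields an empty training set for ",
                set$protein_id, "; skipped")
        next
      }
      train_rows <- with_seed(derive_seed(seed, si * 1000L + fi),
                              sample(pool, n_train))
      train_rec <- rec[train_rows, , drop = FALSE]
      context <- list(score_sets = list(set), provider = provider)
      for (nm in names(imputers)) {
        pred_fun <- imputers[[nm]](train_rec, context)
        pred <- pred_fun(test_rec[, c("protein_id", "position", "wt_aa",
                                      "var_aa")])
        met <- evaluate_predictions(pred, test_rec$norm_score)
        rows[[length(rows) + 1L]] <- data.frame(
          model = nm, fraction = f, protein_id = set$protein_id,
          pearson = met$pearson_r, n = met$n)
      }
    }
  }
  per_dataset <- do.call(rbind, rows)
  if (is.null(per_dataset)) {
    empty <- data.frame(model = character(), fraction = numeric(),
                        median_pearson = numeric())
    return(list(per_dataset = data.frame(), summary = empty))
  }
  summary <- stats::aggregate(pearson ~ model + fraction, per_dataset,
                              stats::median)
  names(summary)[names(summary) == "pearson"] <- "median_pearson"
  list(per_dataset = per_dataset,
       summary = summary[order(summary$model, summary$fraction), ])
}

#' Imputation accuracy under a per-position measurement budget
#'
#' For each budget `N`, at most `N` randomly chosen substitutions per
#' position are kept as training data (all, when fewer are available); all
#' remaining variants form the test side. Positional means are recomputed
#' from the kept substitutions only. Budgets whose test side is empty are
#' skipped with a warning. The summary is the median Pearson correlation
#' across score sets.
#'
#' @param score_sets list of normalized `dms_score_set` objects.
#' @param imputers named list of imputer factories.
#' @param budgets integer mutations-per-position budgets (default 1--20).
#' @param seed master seed.
#' @param provider embedding provider for model imputers.
#' @return List with `per_dataset` and `summary` data.frames.
#' @export
position_budget_curve <- function(score_sets, imputers, budgets = 1:20,
                                  seed = 1L, provider = NULL) {
  stopifnot(all(budgets >= 1L))
  if (inherits(score_sets, "dms_score_set")) score_sets <- list(score_sets)
  rows <- list()
  for (si in seq_along(score_sets)) {
    set <- score_sets[[si]]
    rec <- model_records(set)
    for (bi in seq_along(budgets)) {
      n_keep <- budgets[bi]
      keep <- integer()
      with_seed(derive_seed(seed, si * 10000L + bi), {
        for (pos in unique(rec$position)) {
          rows_pos <- which(rec$position == pos)
          k <- min(n_keep, length(rows_pos))
          keep <- c(keep, if (k == length(rows_pos)) rows_pos else
            sample(rows_pos, k))
        }
      })
      test_rows <- setdiff(seq_len(nrow(rec)), keep)
      if (!length(test_rows)) {
        warning("budget N = ", n_keep, " leaves no test variants for ",
                set$protein_id, "; skipped")
        next
      }
      train_rec <- rec[keep, , drop = FALSE]
      test_rec <- rec[test_rows, , drop = FALSE]
      context <- list(score_sets = list(set), provider = provider)
      for (nm in names(imputers)) {
        pred_fun <- imputers[[nm]](train_rec, context)
        pred <- pred_fun(test_rec[, c("protein_id", "position", "wt_aa",
                                      "var_aa")])
        met <- evaluate_predictions(pred, test_rec$norm_score)
        rows[[length(rows) + 1L]] <- data.frame(
          model = nm, N = n_keep, protein_id = set$protein_id,
          pearson = met$pearson_r, n = met$n)
      }
    }
  }
  per_dataset <- do.call(rbind, rows)
  if (is.null(per_dataset)) {
    empty <- data.frame(model = character(), N = integer(),
                        median_pearson = numeric())
    return(list(per_dataset = data.frame(), summary = empty))
  }
  summary <- stats::aggregate(pearson ~ model + N, per_dataset,
                              stats::median)
  names(summary)[names(summary) == "pearson"] <- "median_pearson"
  list(per_dataset = per_dataset,
       summary = summary[order(summary$model, summary$N), ])
}
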