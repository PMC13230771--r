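#' Run an end-to-end evaluation protocol
#'
#' For each partition produced by the chosen split strategy: positional
#' means are computed from the training side only, feature tables are
#' assembled for both sides with that map, the gradient-boosted imputer is
#' trained on the training side and scored on the test side. No test-side
#' record ever contributes to the positional means or to a training row.
#' Hyperparameters are either supplied (one fixed set for the whole run,
#' the default) or tuned once on the first partition's training side when
#' `tune = TRUE`.
#'
#' @param score_sets a normalized `dms_score_set` or list of them.
#' @param strategy one of [split_strategies()].
#' @param preset feature preset, see [feature_presets()].
#' @param provider embedding provider (for presets that need one).
#' @param params a `dms_hyperparams` object used for every partition.
#' @param tune tune hyperparameters (on the first partition) instead?
#' @param n_trials tuning budget when `tune = TRUE`.
#' @param strategy_params passed to [make_partition()].
#' @param seed integer master seed.
#' @param conservation optional conservation table, see
#'   [assemble_feature_table()].
#' @return Object of class `dms_protocol_result`: list with
#'   `per_partition` (one metrics row per partition), `predictions`
#'   (pooled test-side keys, observed and predicted scores with a partition
#'   index), `pooled` (metrics over all pooled predictions), `summary`
#'   (median and IQR of the per-partition metrics) and the run
#'   configuration.
#' @export
run_protocol <- function(score_sets, strategy, preset = "full_minus_diff",
                         provider = NULL, params = dms_hyperparams(),
                         tune = FALSE, n_trials = 20L,
                         strategy_params = list(), seed = 1L,
                         conservation = NULL) {
  if (inherits(score_sets, "dms_score_set")) score_sets <- list(score_sets)
  rec <- model_records(score_sets)
  parts <- make_partition(rec, strategy, strategy_params, seed)
  if (inherits(parts, "dms_partition")) parts <- list(parts)

  assemble <- function(records, pm) {
    sets <- records_as_sets(records, score_sets)
    assemble_feature_table(sets, preset = preset, provider = provider,
                           positional_means = pm,
                           conservation = conservation)
  }

  if (tune) {
    first_train <- rec[parts[[1L]]$train, , drop = FALSE]
    pm0 <- compute_positional_means(first_train)
    params <- tune_dms_hyperparams(assemble(first_train, pm0),
                                   n_trials = n_trials, seed = seed)
  }

  metric_rows <- list()
  pred_rows <- list()
  for (pi in seq_along(parts)) {
    p <- parts[[pi]]
    train_rec <- rec[p$train, , drop = FALSE]
    test_rec <- rec[p$test, , drop = FALSE]
    pm <- compute_positional_means(train_rec)
    fit <- dms_imputer(assemble(train_rec, pm), params = params,
                       seed = derive_seed(seed, pi),
                       positional_means = pm)
    pred <- predict(fit, assemble(test_rec, pm))
    met <- if (nrow(test_rec) >= 2L) {
      suppressWarnings(evaluate_predictions(pred, test_rec$norm_score))
    } else {
      data.frame(rmse = abs(pred - test_rec$norm_score),
                 mae = abs(pred - test_rec$norm_score),
                 r2 = NA_real_, pearson_r = NA_real_, n = 1L)
    }
    met$partition <- pi
    metric_rows[[pi]] <- met
    pred_rows[[pi]] <- data.frame(
      partition = pi, test_rec[, c("protein_id", "position", "wt_aa",
                                   "var_aa")],
      observed = test_rec$norm_score, predicted = pred,
      stringsAsFactors = FALSE)
  }
  per_partition <- do.call(rbind, metric_rows)
  predictions <- do.call(rbind, pred_rows)
  pooled <- suppressWarnings(
    evaluate_predictions(predictions$predicted, predictions$observed))
  num <- c("rmse", "mae", "r2", "pearson_r")
  summary <- do.call(rbind, lapply(num, function(m) {
    v <- per_partition[[m]]
    data.frame(metric = m,
               median = stats::median(v, na.rm = TRUE),
               q25 = unname(stats::quantile(v, 0.25, na.rm = TRUE)),
               q75 = unname(stats::quantile(v, 0.75, na.rm = TRUE)))
  }))
  structure(
    list(per_partition = per_partition, predictions = predictions,
         pooled = pooled, summary = summary,
         config = list(strategy = strategy, preset = preset,
                       strategy_params = strategy_params, seed = seed,
                       tuned = tune, params = params,
                       n_partitions = length(parts))),
    class = "dms_protocol_result"
  )
}

#' @export
print.dms_protocol_result <- function(x, ...) {
  cat(sprintf("protocol run: strategy '%s', preset '%s', %d partition%s\n",
              x$config$strategy, x$config$preset, x$config$n_partitions,
              if (x$config$n_partitions == 1L) "" else "s"))
  cat(sprintf("  pooled: rmse %.4f, mae %.4f, r2 %s, pearson %s (n = %d)\n",
              x$pooled$rmse, x$pooled$mae, format(round(x$pooled$r2, 4)),
              format(round(x$pooled$pearson_r, 4)), x$pooled$n))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Write protocol results as tidy tables plus a manifest
#'
#' One row per (partition, metric) in `metrics.tsv`, the pooled test-side
#' predictions in `predictions.tsv`, and a JSON manifest recording the
#' strategy, preset, seed and hyperparameters.
#'
#' @param result a `dms_protocol_result`.
#' @param dir output directory.
#' @export
write_protocol_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pp <- result$per_partition
  tidy <- do.call(rbind, lapply(c("rmse", "mae", "r2", "pearson_r"),
                                function(m) {
    data.frame(partition = pp$partition, metric = m, value = pp[[m]],
               n = pp$n)
  }))
  utils::write.table(tidy, file.path(dir, "metrics.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.table(result$predictions,
                     file.path(dir, "predictions.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    c(result$config[c("strategy", "preset", "seed", "tuned",
                      "n_partitions")],
      list(params = unclass(result$config$params),
           strategy_params = result$config$strategy_params)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
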