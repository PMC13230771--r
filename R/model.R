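#' Gradient-boosting hyperparameters
#'
#' Container for the boosted-tree hyperparameters used by [dms_imputer()].
#' Defaults are conservative settings for medium-sized tabular data; tuned
#' values come from [tune_dms_hyperparams()].
#'
#' @param learning_rate shrinkage per boosting round (> 0).
#' @param max_depth maximum tree depth.
#' @param num_leaves maximum leaves per tree (leaf-wise growth), >= 2.
#' @param subsample row-subsample fraction per round, in (0, 1].
#' @param colsample feature-subsample fraction per tree, in (0, 1].
#' @param reg_alpha,reg_lambda L1/L2 regularization (>= 0).
#' @param nrounds maximum boosting rounds (capped at 1000 by default).
#' @param early_stopping consecutive non-improving rounds before stopping;
#'   `Inf` disables early stopping.
#' @return Object of class `dms_hyperparams`.
#' @export
dms_hyperparams <- function(learning_rate = 0.05, max_depth = 8L,
                            num_leaves = 31L, subsample = 0.8,
                            colsample = 0.8, reg_alpha = 1e-3,
                            reg_lambda = 1e-3, nrounds = 1000L,
                            early_stopping = 50L) {
  if (is.null(early_stopping) || is.na(early_stopping)) {
    early_stopping <- Inf
  }
  stopifnot(learning_rate > 0, num_leaves >= 2L, max_depth >= 1L,
            subsample > 0, subsample <= 1, colsample > 0, colsample <= 1,
            reg_alpha >= 0, reg_lambda >= 0, nrounds >= 1L)
  structure(
    list(learning_rate = learning_rate, max_depth = as.integer(max_depth),
         num_leaves = as.integer(num_leaves), subsample = subsample,
         colsample = colsample, reg_alpha = reg_alpha,
         reg_lambda = reg_lambda, nrounds = as.integer(min(nrounds, 1000L)),
         early_stopping = early_stopping),
    class = "dms_hyperparams"
  )
}

#' @export
print.dms_hyperparams <- function(x, ...) {
  cat("boosted-tree hyperparameters:\n")
  for (nm in names(x)) cat(sprintf("  %-14s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

xgb_params <- function(params, seed) {
  xgboost::xgb.params(
    objective = "reg:squarederror",
    eta = params$learning_rate,
    max_depth = params$max_depth,
    max_leaves = params$num_leaves,
    tree_method = "hist",
    grow_policy = "lossguide",
    subsample = params$subsample,
    colsample_bytree = params$colsample,
    reg_alpha = params$reg_alpha,
    reg_lambda = params$reg_lambda,
    seed = as.integer(seed),
    nthread = 1L
  )
}

train_booster <- function(x_train, y_train, x_val, y_val, params, seed) {
  dtr <- xgboost::xgb.DMatrix(x_train, label = y_train, nthread = 1L)
  evals <- list()
  esr <- NULL
  if (!is.null(x_val) && nrow(x_val) > 0L) {
    evals <- list(val = xgboost::xgb.DMatrix(x_val, label = y_val,
                                             nthread = 1L))
    if (is.finite(params$early_stopping)) {
      esr <- as.integer(params$early_stopping)
    }
  }
  booster <- xgboost::xgb.train(
    params = xgb_params(params, seed), data = dtr,
    nrounds = params$nrounds, evals = evals,
    early_stopping_rounds = esr, verbose = 0
  )
  best <- xgboost::xgb.attr(booster, "best_iteration")
  best_score <- xgboost::xgb.attr(booster, "best_score")
  list(booster = booster,
       best_iteration = if (is.null(best)) params$nrounds
                        else as.integer(best),
       val_rmse = if (is.null(best_score)) NA_real_
                  else as.numeric(best_score))
}

# group-aware (whole proteins) or random 90/10 row split for early stopping
holdout_split <- function(group, valid_fraction, seed) {
  n <- length(group)
  groups <- unique(group)
  with_seed(seed, {
    if (length(groups) > 1L) {
      n_val <- max(1L, floor(valid_fraction * length(groups)))
      n_val <- min(n_val, length(groups) - 1L)
      val_groups <- sample(groups, n_val)
      val <- which(group %in% val_groups)
    } else {
      n_val <- max(1L, floor(valid_fraction * n))
      n_val <- min(n_val, n - 1L)
      val <- sample.int(n, n_val)
    }
    list(train = setdiff(seq_len(n), val), val = val)
  })
}

#' Fit a gradient-boosted DMS score imputer
#'
#' The central model-fitting function: trains a gradient-boosted tree
#' ensemble (leaf-wise growth, squared-error objective) on a feature table,
#' using an internal validation split for early stopping -- group-aware by
#' protein when the table spans more than one protein, random otherwise. The
#' fitted object stores the exact feature schema and the positional-mean map
#' it was trained with, and refuses prediction on tables with a different
#' schema.
#'
#' @param table a `dms_feature_table` (see [assemble_feature_table()]).
#' @param params a `dms_hyperparams` object.
#' @param seed integer seed controlling the validation split and training
#'   stochasticity; fits are bit-reproducible given the same seed and inputs.
#' @param positional_means the training-side positional-mean map (stored for
#'   later feature assembly at prediction time; optional).
#' @param valid_fraction fraction of proteins (or rows) held out internally
#'   for early stopping.
#' @return Object of class `dms_imputer` with `predict`, `print`, `summary`
#'   and `residuals` methods.
#' @export
dms_imputer <- function(table, params = dms_hyperparams(), seed = 1L,
                        positional_means = NULL, valid_fraction = 0.1) {
  stopifnot(inherits(table, "dms_feature_table"))
  if (!inherits(params, "dms_hyperparams")) {
    params <- do.call(dms_hyperparams, as.list(params))
  }
  if (!nrow(table$x)) stop("empty feature table")
  if (any(!is.finite(table$y))) {
    bad <- table$keys[!is.finite(table$y), , drop = FALSE]
    stop("non-finite target values for variant(s): ",
         paste(utils::head(variant_id(bad$protein_id, bad$position,
                                      bad$wt_aa, bad$var_aa), 5L),
               collapse = ", "))
  }
  split <- holdout_split(table$group, valid_fraction, seed)
  fit <- train_booster(table$x[split$train, , drop = FALSE],
                       table$y[split$train],
                       table$x[split$val, , drop = FALSE],
                       table$y[split$val], params, seed)
  fitted_all <- predict(fit$booster,
                        xgboost::xgb.DMatrix(table$x, nthread = 1L))
  structure(
    list(booster_raw = xgboost::xgb.save.raw(fit$booster),
         schema = table$schema, preset = table$preset,
         params = params, seed = as.integer(seed),
         positional_means = positional_means,
         best_iteration = fit$best_iteration,
         val_rmse = fit$val_rmse,
         n_train = length(split$train), n_val = length(split$val),
         n_features = ncol(table$x),
         train_groups = unique(table$group),
         fitted = fitted_all, y = table$y),
    class = "dms_imputer"
  )
}

imputer_booster <- function(object) {
  xgboost::xgb.load.raw(object$booster_raw)
}

#' Predict normalized scores for new variants
#'
#' @param object a fitted `dms_imputer`.
#' @param table a `dms_feature_table` whose schema matches the one the model
#'   was trained with (missing-capable columns may be `NA`).
#' @param ... unused.
#' @return Numeric vector of predicted normalized scores, one per row;
#'   predictions are not clipped to `[0, 1]`.
#' @export
predict.dms_imputer <- function(object, table, ...) {
  stopifnot(inherits(table, "dms_feature_table"))
  if (!identical(object$schema, table$schema)) {
    n <- max(length(object$schema), length(table$schema))
    a <- c(object$schema, rep("<absent>", n - length(object$schema)))
    b <- c(table$schema, rep("<absent>", n - length(table$schema)))
    first <- which(a != b)[1L]
    stop("feature schema mismatch (first differing column: expected '",
         a[first], "', got '", b[first], "')")
  }
  if (!nrow(table$x)) return(numeric(0))
  predict(imputer_booster(object),
          xgboost::xgb.DMatrix(table$x, nthread = 1L))
}

#' @export
print.dms_imputer <- function(x, ...) {
  cat("gradient-boosted DMS imputer\n")
  cat(sprintf("  preset '%s', %d features, %d training rows (%d proteins)\n",
              x$preset, x$n_features, x$n_train, length(x$train_groups)))
  cat(sprintf("  boosting rounds used: %d (cap %d); validation RMSE %.4f\n",
              x$best_iteration, x$params$nrounds, x$val_rmse))
  invisible(x)
}

#' @export
summary.dms_imputer <- function(object, ...) {
  res <- object$y - object$fitted
  out <- list(
    preset = object$preset, n_features = object$n_features,
    n_train = object$n_train, n_val = object$n_val,
    n_proteins = length(object$train_groups),
    best_iteration = object$best_iteration, val_rmse = object$val_rmse,
    train_rmse = sqrt(mean(res^2)), params = object$params
  )
  class(out) <- "summary.dms_imputer"
  out
}

#' @export
print.summary.dms_imputer <- function(x, ...) {
  cat("gradient-boosted DMS imputer\n")
  cat(sprintf("  preset: %s; features: %d; training rows: %d (%d proteins)\n",
              x$preset, x$n_features, x$n_train, x$n_proteins))
  cat(sprintf("  rounds: %d; in-sample RMSE: %.4f; validation RMSE: %.4f\n",
              x$best_iteration, x$train_rmse, x$val_rmse))
  print(x$params)
  invisible(x)
}

#' @export
residuals.dms_imputer <- function(object, ...) {
  object$y - object$fitted
}

#' Persist a fitted imputer to a directory
#'
#' Writes the serialized ensemble, a schema manifest (JSON), the stored
#' positional-mean map (TSV) and training metadata (JSON). The round trip
#' through [load_imputer()] yields bit-identical predictions.
#'
#' @param object a `dms_imputer`.
#' @param dir output directory (created if needed).
#' @export
save_imputer <- function(object, dir) {
  stopifnot(inherits(object, "dms_imputer"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  xgboost::xgb.save(imputer_booster(object),
                    file.path(dir, "ensemble.ubj"))
  jsonlite::write_json(
    list(schema = object$schema, preset = object$preset,
         n_features = object$n_features),
    file.path(dir, "schema.json"), auto_unbox = TRUE, digits = NA
  )
  jsonlite::write_json(
    list(seed = object$seed, params = unclass(object$params),
         best_iteration = object$best_iteration,
         val_rmse = object$val_rmse, n_train = object$n_train,
         n_val = object$n_val, train_groups = object$train_groups),
    file.path(dir, "metadata.json"), auto_unbox = TRUE, digits = NA
  )
  pm <- object$positional_means
  if (!is.null(pm)) {
    utils::write.table(as.data.frame(pm),
                       file.path(dir, "positional_means.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' Load a fitted imputer saved with [save_imputer()]
#'
#' @param dir directory written by [save_imputer()].
#' @return A `dms_imputer` (without the stored training fit diagnostics).
#' @export
load_imputer <- function(dir) {
  booster <- xgboost::xgb.load(file.path(dir, "ensemble.ubj"))
  schema <- jsonlite::read_json(file.path(dir, "schema.json"),
                                simplifyVector = TRUE)
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  pm_path <- file.path(dir, "positional_means.tsv")
  pm <- NULL
  if (file.exists(pm_path)) {
    pm <- utils::read.delim(pm_path, stringsAsFactors = FALSE)
    class(pm) <- c("dms_positional_means", "data.frame")
  }
  structure(
    list(booster_raw = xgboost::xgb.save.raw(booster),
         schema = schema$schema, preset = schema$preset,
         params = do.call(dms_hyperparams, as.list(meta$params)),
         seed = meta$seed, positional_means = pm,
         best_iteration = meta$best_iteration, val_rmse = meta$val_rmse,
         n_train = meta$n_train, n_val = meta$n_val,
         n_features = schema$n_features,
         train_groups = meta$train_groups,
         fitted = NULL, y = NULL),
    class = "dms_imputer"
  )
}
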