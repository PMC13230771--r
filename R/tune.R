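#' Group-aware k-fold assignment
#'
#' Assigns whole proteins to folds so that no protein spans the training and
#' validation side of any fold.
#'
#' @param group character vector of protein ids, one per row.
#' @param n_folds requested fold count; reduced (with a warning) when there
#'   are fewer groups than folds.
#' @param seed integer seed.
#' @return Integer vector of fold ids, one per row.
#' @export
group_kfold <- function(group, n_folds = 5L, seed = 1L) {
  groups <- unique(group)
  if (length(groups) < 2L) {
    stop("group-aware cross-validation requires at least 2 protein groups")
  }
  if (length(groups) < n_folds) {
    warning("fewer groups (", length(groups), ") than folds (", n_folds,
            "); using ", length(groups), " folds")
    n_folds <- length(groups)
  }
  with_seed(seed, {
    shuffled <- sample(groups)
    fold_of_group <- stats::setNames(
      rep_len(seq_len(n_folds), length(groups)), shuffled)
    unname(fold_of_group[group])
  })
}

# hyperparameter search space: standard ranges for boosted trees on tabular
# data (the search dimensions mirror the model's tunable parameters)
tpe_search_space <- function() {
  list(
    learning_rate = list(type = "loguniform", lo = 1e-3, hi = 0.3),
    max_depth = list(type = "int", lo = 3L, hi = 12L),
    num_leaves = list(type = "int", lo = 16L, hi = 256L),
    subsample = list(type = "uniform", lo = 0.5, hi = 1.0),
    colsample = list(type = "uniform", lo = 0.5, hi = 1.0),
    reg_alpha = list(type = "loguniform", lo = 1e-8, hi = 10),
    reg_lambda = list(type = "loguniform", lo = 1e-8, hi = 10)
  )
}

tpe_to_internal <- function(value, dim) {
  switch(dim$type,
         loguniform = log(value),
         int = as.numeric(value),
         uniform = value)
}

tpe_from_internal <- function(z, dim) {
  switch(dim$type,
         loguniform = exp(pmin(pmax(z, log(dim$lo)), log(dim$hi))),
         int = as.integer(round(pmin(pmax(z, dim$lo), dim$hi))),
         uniform = pmin(pmax(z, dim$lo), dim$hi))
}

tpe_random_draw <- function(dim) {
  switch(dim$type,
         loguniform = exp(stats::runif(1, log(dim$lo), log(dim$hi))),
         int = sample(seq.int(dim$lo, dim$hi), 1L),
         uniform = stats::runif(1, dim$lo, dim$hi))
}

# Gaussian kernel density of observations zs (internal scale) at points z
tpe_log_density <- function(z, zs, dim) {
  span <- switch(dim$type,
                 loguniform = log(dim$hi) - log(dim$lo),
                 as.numeric(dim$hi - dim$lo))
  bw <- max(stats::sd(zs), span / max(length(zs), 2), 1e-6)
  dens <- vapply(z, function(zz) {
    mean(stats::dnorm(zz, mean = zs, sd = bw))
  }, 0)
  log(pmax(dens, 1e-300))
}

# one TPE suggestion from the trial history (independent per-dimension
# kernel-density models of the good and bad trials, candidate scored by the
# density ratio l/g)
tpe_suggest <- function(history, losses, space, n_candidates = 24L,
                        gamma = 0.25) {
  n <- length(losses)
  n_good <- max(1L, ceiling(gamma * n))
  ord <- order(losses)
  good <- ord[seq_len(n_good)]
  bad <- ord[-seq_len(n_good)]
  if (!length(bad)) bad <- ord  # degenerate tiny history
  cand <- vector("list", n_candidates)
  score <- numeric(n_candidates)
  for (k in seq_len(n_candidates)) {
    params <- list()
    s <- 0
    for (nm in names(space)) {
      dim <- space[[nm]]
      zg <- vapply(good, function(i) tpe_to_internal(history[[i]][[nm]], dim),
                   0)
      zb <- vapply(bad, function(i) tpe_to_internal(history[[i]][[nm]], dim),
                   0)
      span <- switch(dim$type,
                     loguniform = log(dim$hi) - log(dim$lo),
                     as.numeric(dim$hi - dim$lo))
      bw <- max(stats::sd(zg), span / max(length(zg), 2), 1e-6)
      z <- stats::rnorm(1, mean = zg[sample.int(length(zg), 1L)], sd = bw)
      value <- tpe_from_internal(z, dim)
      z_used <- tpe_to_internal(value, dim)
      s <- s + tpe_log_density(z_used, zg, dim) -
        tpe_log_density(z_used, zb, dim)
      params[[nm]] <- value
    }
    cand[[k]] <- params
    score[k] <- s
  }
  cand[[which.max(score)]]
}

cv_rmse <- function(table, params, fold_id, seed) {
  rmses <- vapply(sort(unique(fold_id)), function(f) {
    tr <- which(fold_id != f)
    va <- which(fold_id == f)
    fit <- train_booster(table$x[tr, , drop = FALSE], table$y[tr],
                         table$x[va, , drop = FALSE], table$y[va],
                         params, seed)
    pred <- predict(fit$booster,
                    xgboost::xgb.DMatrix(table$x[va, , drop = FALSE],
                                         nthread = 1L))
    sqrt(mean((pred - table$y[va])^2))
  }, 0)
  mean(rmses)
}

#' Tune hyperparameters by Bayesian (TPE) search over group-aware CV
#'
#' Minimizes the mean validation RMSE over group-aware k-fold
#' cross-validation (folds are whole proteins, so no protein spans train and
#' validation). The sampler is a tree-structured Parzen estimator: after a
#' random start-up phase, trials are split into "good" and "bad" by RMSE
#' quantile, each modelled by per-dimension kernel densities, and the next
#' configuration maximizes the good/bad density ratio. Each trial trains
#' with the usual round cap and early stopping on the fold's validation
#' side. Deterministic given `seed`.
#'
#' @param table a `dms_feature_table` spanning >= 2 proteins.
#' @param n_trials number of search trials (>= 1).
#' @param seed integer seed.
#' @param n_folds fold count (reduced to the group count if needed).
#' @param nrounds,early_stopping round cap and patience used in every trial.
#' @return The best trial's `dms_hyperparams`, with attributes
#'   `"cv_rmse"` (its mean CV RMSE) and `"trials"` (a data.frame of all
#'   trials).
#' @export
tune_dms_hyperparams <- function(table, n_trials = 50L, seed = 1L,
                                 n_folds = 5L, nrounds = 1000L,
                                 early_stopping = 50L) {
  stopifnot(inherits(table, "dms_feature_table"), n_trials >= 1L)
  fold_id <- group_kfold(table$group, n_folds, seed)
  space <- tpe_search_space()
  n_startup <- min(max(5L, ceiling(n_trials / 4)), n_trials)
  history <- vector("list", n_trials)
  losses <- numeric(n_trials)
  defaults <- dms_hyperparams()
  with_seed(derive_seed(seed, 77L), {
    for (i in seq_len(n_trials)) {
      sampled <- if (i == 1L) {
        # the documented default configuration is always evaluated first,
        # so the search can only improve on it
        defaults[names(space)]
      } else if (i <= n_startup) {
        stats::setNames(lapply(space, tpe_random_draw), names(space))
      } else {
        tpe_suggest(history[seq_len(i - 1L)], losses[seq_len(i - 1L)], space)
      }
      params <- dms_hyperparams(
        learning_rate = sampled$learning_rate,
        max_depth = sampled$max_depth, num_leaves = sampled$num_leaves,
        subsample = sampled$subsample, colsample = sampled$colsample,
        reg_alpha = sampled$reg_alpha, reg_lambda = sampled$reg_lambda,
        nrounds = nrounds, early_stopping = early_stopping
      )
      history[[i]] <- sampled
      losses[i] <- cv_rmse(table, params, fold_id, derive_seed(seed, i))
    }
  })
  best <- which.min(losses)
  out <- dms_hyperparams(
    learning_rate = history[[best]]$learning_rate,
    max_depth = history[[best]]$max_depth,
    num_leaves = history[[best]]$num_leaves,
    subsample = history[[best]]$subsample,
    colsample = history[[best]]$colsample,
    reg_alpha = history[[best]]$reg_alpha,
    reg_lambda = history[[best]]$reg_lambda,
    nrounds = nrounds, early_stopping = early_stopping
  )
  trials <- cbind(do.call(rbind, lapply(history, as.data.frame)),
                  cv_rmse = losses)
  attr(out, "cv_rmse") <- losses[best]
  attr(out, "trials") <- trials
  out
}
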