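#' Regression metrics for imputed scores
#'
#' Standard definitions: RMSE, MAE, coefficient of determination
#' `R2 = 1 - SS_res / SS_tot`, and the Pearson correlation. When the
#' observed values have zero variance, the correlation is undefined and
#' reported as `NA` with a warning (never silently as 0); `R2` is likewise
#' `NA` in that case.
#'
#' @param predicted,observed equal-length numeric vectors (length >= 1 for
#'   the error metrics; correlation needs >= 2).
#' @return A one-row data.frame with columns `rmse`, `mae`, `r2`,
#'   `pearson_r`, `n`.
#' @export
evaluate_predictions <- function(predicted, observed) {
  stopifnot(length(predicted) == length(observed), length(observed) >= 1L)
  err <- predicted - observed
  rmse <- sqrt(mean(err^2))
  mae <- mean(abs(err))
  ss_tot <- sum((observed - mean(observed))^2)
  if (length(observed) < 2L || ss_tot == 0) {
    if (ss_tot == 0 && length(observed) >= 2L) {
      warning("observed values have zero variance; ",
              "correlation and R2 undefined")
    }
    r2 <- NA_real_
    r <- NA_real_
  } else {
    r2 <- 1 - sum(err^2) / ss_tot
    r <- if (stats::sd(predicted) == 0) {
      NA_real_
    } else {
      stats::cor(predicted, observed)
    }
  }
  data.frame(rmse = rmse, mae = mae, r2 = r2, pearson_r = r,
             n = length(observed))
}

#' RMSE in quantile-based bins
#'
#' Bins points by quantiles of either the observed or the predicted scores
#' and reports the per-bin RMSE -- revealing how error varies across the
#' effect spectrum (binned by observed) or model calibration (binned by
#' predicted). Tied quantile edges are merged, so fewer than `n_bins` bins
#' may be returned; reported edges are the actual ones used.
#'
#' @param predicted,observed equal-length numeric vectors.
#' @param n_bins requested number of quantile bins (>= 2).
#' @param bin_by `"observed"` or `"predicted"`.
#' @return data.frame with columns `bin`, `lo`, `hi`, `rmse`, `n`.
#' @export
binned_rmse <- function(predicted, observed, n_bins = 10L,
                        bin_by = c("observed", "predicted")) {
  bin_by <- match.arg(bin_by)
  stopifnot(length(predicted) == length(observed), n_bins >= 2L,
            length(observed) >= n_bins)
  axis <- if (bin_by == "observed") observed else predicted
  edges <- unique(stats::quantile(axis, probs = seq(0, 1, length.out =
                                                      n_bins + 1L),
                                  names = FALSE, type = 7))
  if (length(edges) < 2L) stop("all binning values identical")
  # interior edges define the bins; points on an edge go to the upper bin,
  # the maximum goes to the last bin
  bin <- findInterval(axis, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    in_bin <- bin == b
    data.frame(bin = b, lo = edges[b], hi = edges[b + 1L],
               rmse = sqrt(mean((predicted[in_bin] - observed[in_bin])^2)),
               n = sum(in_bin))
  }))
  rownames(out) <- NULL
  out
}
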