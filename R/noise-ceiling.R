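#' Estimate the assay noise ceiling of a score set
#'
#' Simulates replicate experiments under the reported heteroscedastic
#' per-variant uncertainty: for each replicate `b`, noise
#' `eps_i ~ Normal(0, sigma_i^2)` is added to every score and the Pearson
#' correlation between the original and the noisy replicate is recorded. The
#' noise ceiling is the mean of these `B` correlations -- the expected
#' agreement between two realizations of the same assay and thus an upper
#' bound on any model's correlation with the observations.
#'
#' Variants with missing uncertainty are excluded (the count is recorded in
#' the result). For homoscedastic noise the ceiling approaches the
#' closed-form attenuation `sqrt(V / (V + sigma^2))`, with `V` the score
#' variance.
#'
#' @param scores numeric vector of (normalized) scores.
#' @param sigmas per-variant measurement uncertainties (>= 0; `NA` excludes
#'   the variant).
#' @param B number of simulated replicates (default 300).
#' @param seed integer seed; the replicate correlations are reproducible.
#' @return Object of class `dms_noise_ceiling`: list with `ceiling`, the
#'   per-replicate correlations `r`, `B`, `n` (variants used),
#'   `n_excluded`, `sd_r` and `seed`.
#' @export
estimate_noise_ceiling <- function(scores, sigmas, B = 300L, seed = 1L) {
  stopifnot(length(scores) == length(sigmas), B >= 1L)
  keep <- is.finite(scores) & !is.na(sigmas)
  n_excluded <- sum(!keep)
  s <- scores[keep]
  sg <- sigmas[keep]
  if (any(sg < 0)) stop("sigmas must be >= 0")
  if (length(s) < 3L) {
    stop("too few variants with finite score and uncertainty (need >= 3)")
  }
  if (stats::sd(s) == 0) {
    stop("zero variance in scores; correlation undefined")
  }
  r <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      stats::cor(s, s + stats::rnorm(length(s), 0, sg))
    }, 0)
  })
  structure(
    list(ceiling = mean(r), r = r, B = as.integer(B),
         n = length(s), n_excluded = n_excluded,
         sd_r = stats::sd(r), seed = as.integer(seed)),
    class = "dms_noise_ceiling"
  )
}

#' @export
print.dms_noise_ceiling <- function(x, ...) {
  cat(sprintf(
    "noise ceiling: %.4f (sd %.4f over B = %d replicates, n = %d variants%s)\n",
    x$ceiling, x$sd_r, x$B, x$n,
    if (x$n_excluded) paste0(", ", x$n_excluded, " excluded") else ""))
  invisible(x)
}

#' Noise ceiling of a normalized score set
#'
#' Convenience wrapper applying [estimate_noise_ceiling()] to the missense
#' records of a score set, on the normalized scale (scores `norm_score`,
#' uncertainties `sigma_norm`).
#'
#' @param score_set a normalized `dms_score_set`.
#' @inheritParams estimate_noise_ceiling
#' @export
score_set_noise_ceiling <- function(score_set, B = 300L, seed = 1L) {
  rec <- model_records(score_set)
  estimate_noise_ceiling(rec$norm_score, rec$sigma_norm, B = B, seed = seed)
}
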