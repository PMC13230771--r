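# --- shared deterministic primitives -------------------------------------
# Local 3-mer context codes: for each position, the integer codes of the
# residues at (pos-1, pos, pos+1), edges padded by repeating the terminal
# residue. Both the tolerance model and the synthetic embedding provider
# derive from these, so positional tolerance is recoverable from sequence.
trigram_codes <- function(sequence) {
  aa <- strsplit(sequence, "")[[1]]
  idx <- aa_index(aa)
  L <- length(idx)
  cbind(left = idx[c(1L, seq_len(L - 1L))],
        center = idx,
        right = idx[c(seq_len(L - 1L) + 1L, L)])
}

# deterministic hash of the 3-mer context onto [0, 1]
trigram_hash <- function(codes) {
  ((7 * codes[, 1L] + 31 * codes[, 2L] + 131 * codes[, 3L]) %% 97) / 96
}

#' Default parameters of the synthetic variant-effect generator
#'
#' The generative model is `y = 1 - t(pos) * sev(wt, var)`: per-position
#' mutational tolerance `t` times per-substitution severity `sev`, on the
#' normalized scale (1 = wild-type-like, 0 = nonsense-like). `t` is a
#' logistic function (steepness `tolerance_steepness`) of a deterministic
#' hash of the local 3-mer sequence context, so tolerance is recoverable
#' from sequence alone; `sev` is the normalized Euclidean distance between
#' the wild-type and variant residues in a two-dimensional physicochemical
#' space (Kyte-Doolittle hydropathy, residue volume), raised to
#' `severity_power`. The defaults (steepness 10, power 0.5) give synthetic
#' maps whose normalized scores have a spread (sd about 0.3) typical of
#' stability-assay variant-effect maps. Observation noise is heteroscedastic
#' Gaussian with per-variant sigma drawn uniformly from `sigma_range`; raw
#' scores are produced by inverting the normalization with the `anchors`.
#'
#' @param sigma_range per-variant noise sd range (normalized scale).
#' @param anchors raw-score anchors `c(wt, nonsense)`.
#' @param tolerance_steepness logistic steepness of the tolerance model.
#' @param severity_power exponent applied to the normalized property
#'   distance.
#' @param tolerance_const,severity_const optional constants overriding the
#'   tolerance/severity models (used for degenerate-limit testing).
#' @return Named list of generator parameters.
#' @export
simulate_params <- function(sigma_range = c(0.05, 0.15),
                            anchors = c(wt = 0, nonsense = -4),
                            tolerance_steepness = 10,
                            severity_power = 0.5,
                            tolerance_const = NULL,
                            severity_const = NULL) {
  if (sigma_range[1L] > sigma_range[2L] || any(sigma_range < 0)) {
    stop("degenerate sigma_range")
  }
  if (anchors[1L] == anchors[2L]) stop("degenerate anchors (wt == nonsense)")
  list(sigma_range = sigma_range, anchors = anchors,
       tolerance_steepness = tolerance_steepness,
       severity_power = severity_power,
       tolerance_const = tolerance_const,
       severity_const = severity_const)
}

tolerance_profile <- function(sequence, params) {
  if (!is.null(params$tolerance_const)) {
    return(rep(params$tolerance_const, nchar(sequence)))
  }
  h <- trigram_hash(trigram_codes(sequence))
  stats::plogis(params$tolerance_steepness * (h - 0.5))
}

severity_matrix <- function(params) {
  if (!is.null(params$severity_const)) {
    m <- matrix(params$severity_const, 20L, 20L,
                dimnames = list(AMINO_ACIDS, AMINO_ACIDS))
    diag(m) <- 0
    return(m)
  }
  xy <- aa_unit_coords()
  d <- as.matrix(stats::dist(xy))
  m <- (d / max(d))^params$severity_power
  m[AMINO_ACIDS, AMINO_ACIDS]
}

#' Simulate one protein domain's variant-effect map
#'
#' Generates a random domain sequence, the ground-truth normalized score
#' `y = 1 - t(pos) * sev(wt, var)` for every possible missense substitution,
#' heteroscedastic Gaussian observation noise with recorded per-variant
#' uncertainty, one nonsense (Ter) record per position at truth 0, and raw
#' scores obtained by inverting the wild-type/nonsense normalization with
#' the generator anchors. A seeded random subset of missense variants is
#' kept to hit the target completeness.
#'
#' @param protein_id identifier for the simulated domain.
#' @param length domain length (>= 5 residues).
#' @param completeness fraction of possible missense substitutions retained,
#'   in (0, 1].
#' @param seed integer seed; the same seed reproduces the domain exactly.
#' @param params generator parameters from [simulate_params()].
#' @return List with `score_set` (a normalized `dms_score_set`) and `truth`
#'   (class `dms_synthetic_truth`: tolerance profile, severity matrix,
#'   per-record true scores `y`, anchors, seed, params).
#' @export
simulate_domain <- function(protein_id, length = 60L, completeness = 0.8,
                            seed = 1L, params = simulate_params()) {
  stopifnot(length >= 5L, completeness > 0, completeness <= 1)
  s_wt <- unname(params$anchors[1L])
  s_nons <- unname(params$anchors[2L])
  res <- with_seed(seed, {
    sequence <- paste(sample(AMINO_ACIDS, length, replace = TRUE),
                      collapse = "")
    tol <- tolerance_profile(sequence, params)
    sev <- severity_matrix(params)
    wt <- strsplit(sequence, "")[[1]]
    grid <- data.frame(
      position = rep(seq_len(length), each = 19L),
      wt_aa = rep(wt, each = 19L), stringsAsFactors = FALSE
    )
    grid$var_aa <- unlist(lapply(wt, function(a) setdiff(AMINO_ACIDS, a)))
    n_keep <- round(completeness * nrow(grid))
    keep <- sort(sample.int(nrow(grid), n_keep))
    grid <- grid[keep, , drop = FALSE]
    y <- 1 - tol[grid$position] * sev[cbind(grid$wt_aa, grid$var_aa)]
    # nonsense records: one Ter per position, truth 0
    non <- data.frame(position = seq_len(length), wt_aa = wt,
                      var_aa = TER, stringsAsFactors = FALSE)
    y_all <- c(y, rep(0, nrow(non)))
    rec <- rbind(grid, non)
    sigma_norm <- stats::runif(nrow(rec), params$sigma_range[1L],
                               params$sigma_range[2L])
    eps <- stats::rnorm(nrow(rec), 0, sigma_norm)
    norm_obs <- y_all + eps
    gap <- s_wt - s_nons
    rec$raw_score <- denormalize_scores(norm_obs, s_wt, s_nons)
    rec$sigma <- sigma_norm * abs(gap)
    list(sequence = sequence, tol = tol, sev = sev, rec = rec, y = y_all)
  })
  set <- dms_score_set(protein_id, res$rec, sequence = res$sequence,
                       s_wt = s_wt, s_nons = s_nons)
  set <- normalize_scores(set)
  truth <- structure(
    list(protein_id = protein_id, tolerance = res$tol,
         severity = res$sev,
         y = data.frame(position = res$rec$position,
                        wt_aa = res$rec$wt_aa, var_aa = res$rec$var_aa,
                        y = res$y, stringsAsFactors = FALSE),
         anchors = params$anchors, seed = as.integer(seed),
         params = params),
    class = "dms_synthetic_truth"
  )
  list(score_set = set, truth = truth)
}

#' Simulate a panel of protein domains
#'
#' Independent domains with per-protein seeds derived deterministically from
#' the master seed; the same master seed reproduces the panel exactly.
#'
#' @param n_proteins number of domains (>= 1).
#' @param length_range inclusive range domain lengths are drawn from (a
#'   single number fixes the length).
#' @param completeness per-domain completeness (recycled).
#' @param seed master seed.
#' @param params generator parameters, see [simulate_params()].
#' @return List of `simulate_domain()` results; protein ids are
#'   `"SYNP001"`, `"SYNP002"`, ...
#' @export
simulate_panel <- function(n_proteins = 20L, length_range = c(60L, 60L),
                           completeness = 0.8, seed = 1L,
                           params = simulate_params()) {
  stopifnot(n_proteins >= 1L)
  completeness <- rep_len(completeness, n_proteins)
  lengths <- with_seed(derive_seed(seed, 0L), {
    if (length(length_range) == 1L || length_range[1L] == length_range[2L]) {
      rep(length_range[1L], n_proteins)
    } else {
      sample(seq.int(length_range[1L], length_range[2L]), n_proteins,
             replace = TRUE)
    }
  })
  lapply(seq_len(n_proteins), function(i) {
    simulate_domain(sprintf("SYNP%03d", i), length = lengths[i],
                    completeness = completeness[i],
                    seed = derive_seed(seed, i), params = params)
  })
}

#' Deterministic synthetic embedding provider
#'
#' A stand-in for a protein language model that, by construction, carries
#' the synthetic generator's signal: each residue's embedding row encodes
#' (a) the residue's two physicochemical coordinates (hydropathy, volume),
#' (b) the hashed 3-mer context value that determines the generator's
#' positional tolerance, and (c) seeded pseudo-random filler dimensions
#' formed from fixed per-residue vectors of the 3-mer context. Rows depend
#' only on the local 3-mer, so a substitution changes embeddings only within
#' the window of positions whose context includes the mutated site, and
#' identical sequences always yield identical matrices.
#'
#' @param dim embedding dimensionality (>= 8).
#' @param seed seed fixing the filler basis vectors.
#' @return A `dms_embedding_provider`.
#' @export
synthetic_embedding_provider <- function(dim = 32L, seed = 1L) {
  stopifnot(dim >= 8L)
  dim <- as.integer(dim)
  n_fill <- dim - 3L
  basis <- with_seed(derive_seed(seed, 991L), {
    matrix(stats::rnorm(20L * n_fill), 20L, n_fill,
           dimnames = list(AMINO_ACIDS, NULL))
  })
  coords <- aa_unit_coords()[AMINO_ACIDS, , drop = FALSE]
  embed <- function(sequence) {
    codes <- trigram_codes(sequence)
    h <- trigram_hash(codes)
    fill <- 0.3 * basis[codes[, 1L], , drop = FALSE] +
      basis[codes[, 2L], , drop = FALSE] +
      0.3 * basis[codes[, 3L], , drop = FALSE]
    m <- cbind(coords[codes[, 2L], 1L], coords[codes[, 2L], 2L], h, fill)
    colnames(m) <- NULL
    rownames(m) <- NULL
    m
  }
  embedding_provider(embed, dim = dim,
                     name = sprintf("synthetic-%d", seed))
}

#' Write a simulated panel to a directory
#'
#' Emits, per domain, the score set in both supported dialects
#' (`<id>.csv` MaveDB-style and `<id>.tsv` long format), the domain sequence
#' in one panel-level FASTA, a ground-truth table
#' (`<id>_truth.tsv`: position, wt_aa, var_aa, true normalized score) and a
#' JSON manifest recording seeds and parameters.
#'
#' @param panel result of [simulate_panel()].
#' @param dir output directory.
#' @param seed the master seed to record in the manifest.
#' @export
write_panel <- function(panel, dir, seed = NA_integer_) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- character()
  for (item in panel) {
    set <- item$score_set
    write_score_set(set, file.path(dir, paste0(set$protein_id, ".csv")),
                    "mavedb_csv")
    write_score_set(set, file.path(dir, paste0(set$protein_id, ".tsv")),
                    "long_tsv")
    utils::write.table(item$truth$y,
                       file.path(dir,
                                 paste0(set$protein_id, "_truth.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    fasta <- c(fasta, paste0(">", set$protein_id), set$sequence)
  }
  writeLines(fasta, file.path(dir, "panel.fasta"))
  jsonlite::write_json(
    list(seed = seed, n_proteins = length(panel),
         protein_ids = vapply(panel, function(p) p$score_set$protein_id,
                              ""),
         anchors = as.list(panel[[1L]]$truth$anchors),
         sigma_range = panel[[1L]]$truth$params$sigma_range),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
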