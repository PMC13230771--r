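#' Load the default substitution-matrix set
#'
#' Returns the named list of amino-acid substitution matrices shipped with
#' Biostrings (BLOSUM45/50/62/80/100 and PAM30/40/70/120/250), restricted to
#' the 20 standard residues plus the stop symbol where present. The set is
#' configurable: matrices read with [read_substitution_matrix()] can be added
#' or substituted.
#'
#' @param names optional character vector selecting a subset.
#' @return Named list of numeric matrices, sorted by name.
#' @export
default_matrix_set <- function(names = NULL) {
  available <- c("BLOSUM45", "BLOSUM50", "BLOSUM62", "BLOSUM80", "BLOSUM100",
                 "PAM30", "PAM40", "PAM70", "PAM120", "PAM250")
  if (is.null(names)) names <- available
  bad <- setdiff(names, available)
  if (length(bad)) stop("unknown matrix name(s): ", paste(bad, collapse = ", "))
  env <- new.env()
  out <- lapply(names, function(nm) {
    utils::data(list = nm, package = "Biostrings", envir = env)
    m <- get(nm, envir = env)
    keep <- intersect(rownames(m), c(AMINO_ACIDS, TER))
    m[keep, keep, drop = FALSE]
  })
  names(out) <- names
  out[order(names(out))]
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the standard whitespace-delimited matrix format used by NCBI tools
#' (a header row of residue symbols, one labelled row per residue, `#`
#' comments).
#'
#' @param path file path.
#' @return Numeric matrix with residue symbols as dimnames.
#' @export
read_substitution_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("not a substitution matrix file: ", path)
  header <- strsplit(trimws(lines[[1]]), "\\s+")[[1]]
  rows <- lapply(lines[-1], function(l) strsplit(trimws(l), "\\s+")[[1]])
  row_names <- vapply(rows, `[`, "", 1L)
  vals <- t(vapply(rows, function(r) as.numeric(r[-1]),
                   numeric(length(header))))
  dimnames(vals) <- list(row_names, header)
  vals
}

#' Substitution-matrix features for one substitution
#'
#' One feature per matrix: the matrix entry for the ordered pair
#' `(wt_aa, var_aa)`. Feature order follows the sorted matrix names.
#'
#' @param wt_aa,var_aa one-letter residue codes.
#' @param matrix_set named list of matrices (default [default_matrix_set()]).
#' @return Named numeric vector, one value per matrix.
#' @export
substitution_features <- function(wt_aa, var_aa,
                                  matrix_set = default_matrix_set()) {
  matrix_set <- matrix_set[order(names(matrix_set))]
  out <- vapply(names(matrix_set), function(nm) {
    m <- matrix_set[[nm]]
    for (r in c(wt_aa, var_aa)) {
      if (!r %in% rownames(m)) {
        stop("residue '", r, "' absent from matrix ", nm)
      }
    }
    m[wt_aa, var_aa]
  }, 0)
  names(out) <- paste0("subst_", names(matrix_set))
  out
}

# vectorized lookup used during table assembly
substitution_feature_matrix <- function(wt_aa, var_aa, matrix_set) {
  matrix_set <- matrix_set[order(names(matrix_set))]
  cols <- lapply(names(matrix_set), function(nm) {
    m <- matrix_set[[nm]]
    bad <- setdiff(unique(c(wt_aa, var_aa)), rownames(m))
    if (length(bad)) stop("residue(s) absent from matrix ", nm, ": ",
                          paste(bad, collapse = ", "))
    m[cbind(wt_aa, var_aa)]
  })
  out <- do.call(cbind, cols)
  colnames(out) <- paste0("subst_", names(matrix_set))
  out
}

#' Physicochemical property features for one substitution
#'
#' Numeric properties contribute wild-type value, variant value and their
#' absolute difference; logical properties contribute 0/1 indicators for
#' wild type and variant; categorical properties are one-hot encoded for the
#' wild-type and variant classes.
#'
#' @param wt_aa,var_aa one-letter residue codes.
#' @param property_table see [aa_property_table()].
#' @return Named numeric vector.
#' @export
property_features <- function(wt_aa, var_aa,
                              property_table = aa_property_table()) {
  property_feature_matrix(wt_aa, var_aa, property_table)[1L, ]
}

property_feature_matrix <- function(wt_aa, var_aa,
                                    property_table = aa_property_table()) {
  p <- property_table
  if (!all(c(wt_aa, var_aa) %in% rownames(p))) {
    stop("residue(s) without property values: ",
         paste(setdiff(unique(c(wt_aa, var_aa)), rownames(p)),
               collapse = ", "))
  }
  prop_cols <- setdiff(names(p), "aa")
  cols <- list()
  for (nm in prop_cols) {
    v <- p[[nm]]
    names(v) <- rownames(p)
    if (is.numeric(v)) {
      if (any(!is.finite(v))) stop("non-finite property values in ", nm)
      cols[[paste0("prop_", nm, "_wt")]] <- unname(v[wt_aa])
      cols[[paste0("prop_", nm, "_var")]] <- unname(v[var_aa])
      cols[[paste0("prop_", nm, "_absdiff")]] <-
        abs(unname(v[wt_aa]) - unname(v[var_aa]))
    } else if (is.logical(v)) {
      cols[[paste0("prop_", nm, "_wt")]] <- as.numeric(v[wt_aa])
      cols[[paste0("prop_", nm, "_var")]] <- as.numeric(v[var_aa])
    } else {
      lev <- sort(unique(as.character(v)))
      for (lv in lev) {
        cols[[paste0("prop_", nm, "_", lv, "_wt")]] <-
          as.numeric(v[wt_aa] == lv)
        cols[[paste0("prop_", nm, "_", lv, "_var")]] <-
          as.numeric(v[var_aa] == lv)
      }
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- NULL
  out
}

#' Single-nucleotide-variant indicator
#'
#' `TRUE` when some codon of the wild-type residue differs from some codon of
#' the variant residue (standard genetic code; any codon pair, no codon
#' context) at exactly one nucleotide position. The variant may be the stop
#' symbol `"*"`.
#'
#' @param wt_aa,var_aa one-letter residue codes (`var_aa` may be `"*"`).
#' @return Logical scalar (vectorized over inputs of equal length).
#' @export
snv_indicator <- function(wt_aa, var_aa) {
  stopifnot(length(wt_aa) == length(var_aa))
  if (any(wt_aa == var_aa)) stop("snv_indicator requires wt_aa != var_aa")
  tab <- snv_reachability_table()
  out <- tab[cbind(wt_aa, var_aa)]
  if (anyNA(out)) stop("non-standard residue(s) passed to snv_indicator")
  out
}

# 21x21 reachability lookup, built once from the standard genetic code by
# comparing codons that differ at a single base
snv_reachability_table <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    code <- Biostrings::GENETIC_CODE
    codons <- names(code)
    sym <- c(AMINO_ACIDS, TER)
    reach <- matrix(FALSE, length(sym), length(sym),
                    dimnames = list(sym, sym))
    split_codon <- do.call(rbind, strsplit(codons, ""))
    for (i in seq_along(codons)) {
      diffs <- rowSums(split_codon != matrix(split_codon[i, ],
                                             nrow = nrow(split_codon),
                                             ncol = 3L, byrow = TRUE))
      nb <- which(diffs == 1L)
      reach[code[[i]], unique(code[nb])] <- TRUE
    }
    diag(reach) <- FALSE
    cache <<- reach
    cache
  }
})

#' Create an embedding provider from an embedding function
#'
#' An embedding provider supplies per-residue embedding matrices for
#' arbitrary sequences; it is the adapter point for protein language models.
#' Providers must be deterministic: the same sequence always yields the same
#' matrix.
#'
#' @param embed function(sequence) returning an `nchar(sequence) x dim`
#'   numeric matrix.
#' @param dim embedding dimensionality.
#' @param name provider label stored in feature-table metadata.
#' @return Object of class `dms_embedding_provider`.
#' @export
embedding_provider <- function(embed, dim, name = "custom") {
  stopifnot(is.function(embed), dim >= 1L)
  structure(list(embed = embed, dim = as.integer(dim), name = name),
            class = "dms_embedding_provider")
}

#' @export
print.dms_embedding_provider <- function(x, ...) {
  cat("embedding provider '", x$name, "' (dim = ", x$dim, ")\n", sep = "")
  invisible(x)
}

provider_embed <- function(provider, sequence) {
  m <- provider$embed(sequence)
  if (!is.matrix(m) || nrow(m) != nchar(sequence) ||
      ncol(m) != provider$dim) {
    stop("embedding provider returned a ", paste(dim(m), collapse = "x"),
         " matrix; expected ", nchar(sequence), "x", provider$dim)
  }
  m
}

#' Embedding features for one variant
#'
#' Extracts the wild-type residue embedding `e_wt` (row `position` of the
#' wild-type sequence embedding), the variant embedding `e_var` (same row of
#' the mutated sequence embedding) and, optionally, the difference vector
#' `e_var - e_wt` capturing the local contextual shift induced by the
#' substitution.
#'
#' @param provider an embedding provider.
#' @param wt_sequence wild-type amino-acid sequence.
#' @param position,var_aa the substitution (1-based; `var_aa` not Ter).
#' @param include_diff include the difference vector?
#' @return List with `e_wt`, `e_var` and (optionally) `e_diff`.
#' @export
embedding_features <- function(provider, wt_sequence, position, var_aa,
                               include_diff = TRUE) {
  stopifnot(position >= 1L, position <= nchar(wt_sequence))
  if (var_aa == TER) stop("embedding features are undefined for Ter variants")
  e_wt <- provider_embed(provider, wt_sequence)[position, ]
  mut <- mutate_sequence(wt_sequence, position, var_aa)
  e_var <- provider_embed(provider, mut)[position, ]
  out <- list(e_wt = e_wt, e_var = e_var)
  if (include_diff) out$e_diff <- e_var - e_wt
  out
}

mutate_sequence <- function(sequence, position, var_aa) {
  substr(sequence, position, position) <- var_aa
  sequence
}

#' Positional mean normalized scores
#'
#' The per-(protein, position) arithmetic mean of normalized scores over the
#' supplied records -- the data-driven prior for site-specific mutational
#' tolerance. The caller is responsible for restricting `records` to the
#' training side of a split; positions absent from `records` have no entry
#' and later receive the missing-value sentinel as a feature.
#'
#' @param records a records data.frame (e.g. from a `dms_score_set`) with
#'   finite `norm_score`, or a `dms_score_set`/list of them (missense records
#'   are used).
#' @return Object of class `dms_positional_means`: a data.frame with columns
#'   `protein_id`, `position`, `mean`, `count`.
#' @export
compute_positional_means <- function(records) {
  if (!is.data.frame(records)) records <- model_records(records)
  stopifnot(all(c("protein_id", "position", "norm_score") %in%
                  names(records)))
  records <- records[!is.na(records$norm_score), , drop = FALSE]
  if (!nrow(records)) {
    out <- data.frame(protein_id = character(), position = integer(),
                      mean = numeric(), count = integer(),
                      stringsAsFactors = FALSE)
    class(out) <- c("dms_positional_means", "data.frame")
    return(out)
  }
  key <- paste(records$protein_id, records$position, sep = ":")
  agg <- stats::aggregate(records$norm_score, by = list(key = key),
                          FUN = function(x) c(mean(x), length(x)))
  first <- records[!duplicated(key), c("protein_id", "position")]
  first_key <- paste(first$protein_id, first$position, sep = ":")
  idx <- match(first_key, agg$key)
  out <- data.frame(protein_id = first$protein_id,
                    position = first$position,
                    mean = agg$x[idx, 1L],
                    count = as.integer(agg$x[idx, 2L]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$protein_id, out$position), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dms_positional_means", "data.frame")
  out
}

#' Merge two positional-mean maps
#'
#' Count-weighted merge; equivalent to computing the map on the union of the
#' two underlying record sets.
#'
#' @param a,b `dms_positional_means` objects.
#' @export
merge_positional_means <- function(a, b) {
  both <- rbind(as.data.frame(a), as.data.frame(b))
  key <- paste(both$protein_id, both$position, sep = ":")
  tot <- tapply(both$count, key, sum)
  wsum <- tapply(both$mean * both$count, key, sum)
  first <- both[!duplicated(key), c("protein_id", "position")]
  fk <- paste(first$protein_id, first$position, sep = ":")
  out <- data.frame(protein_id = first$protein_id,
                    position = first$position,
                    mean = as.numeric(wsum[fk] / tot[fk]),
                    count = as.integer(tot[fk]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$protein_id, out$position), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("dms_positional_means", "data.frame")
  out
}

lookup_positional_means <- function(pos_means, protein_id, position) {
  if (is.null(pos_means) || !nrow(pos_means)) {
    return(rep(NA_real_, length(protein_id)))
  }
  key <- paste(protein_id, position, sep = ":")
  map_key <- paste(pos_means$protein_id, pos_means$position, sep = ":")
  pos_means$mean[match(key, map_key)]
}

#' Feature-set presets
#'
#' Named presets controlling which feature families enter the model:
#' \describe{
#'   \item{full}{positional mean, substitution matrices, physicochemical
#'     properties, SNV indicator, conservation, wild-type/variant/difference
#'     embeddings.}
#'   \item{full_minus_diff}{`full` without the embedding difference vector
#'     (the best-performing cross-protein configuration).}
#'   \item{min}{positional mean plus wild-type, variant and difference
#'     embeddings only.}
#'   \item{mean_only}{positional mean only.}
#'   \item{no_embedding}{`full` without any embedding columns.}
#'   \item{zero_shot_no_mean}{`full_minus_diff` without the positional mean
#'     (no experiment-derived features; genuine zero-shot).}
#' }
#' @return Character vector of preset names.
#' @export
feature_presets <- function() {
  c("full", "full_minus_diff", "min", "mean_only", "no_embedding",
    "zero_shot_no_mean")
}

preset_families <- function(preset) {
  all_fam <- c("posmean", "subst", "prop", "snv", "conservation",
               "emb_wt", "emb_var", "emb_diff")
  switch(preset,
    full = all_fam,
    full_minus_diff = setdiff(all_fam, "emb_diff"),
    min = c("posmean", "emb_wt", "emb_var", "emb_diff"),
    mean_only = "posmean",
    no_embedding = setdiff(all_fam, c("emb_wt", "emb_var", "emb_diff")),
    zero_shot_no_mean = setdiff(all_fam, c("emb_diff", "posmean")),
    stop("unknown preset '", preset, "'; see feature_presets()")
  )
}

#' Assemble the per-variant feature table
#'
#' Builds the numeric design matrix for the imputation model from one or more
#' (normalized) score sets. Rows are missense variants with a finite
#' normalized score; synonymous and nonsense records never become rows.
#' Columns follow a fixed family order (positional mean, substitution
#' matrices, properties, SNV, conservation, embeddings), with deterministic
#' names, so tables built from the same inputs are identical and trained
#' models are schema-portable. Positions without a positional-mean entry and
#' variants without a conservation score get `NA`, which the tree learner
#' handles natively.
#'
#' @param score_sets a `dms_score_set` or list of them (normalized).
#' @param preset one of [feature_presets()].
#' @param provider embedding provider (required by presets with embedding
#'   families).
#' @param positional_means a `dms_positional_means` map, computed from
#'   training data only (`NULL` leaves the column all-`NA`).
#' @param conservation optional data.frame `protein_id`,
#'   `uniprot_position`, `var_aa`, `score`; joined via each set's offset.
#' @param matrix_set,property_table feature sources; defaults are the bundled
#'   ones.
#' @return Object of class `dms_feature_table`: list with the feature matrix
#'   `x`, target `y`, `group` (protein id per row), `keys` (variant identity
#'   data.frame), `preset` and `schema`.
#' @export
assemble_feature_table <- function(score_sets, preset = "full_minus_diff",
                                   provider = NULL, positional_means = NULL,
                                   conservation = NULL,
                                   matrix_set = default_matrix_set(),
                                   property_table = aa_property_table()) {
  preset <- match.arg(preset, feature_presets())
  fams <- preset_families(preset)
  if (inherits(score_sets, "dms_score_set")) score_sets <- list(score_sets)
  rec <- model_records(score_sets)
  seqs <- lapply(score_sets, `[[`, "sequence")
  names(seqs) <- vapply(score_sets, `[[`, "", "protein_id")
  offsets <- vapply(score_sets, `[[`, 0L, "offset")
  names(offsets) <- names(seqs)

  needs_emb <- any(c("emb_wt", "emb_var", "emb_diff") %in% fams)
  if (needs_emb && is.null(provider)) {
    stop("preset '", preset, "' requires an embedding provider")
  }

  blocks <- list()
  if ("posmean" %in% fams) {
    blocks$posmean <- matrix(
      lookup_positional_means(positional_means, rec$protein_id,
                              rec$position),
      ncol = 1L, dimnames = list(NULL, "posmean")
    )
  }
  if ("subst" %in% fams) {
    blocks$subst <- substitution_feature_matrix(rec$wt_aa, rec$var_aa,
                                                matrix_set)
  }
  if ("prop" %in% fams) {
    blocks$prop <- property_feature_matrix(rec$wt_aa, rec$var_aa,
                                           property_table)
  }
  if ("snv" %in% fams) {
    blocks$snv <- matrix(as.numeric(snv_indicator(rec$wt_aa, rec$var_aa)),
                         ncol = 1L, dimnames = list(NULL, "snv"))
  }
  if ("conservation" %in% fams) {
    if (is.null(conservation)) {
      if (nrow(rec)) {
        warning("no conservation scores supplied; ",
                "conservation column filled with NA")
      }
      cons <- rep(NA_real_, nrow(rec))
    } else {
      up <- map_position(rec$position, 0L) +
        unname(offsets[rec$protein_id])
      key <- paste(rec$protein_id, up, rec$var_aa, sep = ":")
      ckey <- paste(conservation$protein_id, conservation$uniprot_position,
                    conservation$var_aa, sep = ":")
      cons <- conservation$score[match(key, ckey)]
    }
    blocks$conservation <- matrix(cons, ncol = 1L,
                                  dimnames = list(NULL, "conservation"))
  }
  if (needs_emb) {
    d <- provider$dim
    e_wt <- matrix(NA_real_, nrow(rec), d)
    e_var <- matrix(NA_real_, nrow(rec), d)
    for (pid in unique(rec$protein_id)) {
      sq <- seqs[[pid]]
      if (is.null(sq) || is.na(sq)) {
        stop("embedding features require a sequence for protein ", pid)
      }
      idx <- which(rec$protein_id == pid)
      wt_mat <- provider_embed(provider, sq)
      e_wt[idx, ] <- wt_mat[rec$position[idx], , drop = FALSE]
      for (i in idx) {
        mut <- mutate_sequence(sq, rec$position[i], rec$var_aa[i])
        e_var[i, ] <- provider_embed(provider, mut)[rec$position[i], ]
      }
    }
    if ("emb_wt" %in% fams) {
      colnames(e_wt) <- sprintf("emb_wt_%03d", seq_len(d))
      blocks$emb_wt <- e_wt
    }
    if ("emb_var" %in% fams) {
      ev <- e_var
      colnames(ev) <- sprintf("emb_var_%03d", seq_len(d))
      blocks$emb_var <- ev
    }
    if ("emb_diff" %in% fams) {
      ed <- e_var - e_wt
      colnames(ed) <- sprintf("emb_diff_%03d", seq_len(d))
      blocks$emb_diff <- ed
    }
  }
  fam_order <- c("posmean", "subst", "prop", "snv", "conservation",
                 "emb_wt", "emb_var", "emb_diff")
  x <- do.call(cbind, blocks[intersect(fam_order, names(blocks))])
  if (is.null(x)) x <- matrix(numeric(), nrow(rec), 0L)
  structure(
    list(x = x, y = rec$norm_score, group = rec$protein_id,
         keys = rec[, c("protein_id", "position", "wt_aa", "var_aa")],
         preset = preset, schema = colnames(x)),
    class = "dms_feature_table"
  )
}

#' @export
print.dms_feature_table <- function(x, ...) {
  cat(sprintf(
    "DMS feature table: %d variants x %d features (preset '%s', %d protein%s)\n",
    nrow(x$x), ncol(x$x), x$preset, length(unique(x$group)),
    if (length(unique(x$group)) == 1L) "" else "s"))
  invisible(x)
}

#' Subset the rows of a feature table
#'
#' Keeps the schema and preset; typically used with the `train`/`test`
#' indices of a [make_partition()] result.
#'
#' @param table a `dms_feature_table`.
#' @param idx integer (or logical) row index.
#' @return A `dms_feature_table` with the selected rows.
#' @export
feature_table_subset <- function(table, idx) {
  structure(
    list(x = table$x[idx, , drop = FALSE], y = table$y[idx],
         group = table$group[idx],
         keys = table$keys[idx, , drop = FALSE],
         preset = table$preset, schema = table$schema),
    class = "dms_feature_table"
  )
}
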