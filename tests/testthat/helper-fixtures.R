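# Shared fixtures and independent oracles used across the suite.

# a small hand-built score set: 3 positions of the sequence "MKT",
# several missense records plus nonsense and synonymous anchors
toy_records <- function() {
  data.frame(
    position = c(1L, 1L, 2L, 2L, 3L, 1L, 2L, 3L),
    wt_aa = c("M", "M", "K", "K", "T", "M", "K", "T"),
    var_aa = c("A", "I", "R", "E", "S", "*", "*", "T"),
    raw_score = c(-1.0, -0.2, -2.5, -3.0, -0.5, -4.1, -3.9, 0.05),
    sigma = c(0.2, 0.1, 0.3, 0.2, 0.1, 0.2, 0.2, 0.1),
    stringsAsFactors = FALSE
  )
}

toy_score_set <- function(normalized = TRUE) {
  set <- dms_score_set("TOY1", toy_records(), sequence = "MKT",
                       s_wt = 0, s_nons = -4)
  if (normalized) set <- normalize_scores(set) else set
}

# a saturation score set: every missense + Ter at every position
saturation_score_set <- function(protein_id = "SAT1", length = 10L,
                                 seed = 42L) {
  sim <- simulate_domain(protein_id, length = length, completeness = 1,
                         seed = seed)
  sim$score_set
}

# independent brute-force SNV oracle: enumerate every codon pair and check
# whether any pair encoding (wt, var) differs at exactly one base
oracle_snv <- function(wt_aa, var_aa) {
  code <- Biostrings::GENETIC_CODE
  wt_codons <- names(code)[code == wt_aa]
  var_codons <- names(code)[code == var_aa]
  for (a in wt_codons) {
    for (b in var_codons) {
      d <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
      if (d == 1L) return(TRUE)
    }
  }
  FALSE
}

# brute-force residue-mean oracle
oracle_residue_mean <- function(train, pid, pos, var) {
  vals <- c()
  for (i in seq_len(nrow(train))) {
    if (train$protein_id[i] == pid && train$position[i] == pos &&
        train$var_aa[i] != var) {
      vals <- c(vals, train$norm_score[i])
    }
  }
  if (!length(vals)) return(NA_real_)
  sum(vals) / length(vals)
}

# brute-force 5NN-BLOSUM oracle with the documented tie-break
# (descending similarity, then alphabetical variant residue)
oracle_knn_blosum <- function(train, pid, pos, var, k, mat) {
  cand <- train[train$protein_id == pid & train$position == pos &
                  train$var_aa != var, ]
  if (!nrow(cand)) return(NA_real_)
  sims <- sapply(seq_len(nrow(cand)), function(i) mat[var, cand$var_aa[i]])
  ord <- order(-sims, cand$var_aa)
  sel <- ord[seq_len(min(k, length(ord)))]
  median(cand$norm_score[sel])
}

# brute-force 5NN-functional oracle
oracle_knn_functional <- function(train, pid, pos, var, k) {
  prot <- train[train$protein_id == pid, ]
  profile <- sapply(unique(prot$var_aa), function(a) {
    mean(prot$norm_score[prot$var_aa == a])
  })
  if (!var %in% names(profile)) return(NA_real_)
  cand <- prot[prot$position == pos & prot$var_aa != var, ]
  if (!nrow(cand)) return(NA_real_)
  dists <- abs(profile[var] - profile[cand$var_aa])
  ord <- order(dists, cand$var_aa)
  sel <- ord[seq_len(min(k, length(ord)))]
  mean(cand$norm_score[sel])
}

# small synthetic panel shared by model-level tests (built once per run)
small_panel <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_panel(n_proteins = 4L, length_range = 30L,
                               completeness = 0.9, seed = 404L)
    }
    cache
  }
})

small_panel_sets <- function() lapply(small_panel(), `[[`, "score_set")

small_provider <- function(dim = 16L) {
  synthetic_embedding_provider(dim = dim, seed = 7L)
}
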