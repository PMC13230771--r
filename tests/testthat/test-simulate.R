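test_that("simulation is reproducible and respects its record structure", {
  a <- simulate_domain("S1", length = 20L, completeness = 0.7, seed = 3)
  b <- simulate_domain("S1", length = 20L, completeness = 0.7, seed = 3)
  expect_identical(a$score_set$records, b$score_set$records)
  expect_identical(a$score_set$sequence, b$score_set$sequence)
  rec <- a$score_set$records
  # count audit: missense kept to completeness, one Ter per position
  expect_identical(sum(rec$type == "missense"),
                   as.integer(round(0.7 * 20 * 19)))
  expect_identical(sum(rec$type == "nonsense"), 20L)
  # wild types match the sequence
  seq_aa <- strsplit(a$score_set$sequence, "")[[1]]
  expect_identical(rec$wt_aa, seq_aa[rec$position])
  # different seeds differ
  c2 <- simulate_domain("S1", length = 20L, completeness = 0.7, seed = 4)
  expect_false(identical(a$score_set$sequence, c2$score_set$sequence))
})

test_that("generated raw scores invert the normalization exactly", {
  sim <- simulate_domain("S2", length = 15L, completeness = 1, seed = 9)
  set <- sim$score_set
  # the shipped set is already normalized; renormalizing from raw scores
  # with the same anchors reproduces norm_score to numerical precision
  fresh <- dms_score_set("S2", set$records[, c("position", "wt_aa",
                                               "var_aa", "raw_score",
                                               "sigma")],
                         sequence = set$sequence, s_wt = set$s_wt,
                         s_nons = set$s_nons)
  fresh <- normalize_scores(fresh)
  expect_equal(fresh$records$norm_score, set$records$norm_score,
               tolerance = 1e-10)
})

test_that("degenerate generator limits behave as the truth model dictates", {
  # no tolerance anywhere: every missense score is exactly 1 (no noise)
  flat <- simulate_domain("S3", length = 10L, completeness = 1, seed = 2,
                          params = simulate_params(
                            sigma_range = c(0, 0),
                            tolerance_const = 0))
  rec <- flat$score_set$records
  expect_equal(rec$norm_score[rec$type == "missense"],
               rep(1, sum(rec$type == "missense")))
  # full tolerance and maximal severity: every missense score is 0
  dead <- simulate_domain("S4", length = 10L, completeness = 1, seed = 2,
                          params = simulate_params(
                            sigma_range = c(0, 0),
                            tolerance_const = 1, severity_const = 1))
  drec <- dead$score_set$records
  expect_equal(drec$norm_score[drec$type == "missense"],
               rep(0, sum(drec$type == "missense")))
  expect_error(simulate_params(sigma_range = c(0.2, 0.1)), "degenerate")
})

test_that("the truth model is recoverable from the stored ground truth", {
  sim <- simulate_domain("S5", length = 25L, completeness = 0.9, seed = 6)
  truth <- sim$truth
  rec <- sim$score_set$records
  mis <- rec$type == "missense"
  y <- truth$y$y[match(
    paste(rec$position, rec$var_aa),
    paste(truth$y$position, truth$y$var_aa))]
  # oracle reconstruction from tolerance and severity
  y_oracle <- 1 - truth$tolerance[rec$position[mis]] *
    truth$severity[cbind(rec$wt_aa[mis], rec$var_aa[mis])]
  expect_equal(y[mis], y_oracle, tolerance = 1e-12)
  # observation = truth + noise within plausible range
  resid <- rec$norm_score[mis] - y[mis]
  expect_lt(sd(resid), 0.2)
})

test_that("noise ceiling of a generated panel matches its closed form", {
  sim <- simulate_domain("S6", length = 60L, completeness = 1, seed = 12)
  rec <- model_records(sim$score_set)
  truth_y <- sim$truth$y$y[seq_len(nrow(rec))]
  V <- var(truth_y)
  e_sig2 <- mean(rec$sigma_norm^2)
  nc <- score_set_noise_ceiling(sim$score_set, B = 300, seed = 5)
  # observed-score variance is V + E[sigma^2]; replicate correlation with
  # the observation attenuates accordingly
  V_obs <- V + e_sig2
  expect_equal(nc$ceiling, sqrt(V_obs / (V_obs + e_sig2)),
               tolerance = 0.03)
})

test_that("panels derive per-protein seeds from the master seed", {
  p1 <- simulate_panel(3, length_range = 12L, completeness = 0.8,
                       seed = 500)
  p2 <- simulate_panel(3, length_range = 12L, completeness = 0.8,
                       seed = 500)
  expect_identical(lapply(p1, function(x) x$score_set$records),
                   lapply(p2, function(x) x$score_set$records))
  ids <- vapply(p1, function(x) x$score_set$protein_id, "")
  expect_identical(ids, c("SYNP001", "SYNP002", "SYNP003"))
  expect_identical(anyDuplicated(vapply(p1, function(x)
    x$score_set$sequence, "")), 0L)
})

test_that("synthetic embeddings are deterministic, local and signal-bearing", {
  prov <- synthetic_embedding_provider(16, seed = 8)
  s1 <- "MKTAYIAKQRQISFVK"
  expect_identical(prov$embed(s1), prov$embed(s1))
  m1 <- prov$embed(s1)
  expect_identical(dim(m1), c(nchar(s1), 16L))
  # locality: mutating position p changes only rows within the 3-mer window
  pos <- 8L
  s2 <- paste0(substr(s1, 1, pos - 1), "W", substr(s1, pos + 1, nchar(s1)))
  m2 <- prov$embed(s2)
  changed <- which(rowSums(m1 != m2) > 0)
  expect_true(all(changed %in% (pos - 1):(pos + 1)))
  expect_true(pos %in% changed)
  # the hash feature (column 3) encodes the tolerance driver
  h <- dmsimpute:::trigram_hash(dmsimpute:::trigram_codes(s1))
  expect_equal(m1[, 3], h)
  expect_error(synthetic_embedding_provider(4), "dim >= 8")
})

test_that("panel files round-trip through the package readers", {
  panel <- simulate_panel(2, length_range = 10L, completeness = 0.9,
                          seed = 31)
  dir <- tempfile()
  write_panel(panel, dir, seed = 31)
  for (item in panel) {
    set <- item$score_set
    for (ext in c("csv", "tsv")) {
      fmt <- if (ext == "csv") "mavedb_csv" else "long_tsv"
      back <- read_score_set(file.path(dir, paste0(set$protein_id, ".",
                                                   ext)),
                             fmt, protein_id = set$protein_id,
                             sequence = set$sequence,
                             s_wt = set$s_wt, s_nons = set$s_nons)
      back <- normalize_scores(back)
      expect_equal(back$records$raw_score, set$records$raw_score,
                   tolerance = 1e-12, info = ext)
      expect_equal(back$records$norm_score, set$records$norm_score,
                   tolerance = 1e-10, info = ext)
    }
  }
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_identical(manifest$n_proteins, 2L)
  fasta <- Biostrings::readAAStringSet(file.path(dir, "panel.fasta"))
  expect_identical(as.character(fasta[["SYNP001"]]),
                   panel[[1]]$score_set$sequence)
  unlink(dir, recursive = TRUE)
})
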