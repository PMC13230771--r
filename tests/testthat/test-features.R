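test_that("substitution features read the packaged matrices", {
  ms <- default_matrix_set()
  expect_length(ms, 10L)
  f <- substitution_features("W", "W", ms)
  expect_length(f, length(ms))
  expect_equal(unname(f["subst_BLOSUM62"]),
               unname(ms$BLOSUM62["W", "W"]))
  # symmetric matrix symmetry
  expect_equal(substitution_features("A", "R", ms["BLOSUM62"]),
               substitution_features("R", "A", ms["BLOSUM62"]))
  # feature order follows sorted matrix names
  expect_identical(names(f), paste0("subst_", sort(names(ms))))
  expect_error(substitution_features("A", "U", ms), "absent")
})

test_that("NCBI-format matrix files are parsed correctly", {
  path <- tempfile(fileext = ".txt")
  writeLines(c("# tiny demo matrix", "   A  R  N",
               "A  4 -1 -2", "R -1  5  0", "N -2  0  6"), path)
  m <- read_substitution_matrix(path)
  expect_identical(dim(m), c(3L, 3L))
  expect_equal(m["A", "A"], 4)
  expect_equal(m["R", "N"], 0)
  expect_true(isSymmetric(m))
  unlink(path)
})

test_that("property features: wt/var values, absolute differences, one-hot", {
  p <- aa_property_table()
  f <- property_features("G", "A", p)
  expect_equal(unname(f["prop_mol_weight_absdiff"]),
               abs(p["G", "mol_weight"] - p["A", "mol_weight"]))
  expect_equal(unname(f["prop_mol_weight_wt"]), p["G", "mol_weight"])
  # identity probe: all absdiff features are zero
  same <- property_features("L", "L", p)
  expect_true(all(same[grepl("absdiff", names(same))] == 0))
  # one-hot class vectors sum to 1 per residue
  cc_wt <- same[grepl("^prop_charge_class_.*_wt$", names(same))]
  cc_var <- f[grepl("^prop_charge_class_.*_var$", names(f))]
  expect_equal(sum(cc_wt), 1)
  expect_equal(sum(cc_var), 1)
  # booleans encoded 0/1
  expect_true(all(f[grepl("prop_hbond", names(f))] %in% c(0, 1)))
})

test_that("snv indicator matches brute-force codon enumeration", {
  # exhaustive over all ordered pairs including Ter targets
  pairs <- expand.grid(wt = AMINO_ACIDS, var = c(AMINO_ACIDS, TER),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$wt != pairs$var, ]
  got <- snv_indicator(pairs$wt, pairs$var)
  want <- mapply(oracle_snv, pairs$wt, pairs$var)
  expect_identical(unname(got), unname(want))
  # documented spot checks
  expect_true(snv_indicator("M", "I"))
  expect_false(snv_indicator("M", "P"))
  expect_error(snv_indicator("A", "A"), "wt_aa != var_aa")
})

test_that("embedding features expose wt, var and difference vectors", {
  prov <- small_provider()
  seqn <- "MKTAYIAKQR"
  ef <- embedding_features(prov, seqn, position = 4L, var_aa = "W")
  expect_length(ef$e_wt, prov$dim)
  expect_equal(ef$e_diff + ef$e_wt, ef$e_var)
  # identity probe: variant equal to wild type gives a zero difference
  same <- embedding_features(prov, seqn, position = 4L, var_aa = "A")
  expect_true(all(same$e_diff == 0))
  # determinism
  again <- embedding_features(prov, seqn, position = 4L, var_aa = "W")
  expect_identical(ef, again)
  expect_error(embedding_features(prov, seqn, 3L, TER), "Ter")
})

test_that("positional means aggregate training records only", {
  rec <- data.frame(
    protein_id = "P", position = c(1L, 2L, 2L),
    wt_aa = "A", var_aa = c("G", "S", "T"),
    norm_score = c(0.7, 0.2, 0.8), stringsAsFactors = FALSE
  )
  pm <- compute_positional_means(rec)
  expect_equal(pm$mean[pm$position == 1L], 0.7)
  expect_equal(pm$count[pm$position == 1L], 1L)
  expect_equal(pm$mean[pm$position == 2L], 0.5)
  expect_equal(pm$count[pm$position == 2L], 2L)
  # leakage-control probe: a sentinel in held-out records changes nothing
  held_out <- data.frame(protein_id = "P", position = 1L, wt_aa = "A",
                         var_aa = "V", norm_score = 999,
                         stringsAsFactors = FALSE)
  pm2 <- compute_positional_means(rec)
  expect_identical(pm, pm2)
  expect_false(any(pm$mean > 10))
  rm(held_out)
})

test_that("positional-mean maps merge by count weighting", {
  rec <- model_records(small_panel_sets()[[1]])
  half <- seq_len(nrow(rec)) <= nrow(rec) / 2
  merged <- merge_positional_means(
    compute_positional_means(rec[half, ]),
    compute_positional_means(rec[!half, ]))
  full <- compute_positional_means(rec)
  expect_equal(as.data.frame(merged), as.data.frame(full))
})

test_that("feature table schemas follow the preset definitions", {
  sets <- small_panel_sets()[1:2]
  prov <- small_provider()
  pm <- compute_positional_means(sets)
  tabs <- lapply(
    c("full", "full_minus_diff", "min", "mean_only", "no_embedding",
      "zero_shot_no_mean"),
    function(ps) suppressWarnings(
      assemble_feature_table(sets, ps, provider = prov,
                             positional_means = pm)))
  names(tabs) <- c("full", "full_minus_diff", "min", "mean_only",
                   "no_embedding", "zero_shot_no_mean")
  d <- prov$dim
  expect_identical(ncol(tabs$mean_only$x), 1L)
  expect_identical(colnames(tabs$mean_only$x), "posmean")
  expect_identical(ncol(tabs$full$x) - ncol(tabs$full_minus_diff$x), d)
  expect_identical(ncol(tabs$min$x), 1L + 3L * d)
  expect_false(any(grepl("emb", tabs$no_embedding$schema)))
  expect_false("posmean" %in% tabs$zero_shot_no_mean$schema)
  expect_true(all(grepl("^emb_diff", setdiff(tabs$full$schema,
                                             tabs$full_minus_diff$schema))))
  # row count equals the missense records with finite normalized scores
  expect_identical(nrow(tabs$full$x), nrow(model_records(sets)))
  # assembly is a pure function of its inputs
  again <- suppressWarnings(
    assemble_feature_table(sets, "full", provider = prov,
                           positional_means = pm))
  expect_identical(tabs$full$x, again$x)
  # missing embeddings provider fails for embedding presets
  expect_error(assemble_feature_table(sets, "min", positional_means = pm),
               "provider")
})

test_that("conservation scores join on mapped UniProt coordinates", {
  sets <- small_panel_sets()[1]
  sets[[1]]$offset <- 100L
  prov <- small_provider()
  rec <- model_records(sets)
  cons <- data.frame(protein_id = rec$protein_id[1],
                     uniprot_position = rec$position[1] + 100L,
                     var_aa = rec$var_aa[1], score = 0.42)
  tab <- assemble_feature_table(sets, "no_embedding",
                                positional_means = NULL,
                                conservation = cons)
  col <- tab$x[, "conservation"]
  expect_equal(col[1], 0.42)
  expect_true(all(is.na(col[-1])))
})
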