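test_that("hgvs_pro tokens parse to one-letter variant keys", {
  cases <- list(
    list(tok = "p.Gly5Ala", wt = "G", pos = 5L, var = "A"),
    list(tok = "p.Trp7Ter", wt = "W", pos = 7L, var = "*"),
    list(tok = "(p.Met1Lys)", wt = "M", pos = 1L, var = "K"),
    list(tok = "Arg100Gln", wt = "R", pos = 100L, var = "Q")
  )
  for (cs in cases) {
    parsed <- parse_hgvs_pro(cs$tok)
    expect_identical(parsed$wt_aa, cs$wt, info = cs$tok)
    expect_identical(parsed$position, cs$pos, info = cs$tok)
    expect_identical(parsed$var_aa, cs$var, info = cs$tok)
    expect_false(parsed$synonymous, info = cs$tok)
  }
})

test_that("synonymous and malformed tokens are handled distinctly", {
  expect_true(parse_hgvs_pro("p.Ala10Ala")$synonymous)
  expect_true(parse_hgvs_pro("p.(=)")$synonymous)
  expect_true(parse_hgvs_pro("p.Leu3=")$synonymous)
  expect_error(parse_hgvs_pro("p.Xyz5Ala"), "Xyz")
  expect_error(parse_hgvs_pro("garbage"), "malformed")
  expect_error(parse_hgvs_pro("p.Ter5Ala"), "malformed|Ter")
})

test_that("score-set construction validates records against the sequence", {
  set <- toy_score_set(normalized = FALSE)
  expect_s3_class(set, "dms_score_set")
  expect_identical(nrow(set$records), 8L)
  # wt mismatch with sequence
  bad <- toy_records()
  bad$wt_aa[1] <- "W"
  expect_error(dms_score_set("TOY1", bad, sequence = "MKT"), "mismatch")
  # position beyond sequence
  bad2 <- toy_records()
  bad2$position[1] <- 9L
  expect_error(dms_score_set("TOY1", bad2, sequence = "MKT"), "beyond")
  expect_error(dms_score_set("X", toy_records(), s_wt = 1, s_nons = 1),
               "anchors")
})

test_that("duplicate variant keys follow the configured policy", {
  rec <- toy_records()[c(1, 1, 2), ]
  rec$raw_score <- c(0.2, 0.4, 1.0)
  rec$sigma <- c(0.3, 0.4, 0.1)
  set_mean <- dms_score_set("D1", rec)
  m <- set_mean$records[set_mean$records$var_aa == "A", ]
  expect_equal(m$raw_score, 0.3)
  expect_equal(m$sigma, sqrt(mean(c(0.3, 0.4)^2)))
  set_first <- dms_score_set("D1", rec, duplicate_policy = "first")
  expect_equal(set_first$records$raw_score[
    set_first$records$var_aa == "A"], 0.2)
  expect_error(dms_score_set("D1", rec, duplicate_policy = "error"),
               "duplicate")
})

test_that("normalization anchors wild type at 1 and nonsense at 0", {
  set <- normalize_scores(toy_score_set(normalized = FALSE))
  rec <- set$records
  # explicit anchors: formula cases
  expect_equal(rec$norm_score[rec$raw_score == 0.05],
               (0.05 - 0) / 4 + 1)
  # direct substitution: s_wt = 0, s_nons = -2, s_dms = -1 -> 0.5
  one <- dms_score_set("Z", data.frame(position = 1L, wt_aa = "A",
                                       var_aa = "G", raw_score = -1),
                       s_wt = 0, s_nons = -2)
  expect_equal(normalize_scores(one)$records$norm_score, 0.5)
  # anchor identities
  expect_equal((set$s_wt - set$s_wt) / (set$s_wt - set$s_nons) + 1, 1)
  # sigma rescaled by 1/|gap|
  expect_equal(rec$sigma_norm, rec$sigma / 4)
  # derived anchors: mean of nonsense maps exactly to 0
  derived <- toy_score_set(normalized = FALSE)
  derived$s_wt <- NA_real_
  derived$s_nons <- NA_real_
  derived <- normalize_scores(derived, wt_anchor = 0)
  non <- derived$records$norm_score[derived$records$type == "nonsense"]
  expect_equal(mean(non), 0)
  # median option
  med <- toy_score_set(normalized = FALSE)
  med$s_nons <- NA_real_
  med <- normalize_scores(med, nonsense_stat = "median")
  expect_equal(med$s_nons, median(c(-4.1, -3.9)))
})

test_that("normalization round trip is exact", {
  set <- toy_score_set()
  back <- denormalize_scores(set$records$norm_score, set$s_wt, set$s_nons)
  expect_equal(back, set$records$raw_score, tolerance = 1e-12)
})

test_that("normalization errors are informative", {
  no_non <- dms_score_set("N1", data.frame(position = 1L, wt_aa = "A",
                                           var_aa = "G", raw_score = 1))
  expect_error(normalize_scores(no_non, wt_anchor = 0), "nonsense_anchor")
  expect_error(normalize_scores(no_non), "wt_anchor")
})

test_that("domain positions map to full-length coordinates and back", {
  expect_identical(map_position(1L, 0L), 1L)
  expect_identical(map_position(5L, 100L), 105L)
  expect_identical(map_position(map_position(7L, 30L) - 30L, 0L), 7L)
  expect_error(map_position(0L, 5L), ">= 1")
  expect_error(map_position(2L, -10L), "< 1")
})

test_that("score sets round-trip through both file dialects losslessly", {
  set <- toy_score_set(normalized = FALSE)
  for (fmt in c("mavedb_csv", "long_tsv")) {
    path <- tempfile(fileext = if (fmt == "mavedb_csv") ".csv" else ".tsv")
    write_score_set(set, path, fmt)
    back <- read_score_set(path, fmt, protein_id = "TOY1",
                           sequence = "MKT", s_wt = 0, s_nons = -4)
    expect_identical(back$records$position, set$records$position,
                     info = fmt)
    expect_identical(back$records$wt_aa, set$records$wt_aa, info = fmt)
    expect_identical(back$records$var_aa, set$records$var_aa, info = fmt)
    expect_equal(back$records$raw_score, set$records$raw_score, info = fmt)
    expect_equal(back$records$sigma, set$records$sigma, info = fmt)
    unlink(path)
  }
})

test_that("mavedb reader skips synonymous rows and counts them", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("# a comment", "hgvs_pro,score", "p.Met1Ala,-1.0",
               "p.(=),0.0", "p.Lys2Lys,0.1", "p.Lys2Ter,-4.0"), path)
  set <- read_score_set(path, "mavedb_csv", protein_id = "P1")
  # the position-less p.(=) row is skipped; the positioned synonymous
  # record is retained (it carries wild-type anchor information)
  expect_identical(nrow(set$records), 3L)
  expect_identical(sum(set$records$type == "synonymous"), 1L)
  expect_identical(attr(set, "skipped_synonymous"), 1L)
  unlink(path)
})

test_that("long_tsv reader enforces required columns", {
  path <- tempfile(fileext = ".tsv")
  writeLines("protein_id\tposition\twt_aa", path)
  expect_error(read_score_set(path, "long_tsv"), "missing required")
  unlink(path)
})
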