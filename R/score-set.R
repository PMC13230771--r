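#' Parse a protein HGVS substitution token
#'
#' Accepts MaveDB-style `hgvs_pro` tokens of the form `p.Gly5Ala` or
#' `p.Trp7Ter` (a `p.` prefix and surrounding parentheses are tolerated).
#' Three-letter codes are converted to one-letter codes; `Ter` becomes `"*"`.
#' Synonymous tokens (`p.(=)` or wild-type == variant) are flagged rather than
#' returned as variant keys.
#'
#' @param token character scalar, e.g. `"p.Gly5Ala"`.
#' @return A list with elements `wt_aa`, `position`, `var_aa`,
#'   `synonymous` (logical). For synonymous tokens only `synonymous = TRUE`
#'   (plus the parsed fields where present) is meaningful.
#' @examples
#' parse_hgvs_pro("p.Gly5Ala")
#' parse_hgvs_pro("p.Trp7Ter")
#' @export
parse_hgvs_pro <- function(token) {
  stopifnot(is.character(token), length(token) == 1L)
  raw <- token
  x <- gsub("[()]", "", trimws(token))
  x <- sub("^p\\.", "", x)
  if (x == "=" || x == "(=)") {
    return(list(wt_aa = NA_character_, position = NA_integer_,
                var_aa = NA_character_, synonymous = TRUE))
  }
  m <- regexec("^([A-Za-z]{3})([0-9]+)([A-Za-z]{3}|\\*|=)$", x)
  g <- regmatches(x, m)[[1]]
  if (length(g) != 4L) {
    stop("malformed hgvs_pro token: '", raw, "'", call. = FALSE)
  }
  wt <- unname(.AA3[g[2]])
  if (is.na(wt)) stop("malformed hgvs_pro token (unknown residue '",
                      g[2], "'): '", raw, "'", call. = FALSE)
  pos <- as.integer(g[3])
  var <- if (g[4] %in% c("*", "=")) {
    if (g[4] == "=") wt else TER
  } else {
    v <- unname(.AA3[g[4]])
    if (is.na(v)) stop("malformed hgvs_pro token (unknown residue '",
                       g[4], "'): '", raw, "'", call. = FALSE)
    v
  }
  if (wt == TER) stop("malformed hgvs_pro token (wild type cannot be Ter): '",
                      raw, "'", call. = FALSE)
  if (pos < 1L) stop("malformed hgvs_pro token (position < 1): '",
                     raw, "'", call. = FALSE)
  list(wt_aa = wt, position = pos, var_aa = var,
       synonymous = identical(wt, var))
}

record_type <- function(wt_aa, var_aa) {
  ifelse(var_aa == TER, "nonsense",
         ifelse(wt_aa == var_aa, "synonymous", "missense"))
}

variant_id <- function(protein_id, position, wt_aa, var_aa) {
  paste(protein_id, position, wt_aa, var_aa, sep = ":")
}

empty_records <- function() {
  data.frame(protein_id = character(), position = integer(),
             wt_aa = character(), var_aa = character(), type = character(),
             raw_score = numeric(), sigma = numeric(),
             norm_score = numeric(), sigma_norm = numeric(),
             stringsAsFactors = FALSE)
}

#' Construct a DMS score set
#'
#' A score set holds one protein domain's deep-mutational-scanning
#' measurements: a record per variant (missense, nonsense or synonymous) with
#' raw score, optional measurement uncertainty and, after
#' [normalize_scores()], a normalized score on the wild-type = 1 /
#' nonsense = 0 scale. Domain coordinates are 1-based; `offset` maps domain
#' position `i` to full-length (UniProt) position `i + offset`.
#'
#' @param protein_id character scalar identifier.
#' @param records data.frame with columns `position`, `wt_aa`, `var_aa`,
#'   `raw_score` and optionally `sigma` (uncertainty, `NA` allowed),
#'   `norm_score`, `sigma_norm`.
#' @param sequence optional domain amino-acid sequence; when supplied, every
#'   record's `wt_aa` is cross-checked against it.
#' @param offset integer; domain position 1 corresponds to UniProt position
#'   `1 + offset`.
#' @param s_wt,s_nons optional raw-score anchors (wild type, nonsense
#'   baseline) as determined by the study.
#' @param duplicate_policy how to resolve duplicated variant keys: `"mean"`
#'   (arithmetic mean of scores, root-mean-square of sigmas), `"first"`, or
#'   `"error"`.
#' @return An object of class `dms_score_set`.
#' @export
dms_score_set <- function(protein_id, records, sequence = NULL, offset = 0L,
                          s_wt = NA_real_, s_nons = NA_real_,
                          duplicate_policy = c("mean", "first", "error")) {
  duplicate_policy <- match.arg(duplicate_policy)
  stopifnot(is.character(protein_id), length(protein_id) == 1L,
            is.data.frame(records))
  need <- c("position", "wt_aa", "var_aa", "raw_score")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records missing column(s): ",
                         paste(miss, collapse = ", "))
  rec <- data.frame(
    protein_id = protein_id,
    position = as.integer(records$position),
    wt_aa = as.character(records$wt_aa),
    var_aa = as.character(records$var_aa),
    stringsAsFactors = FALSE
  )
  rec$type <- record_type(rec$wt_aa, rec$var_aa)
  rec$raw_score <- as.numeric(records$raw_score)
  rec$sigma <- if ("sigma" %in% names(records)) {
    as.numeric(records$sigma)
  } else NA_real_
  rec$norm_score <- if ("norm_score" %in% names(records)) {
    as.numeric(records$norm_score)
  } else NA_real_
  rec$sigma_norm <- if ("sigma_norm" %in% names(records)) {
    as.numeric(records$sigma_norm)
  } else NA_real_

  if (any(rec$position < 1L)) stop("record positions must be >= 1")
  bad_aa <- setdiff(unique(c(rec$wt_aa, rec$var_aa)), c(AMINO_ACIDS, TER))
  if (length(bad_aa)) stop("non-standard residue(s) in records: ",
                           paste(bad_aa, collapse = ", "))
  if (any(rec$wt_aa == TER)) stop("wild-type residue cannot be Ter")
  if (any(!is.na(rec$sigma) & rec$sigma < 0)) stop("sigma must be >= 0")

  # duplicate variant keys
  key <- variant_id(rec$protein_id, rec$position, rec$wt_aa, rec$var_aa)
  if (anyDuplicated(key)) {
    if (duplicate_policy == "error") {
      stop("duplicate variant keys: ",
           paste(unique(key[duplicated(key)]), collapse = ", "))
    } else if (duplicate_policy == "first") {
      rec <- rec[!duplicated(key), , drop = FALSE]
    } else {
      agg_mean <- function(v) {
        vapply(split(v, key), function(x) mean(x, na.rm = TRUE), 0)
      }
      first <- rec[!duplicated(key), , drop = FALSE]
      ord_key <- variant_id(first$protein_id, first$position,
                            first$wt_aa, first$var_aa)
      raw_m <- agg_mean(rec$raw_score)[ord_key]
      sig_m <- vapply(split(rec$sigma, key), function(x) {
        x <- x[!is.na(x)]
        if (!length(x)) NA_real_ else sqrt(mean(x^2))
      }, 0)[ord_key]
      first$raw_score <- unname(raw_m)
      first$sigma <- unname(sig_m)
      first$norm_score <- NA_real_
      first$sigma_norm <- NA_real_
      rec <- first
    }
    rec[is.nan(rec$raw_score), "raw_score"] <- NA_real_
  }

  sequence <- if (is.null(sequence)) NA_character_ else as.character(sequence)
  if (!is.na(sequence)) {
    if (any(rec$position > nchar(sequence))) {
      stop("record position beyond sequence length for ", protein_id)
    }
    seq_aa <- strsplit(sequence, "")[[1]]
    mism <- which(rec$wt_aa != seq_aa[rec$position])
    if (length(mism)) {
      stop("wild-type/sequence mismatch for ", protein_id, " at position(s) ",
           paste(utils::head(rec$position[mism], 10L), collapse = ", "))
    }
  }
  if (!is.na(s_wt) && !is.na(s_nons) && s_wt == s_nons) {
    stop("wild-type and nonsense anchors must differ")
  }
  rownames(rec) <- NULL
  structure(
    list(protein_id = protein_id, sequence = sequence,
         offset = as.integer(offset), records = rec,
         s_wt = as.numeric(s_wt), s_nons = as.numeric(s_nons)),
    class = "dms_score_set"
  )
}

#' @export
print.dms_score_set <- function(x, ...) {
  n <- table(factor(x$records$type,
                    levels = c("missense", "nonsense", "synonymous")))
  cat("DMS score set: ", x$protein_id,
      if (!is.na(x$sequence)) paste0(" (", nchar(x$sequence), " aa)"), "\n",
      sep = "")
  cat(sprintf("  records: %d missense, %d nonsense, %d synonymous\n",
              n[["missense"]], n[["nonsense"]], n[["synonymous"]]))
  cat(sprintf("  anchors: s_wt = %s, s_nons = %s; offset = %d\n",
              format(x$s_wt), format(x$s_nons), x$offset))
  if (any(!is.na(x$records$norm_score))) cat("  normalized: yes\n")
  invisible(x)
}

#' Map a domain position to a full-length (UniProt) position
#'
#' @param domain_pos integer vector of 1-based domain positions.
#' @param offset integer offset; the result is `domain_pos + offset`.
#' @export
map_position <- function(domain_pos, offset) {
  domain_pos <- as.integer(domain_pos)
  if (any(domain_pos < 1L)) stop("domain positions must be >= 1")
  out <- domain_pos + as.integer(offset)
  if (any(out < 1L)) stop("mapped position < 1 (offset too negative)")
  out
}

#' Read a DMS score set from disk
#'
#' Two dialects are supported. `mavedb_csv` is a MaveDB-style CSV with
#' columns `hgvs_pro`, `score` and optionally `score_sd`; lines starting with
#' `#` are ignored; synonymous rows (including `p.(=)`) are skipped and
#' counted. `long_tsv` is a tab-delimited long table with columns
#' `protein_id`, `position`, `wt_aa`, `var_aa`, `raw_score` and optionally
#' `score_sd`.
#'
#' @param path file path.
#' @param format `"mavedb_csv"` or `"long_tsv"`.
#' @param protein_id identifier (required for `mavedb_csv`; for `long_tsv`
#'   taken from the file when omitted, which must then contain one protein).
#' @param sequence,offset,s_wt,s_nons passed to [dms_score_set()].
#' @param duplicate_policy see [dms_score_set()].
#' @return A `dms_score_set`. The number of skipped synonymous rows is
#'   attached as attribute `"skipped_synonymous"`.
#' @export
read_score_set <- function(path, format = c("mavedb_csv", "long_tsv"),
                           protein_id = NULL, sequence = NULL, offset = 0L,
                           s_wt = NA_real_, s_nons = NA_real_,
                           duplicate_policy = "mean") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  n_skip <- 0L
  if (format == "mavedb_csv") {
    if (is.null(protein_id)) stop("protein_id is required for mavedb_csv")
    df <- utils::read.csv(path, comment.char = "#",
                          stringsAsFactors = FALSE)
    need <- c("hgvs_pro", "score")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("missing required column(s): ",
                           paste(miss, collapse = ", "))
    parsed <- lapply(df$hgvs_pro, parse_hgvs_pro)
    # positioned synonymous tokens (p.Ala10Ala) are retained as synonymous
    # records (they carry anchor information); position-less p.(=) rows
    # cannot become records and are skipped with a count
    positionless <- vapply(parsed, function(p) is.na(p$position), TRUE)
    n_skip <- sum(positionless)
    keep <- which(!positionless)
    records <- data.frame(
      position = vapply(parsed[keep], `[[`, 1L, "position"),
      wt_aa = vapply(parsed[keep], `[[`, "", "wt_aa"),
      var_aa = vapply(parsed[keep], `[[`, "", "var_aa"),
      raw_score = as.numeric(df$score[keep]),
      stringsAsFactors = FALSE
    )
    if ("score_sd" %in% names(df)) {
      records$sigma <- as.numeric(df$score_sd[keep])
    }
  } else {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("protein_id", "position", "wt_aa", "var_aa", "raw_score")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("missing required column(s): ",
                           paste(miss, collapse = ", "))
    ids <- unique(df$protein_id)
    if (is.null(protein_id)) {
      if (length(ids) != 1L) {
        stop("long_tsv contains multiple proteins; supply protein_id")
      }
      protein_id <- ids
    } else {
      df <- df[df$protein_id == protein_id, , drop = FALSE]
      if (!nrow(df)) stop("no rows for protein_id '", protein_id, "'")
    }
    records <- data.frame(
      position = df$position, wt_aa = df$wt_aa, var_aa = df$var_aa,
      raw_score = df$raw_score, stringsAsFactors = FALSE
    )
    if ("score_sd" %in% names(df)) records$sigma <- as.numeric(df$score_sd)
  }
  out <- dms_score_set(protein_id, records, sequence = sequence,
                       offset = offset, s_wt = s_wt, s_nons = s_nons,
                       duplicate_policy = duplicate_policy)
  attr(out, "skipped_synonymous") <- n_skip
  out
}

#' Write a DMS score set to disk
#'
#' Inverse of [read_score_set()] for both dialects; a round trip preserves
#' all record fields.
#'
#' @param score_set a `dms_score_set`.
#' @param path output file.
#' @param format `"mavedb_csv"` or `"long_tsv"`.
#' @export
write_score_set <- function(score_set, path,
                            format = c("mavedb_csv", "long_tsv")) {
  format <- match.arg(format)
  rec <- score_set$records
  if (format == "mavedb_csv") {
    df <- data.frame(
      hgvs_pro = paste0("p.", aa_to_three(rec$wt_aa), rec$position,
                        aa_to_three(rec$var_aa)),
      score = rec$raw_score, stringsAsFactors = FALSE
    )
    if (any(!is.na(rec$sigma))) df$score_sd <- rec$sigma
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    df <- data.frame(
      protein_id = rec$protein_id, position = rec$position,
      wt_aa = rec$wt_aa, var_aa = rec$var_aa, raw_score = rec$raw_score,
      stringsAsFactors = FALSE
    )
    if (any(!is.na(rec$sigma))) df$score_sd <- rec$sigma
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}

#' Normalize raw DMS scores to the wild-type/nonsense scale
#'
#' Rescales raw scores so the wild-type anchor maps to 1 and the nonsense
#' (loss-of-function) anchor maps to 0:
#' `s_norm = (s_raw - s_wt) / (s_wt - s_nons) + 1`.
#' Values outside `[0, 1]` are preserved. Per-variant uncertainties are
#' rescaled by the same factor `1 / |s_wt - s_nons|`.
#'
#' Anchor precedence: explicit arguments, then anchors stored on the score
#' set, then derivation from the data (wild type from the mean of synonymous
#' records; nonsense from the mean -- or median, see `nonsense_stat` -- of
#' nonsense records).
#'
#' @param score_set a `dms_score_set`.
#' @param wt_anchor,nonsense_anchor optional explicit raw-score anchors.
#' @param nonsense_stat statistic used when deriving the nonsense anchor from
#'   nonsense records: `"mean"` (default) or `"median"`.
#' @return The score set with `norm_score`/`sigma_norm` filled and anchors
#'   recorded in `s_wt`/`s_nons`.
#' @export
normalize_scores <- function(score_set, wt_anchor = NULL,
                             nonsense_anchor = NULL,
                             nonsense_stat = c("mean", "median")) {
  nonsense_stat <- match.arg(nonsense_stat)
  rec <- score_set$records
  s_wt <- if (!is.null(wt_anchor)) as.numeric(wt_anchor) else score_set$s_wt
  if (is.na(s_wt)) {
    syn <- rec$raw_score[rec$type == "synonymous" & !is.na(rec$raw_score)]
    if (!length(syn)) {
      stop("no wild-type anchor: supply wt_anchor explicitly ",
           "(no synonymous records to derive it from)")
    }
    s_wt <- mean(syn)
  }
  s_nons <- if (!is.null(nonsense_anchor)) {
    as.numeric(nonsense_anchor)
  } else score_set$s_nons
  if (is.na(s_nons)) {
    non <- rec$raw_score[rec$type == "nonsense" & !is.na(rec$raw_score)]
    if (!length(non)) {
      stop("no nonsense anchor: supply nonsense_anchor explicitly ",
           "(no nonsense records to derive it from)")
    }
    s_nons <- if (nonsense_stat == "mean") mean(non) else stats::median(non)
  }
  gap <- s_wt - s_nons
  if (gap == 0) stop("anchor gap is zero (s_wt == s_nons)")
  rec$norm_score <- (rec$raw_score - s_wt) / gap + 1
  rec$sigma_norm <- rec$sigma / abs(gap)
  score_set$records <- rec
  score_set$s_wt <- s_wt
  score_set$s_nons <- s_nons
  score_set
}

#' Invert score normalization
#'
#' @param norm_score numeric vector of normalized scores.
#' @param s_wt,s_nons the anchors used for normalization.
#' @return Raw scores such that [normalize_scores()] reproduces
#'   `norm_score`.
#' @export
denormalize_scores <- function(norm_score, s_wt, s_nons) {
  (norm_score - 1) * (s_wt - s_nons) + s_wt
}

#' Extract model-ready records from score sets
#'
#' Returns the missense records with a finite normalized score across one or
#' more score sets -- the rows that enter feature tables and partitions.
#' Synonymous and nonsense records are excluded (they anchor normalization
#' and count toward completeness but are never model rows).
#'
#' @param score_sets a `dms_score_set` or list of them.
#' @return A records data.frame.
#' @export
model_records <- function(score_sets) {
  if (inherits(score_sets, "dms_score_set")) score_sets <- list(score_sets)
  rec <- do.call(rbind, lapply(score_sets, function(s) s$records))
  rec <- rec[rec$type == "missense" & !is.na(rec$norm_score), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}
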