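#' @keywords internal
"_PACKAGE"

#' The 20 standard amino acids (one-letter codes)
#'
#' Order is fixed (alphabetical) and used throughout the package for
#' deterministic iteration, one-hot encodings and tie-breaking.
#'
#' @export
AMINO_ACIDS <- sort(c(
  "A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
  "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V"
))

#' Stop (termination) symbol used for nonsense variants
#' @export
TER <- "*"

# three-letter <-> one-letter lookup; "Ter" maps to "*"
.AA3 <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V", Ter = "*"
)
.AA1TO3 <- stats::setNames(names(.AA3), unname(.AA3))

#' Physicochemical amino-acid property table
#'
#' One row per standard amino acid. Numeric columns are classical biochemical
#' descriptors (molecular weight in Da; pKa of the alpha-carboxyl and
#' alpha-amino groups; isoelectric point; Kyte-Doolittle hydropathy index;
#' residue volume in cubic Angstroms). Logical columns flag side-chain
#' hydrogen-bonding capability and aromaticity. The two factor columns give a
#' coarse chemical-group classification and the charge class at physiological
#' pH; these are one-hot encoded when used as model features.
#'
#' @return A data.frame with 20 rows (rownames = one-letter codes).
#' @export
aa_property_table <- function() {
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  tab <- data.frame(
    aa = aa,
    mol_weight = c(89.09, 174.20, 132.12, 133.10, 121.16, 146.15, 147.13,
                   75.07, 155.16, 131.17, 131.17, 146.19, 149.21, 165.19,
                   115.13, 105.09, 119.12, 204.23, 181.19, 117.15),
    pka_carboxyl = c(2.34, 2.17, 2.02, 1.88, 1.96, 2.17, 2.19, 2.34, 1.82,
                     2.36, 2.36, 2.18, 2.28, 1.83, 1.99, 2.21, 2.09, 2.83,
                     2.20, 2.32),
    pka_amino = c(9.69, 9.04, 8.80, 9.60, 10.28, 9.13, 9.67, 9.60, 9.17,
                  9.60, 9.60, 8.95, 9.21, 9.13, 10.60, 9.15, 9.10, 9.39,
                  9.11, 9.62),
    isoelectric_point = c(6.01, 10.76, 5.41, 2.77, 5.07, 5.65, 3.22, 5.97,
                          7.59, 6.02, 5.98, 9.74, 5.74, 5.48, 6.48, 5.68,
                          5.60, 5.89, 5.66, 5.97),
    hydropathy = c(1.8, -4.5, -3.5, -3.5, 2.5, -3.5, -3.5, -0.4, -3.2, 4.5,
                   3.8, -3.9, 1.9, 2.8, -1.6, -0.8, -0.7, -0.9, -1.3, 4.2),
    volume = c(88.6, 173.4, 114.1, 111.1, 108.5, 143.8, 138.4, 60.1, 153.2,
               166.7, 166.7, 168.6, 162.9, 189.9, 112.7, 89.0, 116.1, 227.8,
               193.6, 140.0),
    hbond = c(FALSE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE, TRUE, FALSE,
              FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE, TRUE,
              FALSE),
    aromatic = aa %in% c("F", "W", "Y", "H"),
    chemical_group = c("aliphatic", "positive", "amide", "negative",
                       "sulfur", "amide", "negative", "aliphatic",
                       "positive", "aliphatic", "aliphatic", "positive",
                       "sulfur", "aromatic", "aliphatic", "hydroxyl",
                       "hydroxyl", "aromatic", "aromatic", "aliphatic"),
    charge_class = c("neutral", "positive", "neutral", "negative", "neutral",
                     "neutral", "negative", "neutral", "positive", "neutral",
                     "neutral", "positive", "neutral", "neutral", "neutral",
                     "neutral", "neutral", "neutral", "neutral", "neutral"),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- tab$aa
  tab[order(tab$aa), , drop = FALSE]
}

# residue coordinates on a unit scale: Kyte-Doolittle hydropathy and volume.
# Used by the synthetic generator as the two-dimensional severity space.
aa_unit_coords <- function() {
  p <- aa_property_table()
  m <- cbind(
    hydropathy = (p$hydropathy + 4.5) / 9,
    volume = (p$volume - min(p$volume)) / (max(p$volume) - min(p$volume))
  )
  rownames(m) <- p$aa
  m
}

aa_index <- function(aa) {
  i <- match(aa, AMINO_ACIDS)
  if (anyNA(i)) {
    stop("non-standard amino acid(s): ",
         paste(unique(aa[is.na(i)]), collapse = ", "))
  }
  i
}

aa_to_three <- function(aa) {
  out <- .AA1TO3[aa]
  if (anyNA(out)) stop("cannot convert to three-letter code: ",
                       paste(unique(aa[is.na(out)]), collapse = ", "))
  unname(out)
}

# run `expr` under a fixed RNG seed without disturbing the caller's stream
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# derive a bounded child seed from a master seed and an index (< 2^31)
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 2654435761 + as.double(index) * 40503) %%
               2147483587) + 1L
}
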