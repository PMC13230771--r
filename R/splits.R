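new_partition <- function(strategy, params, train, test, seed = NA_integer_) {
  if (!length(train) || !length(test)) {
    stop("strategy '", strategy, "' produced an empty train or test side")
  }
  if (length(intersect(train, test))) {
    stop("internal error: train/test overlap in strategy ", strategy)
  }
  structure(list(strategy = strategy, params = params,
                 train = sort(train), test = sort(test),
                 seed = seed),
            class = "dms_partition")
}

#' @export
print.dms_partition <- function(x, ...) {
  cat(sprintf("partition [%s]: %d train / %d test\n",
              x$strategy, length(x$train), length(x$test)))
  invisible(x)
}

#' Split strategies
#'
#' Names accepted by [make_partition()]:
#' `random_ratio` (variant-level split by ratio within each protein),
#' `leave_protein_out_ratio` (whole proteins split by ratio),
#' `lopo` (one partition per protein, that protein as test),
#' `lposo_ratio` (positions split by ratio within each protein; all variants
#' at a position land on the same side),
#' `loposo` (one partition per (protein, position); train = the same
#' protein's other variants),
#' `lovaro` (one partition per variant; train = the same protein's other
#' variants),
#' `snv_only` (train = SNV-reachable substitutions, test = the rest),
#' `substitution_whitelist` (train = variants whose substituted residue is
#' in the whitelist, default H/E/N/I/G -- one representative per
#' physicochemical class).
#' @return Character vector of strategy names.
#' @export
split_strategies <- function() {
  c("random_ratio", "leave_protein_out_ratio", "lopo", "lposo_ratio",
    "loposo", "lovaro", "snv_only", "substitution_whitelist")
}

#' Build a train/test partition (or list of partitions)
#'
#' @param keys data.frame of variant keys with columns `protein_id`,
#'   `position`, `wt_aa`, `var_aa` (e.g. the `keys` element of a feature
#'   table, or `model_records()` output).
#' @param strategy one of [split_strategies()].
#' @param params strategy parameters: `ratio` (train fraction, in (0,1)) for
#'   the ratio strategies; `whitelist` for `substitution_whitelist`;
#'   `protein` to restrict `loposo`/`lovaro` to one protein.
#' @param seed integer seed for the randomized strategies.
#' @return A `dms_partition` (train/test as integer row indices into `keys`)
#'   for the single-split strategies, or a list of partitions (class
#'   `dms_partition_list`) for `lopo`, `loposo` and `lovaro`.
#' @export
make_partition <- function(keys, strategy, params = list(), seed = 1L) {
  strategy <- match.arg(strategy, split_strategies())
  stopifnot(is.data.frame(keys),
            all(c("protein_id", "position", "wt_aa", "var_aa") %in%
                  names(keys)))
  n <- nrow(keys)
  idx <- seq_len(n)
  ratio <- params$ratio
  check_ratio <- function() {
    if (is.null(ratio) || ratio <= 0 || ratio >= 1) {
      stop("strategy '", strategy,
           "' requires params$ratio in (0, 1)")
    }
  }
  as_list <- function(parts) {
    structure(parts, class = "dms_partition_list")
  }

  if (strategy == "random_ratio") {
    check_ratio()
    train <- integer()
    with_seed(seed, {
      for (pid in unique(keys$protein_id)) {
        rows <- idx[keys$protein_id == pid]
        k <- round(ratio * length(rows))
        k <- min(max(k, 1L), length(rows) - 1L)
        train <- c(train, sample(rows, k))
      }
    })
    new_partition(strategy, list(ratio = ratio), train, setdiff(idx, train),
                  seed)
  } else if (strategy == "leave_protein_out_ratio") {
    check_ratio()
    prot <- unique(keys$protein_id)
    if (length(prot) < 2L) {
      stop("leave_protein_out_ratio requires >= 2 proteins")
    }
    with_seed(seed, {
      k <- round(ratio * length(prot))
      k <- min(max(k, 1L), length(prot) - 1L)
      train_prot <- sample(prot, k)
    })
    train <- idx[keys$protein_id %in% train_prot]
    new_partition(strategy, list(ratio = ratio, train_proteins = train_prot),
                  train, setdiff(idx, train), seed)
  } else if (strategy == "lopo") {
    prot <- unique(keys$protein_id)
    if (length(prot) < 2L) stop("lopo requires >= 2 proteins")
    as_list(lapply(prot, function(pid) {
      test <- idx[keys$protein_id == pid]
      new_partition("lopo", list(held_out_protein = pid),
                    setdiff(idx, test), test, seed)
    }))
  } else if (strategy == "lposo_ratio") {
    check_ratio()
    train <- integer()
    with_seed(seed, {
      for (pid in unique(keys$protein_id)) {
        rows <- idx[keys$protein_id == pid]
        pos <- unique(keys$position[rows])
        k <- round(ratio * length(pos))
        k <- min(max(k, 1L), length(pos) - 1L)
        if (length(pos) < 2L) {
          stop("lposo_ratio: protein ", pid, " has a single position")
        }
        train_pos <- sample(pos, k)
        train <- c(train, rows[keys$position[rows] %in% train_pos])
      }
    })
    new_partition(strategy, list(ratio = ratio), train, setdiff(idx, train),
                  seed)
  } else if (strategy == "loposo") {
    rows_scope <- if (!is.null(params$protein)) {
      idx[keys$protein_id == params$protein]
    } else idx
    combos <- unique(keys[rows_scope, c("protein_id", "position")])
    as_list(lapply(seq_len(nrow(combos)), function(i) {
      pid <- combos$protein_id[i]
      pos <- combos$position[i]
      same_prot <- idx[keys$protein_id == pid]
      test <- same_prot[keys$position[same_prot] == pos]
      new_partition("loposo",
                    list(held_out_protein = pid, held_out_position = pos),
                    setdiff(same_prot, test), test, seed)
    }))
  } else if (strategy == "lovaro") {
    rows_scope <- if (!is.null(params$protein)) {
      idx[keys$protein_id == params$protein]
    } else idx
    as_list(lapply(rows_scope, function(i) {
      pid <- keys$protein_id[i]
      same_prot <- idx[keys$protein_id == pid]
      new_partition("lovaro",
                    list(held_out_variant = variant_id(
                      pid, keys$position[i], keys$wt_aa[i], keys$var_aa[i])),
                    setdiff(same_prot, i), i, seed)
    }))
  } else if (strategy == "snv_only") {
    is_snv <- snv_indicator(keys$wt_aa, keys$var_aa)
    new_partition(strategy, list(), idx[is_snv], idx[!is_snv], seed)
  } else {  # substitution_whitelist
    whitelist <- params$whitelist
    if (is.null(whitelist)) whitelist <- c("H", "E", "N", "I", "G")
    in_wl <- keys$var_aa %in% whitelist
    new_partition(strategy, list(whitelist = whitelist),
                  idx[in_wl], idx[!in_wl], seed)
  }
}

#' @export
print.dms_partition_list <- function(x, ...) {
  cat(sprintf("%d partitions [%s]\n", length(x),
              if (length(x)) x[[1L]]$strategy else "?"))
  invisible(x)
}
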