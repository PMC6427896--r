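# Readers and writers for count tables, pair maps, length tables and
# screen results. All files are plain tab-separated text with a header row.

#' Read an htseq-count style count table
#'
#' Column 1 holds gene identifiers; every remaining column is one
#' replicate's integer counts. htseq-count summary rows (ids starting with
#' `__`, e.g. `__no_feature`) are dropped with a message. Sequencing depths
#' default to column totals divided by 1e6 (millions of mapped reads);
#' supply `depths` explicitly when the table is pre-filtered to homeologs,
#' since only whole-library totals estimate depth correctly.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param condition Condition label attached to the result.
#' @param depths Optional explicit per-replicate depths (millions of
#'   mapped reads), overriding the column-total default.
#' @return A list with `counts` (integer matrix, genes x replicates, gene
#'   ids as rownames), `depths`, `condition`, and `dropped` (excluded
#'   summary-row ids).
#' @export
read_count_table <- function(path, condition = "", depths = NULL) {
  if (!file.exists(path)) stop("count table not found: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2L) stop("count table needs a gene id column plus counts: ",
                           path)
  ids <- as.character(tab[[1L]])
  special <- startsWith(ids, "__")
  dropped <- ids[special]
  if (length(dropped) > 0L)
    message("dropping ", length(dropped), " special row(s): ",
            paste(dropped, collapse = ", "))
  tab <- tab[!special, , drop = FALSE]
  ids <- ids[!special]
  if (anyDuplicated(ids))
    stop("duplicate gene ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  if (anyNA(mat) || any(mat < 0) || any(mat != floor(mat)))
    stop("counts must parse as non-negative integers: ", path)
  storage.mode(mat) <- "integer"
  rownames(mat) <- ids
  if (is.null(depths)) {
    depths <- colSums(mat) / 1e6
    if (any(depths <= 0))
      stop("a replicate column has zero total reads; supply depths explicitly")
  } else {
    depths <- as.numeric(depths)
    if (length(depths) != ncol(mat) || any(depths <= 0) || anyNA(depths))
      stop("depths must be one positive value per replicate column")
  }
  list(counts = mat, depths = depths, condition = condition,
       dropped = dropped)
}

#' Read a homeolog pair map
#'
#' Two tab-separated columns: the gene id of homeolog A (the reference)
#' and of homeolog B. No gene may appear in two pairs.
#'
#' @param path Path to the file (header row expected).
#' @return A data frame with columns `id_a` and `id_b`.
#' @export
read_pair_map <- function(path) {
  if (!file.exists(path)) stop("pair map not found: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2L) stop("pair map needs two id columns: ", path)
  out <- data.frame(id_a = as.character(tab[[1L]]),
                    id_b = as.character(tab[[2L]]),
                    stringsAsFactors = FALSE)
  all_ids <- c(out$id_a, out$id_b)
  if (anyDuplicated(all_ids))
    stop("gene(s) appear in more than one pair: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  out
}

#' Read a gene length table
#'
#' Two tab-separated columns: gene id and length in kilobases.
#'
#' @param path Path to the file (header row expected).
#' @return A named numeric vector of lengths (kb), names are gene ids.
#' @export
read_length_table <- function(path) {
  if (!file.exists(path)) stop("length table not found: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(tab) < 2L) stop("length table needs id and length columns: ", path)
  len <- as.numeric(tab[[2L]])
  if (anyNA(len) || any(len <= 0))
    stop("lengths must be positive (kilobases): ", path)
  stats::setNames(len, as.character(tab[[1L]]))
}

#' Join counts, pair map and lengths into screen-ready records
#'
#' Builds one record per pair with a [homeolog_pair] and one [count_set]
#' per supplied condition. Pairs with either gene missing from any count
#' table or the length table are dropped with a warning.
#'
#' @param pair_map Data frame from [read_pair_map].
#' @param lengths Named length vector (kb) from [read_length_table].
#' @param ... One or two named count-table lists from [read_count_table];
#'   with one, records carry `counts`; with two, `counts_1` and `counts_2`.
#' @return A list of records for [run_heb_screen] or [run_dheb_screen].
#' @export
assemble_pairs <- function(pair_map, lengths, ...) {
  conds <- list(...)
  if (length(conds) < 1L || length(conds) > 2L)
    stop("supply one or two count tables")
  keep <- rep(TRUE, nrow(pair_map))
  for (i in seq_len(nrow(pair_map))) {
    ids <- c(pair_map$id_a[i], pair_map$id_b[i])
    ok <- all(ids %in% names(lengths)) &&
      all(vapply(conds, function(cc) all(ids %in% rownames(cc$counts)),
                 logical(1)))
    if (!ok) {
      warning("dropping pair ", ids[1L], "/", ids[2L],
              ": gene missing from counts or lengths", call. = FALSE)
      keep[i] <- FALSE
    }
  }
  pair_map <- pair_map[keep, , drop = FALSE]
  if (nrow(pair_map) == 0L) stop("no pairs left after joining inputs")
  lapply(seq_len(nrow(pair_map)), function(i) {
    ida <- pair_map$id_a[i]; idb <- pair_map$id_b[i]
    rec <- list(pair = homeolog_pair(ida, idb, lengths[[ida]], lengths[[idb]]))
    sets <- lapply(conds, function(cc) {
      count_set(cc$counts[ida, ], cc$counts[idb, ],
                depths = cc$depths, condition = cc$condition)
    })
    if (length(sets) == 1L) rec$counts <- sets[[1L]]
    else { rec$counts_1 <- sets[[1L]]; rec$counts_2 <- sets[[2L]] }
    rec
  })
}

#' Write and read a screen results table
#'
#' Tab-separated, one row per input pair in input order, numeric columns
#' serialized at 6 significant digits so that write-read-write round trips
#' are byte-identical.
#'
#' @param results A data frame from [run_heb_screen] or [run_dheb_screen].
#' @param path Output path.
#' @return `write_results_table` returns `path` invisibly;
#'   `read_results_table` returns the data frame.
#' @export
write_results_table <- function(results, path) {
  out <- results
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) signif(x, 6))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_table
#' @export
read_results_table <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  # blank note fields (no remark) come back as NA; restore ""
  if ("note" %in% names(tab)) {
    tab$note <- as.character(tab$note)
    tab$note[is.na(tab$note)] <- ""
  }
  tab
}
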