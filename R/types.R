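#' Homeolog pair descriptor
#'
#' Bundles the identifiers and lengths of a pair of homeologous genes, A
#' (the reference homeolog) and B. Lengths are total exonic length in
#' kilobases, the RPKM convention.
#'
#' @param id_a,id_b Gene identifiers (distinct, non-empty strings).
#' @param length_a,length_b Gene lengths in kilobases (positive).
#' @return An object of class `"homeolog_pair"`.
#' @examples
#' homeolog_pair("MlA.001", "MlB.001", 1.5, 1.42)
#' @export
homeolog_pair <- function(id_a, id_b, length_a, length_b) {
  stopifnot(is.character(id_a) || is.factor(id_a),
            is.character(id_b) || is.factor(id_b))
  id_a <- as.character(id_a); id_b <- as.character(id_b)
  if (length(id_a) != 1L || length(id_b) != 1L || !nzchar(id_a) || !nzchar(id_b))
    stop("gene ids must be single non-empty strings")
  if (identical(id_a, id_b))
    stop("homeolog ids must differ: ", id_a)
  length_a <- as.numeric(length_a); length_b <- as.numeric(length_b)
  if (!is.finite(length_a) || !is.finite(length_b) ||
      length_a <= 0 || length_b <= 0)
    stop("gene lengths must be positive and finite (kilobases)")
  structure(list(id_a = id_a, id_b = id_b,
                 length_a = length_a, length_b = length_b),
            class = "homeolog_pair")
}

#' Replicated homeolog read counts for one condition
#'
#' Holds the per-replicate read counts of both homeologs together with the
#' sequencing depth of each replicate. Depths are in millions of mapped
#' reads; only their values relative to the expression-level units matter,
#' so any consistent scale works.
#'
#' @param counts_a,counts_b Non-negative integer vectors of equal length,
#'   one count per replicate for homeologs A and B.
#' @param depths Positive numeric vector of per-replicate sequencing depths,
#'   recycled from length 1.
#' @param condition Optional condition label.
#' @return An object of class `"count_set"`.
#' @examples
#' count_set(c(12L, 30L, 8L), c(25L, 61L, 20L), depths = c(1.2, 2.1, 0.8))
#' @export
count_set <- function(counts_a, counts_b, depths = 1, condition = "") {
  check_counts <- function(x, what) {
    if (length(x) < 1L || anyNA(x) || any(x < 0) || any(x != floor(x)))
      stop(what, " must be non-negative integers")
    as.numeric(x)
  }
  counts_a <- check_counts(counts_a, "counts_a")
  counts_b <- check_counts(counts_b, "counts_b")
  if (length(counts_a) != length(counts_b))
    stop("counts_a and counts_b must have one entry per replicate")
  n <- length(counts_a)
  depths <- as.numeric(depths)
  if (length(depths) == 1L) depths <- rep(depths, n)
  if (length(depths) != n)
    stop("depths must match the number of replicates")
  if (anyNA(depths) || any(depths <= 0) || any(!is.finite(depths)))
    stop("depths must be positive and finite")
  structure(list(counts_a = counts_a, counts_b = counts_b,
                 depths = depths, condition = as.character(condition)[1L]),
            class = "count_set")
}

#' @export
print.homeolog_pair <- function(x, ...) {
  cat(sprintf("homeolog pair: A=%s (%.3g kb)  B=%s (%.3g kb)\n",
              x$id_a, x$length_a, x$id_b, x$length_b))
  invisible(x)
}

#' @export
print.count_set <- function(x, ...) {
  cat(sprintf("count set (%s): %d replicates\n",
              if (nzchar(x$condition)) x$condition else "unlabelled",
              length(x$counts_a)))
  cat("  A:", paste(x$counts_a, collapse = " "), "\n")
  cat("  B:", paste(x$counts_b, collapse = " "), "\n")
  cat("  depth:", paste(signif(x$depths, 4), collapse = " "), "\n")
  invisible(x)
}

# internal: recycle a dispersion spec (scalar or per-replicate vector) to n
# replicates and validate positivity.
check_dispersion <- function(r, n) {
  r <- as.numeric(r)
  if (length(r) == 1L) r <- rep(r, n)
  if (length(r) != n)
    stop("dispersion r must be a scalar or one value per replicate")
  if (anyNA(r) || any(r <= 0) || any(!is.finite(r)))
    stop("dispersion r must be positive and finite")
  r
}
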