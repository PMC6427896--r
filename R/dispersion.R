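# Per-replicate aggregation (overdispersion) estimation.
#
# With few replicates, per-gene dispersion estimation is hopeless; instead a
# single aggregation parameter r is fitted per replicate from the
# mean-variance relation var = mu + mu^2/r pooled across all genes, after
# rescaling every replicate's counts to the target replicate's depth.

# r is clamped to [1/PHI_MAX, 1/PHI_MIN]; phi = 1/r is the fitted quantity.
PHI_MIN <- 1e-8
PHI_MAX <- 1e3

#' Rescale a count matrix to one replicate's sequencing depth
#'
#' Produces the auxiliary data `y[j, i] = (d_k / d_i) * x[j, i]`: the counts
#' every replicate would have shown had it been sequenced at the depth of
#' replicate `k`. Only depth ratios enter, so the depth units cancel.
#'
#' @param counts Numeric matrix of non-negative counts, genes in rows,
#'   replicates in columns.
#' @param depths Positive per-replicate depths (one per column).
#' @param k Index of the target replicate.
#' @return A numeric matrix of the same shape as `counts`.
#' @export
rescale_to_depth <- function(counts, depths, k) {
  counts <- as.matrix(counts)
  depths <- as.numeric(depths)
  if (ncol(counts) != length(depths))
    stop("need one depth per replicate column")
  if (any(depths <= 0) || anyNA(depths))
    stop("depths must be positive")
  if (length(k) != 1L || k < 1 || k > length(depths) || k != floor(k))
    stop("k must be a valid replicate index")
  sweep(counts, 2L, depths[k] / depths, `*`)
}

#' Per-gene mean and variance across replicates
#'
#' @param rescaled Numeric matrix, genes in rows, replicates (>= 2) in
#'   columns, typically from [rescale_to_depth].
#' @return A data frame with columns `mu` (per-gene mean) and `var`
#'   (per-gene sample variance, divisor n - 1).
#' @export
mean_var_by_gene <- function(rescaled) {
  rescaled <- as.matrix(rescaled)
  if (ncol(rescaled) < 2L)
    stop("variance needs at least 2 replicates")
  data.frame(mu = rowMeans(rescaled),
             var = apply(rescaled, 1L, var))
}

#' Fit the aggregation parameter from a mean-variance table
#'
#' Finds the `r` minimizing `sum_j (var_j - mu_j - mu_j^2 / r)^2`. The
#' objective is nonlinear in `r` but linear in `phi = 1/r`, giving the
#' closed-form least squares solution
#' `phi = sum(mu^2 * (var - mu)) / sum(mu^4)`. `phi` is clamped to
#' `[1e-8, 1e3]` (`r` in `[1e-3, 1e8]`) so that underdispersed or
#' pathological tables yield a finite, effectively-Poisson (or extremely
#' overdispersed) `r` rather than a sign flip; clamping is reported with a
#' message.
#'
#' @param mu Per-gene means (at least two must be positive), or a data frame
#'   with columns `mu` and `var` as from [mean_var_by_gene].
#' @param var Per-gene variances (ignored when `mu` is a data frame).
#' @return The fitted aggregation parameter `r` (positive scalar).
#' @export
fit_aggregation <- function(mu, var = NULL) {
  if (is.data.frame(mu)) {
    var <- mu$var
    mu <- mu$mu
  }
  if (length(mu) != length(var))
    stop("mu and var must have equal length")
  keep <- is.finite(mu) & is.finite(var) & mu > 0
  mu <- mu[keep]; var <- var[keep]
  if (length(mu) < 2L)
    stop("need at least 2 genes with positive mean to fit aggregation")
  phi <- sum(mu^2 * (var - mu)) / sum(mu^4)
  if (phi < PHI_MIN || phi > PHI_MAX) {
    phi_c <- min(max(phi, PHI_MIN), PHI_MAX)
    message(sprintf(
      "aggregation fit clamped: phi = %.3g -> %.3g (r = %.3g)",
      phi, phi_c, 1 / phi_c))
    phi <- phi_c
  }
  1 / phi
}

#' Estimate per-replicate aggregation parameters
#'
#' For each replicate `k`, rescales all replicates to `k`'s depth, computes
#' per-gene means and variances, and fits the negative binomial
#' mean-variance relation by least squares ([fit_aggregation]). Rows with
#' zero mean are dropped inside the fit (they carry no mean-variance
#' information). Conditions should be processed separately, one call per
#' condition.
#'
#' @param counts Numeric matrix of non-negative counts, genes (individual
#'   homeologs) in rows, replicates in columns.
#' @param depths Positive per-replicate depths; equal depths make the
#'   rescaling the identity, so all replicates then share one `r`.
#' @return Numeric vector of fitted `r`, one per replicate.
#' @examples
#' set.seed(1)
#' x <- matrix(rnbinom(500 * 3, mu = 100, size = 10), ncol = 3)
#' estimate_dispersions(x, depths = c(1, 1, 1))
#' @export
estimate_dispersions <- function(counts, depths = rep(1, ncol(counts))) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L)
    stop("aggregation estimation needs at least 2 replicates")
  vapply(seq_len(ncol(counts)), function(k) {
    fit_aggregation(mean_var_by_gene(rescale_to_depth(counts, depths, k)))
  }, numeric(1))
}
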