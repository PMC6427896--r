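#' Negative binomial log probability mass
#'
#' Log pmf of the negative binomial distribution in the mean/aggregation
#' parameterization used throughout the package:
#' `f(x; mu, r) = Gamma(r+x)/(Gamma(r) x!) * (mu/(mu+r))^x * (r/(mu+r))^r`.
#' The aggregation parameter `r` sets the overdispersion through the
#' mean-variance relation `var = mu + mu^2/r`; `r -> Inf` recovers the
#' Poisson distribution. All arithmetic uses `lgamma`, never `gamma`, so
#' large counts do not overflow.
#'
#' @param x Non-negative integer count(s).
#' @param mu Positive mean(s).
#' @param r Positive aggregation parameter(s).
#' @return Log probability mass, vectorized over the arguments.
#' @examples
#' nb_logpmf(0, 10, 10)   # = 10 * log(0.5)
#' sum(exp(nb_logpmf(0:2000, 50, 10)))  # ~ 1
#' @export
nb_logpmf <- function(x, mu, r) {
  if (anyNA(x) || any(x < 0) || any(x != floor(x)))
    stop("x must be non-negative integer(s)")
  if (anyNA(mu) || any(mu <= 0) || any(!is.finite(mu)))
    stop("mu must be positive and finite")
  if (anyNA(r) || any(r <= 0) || any(!is.finite(r)))
    stop("r must be positive and finite")
  lgamma(r + x) - lgamma(r) - lgamma(x + 1) +
    x * log(mu / (mu + r)) + r * log(r / (mu + r))
}

#' Expected read count
#'
#' The model mean for one gene in one replicate: expression level times gene
#' length times sequencing depth, `mu = lambda * length * depth`. For
#' homeolog B the caller passes `omega * lambda` as the expression level.
#'
#' @param lam Expression level (positive, units 1/kb).
#' @param length Gene length in kilobases (positive).
#' @param depth Sequencing depth in millions of mapped reads (positive).
#' @return The expected count `lam * length * depth`.
#' @export
expected_count <- function(lam, length, depth) {
  for (v in list(lam, length, depth))
    if (anyNA(v) || any(v <= 0) || any(!is.finite(v)))
      stop("all arguments must be positive and finite")
  lam * length * depth
}

# internal log-likelihood on raw vectors; callers guarantee alignment
loglik_heb_raw <- function(a, b, la, lb, d, r, lam, omega) {
  sum(nb_logpmf(a, lam * la * d, r)) +
    sum(nb_logpmf(b, omega * lam * lb * d, r))
}

#' Log-likelihood of one condition's counts for a homeolog pair
#'
#' Sum over replicates of the negative binomial log pmf of both homeologs,
#' with means `lambda * l_a * d_i` (homeolog A) and
#' `omega * lambda * l_b * d_i` (homeolog B). The null-hypothesis
#' log-likelihood of the HEB test is this function at `omega = 1`.
#'
#' @param counts A [count_set].
#' @param pair A [homeolog_pair].
#' @param r Aggregation parameter, scalar or one value per replicate.
#' @param lam Expression level of homeolog A (positive).
#' @param omega Expression-level ratio B/A (positive).
#' @return The log-likelihood (scalar).
#' @export
loglik_heb <- function(counts, pair, r, lam, omega = 1) {
  stopifnot(inherits(counts, "count_set"), inherits(pair, "homeolog_pair"))
  if (length(lam) != 1L || lam <= 0 || length(omega) != 1L || omega <= 0)
    stop("lam and omega must be positive scalars")
  n <- length(counts$counts_a)
  r <- check_dispersion(r, n)
  loglik_heb_raw(counts$counts_a, counts$counts_b,
                 pair$length_a, pair$length_b, counts$depths, r, lam, omega)
}

#' Log-likelihood of two conditions' counts for a homeolog pair
#'
#' The two-condition log-likelihood used by the delta-HEB test: the sum of
#' [loglik_heb] over conditions, each with its own expression level and
#' ratio. The delta-HEB null log-likelihood constrains
#' `omega_1 = omega_2 = omega`.
#'
#' @param counts_1,counts_2 [count_set]s for conditions 1 and 2.
#' @param pair A [homeolog_pair].
#' @param r_1,r_2 Aggregation parameters per condition (scalar or
#'   per-replicate).
#' @param lam_1,lam_2 Expression levels of homeolog A per condition.
#' @param omega_1,omega_2 Expression-level ratios per condition.
#' @return The log-likelihood (scalar).
#' @export
loglik_dheb <- function(counts_1, counts_2, pair, r_1, r_2,
                        lam_1, lam_2, omega_1, omega_2) {
  loglik_heb(counts_1, pair, r_1, lam_1, omega_1) +
    loglik_heb(counts_2, pair, r_2, lam_2, omega_2)
}
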