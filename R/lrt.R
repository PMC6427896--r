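# Likelihood ratio tests and multi-pair screens.

W_SLACK <- 1e-8   # numerical slack on the nesting inequality lnL1 >= lnL0
W_FAIL <- 1e-6    # beyond this the optimizer genuinely failed

#' Homeolog expression bias statistic
#'
#' `HEB = log2(mean_b / mean_a)` where the means are expression levels
#' normalized by gene length and sequencing depth (RPKM-style). HEB = 0 is
#' no bias; HEB = -3 is 8-fold bias towards homeolog A.
#'
#' @param mean_a,mean_b Positive normalized mean expression of homeologs A
#'   and B.
#' @param log_base Base of the logarithm (default 2).
#' @return The (vectorized) bias statistic.
#' @export
heb_statistic <- function(mean_a, mean_b, log_base = 2) {
  if (anyNA(mean_a) || anyNA(mean_b) || any(mean_a <= 0) || any(mean_b <= 0))
    stop("means must be positive (untestable pairs carry no HEB)")
  log(mean_b / mean_a, base = log_base)
}

#' Change in homeolog expression bias
#'
#' `dHEB = HEB_2 - HEB_1`, the log fold change of the bias ratio between
#' conditions.
#'
#' @param heb_1,heb_2 Finite bias statistics in conditions 1 and 2.
#' @return The (vectorized) difference.
#' @export
dheb_statistic <- function(heb_1, heb_2) {
  if (anyNA(heb_1) || anyNA(heb_2) ||
      any(!is.finite(heb_1)) || any(!is.finite(heb_2)))
    stop("HEB values must be finite")
  heb_2 - heb_1
}

#' Testability filters
#'
#' A pair is testable for HEB when each homeolog has measurable expression:
#' at least one read summed over replicates. The delta-HEB test additionally
#' requires this in each condition (four totals >= 1). Pairs failing the
#' filter have boundary maximum likelihood estimates and are excluded from
#' testing.
#'
#' @param counts,counts_1,counts_2 [count_set]s.
#' @return Logical flag.
#' @export
testable_heb <- function(counts) {
  stopifnot(inherits(counts, "count_set"))
  sum(counts$counts_a) >= 1 && sum(counts$counts_b) >= 1
}

#' @rdname testable_heb
#' @export
testable_dheb <- function(counts_1, counts_2) {
  testable_heb(counts_1) && testable_heb(counts_2)
}

#' Likelihood ratio statistic and chi-squared p-value
#'
#' `W = 2 * (lnL1 - lnL0)` for nested hypotheses differing by one free
#' parameter, referenced to the chi-squared distribution with 1 degree of
#' freedom. Tiny negative differences (within numerical slack, 1e-8) are
#' clamped to zero; materially negative differences indicate an optimizer
#' failure and raise an error.
#'
#' @param loglik_null,loglik_alt Maximized log-likelihoods of the null and
#'   alternative models.
#' @return A list with `W` (non-negative) and `p` (upper chi-squared tail).
#' @examples
#' lrt_statistic(-10, -8)  # W = 4
#' @export
lrt_statistic <- function(loglik_null, loglik_alt) {
  diff <- loglik_alt - loglik_null
  if (any(diff < -W_FAIL))
    stop("alternative log-likelihood below null beyond numerical slack; ",
         "optimizer failure")
  W <- pmax(2 * diff, 0)
  list(W = W, p = pchisq(W, df = 1, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment with rejection flags
#'
#' Standard step-up false discovery rate control: `q_(i)` is the minimum
#' over `j >= i` of `m * p_(j) / j`, capped at 1, returned in the input
#' order; rejection where `q <= alpha`.
#'
#' @param pvals Numeric p-values in `[0, 1]` (NAs pass through as NA).
#' @param alpha FDR level in (0, 1).
#' @return A list with `q` (adjusted values) and `reject` (logical).
#' @export
bh_adjust <- function(pvals, alpha = 0.05) {
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop("p-values must lie in [0, 1]")
  if (length(alpha) != 1L || is.na(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  q <- p.adjust(pvals, method = "BH")
  list(q = q, reject = !is.na(q) & q <= alpha)
}

# internal: RPKM-style normalized mean of one homeolog
rpkm_mean <- function(counts, length_kb, depths) {
  mean(counts / (length_kb * depths))
}

# internal: direction label from a bias value and a rejection flag
bias_direction <- function(stat, rejected) {
  ifelse(!rejected | is.na(stat), "none",
         ifelse(stat < 0, "A-biased", "B-biased"))
}

#' Screen all homeolog pairs for expression bias in one condition
#'
#' For each pair: apply the testability filter, fit the null and
#' alternative models, form the likelihood ratio statistic and chi-squared
#' p-value, and compute the HEB point estimate from length/depth-normalized
#' mean counts. Benjamini-Hochberg correction is applied across all testable
#' pairs. Per-pair fit failures are recorded in the `note` column and never
#' abort the screen.
#'
#' @param records A list of records as built by [assemble_pairs]: each a
#'   list with elements `pair` (a [homeolog_pair]) and `counts` (a
#'   [count_set]).
#' @param r Aggregation parameter(s) for the condition (scalar or
#'   per-replicate), e.g. from [estimate_dispersions]; `NULL` estimates them
#'   from the counts of all homeologs in `records`.
#' @param alpha FDR level (default 0.05).
#' @param log_base Base for reported HEB values (default 2).
#' @param correction `"BH"` (default) or `"none"`.
#' @return A data frame with one row per input pair, in input order:
#'   identifiers, per-homeolog totals, `testable`, `lambda_hat`,
#'   `omega_hat`, `heb`, `log_omega`, `W`, `p`, `q`, `significant`,
#'   `direction`, `converged`, `note`.
#' @export
run_heb_screen <- function(records, r = NULL, alpha = 0.05, log_base = 2,
                           correction = c("BH", "none")) {
  correction <- match.arg(correction)
  stopifnot(length(records) >= 1L)
  if (is.null(r)) {
    mat <- do.call(rbind, lapply(records, function(rec)
      rbind(rec$counts$counts_a, rec$counts$counts_b)))
    r <- estimate_dispersions(mat, records[[1L]]$counts$depths)
  }
  rows <- lapply(records, function(rec) {
    p <- rec$pair; cs <- rec$counts
    out <- data.frame(
      id_a = p$id_a, id_b = p$id_b,
      total_a = sum(cs$counts_a), total_b = sum(cs$counts_b),
      testable = testable_heb(cs),
      lambda_hat = NA_real_, omega_hat = NA_real_,
      heb = NA_real_, log_omega = NA_real_,
      W = NA_real_, p = NA_real_,
      converged = NA, note = "", stringsAsFactors = FALSE)
    if (!out$testable) return(out)
    res <- tryCatch({
      alt <- fit_heb_alt(cs, p, r)
      null <- fit_heb_null(cs, p, r)
      lrt <- lrt_statistic(null$loglik, alt$loglik)
      ma <- rpkm_mean(cs$counts_a, p$length_a, cs$depths)
      mb <- rpkm_mean(cs$counts_b, p$length_b, cs$depths)
      out$lambda_hat <- alt$lambda
      out$omega_hat <- alt$omega
      out$heb <- heb_statistic(ma, mb, log_base)
      out$log_omega <- log(alt$omega, base = log_base)
      out$W <- lrt$W; out$p <- lrt$p
      out$converged <- alt$converged && null$converged
      if (alt$fallback || null$fallback) out$note <- "simplex fallback"
      out
    }, error = function(e) {
      out$note <- conditionMessage(e)
      out
    })
    res
  })
  tab <- do.call(rbind, rows)
  finish_screen(tab, alpha, correction, tab$heb)
}

#' Screen all homeolog pairs for changes in expression bias
#'
#' As [run_heb_screen], for two conditions: the delta-HEB filter requires
#' each homeolog to have at least one read in each condition; the
#' likelihood ratio compares condition-specific ratios against a shared
#' ratio; the reported `dheb` is `HEB_2 - HEB_1` from normalized mean
#' counts.
#'
#' @param records A list of records as built by [assemble_pairs]: each a
#'   list with `pair`, `counts_1`, `counts_2`.
#' @param r_1,r_2 Aggregation parameter(s) per condition; `NULL` estimates
#'   each condition separately.
#' @inheritParams run_heb_screen
#' @return A data frame, one row per pair, with per-condition estimates and
#'   `heb_1`, `heb_2`, `dheb`, `W`, `p`, `q`, `significant`, `direction`.
#' @export
run_dheb_screen <- function(records, r_1 = NULL, r_2 = NULL, alpha = 0.05,
                            log_base = 2, correction = c("BH", "none")) {
  correction <- match.arg(correction)
  stopifnot(length(records) >= 1L)
  est_r <- function(which) {
    mat <- do.call(rbind, lapply(records, function(rec)
      rbind(rec[[which]]$counts_a, rec[[which]]$counts_b)))
    estimate_dispersions(mat, records[[1L]][[which]]$depths)
  }
  if (is.null(r_1)) r_1 <- est_r("counts_1")
  if (is.null(r_2)) r_2 <- est_r("counts_2")
  rows <- lapply(records, function(rec) {
    p <- rec$pair; c1 <- rec$counts_1; c2 <- rec$counts_2
    out <- data.frame(
      id_a = p$id_a, id_b = p$id_b,
      total_a1 = sum(c1$counts_a), total_b1 = sum(c1$counts_b),
      total_a2 = sum(c2$counts_a), total_b2 = sum(c2$counts_b),
      testable = testable_dheb(c1, c2),
      lambda_hat_1 = NA_real_, lambda_hat_2 = NA_real_,
      omega_hat_1 = NA_real_, omega_hat_2 = NA_real_,
      omega_hat_null = NA_real_,
      heb_1 = NA_real_, heb_2 = NA_real_, dheb = NA_real_,
      W = NA_real_, p = NA_real_,
      converged = NA, note = "", stringsAsFactors = FALSE)
    if (!out$testable) return(out)
    tryCatch({
      alt <- fit_dheb_alt(c1, c2, p, r_1, r_2)
      null <- fit_dheb_null(c1, c2, p, r_1, r_2)
      lrt <- lrt_statistic(null$loglik, alt$loglik)
      h1 <- heb_statistic(rpkm_mean(c1$counts_a, p$length_a, c1$depths),
                          rpkm_mean(c1$counts_b, p$length_b, c1$depths),
                          log_base)
      h2 <- heb_statistic(rpkm_mean(c2$counts_a, p$length_a, c2$depths),
                          rpkm_mean(c2$counts_b, p$length_b, c2$depths),
                          log_base)
      out$lambda_hat_1 <- alt$lambda[1]; out$lambda_hat_2 <- alt$lambda[2]
      out$omega_hat_1 <- alt$omega[1]; out$omega_hat_2 <- alt$omega[2]
      out$omega_hat_null <- null$omega
      out$heb_1 <- h1; out$heb_2 <- h2
      out$dheb <- dheb_statistic(h1, h2)
      out$W <- lrt$W; out$p <- lrt$p
      out$converged <- alt$converged && null$converged
      if (alt$fallback || null$fallback) out$note <- "simplex fallback"
      out
    }, error = function(e) {
      out$note <- conditionMessage(e)
      out
    })
  })
  tab <- do.call(rbind, rows)
  finish_screen(tab, alpha, correction, tab$dheb)
}

# internal: attach q, significance, direction to a screen table
finish_screen <- function(tab, alpha, correction, stat) {
  rownames(tab) <- NULL
  if (correction == "BH") {
    adj <- bh_adjust(tab$p, alpha)
    tab$q <- adj$q
    tab$significant <- adj$reject
  } else {
    tab$q <- tab$p
    tab$significant <- !is.na(tab$p) & tab$p <= alpha
  }
  tab$direction <- bias_direction(stat, tab$significant)
  tab
}
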