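# Synthetic data generation and the validation studies: power curves over
# fold changes and replicate numbers, naive t/z comparator tests, and
# full/partial ROC benchmarking.
#
# Simulated counts use unit gene lengths and unit depths so the expression
# level equals the negative binomial mean (mu = lambda); study conditions
# follow the validation protocol: mu_a = 100, mu_b = 2^x * mu_a with
# x in [0, 2] in steps of 0.1, r = 10, N in {3, 6, 12, 24}, 10,000 trials
# per cell, alpha = 0.05, with the true r passed to the test.

#' Simulate a homeolog pair's counts for one condition
#'
#' Draws `n` independent negative binomial counts per homeolog with the
#' given means and aggregation parameter, at unit gene lengths and unit
#' depths (so means are expression levels directly).
#'
#' @param mu_a,mu_b Positive means for homeologs A and B.
#' @param r Positive aggregation parameter (variance is `mu + mu^2/r`).
#' @param n Number of replicates.
#' @param condition Optional label attached to the result.
#' @return A [count_set] with unit depths.
#' @examples
#' set.seed(1)
#' simulate_pair(100, 400, r = 10, n = 3)
#' @export
simulate_pair <- function(mu_a, mu_b, r, n, condition = "") {
  if (anyNA(c(mu_a, mu_b, r)) || mu_a <= 0 || mu_b <= 0 || r <= 0)
    stop("mu_a, mu_b and r must be positive")
  if (length(n) != 1L || n < 1 || n != floor(n))
    stop("n must be a positive integer")
  count_set(rnbinom(n, size = r, mu = mu_a),
            rnbinom(n, size = r, mu = mu_b),
            depths = 1, condition = condition)
}

# internal single-trial LRT p-values on raw vectors (unit offsets).
# Untestable draws return NA (never rejected); at the study means this is
# vanishingly rare.
heb_lrt_p <- function(a, b, r) {
  if (sum(a) < 1 || sum(b) < 1) return(NA_real_)
  alt <- fit_heb_alt_raw(a, b, 1, 1, rep(1, length(a)), r)
  null <- fit_heb_null_raw(a, b, 1, 1, rep(1, length(a)), r)
  lrt_statistic(null$loglik, alt$loglik)$p
}

dheb_lrt_p <- function(a1, b1, r1, a2, b2, r2) {
  if (sum(a1) < 1 || sum(b1) < 1 || sum(a2) < 1 || sum(b2) < 1)
    return(NA_real_)
  d1 <- rep(1, length(a1)); d2 <- rep(1, length(a2))
  f1 <- fit_heb_alt_raw(a1, b1, 1, 1, d1, r1)
  f2 <- fit_heb_alt_raw(a2, b2, 1, 1, d2, r2)
  null <- fit_dheb_null_raw(a1, b1, d1, r1, a2, b2, d2, r2, 1, 1)
  lrt_statistic(null$loglik, f1$loglik + f2$loglik)$p
}

# internal: per-cell seed derived from the master seed; independent of grid
# order and kept below 2^31
cell_seed <- function(seed, mode, n, x) {
  (as.integer(seed) %% 100000L) * 20011L +
    (if (mode == "heb") 0L else 1L) * 10007L +
    as.integer(n) * 211L + as.integer(round(x * 10)) + 1L
}

power_curve_engine <- function(mode, mu_base, x_grid, r, n_grid, trials,
                               alpha, seed, estimate_r) {
  grid <- expand.grid(n = n_grid, x = x_grid, KEEP.OUT.ATTRS = FALSE)
  res <- mapply(function(n, x) {
    set.seed(cell_seed(seed, mode, n, x))
    mu_b <- 2^x * mu_base
    rej <- 0L
    for (t in seq_len(trials)) {
      if (mode == "heb") {
        a <- rnbinom(n, size = r, mu = mu_base)
        b <- rnbinom(n, size = r, mu = mu_b)
        rr <- if (estimate_r) estimate_dispersions(rbind(a, b)) else r
        p <- heb_lrt_p(a, b, rr)
      } else {
        a1 <- rnbinom(n, size = r, mu = mu_base)
        b1 <- rnbinom(n, size = r, mu = mu_base)
        a2 <- rnbinom(n, size = r, mu = mu_base)
        b2 <- rnbinom(n, size = r, mu = mu_b)
        if (estimate_r) {
          r1 <- estimate_dispersions(rbind(a1, b1))
          r2 <- estimate_dispersions(rbind(a2, b2))
        } else {
          r1 <- r; r2 <- r
        }
        p <- dheb_lrt_p(a1, b1, r1, a2, b2, r2)
      }
      if (!is.na(p) && p < alpha) rej <- rej + 1L
    }
    frac <- rej / trials
    c(rejections = rej, fraction = frac,
      mc_stderr = sqrt(frac * (1 - frac) / trials))
  }, grid$n, grid$x)
  out <- cbind(grid, t(res))
  out$trials <- trials
  out[, c("n", "x", "rejections", "trials", "fraction", "mc_stderr")]
}

#' Power of the HEB likelihood ratio test by simulation
#'
#' For each combination of replicate number `n` and fold exponent `x`,
#' simulates `trials` homeolog pairs with means `mu_base` and
#' `2^x * mu_base`, runs the HEB likelihood ratio test on each at level
#' `alpha` (one test per trial; no multiplicity correction), and records the
#' rejection fraction with its binomial Monte Carlo standard error. Cells
#' are seeded independently of grid order, so any sub-grid reproduces the
#' full run's values.
#'
#' @param mu_base Mean of homeolog A (default 100).
#' @param x_grid Fold exponents; homeolog B's mean is `2^x * mu_base`.
#' @param r True aggregation parameter of the generator (default 10).
#' @param n_grid Replicate numbers (default `c(3, 6, 12, 24)`).
#' @param trials Simulated pairs per cell (default 10000).
#' @param alpha Per-trial test level (default 0.05).
#' @param seed Master seed.
#' @param estimate_r Pass the true `r` to the test (default, `FALSE`) or
#'   re-estimate it per trial from the simulated counts (sensitivity
#'   analysis).
#' @return A data frame with columns `n`, `x`, `rejections`, `trials`,
#'   `fraction`, `mc_stderr`.
#' @export
power_curve_heb <- function(mu_base = 100, x_grid = seq(0, 2, by = 0.1),
                            r = 10, n_grid = c(3, 6, 12, 24),
                            trials = 10000, alpha = 0.05, seed = 1,
                            estimate_r = FALSE) {
  power_curve_engine("heb", mu_base, x_grid, r, n_grid, trials, alpha,
                     seed, estimate_r)
}

#' Power of the delta-HEB likelihood ratio test by simulation
#'
#' As [power_curve_heb] but for the two-condition test: three of the four
#' means are fixed at `mu_base` (both homeologs in condition 1, homeolog A
#' in condition 2) and homeolog B in condition 2 has mean `2^x * mu_base`.
#'
#' @inheritParams power_curve_heb
#' @return A data frame with columns `n`, `x`, `rejections`, `trials`,
#'   `fraction`, `mc_stderr`.
#' @export
power_curve_dheb <- function(mu_base = 100, x_grid = seq(0, 2, by = 0.1),
                             r = 10, n_grid = c(3, 6, 12, 24),
                             trials = 10000, alpha = 0.05, seed = 1,
                             estimate_r = FALSE) {
  power_curve_engine("dheb", mu_base, x_grid, r, n_grid, trials, alpha,
                     seed, estimate_r)
}

#' Naive t- and z-tests on per-replicate log count ratios
#'
#' Comparator methods: each replicate is reduced to
#' `s = log2((b + 0.5) / (a + 0.5))` (the pseudo-count guards zeros) and the
#' two conditions' statistics are compared by a Welch unequal-variance
#' t-test and by the analogous z-test (pooled standard error, normal
#' reference). Degenerate inputs with zero pooled variance give p = 1 when
#' the means agree and p = 0 when they differ.
#'
#' @param counts_1,counts_2 [count_set]s with at least 2 replicates each.
#' @return A list with `p_t` and `p_z`.
#' @export
naive_ratio_tests <- function(counts_1, counts_2) {
  stopifnot(inherits(counts_1, "count_set"), inherits(counts_2, "count_set"))
  if (length(counts_1$counts_a) < 2L || length(counts_2$counts_a) < 2L)
    stop("naive tests need at least 2 replicates per condition")
  s1 <- log2((counts_1$counts_b + 0.5) / (counts_1$counts_a + 0.5))
  s2 <- log2((counts_2$counts_b + 0.5) / (counts_2$counts_a + 0.5))
  se2 <- var(s1) / length(s1) + var(s2) / length(s2)
  delta <- mean(s2) - mean(s1)
  if (se2 == 0) {
    p <- if (delta == 0) 1 else 0
    return(list(p_t = p, p_z = p))
  }
  p_t <- t.test(s2, s1, var.equal = FALSE)$p.value
  z <- delta / sqrt(se2)
  list(p_t = p_t, p_z = 2 * pnorm(-abs(z)))
}

#' ROC curve from p-value-like scores
#'
#' Sweeps the score threshold from most to least extreme, grouping tied
#' scores into single points, under the convention that smaller scores
#' (p-values) are called positive first. The curve starts at (0, 0) and
#' ends at (1, 1).
#'
#' @param scores Numeric scores, smaller = more confidently positive.
#' @param labels Logical vector, `TRUE` for true positives.
#' @return A data frame with columns `fpr` and `tpr`.
#' @export
roc_points <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels must align")
  labels <- as.logical(labels)
  if (!any(labels) || all(labels))
    stop("both classes must be present")
  ord <- order(scores)
  scores <- scores[ord]; labels <- labels[ord]
  npos <- sum(labels); nneg <- sum(!labels)
  tp <- cumsum(labels); fp <- cumsum(!labels)
  last <- c(scores[-1] != scores[-length(scores)], TRUE)  # tie grouping
  data.frame(fpr = c(0, fp[last] / nneg), tpr = c(0, tp[last] / npos))
}

#' Area under an ROC curve
#'
#' Trapezoidal integration of `tpr` over `fpr`. [partial_auc] integrates
#' only over `fpr` in `[0, fpr_max]` with linear interpolation at the cut,
#' so a perfect classifier attains `fpr_max` and a random one
#' `fpr_max^2 / 2`.
#'
#' @param fpr Non-decreasing false positive rates.
#' @param tpr True positive rates.
#' @param fpr_max Upper integration limit for the partial area.
#' @return The (partial) area.
#' @export
roc_auc <- function(fpr, tpr) {
  if (is.unsorted(fpr)) stop("fpr must be non-decreasing")
  sum(diff(fpr) * (head_(tpr) + tail_(tpr)) / 2)
}

#' @rdname roc_auc
#' @export
partial_auc <- function(fpr, tpr, fpr_max = 0.1) {
  if (is.unsorted(fpr)) stop("fpr must be non-decreasing")
  if (fpr_max <= 0) return(0)
  if (max(fpr) > fpr_max) {
    i <- which(fpr > fpr_max)[1L]
    # interpolate the curve at the cut
    t_cut <- tpr[i - 1L] +
      (tpr[i] - tpr[i - 1L]) * (fpr_max - fpr[i - 1L]) / (fpr[i] - fpr[i - 1L])
    fpr <- c(fpr[seq_len(i - 1L)], fpr_max)
    tpr <- c(tpr[seq_len(i - 1L)], t_cut)
  }
  roc_auc(fpr, tpr)
}

head_ <- function(x) x[-length(x)]
tail_ <- function(x) x[-1L]

#' ROC benchmark of the delta-HEB LRT against naive tests
#'
#' Repeats the comparator protocol: each simulated data set holds `n_pairs`
#' homeolog pairs with `n_reps` replicates per condition; half the pairs are
#' null (all four means `mu_base`), half have the bias ratio of condition 2
#' multiplied by the fold `level` (homeolog B's condition-2 mean is
#' `level * mu_base`). Every pair is scored by the delta-HEB LRT p-value and
#' by the naive t- and z-test p-values, and each method's full and partial
#' (FPR <= 0.1) ROC areas are recorded per data set.
#'
#' @param levels Fold changes of the bias ratio (default `c(2, 8, 16)`).
#' @param n_datasets Simulated data sets per level (default 50).
#' @param n_pairs Pairs per data set, half non-null (default 10000).
#' @param n_reps Replicates per condition (default 3).
#' @param mu_base Baseline mean (default 100).
#' @param r True aggregation parameter (default 10), passed to the LRT.
#' @param seed Master seed.
#' @return A data frame with columns `method`, `level`, `dataset`, `auc`,
#'   `partial_auc`.
#' @export
roc_benchmark <- function(levels = c(2, 8, 16), n_datasets = 50,
                          n_pairs = 10000, n_reps = 3, mu_base = 100,
                          r = 10, seed = 1) {
  if (n_pairs %% 2 != 0) stop("n_pairs must be even (half null)")
  if (any(levels <= 1)) stop("fold levels must exceed 1")
  rows <- list()
  for (level in levels) {
    for (ds in seq_len(n_datasets)) {
      set.seed(cell_seed(seed, "dheb", ds, level) + 41L)
      half <- n_pairs / 2
      is_pos <- rep(c(FALSE, TRUE), c(half, half))
      p_lrt <- p_t <- p_z <- numeric(n_pairs)
      for (j in seq_len(n_pairs)) {
        mu_b2 <- if (is_pos[j]) level * mu_base else mu_base
        a1 <- rnbinom(n_reps, size = r, mu = mu_base)
        b1 <- rnbinom(n_reps, size = r, mu = mu_base)
        a2 <- rnbinom(n_reps, size = r, mu = mu_base)
        b2 <- rnbinom(n_reps, size = r, mu = mu_b2)
        p <- dheb_lrt_p(a1, b1, r, a2, b2, r)
        p_lrt[j] <- if (is.na(p)) 1 else p
        nv <- naive_ratio_tests(count_set(a1, b1), count_set(a2, b2))
        p_t[j] <- nv$p_t; p_z[j] <- nv$p_z
      }
      for (m in c("LRT", "t", "z")) {
        sc <- switch(m, LRT = p_lrt, t = p_t, z = p_z)
        curve <- roc_points(sc, is_pos)
        rows[[length(rows) + 1L]] <- data.frame(
          method = m, level = level, dataset = ds,
          auc = roc_auc(curve$fpr, curve$tpr),
          partial_auc = partial_auc(curve$fpr, curve$tpr, 0.1),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
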