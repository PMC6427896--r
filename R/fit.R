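# Maximum likelihood fitting of the negative binomial homeolog model.
#
# Likelihoods are maximized in transformed coordinates
#   v = ln sqrt(lambda_a * lambda_b)   (log geometric-mean expression)
#   y = (ln omega) / 2                 (half log ratio)
# so that lambda = exp(v - y) and omega = exp(2y) are positive by
# construction and the score equations are symmetric in A <-> B. The score
# contributions per replicate are
#   A_i = a_i - (a_i + r_i) m_a / (m_a + r_i),  m_a = exp(v - y) l_a d_i
#   B_i = b_i - (b_i + r_i) m_b / (m_b + r_i),  m_b = exp(v + y) l_b d_i
# with dlnL/dv = sum(B + A) and dlnL/dy = sum(B - A). Root-finding is damped
# Newton with the analytic (symmetric, negative-definite) Jacobian; a
# derivative-free simplex maximization of the log-likelihood is the fallback
# and is flagged in the result.

SCORE_TOL <- 1e-10       # Newton convergence on the residual max-norm
SCORE_OK <- 1e-8         # residual norm below which a fit counts as converged
MAX_NEWTON_ITER <- 200L

#' Per-replicate score terms of the transformed log-likelihood
#'
#' Returns the per-replicate quantities `A_i` and `B_i` whose sums and
#' differences are the partial derivatives of the one-condition
#' log-likelihood with respect to `v` and `y`:
#' `dlnL/dv = sum(B_i + A_i)`, `dlnL/dy = sum(B_i - A_i)`.
#'
#' @param v Log geometric mean of the two expression levels.
#' @param y Half log expression ratio (`omega = exp(2 * y)`).
#' @param counts A [count_set].
#' @param pair A [homeolog_pair].
#' @param r Aggregation parameter (scalar or per-replicate).
#' @return A list with numeric vectors `A` and `B`, one entry per replicate.
#' @export
score_terms <- function(v, y, counts, pair, r) {
  stopifnot(inherits(counts, "count_set"), inherits(pair, "homeolog_pair"))
  n <- length(counts$counts_a)
  r <- check_dispersion(r, n)
  st <- score_parts(v, y, counts$counts_a, counts$counts_b,
                    pair$length_a, pair$length_b, counts$depths, r)
  list(A = st$A, B = st$B)
}

# internal: score terms plus the curvature sums used in the Newton Jacobian
score_parts <- function(v, y, a, b, la, lb, d, r) {
  ma <- exp(v - y) * la * d
  mb <- exp(v + y) * lb * d
  A <- a - (a + r) * ma / (ma + r)
  B <- b - (b + r) * mb / (mb + r)
  # -d(sum A)/dv and -d(sum B)/dv (both positive)
  P <- sum((a + r) * r * ma / (ma + r)^2)
  Q <- sum((b + r) * r * mb / (mb + r)^2)
  list(A = A, B = B, sA = sum(A), sB = sum(B), P = P, Q = Q)
}

# internal: damped Newton on an arbitrary score system.
# fscore(theta) -> list(F = residual vector, J = Jacobian matrix)
newton_solve <- function(theta, fscore) {
  st <- fscore(theta)
  fnorm <- max(abs(st$F))
  iter <- 0L
  while (fnorm > SCORE_TOL && iter < MAX_NEWTON_ITER) {
    step <- tryCatch(solve(st$J, -st$F), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    lam <- 1
    repeat {
      cand <- theta + lam * step
      st_new <- tryCatch(fscore(cand), error = function(e) NULL)
      if (!is.null(st_new) && all(is.finite(st_new$F)) &&
          max(abs(st_new$F)) < fnorm) {
        theta <- cand; st <- st_new; fnorm <- max(abs(st_new$F))
        break
      }
      lam <- lam / 2
      if (lam < 1e-12) return(list(theta = theta, score_norm = fnorm,
                                   iterations = iter, stalled = TRUE))
    }
    iter <- iter + 1L
  }
  list(theta = theta, score_norm = fnorm, iterations = iter,
       stalled = fnorm > SCORE_TOL)
}

# internal: moment initialization; +0.5 guards log(0), used only to start
init_vy <- function(a, b, la, lb, d) {
  lam_a <- (sum(a) + 0.5) / (la * sum(d))
  lam_b <- (sum(b) + 0.5) / (lb * sum(d))
  c(v = 0.5 * log(lam_a * lam_b), y = 0.5 * log(lam_b / lam_a))
}

# internal: guard against boundary MLEs; screens filter these upstream
check_testable_totals <- function(a, b, what = "pair") {
  if (sum(a) < 1 || sum(b) < 1)
    stop("untestable ", what,
         ": each homeolog needs at least one read (boundary MLE)")
}

fit_result <- function(lambda, omega, loglik, score_norm, iterations,
                       fallback = FALSE) {
  structure(list(lambda = lambda, omega = omega, loglik = loglik,
                 converged = is.finite(loglik) && score_norm <= SCORE_OK,
                 score_norm = score_norm, iterations = iterations,
                 fallback = fallback),
            class = "heb_fit")
}

#' @export
print.heb_fit <- function(x, ...) {
  cat(sprintf(
    "NB homeolog fit: lambda = %s, omega = %s\n  lnL = %.6g, %s (|score| = %.2g%s)\n",
    paste(signif(x$lambda, 6), collapse = "/"),
    paste(signif(x$omega, 6), collapse = "/"),
    x$loglik, if (x$converged) "converged" else "NOT converged",
    x$score_norm, if (x$fallback) ", simplex fallback" else ""))
  invisible(x)
}

# ---- single-condition fits ------------------------------------------------

fit_heb_alt_raw <- function(a, b, la, lb, d, r) {
  check_testable_totals(a, b)
  fscore <- function(th) {
    st <- score_parts(th[1], th[2], a, b, la, lb, d, r)
    list(F = c(st$sB + st$sA, st$sB - st$sA),
         J = matrix(c(-(st$P + st$Q), st$P - st$Q,
                      st$P - st$Q, -(st$P + st$Q)), 2, 2))
  }
  th0 <- init_vy(a, b, la, lb, d)
  sol <- newton_solve(th0, fscore)
  fallback <- FALSE
  if (sol$score_norm > SCORE_OK) {
    # simplex fallback on the log-likelihood itself
    nll <- function(th) -loglik_heb_raw(a, b, la, lb, d, r,
                                        exp(th[1] - th[2]), exp(2 * th[2]))
    op <- optim(th0, nll, method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-14))
    cand <- fscore(op$par)
    if (max(abs(cand$F)) < sol$score_norm) {
      sol <- list(theta = op$par, score_norm = max(abs(cand$F)),
                  iterations = sol$iterations)
      fallback <- TRUE
    }
  }
  v <- sol$theta[[1]]; y <- sol$theta[[2]]
  lam <- exp(v - y); omega <- exp(2 * y)
  fit_result(lam, omega, loglik_heb_raw(a, b, la, lb, d, r, lam, omega),
             sol$score_norm, sol$iterations, fallback)
}

fit_heb_null_raw <- function(a, b, la, lb, d, r) {
  check_testable_totals(a, b)
  fscore <- function(th) {
    st <- score_parts(th[1], 0, a, b, la, lb, d, r)
    list(F = st$sB + st$sA, J = matrix(-(st$P + st$Q), 1, 1))
  }
  v0 <- init_vy(a, b, la, lb, d)[["v"]]
  sol <- newton_solve(v0, fscore)
  fallback <- FALSE
  if (sol$score_norm > SCORE_OK) {
    # the v-score is strictly decreasing, so bracketing always succeeds
    g <- function(v) fscore(v)$F
    root <- tryCatch({
      lo <- v0 - 30; hi <- v0 + 30
      uniroot(g, c(lo, hi), tol = 1e-14)$root
    }, error = function(e) NULL)
    if (!is.null(root)) {
      fn <- abs(g(root))
      if (fn < sol$score_norm) {
        sol <- list(theta = root, score_norm = fn,
                    iterations = sol$iterations)
        fallback <- TRUE
      }
    }
  }
  lam <- exp(sol$theta[[1]])
  fit_result(lam, 1, loglik_heb_raw(a, b, la, lb, d, r, lam, 1),
             sol$score_norm, sol$iterations, fallback)
}

#' Maximum likelihood fit of the HEB alternative hypothesis
#'
#' Fits the free-ratio model (`lambda`, `omega` both free) for one homeolog
#' pair in one condition by Newton root-finding on the transformed score
#' equations, with a simplex fallback flagged in the result.
#'
#' @param counts A [count_set] in which each homeolog has at least one read
#'   in total (pairs failing [testable_heb] have a boundary MLE and raise an
#'   error).
#' @param pair A [homeolog_pair].
#' @param r Aggregation parameter (scalar or per-replicate).
#' @return An object of class `"heb_fit"`: a list with `lambda`, `omega`,
#'   `loglik`, `converged`, `score_norm`, `iterations`, `fallback`.
#' @examples
#' p <- homeolog_pair("a", "b", 1, 1)
#' fit_heb_alt(count_set(30L, 60L), p, r = 10)  # lambda = 30, omega = 2
#' @export
fit_heb_alt <- function(counts, pair, r) {
  stopifnot(inherits(counts, "count_set"), inherits(pair, "homeolog_pair"))
  n <- length(counts$counts_a)
  fit_heb_alt_raw(counts$counts_a, counts$counts_b,
                  pair$length_a, pair$length_b, counts$depths,
                  check_dispersion(r, n))
}

#' Maximum likelihood fit of the HEB null hypothesis
#'
#' Fits the equal-expression model (`omega` fixed at 1) by solving the
#' single `v`-score equation; the score is strictly monotone so the fit is
#' effectively exact.
#'
#' @inheritParams fit_heb_alt
#' @return An object of class `"heb_fit"` with `omega = 1`.
#' @export
fit_heb_null <- function(counts, pair, r) {
  stopifnot(inherits(counts, "count_set"), inherits(pair, "homeolog_pair"))
  n <- length(counts$counts_a)
  fit_heb_null_raw(counts$counts_a, counts$counts_b,
                   pair$length_a, pair$length_b, counts$depths,
                   check_dispersion(r, n))
}

# ---- two-condition fits ---------------------------------------------------

fit_dheb_null_raw <- function(a1, b1, d1, r1, a2, b2, d2, r2, la, lb) {
  check_testable_totals(a1, b1, "condition 1")
  check_testable_totals(a2, b2, "condition 2")
  fscore <- function(th) {
    s1 <- score_parts(th[1], th[3], a1, b1, la, lb, d1, r1)
    s2 <- score_parts(th[2], th[3], a2, b2, la, lb, d2, r2)
    list(F = c(s1$sB + s1$sA, s2$sB + s2$sA,
               (s1$sB - s1$sA) + (s2$sB - s2$sA)),
         J = matrix(c(-(s1$P + s1$Q), 0,              s1$P - s1$Q,
                      0,              -(s2$P + s2$Q), s2$P - s2$Q,
                      s1$P - s1$Q,    s2$P - s2$Q,
                      -(s1$P + s1$Q + s2$P + s2$Q)), 3, 3))
  }
  i1 <- init_vy(a1, b1, la, lb, d1)
  i2 <- init_vy(a2, b2, la, lb, d2)
  th0 <- c(i1[["v"]], i2[["v"]], (i1[["y"]] + i2[["y"]]) / 2)
  sol <- newton_solve(th0, fscore)
  fallback <- FALSE
  ll <- function(th) {
    loglik_heb_raw(a1, b1, la, lb, d1, r1,
                   exp(th[1] - th[3]), exp(2 * th[3])) +
      loglik_heb_raw(a2, b2, la, lb, d2, r2,
                     exp(th[2] - th[3]), exp(2 * th[3]))
  }
  if (sol$score_norm > SCORE_OK) {
    op <- optim(th0, function(th) -ll(th), method = "Nelder-Mead",
                control = list(maxit = 5000, reltol = 1e-14))
    cand <- fscore(op$par)
    if (max(abs(cand$F)) < sol$score_norm) {
      sol <- list(theta = op$par, score_norm = max(abs(cand$F)),
                  iterations = sol$iterations)
      fallback <- TRUE
    }
  }
  th <- sol$theta
  fit_result(lambda = c(exp(th[1] - th[3]), exp(th[2] - th[3])),
             omega = exp(2 * th[3]), loglik = ll(th),
             score_norm = sol$score_norm, iterations = sol$iterations,
             fallback = fallback)
}

#' Maximum likelihood fit of the delta-HEB alternative hypothesis
#'
#' The alternative model gives each condition its own `(lambda_k, omega_k)`,
#' so the fit decouples into two independent single-condition fits
#' ([fit_heb_alt]); the log-likelihood is their sum.
#'
#' @param counts_1,counts_2 [count_set]s for conditions 1 and 2, each
#'   passing [testable_dheb]'s per-condition requirement.
#' @param pair A [homeolog_pair].
#' @param r_1,r_2 Aggregation parameters per condition.
#' @return An object of class `"heb_fit"` whose `lambda` and `omega` are
#'   length-2 vectors (condition 1, condition 2).
#' @export
fit_dheb_alt <- function(counts_1, counts_2, pair, r_1, r_2) {
  f1 <- fit_heb_alt(counts_1, pair, r_1)
  f2 <- fit_heb_alt(counts_2, pair, r_2)
  fit_result(lambda = c(f1$lambda, f2$lambda),
             omega = c(f1$omega, f2$omega),
             loglik = f1$loglik + f2$loglik,
             score_norm = max(f1$score_norm, f2$score_norm),
             iterations = f1$iterations + f2$iterations,
             fallback = f1$fallback || f2$fallback)
}

#' Maximum likelihood fit of the delta-HEB null hypothesis
#'
#' The null model shares one expression ratio `omega` across conditions
#' while each condition keeps its own `lambda_k`. The coupled three-equation
#' score system in `(v_1, v_2, y)` is solved by damped Newton with the
#' analytic Jacobian; a simplex fallback is flagged.
#'
#' @inheritParams fit_dheb_alt
#' @return An object of class `"heb_fit"` with a length-2 `lambda` and a
#'   single shared `omega`.
#' @export
fit_dheb_null <- function(counts_1, counts_2, pair, r_1, r_2) {
  stopifnot(inherits(counts_1, "count_set"), inherits(counts_2, "count_set"),
            inherits(pair, "homeolog_pair"))
  n1 <- length(counts_1$counts_a); n2 <- length(counts_2$counts_a)
  fit_dheb_null_raw(counts_1$counts_a, counts_1$counts_b, counts_1$depths,
                    check_dispersion(r_1, n1),
                    counts_2$counts_a, counts_2$counts_b, counts_2$depths,
                    check_dispersion(r_2, n2),
                    pair$length_a, pair$length_b)
}
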