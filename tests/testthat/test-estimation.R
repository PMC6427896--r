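# Score equations and maximum likelihood fitting.

test_that("score terms vanish at the observed mean and have the closed forms", {
  p <- unit_pair()
  # choose v, y so the model mean of homeolog A equals the observed count
  v <- log(20); y <- 0
  cs <- count_set(20L, 20L)
  st <- score_terms(v, y, cs, p, r = 10)
  expect_equal(st$A, 0)
  expect_equal(st$B, 0)
  # zero count: A = -r * m / (m + r), strictly negative
  cs0 <- count_set(0L, 5L)
  m <- exp(v - y) * 1 * 1
  st0 <- score_terms(v, y, cs0, p, r = 10)
  expect_equal(st0$A, -10 * m / (m + 10))
  expect_lt(st0$A, 0)
})

test_that("score sums are the gradient of the log-likelihood in (v, y)", {
  fx <- rand_fixture(201, n = 4)
  ll <- function(v, y) loglik_heb(fx$counts, fx$pair, fx$r,
                                  exp(v - y), exp(2 * y))
  h <- 1e-6
  for (theta in list(c(2.1, 0.3), c(3.5, -0.8), c(1.0, 0.0))) {
    v <- theta[1]; y <- theta[2]
    st <- score_terms(v, y, fx$counts, fx$pair, fx$r)
    dv_fd <- (ll(v + h, y) - ll(v - h, y)) / (2 * h)
    dy_fd <- (ll(v, y + h) - ll(v, y - h)) / (2 * h)
    expect_equal(sum(st$B + st$A), dv_fd, tolerance = 1e-4)
    expect_equal(sum(st$B - st$A), dy_fd, tolerance = 1e-4)
  }
})

test_that("single-replicate fits have their closed forms", {
  p <- unit_pair()
  alt <- fit_heb_alt(count_set(30L, 60L), p, r = 10)
  expect_equal(alt$lambda, 30, tolerance = 1e-9)
  expect_equal(alt$omega, 2, tolerance = 1e-9)
  expect_true(alt$converged)
  # null MLE under equal offsets is the grand mean, any r
  for (r in c(1, 10, 300)) {
    null <- fit_heb_null(count_set(30L, 60L), p, r = r)
    expect_equal(null$lambda, 45, tolerance = 1e-9)
    expect_equal(null$omega, 1)
  }
})

test_that("identical homeolog counts give omega = 1 and attain the null", {
  p <- unit_pair()
  cs <- count_set(c(10L, 20L, 30L), c(10L, 20L, 30L))
  alt <- fit_heb_alt(cs, p, r = 10)
  null <- fit_heb_null(cs, p, r = 10)
  expect_equal(alt$omega, 1, tolerance = 1e-9)
  expect_equal(alt$lambda, null$lambda, tolerance = 1e-9)
  expect_equal(alt$loglik, null$loglik, tolerance = 1e-10)
})

test_that("the alternative fit beats a log-spaced grid around the solution", {
  fx <- rand_fixture(202, n = 5)
  alt <- fit_heb_alt(fx$counts, fx$pair, fx$r)
  lam_grid <- alt$lambda * exp(seq(-0.5, 0.5, length.out = 60))
  om_grid <- alt$omega * exp(seq(-0.5, 0.5, length.out = 60))
  best_grid <- max(outer(lam_grid, om_grid, Vectorize(function(l, o)
    loglik_heb(fx$counts, fx$pair, fx$r, l, o))))
  expect_gte(alt$loglik + 1e-10, best_grid)
})

test_that("the null fit matches a 1-D likelihood maximization", {
  fx <- rand_fixture(203, n = 4)
  null <- fit_heb_null(fx$counts, fx$pair, fx$r)
  opt <- optimize(function(l) loglik_heb(fx$counts, fx$pair, fx$r, l, 1),
                  c(null$lambda / 20, null$lambda * 20),
                  maximum = TRUE, tol = 1e-12)
  expect_equal(null$lambda, opt$maximum, tolerance = 1e-6)
  expect_gte(null$loglik + 1e-9, opt$objective)
})

test_that("delta-HEB alternative decouples into per-condition fits", {
  fx1 <- rand_fixture(204, n = 3); fx2 <- rand_fixture(205, n = 3)
  p <- fx1$pair
  alt <- fit_dheb_alt(fx1$counts, fx2$counts, p, fx1$r, fx2$r)
  f1 <- fit_heb_alt(fx1$counts, p, fx1$r)
  f2 <- fit_heb_alt(fx2$counts, p, fx2$r)
  expect_equal(alt$lambda, c(f1$lambda, f2$lambda), tolerance = 1e-10)
  expect_equal(alt$omega, c(f1$omega, f2$omega), tolerance = 1e-10)
  expect_equal(alt$loglik, f1$loglik + f2$loglik, tolerance = 1e-10)
  # identical conditions: same ratio in both
  alt_same <- fit_dheb_alt(fx1$counts, fx1$counts, p, fx1$r, fx1$r)
  expect_equal(alt_same$omega[1], alt_same$omega[2], tolerance = 1e-10)
  # n = 1 per condition closed forms
  pu <- unit_pair()
  alt1 <- fit_dheb_alt(count_set(30L, 60L), count_set(50L, 25L), pu, 10, 10)
  expect_equal(alt1$omega, c(2, 0.5), tolerance = 1e-9)
})

test_that("delta-HEB null attains the alternative when conditions agree", {
  fx <- rand_fixture(206, n = 3)
  p <- fx$pair
  null <- fit_dheb_null(fx$counts, fx$counts, p, fx$r, fx$r)
  alt_one <- fit_heb_alt(fx$counts, p, fx$r)
  expect_equal(null$omega, alt_one$omega, tolerance = 1e-8)
  alt <- fit_dheb_alt(fx$counts, fx$counts, p, fx$r, fx$r)
  expect_equal(null$loglik, alt$loglik, tolerance = 1e-8)
})

test_that("doubling counts and depths preserves the shared ratio", {
  p <- unit_pair()
  c1 <- count_set(c(12L, 30L, 25L), c(20L, 55L, 44L), depths = c(1, 1, 1))
  c2 <- count_set(c(24L, 60L, 50L), c(40L, 110L, 88L), depths = c(2, 2, 2))
  null <- fit_dheb_null(c1, c2, p, 10, 10)
  one <- fit_heb_alt(c1, p, 10)
  expect_equal(null$omega, one$omega, tolerance = 1e-6)
})

test_that("delta-HEB null beats a 3-D grid around its solution", {
  fx1 <- rand_fixture(207, n = 3); fx2 <- rand_fixture(208, n = 3)
  p <- fx1$pair
  null <- fit_dheb_null(fx1$counts, fx2$counts, p, fx1$r, fx2$r)
  g <- exp(seq(-0.3, 0.3, length.out = 15))
  best <- -Inf
  for (l1 in null$lambda[1] * g) for (l2 in null$lambda[2] * g)
    for (om in null$omega * g) {
      best <- max(best,
                  loglik_dheb(fx1$counts, fx2$counts, p, fx1$r, fx2$r,
                              l1, l2, om, om))
    }
  expect_gte(null$loglik + 1e-10, best)
})

test_that("nesting, relabeling and depth-scaling invariances hold", {
  for (seed in 211:218) {
    fx <- rand_fixture(seed)
    p <- fx$pair; cs <- fx$counts
    alt <- fit_heb_alt(cs, p, fx$r)
    null <- fit_heb_null(cs, p, fx$r)
    # nested models: lnL1 >= lnL0, score residuals tiny
    expect_gte(alt$loglik + 1e-8, null$loglik)
    expect_lte(alt$score_norm, 1e-8)
    expect_lte(null$score_norm, 1e-8)
    # relabel A <-> B: omega inverts, likelihoods and W unchanged
    ps <- homeolog_pair("gB", "gA", p$length_b, p$length_a)
    css <- count_set(cs$counts_b, cs$counts_a, depths = cs$depths)
    alt_s <- fit_heb_alt(css, ps, fx$r)
    null_s <- fit_heb_null(css, ps, fx$r)
    expect_equal(alt_s$omega, 1 / alt$omega, tolerance = 1e-8)
    expect_equal(alt_s$loglik, alt$loglik, tolerance = 1e-8)
    expect_equal(alt$loglik - null$loglik, alt_s$loglik - null_s$loglik,
                 tolerance = 1e-8)
    # depth rescaling: omega invariant, lambda scales inversely
    cs2 <- count_set(cs$counts_a, cs$counts_b, depths = 3 * cs$depths)
    alt2 <- fit_heb_alt(cs2, p, fx$r)
    null2 <- fit_heb_null(cs2, p, fx$r)
    expect_equal(alt2$omega, alt$omega, tolerance = 1e-7)
    expect_equal(alt2$lambda, alt$lambda / 3, tolerance = 1e-7)
    expect_equal(alt2$loglik - null2$loglik, alt$loglik - null$loglik,
                 tolerance = 1e-7)
  }
})

test_that("omega estimates center at 1 under the null", {
  set.seed(99)
  om <- replicate(1000, {
    a <- rnbinom(5, size = 10, mu = 100)
    b <- rnbinom(5, size = 10, mu = 100)
    fit_heb_alt(count_set(a, b), unit_pair(), 10)$omega
  })
  expect_gt(median(om), 0.9)
  expect_lt(median(om), 1.1)
})

test_that("boundary (all-zero homeolog) fits are refused", {
  p <- unit_pair()
  expect_error(fit_heb_alt(count_set(c(0L, 0L), c(3L, 5L)), p, 10),
               "untestable")
  expect_error(fit_dheb_null(count_set(c(1L, 2L), c(3L, 5L)),
                             count_set(c(1L, 2L), c(0L, 0L)), p, 10, 10),
               "untestable")
})
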