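# Test statistics, multiple-testing correction and whole-table screens.

test_that("heb_statistic is the log2 ratio of normalized means", {
  expect_equal(heb_statistic(8, 1), -3)   # 8-fold bias towards A
  expect_equal(heb_statistic(3, 3), 0)
  expect_equal(heb_statistic(1, 4), 2)
  expect_error(heb_statistic(0, 1), "positive")
})

test_that("dheb_statistic is the difference of condition biases", {
  expect_equal(dheb_statistic(2, 2), 0)
  expect_equal(dheb_statistic(-1, 3), 4)
  # identity: equals the log2 ratio of bias ratios
  a1 <- 3; b1 <- 7; a2 <- 11; b2 <- 2
  expect_equal(dheb_statistic(heb_statistic(a1, b1), heb_statistic(a2, b2)),
               log2((b2 / a2) / (b1 / a1)))
  expect_error(dheb_statistic(Inf, 0), "finite")
})

test_that("testability needs at least one read per homeolog per condition", {
  expect_false(testable_heb(count_set(c(0L, 0L, 0L), c(5L, 3L, 2L))))
  expect_true(testable_heb(count_set(c(1L, 0L, 0L), c(0L, 0L, 1L))))
  expect_true(testable_heb(count_set(c(10L, 10L), c(10L, 10L))))
  good <- count_set(c(2L, 1L), c(3L, 1L))
  zero_b <- count_set(c(2L, 1L), c(0L, 0L))
  expect_true(testable_dheb(good, good))
  expect_false(testable_dheb(good, zero_b))
  expect_false(testable_dheb(zero_b, zero_b))
})

test_that("lrt_statistic references the chi-squared distribution, df 1", {
  eq <- lrt_statistic(-5, -5)
  expect_equal(eq$W, 0); expect_equal(eq$p, 1)
  # survival function oracle: sf(w) = 2 * pnorm(-sqrt(w)) for df = 1
  crit <- lrt_statistic(0, 3.841459 / 2)
  expect_equal(crit$p, 2 * pnorm(-sqrt(3.841459)), tolerance = 1e-12)
  expect_equal(crit$p, 0.05, tolerance = 1e-6)
  ten <- lrt_statistic(-10, -5)
  expect_equal(ten$W, 10)
  expect_equal(ten$p, 2 * pnorm(-sqrt(10)), tolerance = 1e-12)
  expect_equal(ten$p, 1.565e-3, tolerance = 1e-3)
  # slack handling
  expect_equal(lrt_statistic(0, -1e-9)$W, 0)
  expect_error(lrt_statistic(0, -1e-3), "optimizer failure")
})

test_that("bh_adjust reproduces the step-up rule", {
  one <- bh_adjust(0.03)
  expect_equal(one$q, 0.03)
  # hand enumeration: thresholds i * alpha / m = 0.0167, 0.0333, 0.05
  res <- bh_adjust(c(0.01, 0.02, 0.04), alpha = 0.05)
  expect_true(all(res$reject))
  expect_equal(res$q, c(0.03, 0.03, 0.04))
  none <- bh_adjust(c(0.5, 0.9), alpha = 0.05)
  expect_false(any(none$reject))
  # q >= p elementwise; BH rejections subset of uncorrected rejections
  set.seed(8)
  p <- runif(50)^2
  res2 <- bh_adjust(p, 0.05)
  expect_true(all(res2$q >= p))
  expect_true(all(p[res2$reject] <= 0.05))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("run_heb_screen flags planted extreme bias and keeps books", {
  set.seed(61)
  n_null <- 15
  records <- lapply(seq_len(n_null), function(i) {
    list(pair = homeolog_pair(paste0("A", i), paste0("B", i), 1, 1),
         counts = simulate_pair(100, 100, 10, 5))
  })
  # ten pairs with b = 8a exactly at high counts
  planted <- lapply(seq_len(10), function(i) {
    a <- rep(500L, 5)
    list(pair = homeolog_pair(paste0("PA", i), paste0("PB", i), 1, 1),
         counts = count_set(a, 8L * a))
  })
  # one untestable pair
  dead <- list(list(pair = homeolog_pair("DA", "DB", 1, 1),
                    counts = count_set(rep(0L, 5), rep(3L, 5))))
  res <- run_heb_screen(c(records, planted, dead), r = 10)
  expect_equal(nrow(res), n_null + 10 + 1)
  expect_equal(sum(res$testable), n_null + 10)
  idx <- grepl("^PA", res$id_a)
  expect_true(all(res$significant[idx]))
  expect_equal(res$heb[idx], rep(3, 10), tolerance = 1e-9)
  expect_true(all(res$direction[idx] == "B-biased"))
  expect_true(is.na(res$W[res$id_a == "DA"]))
  expect_true(all(res$q >= res$p, na.rm = TRUE))
})

test_that("uncorrected HEB rejections are calibrated under the null", {
  set.seed(62)
  records <- lapply(seq_len(1000), function(i) {
    list(pair = homeolog_pair(paste0("A", i), paste0("B", i), 1, 1),
         counts = simulate_pair(100, 100, 10, 5))
  })
  res <- run_heb_screen(records, r = 10)
  frac <- mean(res$p < 0.05, na.rm = TRUE)
  expect_gt(frac, 0.03); expect_lt(frac, 0.07)
})

test_that("null p-values are close to uniform", {
  set.seed(63)
  p <- replicate(2000, {
    a <- rnbinom(5, size = 10, mu = 100)
    b <- rnbinom(5, size = 10, mu = 100)
    f1 <- fit_heb_alt(count_set(a, b), unit_pair(), 10)
    f0 <- fit_heb_null(count_set(a, b), unit_pair(), 10)
    lrt_statistic(f0$loglik, f1$loglik)$p
  })
  ks <- max(abs(sort(p) - (seq_along(p) - 0.5) / length(p)))
  expect_lt(ks, 0.05)
})

test_that("run_dheb_screen is null-calibrated and label-antisymmetric", {
  set.seed(64)
  records <- lapply(seq_len(300), function(i) {
    list(pair = homeolog_pair(paste0("A", i), paste0("B", i), 1, 1),
         counts_1 = simulate_pair(100, 150, 10, 4),
         counts_2 = simulate_pair(100, 150, 10, 4))
  })
  res <- run_dheb_screen(records, r_1 = 10, r_2 = 10)
  # identical generating conditions: rejections at most nominal + 3 MC SE
  frac <- mean(res$p < 0.05, na.rm = TRUE)
  expect_lte(frac, 0.05 + 3 * sqrt(0.05 * 0.95 / 300))
  # dheb column equals HEB_2 - HEB_1 recomputed from normalized means
  expect_equal(res$dheb, res$heb_2 - res$heb_1, tolerance = 1e-10)
  # swapping condition labels negates dheb, keeps W, p, q
  swapped <- lapply(records, function(rec)
    list(pair = rec$pair, counts_1 = rec$counts_2, counts_2 = rec$counts_1))
  res_s <- run_dheb_screen(swapped, r_1 = 10, r_2 = 10)
  expect_equal(res_s$dheb, -res$dheb, tolerance = 1e-10)
  expect_equal(res_s$W, res$W, tolerance = 1e-6)
  expect_equal(res_s$q, res$q, tolerance = 1e-6)
})

test_that("run_dheb_screen detects large planted bias changes", {
  set.seed(65)
  records <- lapply(seq_len(20), function(i) {
    shift <- i <= 5  # five pairs with a 16-fold change in bias
    list(pair = homeolog_pair(paste0("A", i), paste0("B", i), 1, 1),
         counts_1 = simulate_pair(400, 400, 10, 6),
         counts_2 = simulate_pair(400, if (shift) 6400 else 400, 10, 6))
  })
  res <- run_dheb_screen(records, r_1 = 10, r_2 = 10)
  expect_true(all(res$significant[1:5]))
  expect_true(all(res$direction[1:5] == "B-biased"))
  expect_lte(sum(res$significant[6:20]), 2)
})
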