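test_that("median rate CI comes from order statistics", {
  e <- estimate_gcr_rate(rep(3e-8, 7))
  expect_equal(e$median, 3e-8)
  expect_equal(c(e$ci_low, e$ci_high), c(3e-8, 3e-8))

  e5 <- estimate_gcr_rate(c(1, 2, 3, 4, 5) * 1e-8)
  expect_equal(e5$median, 3e-8)
  expect_equal(c(e5$ci_low, e5$ci_high), c(1e-8, 5e-8))
  expect_equal(e5$coverage, 1 - 2 * 0.5^5)  # 93.75%: best available at n = 5

  e4 <- estimate_gcr_rate(c(1, 2, 3, 4) * 1e-8)
  expect_equal(e4$median, 2.5e-8)
  expect_error(estimate_gcr_rate(numeric(0)))
})

test_that("rate CI achieves nominal coverage once n is large enough", {
  # at n = 49 the order-statistic interval (x_(18), x_(32)) covers >= 95%
  e <- estimate_gcr_rate(seq_len(49))
  expect_gte(e$coverage, 0.95)
  expect_lte(e$ci_low, e$median)
  expect_gte(e$ci_high, e$median)
})

test_that("fold changes reproduce strain-table rounding", {
  expect_equal(as.numeric(fold_change(8.4e-8, 8.4e-8)), 1)
  expect_equal(as.numeric(fold_change(1.7e-6, 8.4e-8)), 20)
  expect_equal(as.numeric(fold_change(1.0e-5, 8.4e-8)), 120)
  expect_equal(as.numeric(fold_change(2.2e-7, 8.4e-8)), 3)
  expect_equal(as.numeric(fold_change(1.3e-8, 8.4e-8)), 0.2)
  expect_equal(as.numeric(fold_change(6.1e-8, 8.4e-8)), 0.7)
  e <- estimate_gcr_rate(rep(2e-8, 3))
  expect_equal(as.numeric(fold_change(e, e)), 1)
  expect_error(fold_change(1e-8, 0))
})

test_that("observed arm rates split the total rate by duplication fraction", {
  t2 <- arm_duplication_rates(2.4e-7, structure(c(A = 2L, B = 1L), n = 3L),
                              arms = c("A", "B"))
  expect_equal(t2$rate, c(1.6e-7, 0.8e-7))
  # wild-type chrIII-R worked example: 8.4e-8 * 28 / 112
  wt <- arm_duplication_rates(8.4e-8, structure(c(`chrIII-R` = 28L), n = 112L),
                              arms = c("chrIII-R", "chrXI-L"))
  expect_equal(wt$rate[1], 2.1e-8)
  expect_equal(wt$rate[2], 0)
  expect_false(is.na(wt$upper_limit[2]))
  # all-zero cohort: rates 0 with upper limits everywhere
  z <- arm_duplication_rates(1e-7, structure(integer(0), n = 10L),
                             arms = c("A", "B"))
  expect_equal(z$rate, c(0, 0))
  expect_true(all(!is.na(z$upper_limit)))
})

test_that("expected arm rates: identity, uniform scaling, and hand example", {
  ctrl <- arm_duplication_rates(8e-8, structure(c(A = 1L, B = 1L), n = 2L),
                                arms = c("A", "B"))
  idm <- expected_arm_rates(ctrl, ctrl)
  expect_equal(idm$ratio, c(1, 1))
  expect_equal(idm$log2_ratio, c(0, 0))
  expect_equal(attr(idm, "scaling_constant"), 1)

  t3 <- ctrl
  t3$rate <- 3 * ctrl$rate
  t3$upper_limit <- 3 * ctrl$upper_limit
  sc <- expected_arm_rates(ctrl, t3)
  expect_equal(sc$ratio, c(1, 1))
  expect_equal(sc$expected_rate, 3 * ctrl$rate)
  expect_equal(attr(sc, "scaling_constant"), 3)

  test <- arm_duplication_rates(2.4e-7, structure(c(A = 2L, B = 1L), n = 3L),
                                arms = c("A", "B"))
  ex <- expected_arm_rates(ctrl, test)
  expect_equal(attr(ex, "scaling_constant"), 3)
  expect_equal(ex$expected_rate, c(1.2e-7, 1.2e-7))
  expect_equal(ex$ratio, c(4 / 3, 2 / 3), tolerance = 1e-12)
  expect_equal(ex$log2_ratio, c(log2(4 / 3), log2(2 / 3)), tolerance = 1e-12)
})

test_that("expected arm rates apply the zero-count rules", {
  ctrl <- arm_duplication_rates(1e-7, structure(c(A = 4L, B = 0L) [1],
                                                n = 10L),
                                arms = c("A", "B", "C"))
  test <- arm_duplication_rates(4e-7, structure(c(A = 6L, B = 2L), n = 10L),
                                arms = c("A", "B", "C"))
  ex <- expected_arm_rates(ctrl, test)
  # control B count 0 -> expected from the control upper limit, scaled
  i <- match("B", ex$arm)
  expect_equal(ex$expected_rate[i],
               ctrl$upper_limit[match("B", ctrl$arm)] *
                 attr(ex, "scaling_constant"))
  # both zero on C -> ratio 1
  expect_equal(ex$ratio[match("C", ex$arm)], 1)
  # test zero with upper limit below expectation -> upper limit stands in
  test2 <- arm_duplication_rates(1e-6, structure(c(B = 5L), n = 10L),
                                 arms = c("A", "B", "C"))
  ex2 <- expected_arm_rates(ctrl, test2)
  iA <- match("A", ex2$arm)
  expect_equal(ex2$observed_rate[iA], 1e-6 / 5)
  expect_equal(ex2$ratio[iA], (1e-6 / 5) / ex2$expected_rate[iA])
  # significance flags from a bulk-rate fold interval
  ex3 <- expected_arm_rates(ctrl, test, fold_ci = c(3, 5))
  expect_type(ex3$significant, "logical")
  expect_false(any(is.na(ex3$significant)))
})

test_that("MC multinomial test: degenerate and enumerable cases", {
  # observed exactly at expectation -> statistic 0 -> p = 1
  r <- mc_multinomial_test(c(5, 5), c(0.5, 0.5), replicates = 500, seed = 1)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # (10, 0) under p = (1/2, 1/2): exact two-sided tail is 2 * (1/2)^10
  exact <- 2 * 0.5^10
  r2 <- mc_multinomial_test(c(10, 0), c(0.5, 0.5), replicates = 2000,
                            seed = 2)
  se <- sqrt(exact * (1 - exact) / 2000)
  expect_lt(abs(r2$p_value - exact), 4 * se + 1 / 2001)
  expect_error(mc_multinomial_test(c(1, 2, 3), c(0.5, 0.5), 10, 1))
  expect_error(mc_multinomial_test(c(1, 2), c(0.5, 0.4), 10, 1))
})

test_that("MC multinomial p-values are reproducible given a seed", {
  obs <- c(12, 3, 1, 4)
  p <- c(0.5, 0.25, 0.15, 0.1)
  r1 <- mc_multinomial_test(obs, p, 1000, seed = 7)
  r2 <- mc_multinomial_test(obs, p, 1000, seed = 7)
  expect_identical(r1$p_value, r2$p_value)
})

test_that("exact binomial tail matches brute-force pmf summation", {
  expect_equal(exact_binomial_overrep(0, 10, 0.3)$p_value, 1)
  expect_equal(signif(exact_binomial_overrep(5, 10, 0.1)$p_value, 3), 1.63e-3)
  expect_equal(exact_binomial_overrep(3, 3, 0.5)$p_value, 0.125)
  brute <- function(k, N, p) {
    if (k == 0) return(1)
    sum(vapply(k:N, function(j)
      choose(N, j) * p^j * (1 - p)^(N - j), numeric(1)))
  }
  set.seed(11)
  for (rep in 1:20) {
    N <- sample(5:30, 1)
    k <- sample(0:N, 1)
    p <- runif(1, 0.05, 0.95)
    expect_equal(exact_binomial_overrep(k, N, p)$p_value, brute(k, N, p),
                 tolerance = 1e-12)
  }
  expect_error(exact_binomial_overrep(1, 10, 0))
})

test_that("Fisher's exact test matches enumeration on small tables", {
  expect_equal(fisher_exact_2x2(matrix(5, 2, 2))$p_value, 1)
  expect_equal(fisher_exact_2x2(matrix(c(3, 0, 0, 3), 2))$p_value, 0.1)
  expect_error(fisher_exact_2x2(matrix(0, 2, 2)))
})

test_that("paired exact test doubles the smaller discordant tail", {
  expect_equal(paired_exact_test(4, 4)$p_value, 1)
  expect_equal(paired_exact_test(5, 0)$p_value, 2 * 0.5^5)
  expect_equal(paired_exact_test(11, 2)$p_value, 184 / 8192)
  expect_warning(r <- paired_exact_test(0, 0))
  expect_equal(r$p_value, 1)
})

test_that("hypergeometric overlap matches exact tail sums", {
  expect_equal(hypergeom_overlap(20, 0, 5, 0)$p_value, 1)
  expect_equal(hypergeom_overlap(32, 7, 7, 5)$p_value, 6476 / 3365856,
               tolerance = 1e-9)
  expect_equal(hypergeom_overlap(10, 5, 5, 5)$p_value, 1 / choose(10, 5))
  expect_error(hypergeom_overlap(10, 11, 5, 2))
})

test_that("rank-sum test: exact small-sample and degenerate behaviour", {
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p_value, 0.1)
  expect_equal(rank_sum_test(c(2, 2, 2), c(2, 2, 2))$p_value, 1)
  x <- c(1.2, 3.1, 0.8, 2.2)
  expect_equal(rank_sum_test(x, x)$p_value, 1)
})

test_that("Bonferroni correction thresholds and decisions", {
  b <- adjust_bonferroni(c(0.01, 0.02, 0.5), alpha = 0.05)
  expect_equal(b$threshold, 0.05 / 3)
  expect_equal(b$reject, c(TRUE, FALSE, FALSE))
  expect_equal(adjust_bonferroni(0.03)$threshold, 0.05)
})
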