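test_that("contingency counts exposure by arm and ignores input order", {
  t <- contingency(c(rep(TRUE, 4), rep(FALSE, 6)),
                   c(rep(TRUE, 2), rep(FALSE, 8)))
  expect_identical(c(t$a, t$b, t$c, t$d), c(4L, 6L, 2L, 8L))
  withr::with_seed(1, {
    t2 <- contingency(sample(c(rep(TRUE, 4), rep(FALSE, 6))),
                      sample(c(rep(TRUE, 2), rep(FALSE, 8))))
  })
  expect_equal(t, t2)
  # all-exposed boundary
  t3 <- contingency(rep(TRUE, 3), rep(TRUE, 3))
  expect_identical(c(t3$b, t3$d), c(0L, 0L))
  expect_error(contingency(logical(0), TRUE),
               class = "cohortsens_empty_cohort")
})

test_that("fisher_exact reproduces hand-enumerated tables", {
  # symmetric table: no association
  r <- fisher_exact(table2x2(10, 10, 10, 10))
  expect_equal(r$odds_ratio, 1.0)
  expect_equal(r$p_value, 1.0)
  # margins (4,4,4,4): five tables, point probs (1,16,36,16,1)/70;
  # observed a=3 has 16/70, so p = (1+16+16+1)/70 = 34/70
  r2 <- fisher_exact(table2x2(3, 1, 1, 3))
  expect_equal(r2$odds_ratio, 9.0)
  expect_equal(r2$p_value, 34 / 70)
  # cohort-scale table built from case/baseline-control depression rates
  r3 <- fisher_exact(table2x2(1751, 8249, 1424, 8576))
  expect_equal(r3$odds_ratio, 1751 * 8576 / (8249 * 1424))
  expect_lt(abs(r3$odds_ratio - 1.2784), 1e-3)
  expect_lt(r3$p_value, 1e-3)
  # zero margin is degenerate
  expect_error(fisher_exact(table2x2(0, 5, 0, 5)),
               class = "cohortsens_degenerate_table")
})

test_that("fisher_exact agrees with brute-force enumeration on random
           small tables", {
  withr::with_seed(12, {
    for (i in 1:200) {
      cells <- rmultinom(1, sample(4:40, 1), prob = runif(4, 0.05, 1))[, 1]
      a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
      if (a + b == 0 || c + d == 0 || a + c == 0 || b + d == 0) next
      got <- fisher_exact(table2x2(a, b, c, d))
      want <- oracle_fisher(a, b, c, d)
      expect_equal(got$p_value, want$p_value)
      expect_equal(got$odds_ratio, want$odds_ratio)
      # and the p-value matches stats::fisher.test's two-sided convention
      expect_equal(got$p_value,
                   stats::fisher.test(matrix(c(a, c, b, d), 2))$p.value,
                   tolerance = 1e-12)
    }
  })
})

test_that("swapping exposure labels inverts the OR and preserves p", {
  withr::with_seed(3, {
    for (i in 1:50) {
      cells <- 1 + rpois(4, 20)
      r1 <- fisher_exact(table2x2(cells[1], cells[2], cells[3], cells[4]))
      r2 <- fisher_exact(table2x2(cells[2], cells[1], cells[4], cells[3]))
      expect_equal(r2$odds_ratio, 1 / r1$odds_ratio)
      expect_equal(r2$p_value, r1$p_value)
    }
  })
})

test_that("prevalence-implied odds ratios match the closed form", {
  expect_equal(odds_ratio_from_prevalence(0.5, 0.5), 1.0)
  expect_lt(abs(odds_ratio_from_prevalence(0.1751, 0.1424) - 1.2784), 1e-4)
  expect_lt(abs(odds_ratio_from_prevalence(0.1761, 0.0661) - 3.0198), 1e-4)
  expect_error(odds_ratio_from_prevalence(0, 0.5),
               class = "cohortsens_config_error")
  # inverse round-trips
  p0 <- prevalence_for_odds_ratio(0.1761, 1.168)
  expect_equal(odds_ratio_from_prevalence(0.1761, p0), 1.168)
})

test_that("bootstrap resampling is reproducible and respects the
           replacement flag", {
  pop_case <- rep(c(TRUE, FALSE), c(30, 70))
  pop_ctrl <- rep(c(TRUE, FALSE), c(20, 80))
  r1 <- bootstrap_association(pop_case, pop_ctrl, n = 50, reps = 5,
                              seed = 101)
  r2 <- bootstrap_association(pop_case, pop_ctrl, n = 50, reps = 5,
                              seed = 101)
  expect_identical(r1, r2)
  expect_identical(nrow(r1), 5L)
  expect_error(bootstrap_association(pop_case, pop_ctrl, n = 200, reps = 2,
                                     replace = FALSE),
               class = "cohortsens_config_error")
  r3 <- bootstrap_association(pop_case, pop_ctrl, n = 100, reps = 2,
                              seed = 1, replace = FALSE)
  # without replacement at n = population, counts are exact
  expect_identical(r3$a, c(30L, 30L))
  expect_identical(r3$c, c(20L, 20L))
})

test_that("median replicate OR converges to the population odds ratio", {
  target <- odds_ratio_from_prevalence(0.1751, 0.1424)
  s <- summarize_replicates(
    simulate_association(0.1751, 0.1424, n = 10000, reps = 100, seed = 55))
  expect_lt(abs(s$median_or - target), 0.03)
  # smaller n: wider distribution around the same center
  s_small <- summarize_replicates(
    simulate_association(0.1751, 0.1424, n = 1000, reps = 100, seed = 56))
  expect_gt(s_small$ci_range, s$ci_range)
})

test_that("replicate summaries are order statistics of the OR distribution", {
  res <- tibble::tibble(replicate = 1:3, n = 10, odds_ratio = c(3, 1, 2),
                        p_value = c(0.01, 0.5, 0.04))
  s <- summarize_replicates(res)
  expect_equal(s$median_or, 2)
  expect_lt(s$ci_low, 1.11)
  expect_gt(s$ci_high, 2.89)
  expect_identical(s$n_nonsignificant, 1L)
  expect_true(s$ci_low <= s$median_or && s$median_or <= s$ci_high)
})

test_that("CI width ratios compare like for like", {
  s1 <- tibble::tibble(ci_range = 2)
  expect_equal(ci_width_ratio(s1, s1), 1.0)
  expect_error(ci_width_ratio(s1, tibble::tibble(ci_range = 0)),
               class = "cohortsens_degenerate_table")
  # 1/sqrt(n) scaling oracle at n = 2500 vs 10000
  a <- summarize_replicates(
    simulate_association(0.1751, 0.1424, 2500, reps = 200, seed = 77))
  b <- summarize_replicates(
    simulate_association(0.1751, 0.1424, 10000, reps = 200, seed = 78))
  expect_lt(abs(ci_width_ratio(a, b) - 2.0), 0.5)
})
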