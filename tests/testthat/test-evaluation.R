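test_that("the binomial chance level matches theory and simulation", {
  expect_equal(chance_level(80, 0.05), 58.75)
  expect_gt(chance_level(80, 1e-6), chance_level(80, 0.05))
  expect_lte(chance_level(80, 1e-12), 100)
  expect_equal(chance_level(20, 0.05), 70)

  # Monte-Carlo oracle: strictly exceeding the threshold controls the
  # false-positive rate; the next-lower cutoff does not
  k <- chance_level(80, 0.05) * 80 / 100
  draws <- withr::with_seed(101, stats::rbinom(1e6, 80, 0.5))
  expect_lt(mean(draws > k), 0.05)
  expect_gte(mean(draws > k - 1), 0.05)
})

test_that("the Friedman statistic matches reference implementations", {
  # identical columns: no effect
  flat <- matrix(rep(c(60, 70, 55), 4), 3, 4)
  f0 <- friedman_rank_test(flat)
  expect_equal(f0$chi2, 0)
  expect_equal(f0$p, 1)

  # tie-free 3x3: brute-force ranks (sort-based, no rank()) + closed form
  y <- matrix(c(1, 5, 3,
                6, 2, 4,
                8, 9, 7), 3, 3, byrow = TRUE)
  brute_ranks <- t(apply(y, 1, function(r) match(seq_along(r), order(r))))
  Rj <- colSums(brute_ranks)
  n <- 3; k <- 3
  chi_closed <- 12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)
  expect_equal(friedman_rank_test(y)$chi2, chi_closed)

  # against stats::friedman.test on random tables with ties
  for (seed in 1:5) {
    tab <- withr::with_seed(seed, matrix(sample(seq(50, 80, 2.5), 24,
                                                replace = TRUE), 6, 4))
    ref <- stats::friedman.test(tab)
    mine <- friedman_rank_test(tab)
    expect_equal(mine$chi2, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
    expect_equal(mine$df, unname(ref$parameter))
  }
})

test_that("post-hoc rank comparisons flag a dominant method and respect Bonferroni", {
  expect_false(any(posthoc_rank_tests(matrix(rep(1:10, 3), 10, 3))$significant))

  base <- withr::with_seed(7, matrix(stats::runif(18 * 4, 50, 70), 18, 4))
  base[, 2] <- base[, 2] + 30
  ph <- posthoc_rank_tests(base)
  expect_true(all(ph$significant[2, -2]))
  expect_true(all(ph$p_adjusted >= ph$p_raw - 1e-15))
})

test_that("t-tests against chance and between methods follow closed forms", {
  col <- c(68, 71, 74, 69, 72, 70, 73, 68, 75, 70, 69, 72, 71, 74, 68, 73, 70, 72)
  p <- compare_to_chance(col, 80)
  tstat <- (mean(col) - 58.75) / (stats::sd(col) / sqrt(18))
  expect_equal(p, stats::pt(tstat, 17, lower.tail = FALSE))
  expect_lt(p, 0.001)
  expect_lt(compare_to_chance(col + 5, 80), p)     # monotone in shift
  expect_equal(compare_to_chance(rep(58.75, 6) + 10, 80), 0)  # zero variance

  tab <- cbind(a = col, b = col, c = col + c(2, -1, 3, 1, 2, 0, 4, -2, 1,
                                             2, 3, -1, 0, 2, 1, 3, 2, 1))
  pp <- paired_ttests(tab)
  expect_equal(pp["a", "b"], 1)                    # identical columns
  raw <- stats::t.test(tab[, "a"], tab[, "c"], paired = TRUE)$p.value
  expect_equal(pp["a", "c"], min(1, raw * 3))
  # hand-computed paired t at n = 5
  x <- c(60, 62, 58, 61, 64); z <- c(55, 57, 56, 54, 57)
  d <- x - z
  tman <- mean(d) / (stats::sd(d) / sqrt(5))
  pman <- 2 * stats::pt(-abs(tman), 4)
  expect_equal(paired_ttests(cbind(x, z))["x", "z"], min(1, pman * 1))
})

test_that("subject exclusion ranks ascending with id tie-breaks", {
  t1 <- ref_table("meg_within")
  rep5 <- exclude_poor(t1$values[, "average"], k = 5,
                       ids = as.integer(rownames(t1$values)))
  expect_identical(rep5$excluded_ids, c(3L, 5L, 11L, 12L, 14L))
  expect_equal(length(rep5$kept_ids), 13L)

  expect_length(exclude_poor(c(`1` = 60, `2` = 70), k = 0)$excluded_ids, 0L)
  tied <- exclude_poor(stats::setNames(rep(50, 6), 6:1), k = 3)
  expect_identical(tied$excluded_ids, c(1L, 2L, 3L))
  expect_error(exclude_poor(c(`1` = 60), k = 5), "below")
})

test_that("reference tables load with the published geometry", {
  dims <- list(meg_within = c(18L, 3L), meg_mi = c(18L, 7L),
               eeg_mi = c(17L, 7L), meg_pm = c(18L, 7L), eeg_pm = c(17L, 7L))
  for (nm in names(dims)) {
    tab <- ref_table(nm)
    expect_equal(dim(tab$values), dims[[nm]], info = nm)
    expect_equal(length(tab$printed_mean), dims[[nm]][2], info = nm)
    expect_true(all(tab$values >= 0 & tab$values <= 100))
  }
})

test_that("within-subject cross-validation scores separable and null subjects", {
  withr::with_seed(21, {
    X <- rbind(matrix(stats::rnorm(300, 4), 30, 10),
               matrix(stats::rnorm(300, -4), 30, 10))
    y <- rep(c(1L, -1L), each = 30)
    fm <- feature_matrix(X, y, 1L, "flattened_timecourse")
  })
  expect_equal(within_subject_l1(fm, rho = 0.5), 100)

  withr::with_seed(22, {
    Xn <- matrix(stats::rnorm(600), 60, 10)
    fmn <- feature_matrix(Xn, y, 1L, "flattened_timecourse")
  })
  acc_null <- within_subject_l1(fmn, rho = 0.5)
  expect_lt(abs(acc_null - 50), 15)
})
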