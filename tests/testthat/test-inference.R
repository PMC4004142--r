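test_that("chi-square homogeneity matches hand examples and edge cases", {
  # hand sum of (O-E)^2/E on successes (1,3) of totals (4,4)
  ht <- chi2_homogeneity(proportion_table(c(1, 3), c(4, 4)))
  expect_equal(ht$statistic, 2.0)
  expect_equal(ht$df, 1)
  # perfectly homogeneous table
  expect_equal(chi2_homogeneity(proportion_table(c(10, 20), c(100, 200)))$statistic, 0)
  expect_error(proportion_table(c(1, 0), c(4, 0)), "positive")
  expect_error(chi2_homogeneity(proportion_table(c(0, 0), c(5, 5))), "expected")
})

test_that("chi-square matches a brute-force Pearson oracle on random tables", {
  set.seed(42)
  for (i in 1:1000) {
    k <- sample(2:6, 1)
    totals <- sample(5:200, k, replace = TRUE)
    successes <- vapply(totals, function(n) sample.int(n - 1, 1), 0L)
    ht <- chi2_homogeneity(proportion_table(successes, totals))
    expect_equal(ht$statistic, oracle_chi2(successes, totals),
                 tolerance = 1e-9)
    expect_equal(ht$df, k - 1)
  }
})

test_that("the 2x2 closed form equals the k=2 homogeneity test", {
  expect_equal(chi2_2x2(200, 800, 100, 900)$statistic, 39.21569,
               tolerance = 1e-6)
  expect_equal(chi2_2x2(10, 30, 20, 60)$statistic, 0)  # equal odds rows
  set.seed(7)
  for (i in 1:200) {
    a <- sample(1:100, 1); b <- sample(1:100, 1)
    c <- sample(1:100, 1); d <- sample(1:100, 1)
    expect_equal(chi2_2x2(a, b, c, d)$statistic,
                 chi2_homogeneity(proportion_table(c(a, c), c(a + b, c + d)))$statistic,
                 tolerance = 1e-9)
  }
  expect_error(chi2_2x2(0, 0, 5, 5), "margin")
})

test_that("Bonferroni adjustment divides the level and only removes decisions", {
  expect_equal(bonferroni_alpha(0.05, 35), 0.05 / 35)
  expect_equal(round(bonferroni_alpha(0.05, 35), 4), 0.0014)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  set.seed(1)
  p <- runif(200)
  expect_true(all(which(p < bonferroni_alpha(0.05, 12)) %in% which(p < 0.05)))
})

test_that("one-way ANOVA matches hand computation and the summary route", {
  ht <- anova_oneway(list(c(0, 1), c(2, 3)))
  expect_equal(ht$statistic, 8)
  expect_equal(ht$df, c(1, 2))
  expect_equal(anova_oneway(list(c(1, 2, 3), c(1, 2, 3)))$statistic, 0)
  expect_equal(anova_from_summary(c(0, 2), c(1, 1), c(2, 2))$statistic, 4)
  expect_equal(anova_from_summary(c(3, 3, 3), c(1, 2, 1), c(5, 5, 9))$statistic, 0)

  set.seed(11)
  for (i in 1:1000) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(j) rnorm(sample(3:20, 1), mean = j))
    raw <- anova_oneway(groups)
    expect_equal(raw$statistic, oracle_anova_F(groups), tolerance = 1e-9)
    summ <- anova_from_summary(vapply(groups, mean, 0),
                               vapply(groups, stats::sd, 0),
                               lengths(groups))
    expect_equal(summ$statistic, raw$statistic, tolerance = 1e-9)
    expect_equal(summ$p_value, raw$p_value, tolerance = 1e-9)
  }
})

test_that("pooled t matches hand values, t.test, and is antisymmetric", {
  ht <- pooled_t(0, 1, 2, 2, 1, 2)
  expect_equal(abs(ht$statistic), 2)
  expect_equal(ht$df, 2)
  expect_equal(pooled_t(5, 2, 10, 5, 3, 12)$statistic, 0)
  set.seed(3)
  for (i in 1:50) {
    x <- rnorm(sample(3:30, 1)); y <- rnorm(sample(3:30, 1), 0.5)
    mine <- pooled_t(mean(x), stats::sd(x), length(x),
                     mean(y), stats::sd(y), length(y))
    ref <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-9)
    flipped <- pooled_t(mean(y), stats::sd(y), length(y),
                        mean(x), stats::sd(x), length(x))
    expect_equal(flipped$statistic, -mine$statistic)
    expect_equal(flipped$p_value, mine$p_value)
  }
})

test_that("Tukey HSD on means finds separated groups and nothing in noise", {
  set.seed(21)
  apart <- list(a = rnorm(50, 0), b = rnorm(50, 10), c = rnorm(50, 20))
  tk <- tukey_hsd_means(apart)
  expect_true(all(tk$significant))
  same <- list(a = rnorm(60), b = rnorm(60), c = rnorm(60))
  tk0 <- tukey_hsd_means(same, alpha = 1e-6)
  expect_false(any(tk0$significant))
  # significant-pair set grows weakly with alpha
  mixed <- list(a = rnorm(30, 0), b = rnorm(30, 0.5), c = rnorm(30, 3))
  t_small <- tukey_hsd_means(mixed, alpha = 0.001)
  t_big <- tukey_hsd_means(mixed, alpha = 0.2)
  expect_true(all(!t_small$significant | t_big$significant))
})

test_that("Tukey-type comparison of proportions behaves like its chi-square analogue", {
  eq <- tukey_hsd_proportions(proportion_table(c(30, 30, 30), c(100, 100, 100)))
  expect_false(any(eq$significant))
  # two groups: direction of the decision agrees with the 2x2 chi-square
  set.seed(9)
  for (i in 1:100) {
    n <- sample(200:2000, 2, replace = TRUE)
    s <- c(rbinom(1, n[1], 0.3), rbinom(1, n[2], sample(c(0.3, 0.4), 1)))
    tk <- tukey_hsd_proportions(proportion_table(s, n), alpha = 0.05)
    chi_p <- chi2_2x2(s[1], n[1] - s[1], s[2], n[2] - s[2])$p_value
    expect_equal(tk$significant, chi_p < 0.05)
  }
  # endpoint proportions use the adjusted transform rather than failing
  ends <- tukey_hsd_proportions(proportion_table(c(0, 50), c(60, 60)))
  expect_true(all(is.finite(ends$q)))
  expect_true(ends$significant)
})

test_that("grid scan labels only genuinely enriched cells and is symmetric", {
  base <- matrix(100L, 7, 5)
  same <- grid_proportion_scan(base, base * 3L)
  expect_true(all(same$label == "no_difference"))

  planted <- base; planted[3, 2] <- 400L      # Tuesday morning excess
  scan <- grid_proportion_scan(planted, base * 3L)
  hit <- scan[scan$weekday == 2 & scan$interval == "morning", ]
  expect_equal(hit$label, "users_enriched")
  expect_gt(hit$chi2, qchisq(1 - 0.05 / 35, 1))
  # swapping the groups swaps the labels
  swapped <- grid_proportion_scan(base * 3L, planted)
  hit2 <- swapped[swapped$weekday == 2 & swapped$interval == "morning", ]
  expect_equal(hit2$label, "dropouts_enriched")
  relabel <- function(l) ifelse(l == "users_enriched", "dropouts_enriched",
                         ifelse(l == "dropouts_enriched", "users_enriched", l))
  expect_equal(swapped$label, relabel(scan$label))
})
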