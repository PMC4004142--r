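test_that("trend fit matches hand OLS and classifies degenerate series", {
  ht <- fit_user_trend(c(0.2, 0.4, 0.3, 0.5))
  expect_equal(ht$slope, 0.08)   # Sxy = 0.4, Sxx = 5
  expect_equal(ht$n_points, 4L)
  flat <- fit_user_trend(rep(0.5, 6))
  expect_equal(flat$slope, 0)
  expect_equal(flat$classification, "NoTrend")
  ramp <- fit_user_trend(seq(0.1, 0.9, length.out = 10))
  expect_equal(ramp$classification, "Improver")
  expect_equal(ramp$p_value, 0)  # noiseless fit
  expect_error(fit_user_trend(c(0.1, 0.2)), "at least 3")
})

test_that("slope and p equal the lm oracle on random series", {
  set.seed(13)
  for (i in 1:1000) {
    y <- runif(sample(3:40, 1))
    mine <- fit_user_trend(y)
    fit <- summary(stats::lm(y ~ x, data = data.frame(x = seq_along(y), y = y)))
    expect_equal(mine$slope, unname(stats::coef(fit)[2, 1]), tolerance = 1e-10)
    expect_equal(mine$p_value, unname(stats::coef(fit)[2, 4]), tolerance = 1e-9)
  }
})

test_that("reversing a series negates the slope and preserves the p-value", {
  set.seed(17)
  for (i in 1:100) {
    y <- runif(sample(4:30, 1))
    a <- fit_user_trend(y); b <- fit_user_trend(rev(y))
    expect_equal(b$slope, -a$slope, tolerance = 1e-12)
    expect_equal(b$p_value, a$p_value, tolerance = 1e-12)
  }
})

test_that("cohort trends classify eligible Actives and partition them", {
  coh <- generate_cohort(recovery_config(
    c(Active = 30, ActiveImprover = 15, ActiveDecliner = 15), seed = 23,
    trend_slope = c(ActiveImprover = 0.02, ActiveDecliner = -0.02),
    rating_noise_sd = 0.05))
  tf <- run_trend_stage(coh)
  expect_equal(nrow(tf$trends), 60)     # all Actives eligible here
  expect_equal(sum(tf$counts), 60)
  arch <- attr(coh, "archetypes")
  merged <- dplyr::inner_join(tf$trends, arch, by = "user_id")
  # steep clean trends are detected in the intended direction
  imp <- merged$archetype == "ActiveImprover"
  dec <- merged$archetype == "ActiveDecliner"
  expect_gt(mean(merged$classification[imp] == "Improver"), 0.9)
  expect_gt(mean(merged$classification[dec] == "Decliner"), 0.9)
  expect_true(all(merged$slope[imp] > 0))
  expect_true(all(merged$slope[dec] < 0))
})

test_that("a cohort of noiseless positive ramps is 100% Improvers", {
  coh <- generate_cohort(recovery_config(
    c(ActiveImprover = 10), seed = 29,
    trend_slope = c(ActiveImprover = 0.004, ActiveDecliner = -0.004),
    rating_noise_sd = 0,
    baseline_rating_law = law("beta", shape1 = 40, shape2 = 60),
    picture_count_law = list(NonUser = law("constant", value = 0),
                             NonActive = law("constant", value = 1),
                             SemiActive = law("nbinom", mu = 4.1, size = 2, lo = 2, hi = 9),
                             Active = law("duniform", lo = 20, hi = 40))))
  tf <- run_trend_stage(coh)
  expect_equal(unname(tf$counts[["Improver"]]), 10)
})

test_that("improver comparisons flag only the variable that differs", {
  trends <- tibble::tibble(
    user_id = sprintf("u%d", 1:12),
    classification = factor(rep(c("Improver", "NoTrend"), each = 6),
                            levels = c("Improver", "Decliner", "NoTrend")))
  base <- c(10, 20, 30, 40, 50, 60)
  users <- tibble::tibble(
    user_id = trends$user_id,
    n_valid_pictures = c(base + 100, base),   # improvers take far more pictures
    usage_period_days = rep(base, 2),
    pictures_per_day = rep(base, 2))
  cmp <- compare_improvers(trends, users)
  expect_lt(cmp$n_pictures$p_value, 0.001)
  expect_equal(cmp$usage_period_days$statistic, 0)
  expect_equal(cmp$pictures_per_day$statistic, 0)
  expect_equal(cmp$n_pictures$df, 10)
})
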