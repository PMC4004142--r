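test_that("generated archetypes respect their usage bounds", {
  coh <- generate_cohort(cohort_config(n_per_archetype = c(Active = 5), seed = 1))
  expect_equal(nrow(coh$users), 5)
  us <- summarize_users(coh)
  expect_true(all(us$n_raw >= 10))
  expect_true(all(us$usage_period_days >= 7))
})

test_that("the same config and seed reproduce the cohort exactly", {
  cfg <- cohort_config(n_per_archetype = c(NonUser = 10, NonActive = 10,
                                           SemiActive = 10, Active = 5),
                       seed = 77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  for (tab in names(a)) expect_identical(a[[tab]], b[[tab]], info = tab)
  c2 <- generate_cohort(cohort_config(n_per_archetype = c(NonUser = 10, NonActive = 10,
                                                          SemiActive = 10, Active = 5),
                                      seed = 78))
  expect_false(identical(a$ratings, c2$ratings))
})

test_that("every generated rating lies in [0, 1] and per-picture means hit their target", {
  coh <- generate_cohort(cohort_config(
    n_per_archetype = c(SemiActive = 30, Active = 20, ActiveImprover = 10),
    seed = 31))
  expect_true(all(coh$ratings$value >= 0 & coh$ratings$value <= 1))
  # per-picture mean is controlled to within 1/(2 n): here it is pinned exactly
  s <- summarize_pictures(drop_empty_pictures(coh$pictures)$pictures, coh$ratings)
  rated <- s[s$n_ratings > 0, ]
  spread <- coh$ratings |>
    dplyr::group_by(picture_id) |>
    dplyr::summarise(m = mean(value), n = dplyr::n())
  expect_true(all(abs(rated$avg_peer_rating -
                      spread$m[match(rated$picture_id, spread$picture_id)]) <
                  1e-12))
})

test_that("label recovery is exact when the validity rule cannot fire", {
  quotas <- c(NonUser = 40, NonActive = 40, SemiActive = 40, Active = 20,
              ActiveImprover = 10, ActiveDecliner = 10)
  cfg <- recovery_config(quotas, seed = 19)
  coh <- generate_cohort(cfg)
  us <- summarize_users(coh)
  got <- table(us$adherence)
  want <- expected_class_counts(cfg)
  expect_equal(as.integer(got[names(want)]), unname(want))
  # per-user confusion matrix is diagonal
  arch <- attr(coh, "archetypes")
  merged <- dplyr::inner_join(us, arch, by = "user_id")
  intended <- dplyr::recode(merged$archetype, ActiveImprover = "Active",
                            ActiveDecliner = "Active")
  expect_equal(as.character(merged$adherence), intended)
})

test_that("expected class counts demand deterministic bounds", {
  cfg <- recovery_config(c(SemiActive = 7, NonActive = 10), seed = 2)
  expect_equal(expected_class_counts(cfg),
               c(NonUser = 0L, NonActive = 10L, SemiActive = 7L, Active = 0L))
  zero <- recovery_config(c(NonUser = 0), seed = 2)
  expect_equal(sum(expected_class_counts(zero)), 0)
  leaky <- cohort_config(n_per_archetype = c(Active = 5), seed = 2)  # default rating law
  expect_error(expected_class_counts(leaky), "not deterministic")
})

test_that("infeasible archetype laws are rejected with an explanation", {
  expect_error(cohort_config(
    n_per_archetype = c(Active = 5),
    picture_count_law = list(NonUser = law("constant", value = 0),
                             NonActive = law("constant", value = 1),
                             SemiActive = law("nbinom", mu = 4, size = 2, lo = 2, hi = 9),
                             Active = law("duniform", lo = 3, hi = 9))),
    "below 10")
  expect_error(cohort_config(
    n_per_archetype = c(Active = 5),
    usage_period_law = list(NonUser = law("constant", value = 0),
                            NonActive = law("constant", value = 0),
                            SemiActive = law("exponential", mean = 9, lo = 0),
                            Active = law("exponential", mean = 40, lo = 0))),
    "below 7")
  expect_error(cohort_config(n_per_archetype = c(Active = -1)), "nonnegative")
})

test_that("test first pictures draw their rating counts below the threshold", {
  cfg <- cohort_config(n_per_archetype = c(NonActive = 200), seed = 41,
                       rating_count_law = law("constant", value = 15),
                       p_test_first_picture = 0.5)
  coh <- generate_cohort(cfg)
  s <- summarize_pictures(drop_empty_pictures(coh$pictures)$pictures, coh$ratings)
  firsts <- s[s$ordinal == 1, ]
  expect_true(all(firsts$n_ratings %in% c(0:9, 15)))
  expect_gt(mean(firsts$n_ratings < 10), 0.35)
  expect_lt(mean(firsts$n_ratings < 10), 0.65)
})
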