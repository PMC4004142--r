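# Shared fixtures and independent oracles, built in code.

# hand-built three-user cohort exercising every schema feature
tiny_cohort <- function() {
  ts <- function(s) as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  users <- tibble::tibble(
    user_id = c("u1", "u2", "u3"),
    registered_at = ts(c("2011-11-01T08:30:00", "2011-12-13T12:30:00", NA)),
    tz_offset_hours = c(-5L, 2L, NA),
    diet_responses = list(character(0), c("Low fat", "I eat everything!"),
                          "Gluten free"))
  pictures <- tibble::tibble(
    picture_id = c("p1", "p2", "p3", "p4", "p5"),
    user_id = c("u1", "u1", "u1", "u2", "u2"),
    taken_at = ts(c("2011-11-01T09:00:00", "2011-11-03T13:00:00",
                    "2011-11-09T20:15:00", "2011-12-13T13:00:00",
                    "2011-12-13T13:00:00")),
    has_image = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    self_rating = c(0.7, NA, 0.4, 0.9, NA),
    description = c("my lunch, with \"quotes\"", NA, "soup", NA, NA))
  ratings <- tibble::tibble(
    rating_id = sprintf("r%02d", 1:5),
    picture_id = c("p1", "p1", "p2", "p4", "p4"),
    rater_id = c("u2", "u3", "u2", "u1", "u3"),
    value = c(0.4, 0.6, 0.5, 0.8, 1.0),
    rated_at = ts(c("2011-11-01T10:00:00", NA, "2011-11-04T00:00:00",
                    "2011-12-14T09:00:00", "2011-12-14T09:30:00")))
  likes <- tibble::tibble(picture_id = c("p1", "p4"), peer_id = c("u3", "u1"))
  comments <- tibble::tibble(picture_id = "p1", peer_id = "u2",
                             text = "looks healthy")
  cohort(users, pictures, ratings, likes, comments)
}

# generator config whose archetype bounds are deterministic: every picture
# gets >= 12 ratings, no test shots, so the validity rule never demotes
recovery_config <- function(n_per_archetype, seed = 1,
                            rating_count_law = law("constant", value = 12),
                            ...) {
  cohort_config(n_per_archetype = n_per_archetype,
                rating_count_law = rating_count_law,
                p_test_first_picture = 0, seed = seed, ...)
}

run_trend_stage <- function(coh, alpha = 0.05) {
  users <- summarize_users(coh)
  summaries <- summarize_pictures(drop_empty_pictures(coh$pictures)$pictures,
                                  coh$ratings, coh$likes, coh$comments)
  classify_cohort_trends(users, summaries, alpha = alpha)
}

# -- independent brute-force oracles -------------------------------------

# Pearson chi-square summed cell by cell over the expanded 2-by-k table
oracle_chi2 <- function(successes, totals) {
  obs <- rbind(successes, totals - successes)
  expd <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  sum((obs - expd)^2 / expd)
}

# one-way F from explicit sums of squares
oracle_anova_F <- function(groups) {
  all <- unlist(groups)
  ssb <- sum(lengths(groups) * (vapply(groups, mean, 0) - mean(all))^2)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0))
  k <- length(groups); n <- length(all)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Monte-Carlo power of the per-user slope t-test at the generator's own
# data model (clipped beta baseline + linear drift + Gaussian noise),
# fitted with stats::lm — independent of the package's closed-form path
oracle_trend_power <- function(reps, slope, noise_sd, count_lo, count_hi,
                               alpha = 0.05) {
  hits <- 0L
  for (r in seq_len(reps)) {
    n <- sample(count_lo:count_hi, 1)
    b <- rbeta(1, 3.14, 2.27)
    y <- pmin(pmax(b + slope * (seq_len(n) - 1) + rnorm(n, 0, noise_sd), 0), 1)
    fit <- summary(stats::lm(y ~ x, data = data.frame(x = seq_len(n), y = y)))
    cf <- stats::coef(fit)
    if (nrow(cf) == 2 && !is.na(cf[2, 4]) && cf[2, 4] < alpha && cf[2, 1] > 0)
      hits <- hits + 1L
  }
  hits / reps
}
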