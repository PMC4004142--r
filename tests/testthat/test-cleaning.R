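test_that("drop_empty_pictures removes exactly the imageless rows", {
  coh <- tiny_cohort()
  out <- drop_empty_pictures(coh$pictures)
  expect_equal(out$n_removed, 1)
  expect_true(all(out$pictures$has_image))
  expect_equal(nrow(out$pictures) + out$n_removed, nrow(coh$pictures))

  none <- drop_empty_pictures(out$pictures)
  expect_equal(none$n_removed, 0)
  expect_equal(none$pictures, out$pictures)

  all_empty <- dplyr::mutate(coh$pictures, has_image = FALSE)
  gone <- drop_empty_pictures(all_empty)
  expect_equal(nrow(gone$pictures), 0)
  expect_equal(gone$n_removed, nrow(coh$pictures))
})

test_that("picture summaries compute means, counts, ordinals and differences", {
  coh <- tiny_cohort()
  s <- summarize_pictures(drop_empty_pictures(coh$pictures)$pictures,
                          coh$ratings, coh$likes, coh$comments)
  p1 <- s[s$picture_id == "p1", ]
  expect_equal(p1$avg_peer_rating, 0.5)   # mean of 0.4, 0.6
  expect_equal(p1$n_ratings, 2L)
  expect_equal(p1$n_likes, 1L)
  expect_equal(p1$n_comments, 1L)
  expect_equal(p1$self_vs_peer_diff, 0.7 - 0.5)
  p3 <- s[s$picture_id == "p3", ]
  expect_equal(p3$n_ratings, 0L)
  expect_true(is.na(p3$avg_peer_rating))
  expect_true(is.na(p3$self_vs_peer_diff))
  # ordinals chronological and consecutive within user
  expect_equal(s$ordinal[s$user_id == "u1"][order(s$taken_at[s$user_id == "u1"])],
               1:3)
})

test_that("validity rule follows the first-two-pictures logic", {
  mk <- function(counts) tibble::tibble(picture_id = paste0("p", seq_along(counts)),
                                        ordinal = seq_along(counts),
                                        n_ratings = counts)
  # first picture invalid, second valid: second becomes the first valid picture
  r <- apply_validity_rule(mk(c(4L, 12L, 11L)))
  expect_equal(r$first_valid$picture_id, "p2")
  expect_equal(r$adjusted_n, 2L)
  # boundary: exactly 10 ratings is valid
  r <- apply_validity_rule(mk(10L))
  expect_equal(r$first_valid$picture_id, "p1")
  expect_equal(r$adjusted_n, 1L)
  # single invalid picture: no valid first picture at all
  r <- apply_validity_rule(mk(3L))
  expect_null(r$first_valid)
  expect_equal(r$adjusted_n, 0L)
  # both of the first two invalid, later pictures never examined
  r <- apply_validity_rule(mk(c(1L, 2L, 0L, 0L)))
  expect_null(r$first_valid)
  expect_equal(r$adjusted_n, 2L)
})

test_that("adjusted counts drop by at most two and shrink with the threshold", {
  set.seed(4)
  for (rep in 1:50) {
    n <- sample(1:6, 1)
    s <- tibble::tibble(picture_id = paste0("p", 1:n), ordinal = 1:n,
                        n_ratings = sample(0:15, n, replace = TRUE))
    prev_n <- Inf; prev_valid <- TRUE
    for (thr in c(0, 5, 10, 16)) {
      r <- apply_validity_rule(s, threshold = thr)
      expect_gte(r$adjusted_n, n - 2)
      expect_lte(r$adjusted_n, n)
      expect_lte(r$adjusted_n, prev_n)            # monotone in threshold
      if (!prev_valid) expect_null(r$first_valid) # validity can only be lost
      prev_n <- r$adjusted_n
      prev_valid <- !is.null(r$first_valid)
    }
  }
})

test_that("vectorised validity agrees with the single-user rule", {
  coh <- generate_cohort(cohort_config(
    n_per_archetype = c(NonActive = 20, SemiActive = 20, Active = 10),
    seed = 5))
  s <- summarize_pictures(drop_empty_pictures(coh$pictures)$pictures,
                          coh$ratings, coh$likes, coh$comments)
  v <- validity_by_user(s, threshold = 10)
  for (uid in sample(v$user_id, 10)) {
    one <- apply_validity_rule(s[s$user_id == uid, ], threshold = 10)
    row <- v[v$user_id == uid, ]
    expect_equal(row$n_valid_pictures, one$adjusted_n)
    expect_equal(row$first_valid_picture_id,
                 if (is.null(one$first_valid)) NA_character_
                 else one$first_valid$picture_id)
  }
})
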