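# Exclusion pipeline: empty-picture removal, per-picture summarisation,
# and the first-picture validity rule.
#
# Manual screening of the original data showed that first pictures with few
# peer ratings were typically not food (test shots). The rule used here is
# the rating-count proxy for that screening: a picture is "valid" when it
# received at least `threshold` (default 10) peer ratings, and only each
# user's first two pictures are ever checked — later pictures count as valid
# unconditionally.

#' Remove empty pictures
#'
#' Drops rows whose `has_image` flag is `FALSE` (entries with no actual image
#' payload). This runs before any summarisation, so ordinals, the validity
#' rule and usage periods are all computed on non-empty pictures only.
#'
#' @param pictures Picture table of a cohort.
#' @return A list with `pictures` (the non-empty rows) and `n_removed`.
#' @export
drop_empty_pictures <- function(pictures) {
  keep <- pictures$has_image
  list(pictures = pictures[keep, , drop = FALSE],
       n_removed = sum(!keep))
}

#' Summarise pictures with their crowdsourced feedback
#'
#' Builds one row per (non-empty) picture: chronological ordinal within its
#' owner (ties broken by ascending `picture_id`), the arithmetic mean of peer
#' rating values (`NA` when the picture received none), rating/like/comment
#' counts, description length in characters (0 when absent), and the
#' difference between the owner's own rating and the peer mean (`NA` when
#' either side is absent).
#'
#' @param pictures Cleaned (non-empty) picture table.
#' @param ratings Peer-rating table.
#' @param likes,comments Feedback tables.
#' @return Tibble of picture summaries, ordered by user then ordinal.
#' @export
summarize_pictures <- function(pictures, ratings,
                               likes = NULL, comments = NULL) {
  empty_fk <- tibble::tibble(picture_id = character(0))
  likes <- likes %||% empty_fk
  comments <- comments %||% empty_fk

  rating_stats <- ratings |>
    dplyr::group_by(.data$picture_id) |>
    dplyr::summarise(avg_peer_rating = mean(.data$value),
                     n_ratings = dplyr::n(), .groups = "drop")
  like_counts <- likes |> dplyr::count(.data$picture_id, name = "n_likes")
  comment_counts <- comments |> dplyr::count(.data$picture_id, name = "n_comments")

  pictures |>
    dplyr::arrange(.data$user_id, .data$taken_at, .data$picture_id) |>
    dplyr::group_by(.data$user_id) |>
    dplyr::mutate(ordinal = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::left_join(rating_stats, by = "picture_id") |>
    dplyr::left_join(like_counts, by = "picture_id") |>
    dplyr::left_join(comment_counts, by = "picture_id") |>
    dplyr::mutate(
      n_ratings = dplyr::coalesce(.data$n_ratings, 0L),
      n_likes = dplyr::coalesce(.data$n_likes, 0L),
      n_comments = dplyr::coalesce(.data$n_comments, 0L),
      description_length = ifelse(is.na(.data$description), 0L,
                                  nchar(.data$description)),
      self_vs_peer_diff = .data$self_rating - .data$avg_peer_rating) |>
    dplyr::select("picture_id", "user_id", "taken_at", "ordinal",
                  "avg_peer_rating", "n_ratings", "n_likes", "n_comments",
                  "self_rating", "self_vs_peer_diff", "description_length")
}

#' Apply the first-picture validity rule for one user
#'
#' Checks only the first two pictures: if the first has at least `threshold`
#' peer ratings it is the valid first picture and nothing is removed; else if
#' a second picture exists and meets the threshold, it becomes the valid
#' first picture and the count drops by one; otherwise the user has no valid
#' first picture and the count drops by the number of failing pictures among
#' the first two. Pictures at ordinal 3 and beyond are never examined, so
#' the adjusted count is at most two below the raw count.
#'
#' @param user_pictures Picture summaries of a single user, ordered by
#'   `ordinal` (as produced by [summarize_pictures()]).
#' @param threshold Minimum peer-rating count for validity (default 10;
#'   the boundary is inclusive).
#' @return List with `first_valid` (the summary row of the valid first
#'   picture, or `NULL`) and `adjusted_n` (the validity-adjusted picture
#'   count).
#' @export
#' @examples
#' s <- tibble::tibble(picture_id = c("p1", "p2", "p3"), ordinal = 1:3,
#'                     n_ratings = c(4L, 12L, 11L))
#' apply_validity_rule(s)  # first valid picture is p2, adjusted count 2
apply_validity_rule <- function(user_pictures, threshold = 10) {
  stopifnot(threshold >= 0)
  n <- nrow(user_pictures)
  if (n == 0) return(list(first_valid = NULL, adjusted_n = 0L))
  user_pictures <- user_pictures[order(user_pictures$ordinal), , drop = FALSE]
  cnt <- user_pictures$n_ratings
  if (cnt[1] >= threshold)
    return(list(first_valid = user_pictures[1, ], adjusted_n = n))
  if (n >= 2 && cnt[2] >= threshold)
    return(list(first_valid = user_pictures[2, ], adjusted_n = n - 1L))
  invalid_head <- sum(cnt[seq_len(min(n, 2))] < threshold)
  list(first_valid = NULL, adjusted_n = as.integer(n - invalid_head))
}

# Vectorised validity rule across all users of a summary table; one row per
# user who has at least one non-empty picture.
validity_by_user <- function(summaries, threshold = 10) {
  summaries |>
    dplyr::arrange(.data$user_id, .data$ordinal) |>
    dplyr::group_by(.data$user_id) |>
    dplyr::summarise(
      n_raw = dplyr::n(),
      first_valid_picture_id = {
        cnt <- .data$n_ratings
        if (cnt[1] >= threshold) .data$picture_id[1]
        else if (dplyr::n() >= 2 && cnt[2] >= threshold) .data$picture_id[2]
        else NA_character_
      },
      first_valid_ordinal = {
        cnt <- .data$n_ratings
        if (cnt[1] >= threshold) 1L
        else if (dplyr::n() >= 2 && cnt[2] >= threshold) 2L
        else NA_integer_
      },
      n_valid_pictures = {
        cnt <- .data$n_ratings
        n <- dplyr::n()
        if (cnt[1] >= threshold) n
        else if (n >= 2 && cnt[2] >= threshold) n - 1L
        else n - sum(cnt[seq_len(min(n, 2))] < threshold)
      },
      .groups = "drop")
}
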