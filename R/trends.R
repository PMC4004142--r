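# Per-user healthiness-trend detection among Active users.
#
# The trend regresses a picture's average crowdsourced healthiness rating on
# its picture index 1, 2, ..., N (the ordered list of pictures, not real
# time). A user with a significant positive slope is an "Improver", with a
# significant negative slope a "Decliner", otherwise "NoTrend". The slope is
# computed closed-form (Sxy/Sxx with the usual t test on the coefficient),
# vectorised so thousands of users fit in milliseconds.

new_trend_result <- function(slope, p_value, n_points, classification) {
  structure(list(slope = slope, p_value = p_value, n_points = n_points,
                 classification = classification),
            class = "eatlog_trend")
}

#' @export
print.eatlog_trend <- function(x, ...) {
  cat(sprintf("trend: slope %.5g per picture over %d pictures, p = %.3g -> %s\n",
              x$slope, x$n_points, x$p_value, x$classification))
  invisible(x)
}

trend_components <- function(y) {
  n <- length(y)
  x <- seq_len(n)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  sse <- sum((y - mean(y) - slope * (x - mean(x)))^2)
  list(slope = slope, sxx = sxx, sse = sse, n = n)
}

trend_p_value <- function(slope, sxx, sse, n) {
  if (sse <= 0) {
    # perfect fit: a nonzero slope is unambiguous, a flat series carries no trend
    return(if (slope == 0) 1 else 0)
  }
  se <- sqrt(sse / (n - 2) / sxx)
  2 * pt(-abs(slope / se), n - 2)
}

#' Fit the healthiness trend of one user
#'
#' Ordinary least-squares regression of the ordered average peer ratings on
#' the picture index `1..N`, with the two-sided t test on the slope.
#'
#' @param ratings Numeric vector of per-picture average healthiness ratings
#'   in chronological order; at least 3 values (the slope test needs a
#'   residual degree of freedom).
#' @param alpha Significance level for the Improver/Decliner call
#'   (default 0.05).
#' @return An `eatlog_trend` with `slope` (rating units per picture index),
#'   `p_value`, `n_points` and `classification`.
#' @export
#' @examples
#' fit_user_trend(c(0.2, 0.4, 0.3, 0.5))  # slope 0.08
fit_user_trend <- function(ratings, alpha = 0.05) {
  if (length(ratings) < 3)
    abort("need at least 3 ratings to test a trend")
  tc <- trend_components(ratings)
  p <- trend_p_value(tc$slope, tc$sxx, tc$sse, tc$n)
  cls <- if (tc$slope > 0 && p < alpha) "Improver"
         else if (tc$slope < 0 && p < alpha) "Decliner"
         else "NoTrend"
  new_trend_result(tc$slope, p, tc$n, cls)
}

#' Fit healthiness trends for all eligible Active users
#'
#' Eligible users are Actives with a valid first-or-second picture. For
#' each, the trend is fitted on the chronologically ordered average peer
#' ratings of their pictures from the valid first picture onward; pictures
#' that received no peer rating carry no average and are skipped, with the
#' index running over the rated pictures. Users with fewer than 3 rated
#' pictures cannot be tested and are reported as `NoTrend` with `NA` slope.
#'
#' @param user_summaries Output of [summarize_users()].
#' @param picture_summaries Output of [summarize_pictures()].
#' @param alpha Significance level (default 0.05).
#' @return List with `trends` (tibble: `user_id`, `slope`, `p_value`,
#'   `n_points`, `classification`) and `counts` (named counts of Improvers,
#'   Decliners and NoTrend).
#' @export
classify_cohort_trends <- function(user_summaries, picture_summaries,
                                   alpha = 0.05) {
  eligible <- user_summaries |>
    dplyr::filter(.data$adherence == "Active",
                  !is.na(.data$first_valid_picture_id))
  trends <- picture_summaries |>
    dplyr::inner_join(dplyr::select(eligible, "user_id", "first_valid_ordinal"),
                      by = "user_id") |>
    dplyr::filter(.data$ordinal >= .data$first_valid_ordinal,
                  .data$n_ratings > 0) |>
    dplyr::arrange(.data$user_id, .data$ordinal) |>
    dplyr::group_by(.data$user_id) |>
    dplyr::summarise(
      n_points = dplyr::n(),
      slope = {
        y <- .data$avg_peer_rating; x <- seq_along(y)
        if (length(y) >= 3) sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
        else NA_real_
      },
      p_value = {
        y <- .data$avg_peer_rating
        if (length(y) >= 3) {
          tc <- trend_components(y)
          trend_p_value(tc$slope, tc$sxx, tc$sse, tc$n)
        } else NA_real_
      },
      .groups = "drop") |>
    dplyr::mutate(
      classification = factor(
        dplyr::case_when(
          is.na(.data$slope) ~ "NoTrend",
          .data$slope > 0 & .data$p_value < alpha ~ "Improver",
          .data$slope < 0 & .data$p_value < alpha ~ "Decliner",
          TRUE ~ "NoTrend"),
        levels = TREND_LEVELS))
  # eligible Actives whose pictures all lack ratings still partition
  trends <- eligible |>
    dplyr::select("user_id") |>
    dplyr::left_join(trends, by = "user_id") |>
    dplyr::mutate(
      n_points = dplyr::coalesce(.data$n_points, 0L),
      classification = factor(
        dplyr::coalesce(as.character(.data$classification), "NoTrend"),
        levels = TREND_LEVELS))
  list(trends = trends,
       counts = table(trends$classification))
}

#' Compare Improvers with other Actives on usage activity
#'
#' Pooled two-sample t tests of Improvers versus all other eligible Actives
#' on the three usage-activity variables: number of (valid) pictures, usage
#' period in days, and pictures per day.
#'
#' @param trends Trend tibble from [classify_cohort_trends()].
#' @param user_summaries Output of [summarize_users()].
#' @return Named list of three `eatlog_test` objects (`n_pictures`,
#'   `usage_period_days`, `pictures_per_day`), each with the two group
#'   means attached as attribute `group_means`.
#' @export
compare_improvers <- function(trends, user_summaries) {
  merged <- dplyr::inner_join(trends, user_summaries, by = "user_id")
  imp <- merged[merged$classification == "Improver", , drop = FALSE]
  rest <- merged[merged$classification != "Improver", , drop = FALSE]
  if (nrow(imp) < 2 || nrow(rest) < 2)
    abort("need at least two Improvers and two other Actives")
  one <- function(var) {
    ht <- pooled_t_raw(imp[[var]], rest[[var]])
    attr(ht, "group_means") <- c(improvers = mean(imp[[var]]),
                                 others = mean(rest[[var]]))
    ht
  }
  list(n_pictures = one("n_valid_pictures"),
       usage_period_days = one("usage_period_days"),
       pictures_per_day = one("pictures_per_day"))
}
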