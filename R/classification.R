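# Adherence levels, dietary-preference categories, registration-time bins.

#' Classify a user's adherence level
#'
#' Adherence is defined from the validity-adjusted picture count and the
#' usage period (elapsed days between the first and last picture):
#' `NonUser` with no valid pictures, `NonActive` with exactly one,
#' `Active` with at least 10 pictures and a period of at least a week,
#' and `SemiActive` otherwise (two or more pictures, but fewer than 10 or a
#' shorter period). `NonUser` and `NonActive` form the "Dropouts" group,
#' `SemiActive` and `Active` the "Users" group.
#'
#' The week boundary is inclusive (`usage_period_days >= 7` counts as a
#' week) and configurable via `min_period_days`.
#'
#' @param n_valid_pictures Integer vector of adjusted picture counts.
#' @param usage_period_days Numeric vector of usage periods in (fractional)
#'   days.
#' @param min_pictures,min_period_days Active-level thresholds (default 10
#'   pictures and 7 days).
#' @return Factor with levels `NonUser`, `NonActive`, `SemiActive`, `Active`.
#' @export
#' @examples
#' classify_adherence(c(0, 1, 15, 10), c(0, 0, 3, 8))
classify_adherence <- function(n_valid_pictures, usage_period_days,
                               min_pictures = 10, min_period_days = 7) {
  if (any(n_valid_pictures < 0) || any(usage_period_days < 0))
    abort("picture counts and usage periods must be nonnegative")
  out <- ifelse(n_valid_pictures == 0, "NonUser",
         ifelse(n_valid_pictures == 1, "NonActive",
         ifelse(n_valid_pictures >= min_pictures &
                usage_period_days >= min_period_days, "Active", "SemiActive")))
  factor(out, levels = ADHERENCE_LEVELS)
}

# Canonical answer options to the app's "How do you eat?" question, with
# minor wording variants. Matching is case-insensitive on these strings;
# anything unrecognised is free text and falls into the Other category.
STRICT_OPTIONS <- c("low fat",
                    "low carbs, no carbs, or paleo",
                    "low carb, no carb, or paleo",
                    "vegan or vegetarian",
                    "vegan/vegetarian")
EVERYTHING_OPTIONS <- c("i eat everything!", "i eat everything")

#' Categorise a user's dietary preference
#'
#' Maps the raw responses to the app's "How do you eat?" question onto four
#' categories. `Strict` if any restricting option was chosen (low fat;
#' low/no carb or paleo; vegan/vegetarian); otherwise `Other` if any
#' response besides "I eat everything!" is present (complex carb diet,
#' gluten free, "Other", "None of the above", or free text); otherwise
#' `Everything`; and `NotDefined` when no response was given. Users could
#' give multiple responses, hence the precedence
#' Strict > Other > Everything; the result is invariant to response order
#' and duplication.
#'
#' @param responses Character vector of raw responses for one user, or a
#'   list of such vectors for many users.
#' @return Factor with levels `NotDefined`, `Everything`, `Strict`, `Other`.
#' @export
#' @examples
#' categorize_diet(c("I eat everything!", "Low fat"))  # Strict
#' categorize_diet(list(character(0), "Gluten free"))  # NotDefined, Other
categorize_diet <- function(responses) {
  if (!is.list(responses)) responses <- list(responses)
  one <- function(resp) {
    resp <- tolower(trimws(resp[!is.na(resp) & trimws(resp) != ""]))
    if (length(resp) == 0) return("NotDefined")
    if (any(resp %in% STRICT_OPTIONS)) return("Strict")
    if (any(!resp %in% EVERYTHING_OPTIONS)) return("Other")
    "Everything"
  }
  factor(vapply(responses, one, ""), levels = DIET_LEVELS)
}

#' Bin a registration timestamp into the weekday-by-daypart grid
#'
#' Splits the first-use timestamp (local civil time) into one of 35 cells:
#' weekday 0 (Sunday) through 6 (Saturday) crossed with five dayparts by
#' hour of day, half-open on the right: night \[0, 5), morning \[5, 10),
#' daytime \[10, 15), late_afternoon \[15, 19), evening \[19, 24).
#'
#' @param registered_at POSIXct vector of registration times (civil local
#'   time). `NA` entries yield `NA` bins; such users are excluded from
#'   registration-time analyses.
#' @return Tibble with `weekday` (integer 0-6, 0 = Sunday), `weekday_name`,
#'   and `interval` (factor over the five dayparts).
#' @export
#' @examples
#' bin_registration(as.POSIXct("2011-11-15 12:30:00", tz = "UTC"))
bin_registration <- function(registered_at) {
  lt <- as.POSIXlt(registered_at, tz = "UTC")
  wd <- lt$wday                      # 0 = Sunday, matching the grid anchor
  h <- lt$hour
  interval <- ifelse(h < 5, "night",
              ifelse(h < 10, "morning",
              ifelse(h < 15, "daytime",
              ifelse(h < 19, "late_afternoon", "evening"))))
  tibble::tibble(
    weekday = as.integer(wd),
    weekday_name = ifelse(is.na(wd), NA_character_, WEEKDAY_LEVELS[wd + 1]),
    interval = factor(interval, levels = INTERVAL_LEVELS))
}

#' Summarise per-user usage, adherence and classifications
#'
#' The central derived table of the pipeline: for every user, the
#' validity-adjusted picture count, usage period (elapsed fractional days
#' between first and last non-empty picture; 0 with at most one picture),
#' pictures per day (`n / max(period, 1)` so single-day users are not
#' divided by a near-zero period), ratings given to peers, adherence level,
#' diet category, registration bin and the id of the valid first picture.
#'
#' @param x An `eatlog_cohort`.
#' @param threshold Validity threshold on peer-rating counts (default 10).
#' @param min_pictures,min_period_days Active-level thresholds, passed to
#'   [classify_adherence()].
#' @param study_end Optional POSIXct; users registered less than
#'   `min_period_days` before it are flagged in `late_registrant` (they
#'   could not have reached an Active-length period) but are never
#'   reclassified.
#' @return Tibble with one row per user.
#' @export
summarize_users <- function(x, threshold = 10, min_pictures = 10,
                            min_period_days = 7, study_end = NULL) {
  stopifnot(inherits(x, "eatlog_cohort"))
  cleaned <- drop_empty_pictures(x$pictures)
  summaries <- summarize_pictures(cleaned$pictures, x$ratings, x$likes, x$comments)
  validity <- validity_by_user(summaries, threshold = threshold)

  periods <- summaries |>
    dplyr::group_by(.data$user_id) |>
    dplyr::summarise(
      usage_period_days = as.numeric(difftime(max(.data$taken_at),
                                              min(.data$taken_at),
                                              units = "days")),
      .groups = "drop")

  ratings_given <- x$ratings |>
    dplyr::count(.data$rater_id, name = "n_ratings_given")

  out <- x$users |>
    dplyr::select("user_id", "registered_at", "diet_responses") |>
    dplyr::left_join(validity, by = "user_id") |>
    dplyr::left_join(periods, by = "user_id") |>
    dplyr::left_join(ratings_given, by = c(user_id = "rater_id")) |>
    dplyr::mutate(
      n_raw = dplyr::coalesce(.data$n_raw, 0L),
      n_valid_pictures = dplyr::coalesce(.data$n_valid_pictures, 0L),
      usage_period_days = dplyr::coalesce(.data$usage_period_days, 0),
      usage_period_days = ifelse(.data$n_valid_pictures <= 1, 0,
                                 .data$usage_period_days),
      pictures_per_day = .data$n_valid_pictures / pmax(.data$usage_period_days, 1),
      n_ratings_given = dplyr::coalesce(.data$n_ratings_given, 0L),
      adherence = classify_adherence(.data$n_valid_pictures,
                                     .data$usage_period_days,
                                     min_pictures = min_pictures,
                                     min_period_days = min_period_days),
      diet_category = categorize_diet(.data$diet_responses))

  out <- dplyr::bind_cols(out, bin_registration(out$registered_at))
  if (!is.null(study_end)) {
    out$late_registrant <- !is.na(out$registered_at) &
      as.numeric(difftime(study_end, out$registered_at, units = "days")) <
        min_period_days
  }
  out |>
    dplyr::select("user_id", "registered_at", "n_raw", "n_valid_pictures",
                  "usage_period_days", "pictures_per_day", "n_ratings_given",
                  "adherence", "diet_category", "weekday", "weekday_name",
                  "interval", "first_valid_picture_id", "first_valid_ordinal",
                  dplyr::any_of("late_registrant"))
}
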