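# Cohort container and flat-file event-log I/O.
#
# A cohort is five cross-referenced tables: users, pictures, peer ratings,
# likes and comments. Timestamps are local civil time throughout (the clock
# of the user's phone); they are stored as POSIXct in the "UTC" zone purely
# as a fixed civil-time carrier and are never converted across zones.
# tz_offset_hours is descriptive metadata only.

TS_FORMAT <- "%Y-%m-%dT%H:%M:%S"

#' Assemble an event-log cohort
#'
#' Bundles the five event-log tables into a validated cohort object. Checks
#' uniqueness of identifiers, referential integrity (every rating, like and
#' comment resolves to a picture; every picture to a user), value ranges of
#' ratings, and the time-zone offset range.
#'
#' @param users Tibble with columns `user_id`, `registered_at` (POSIXct,
#'   civil local time, may be `NA`), `tz_offset_hours` (integer UTC offset,
#'   may be `NA`), `diet_responses` (list-column of character vectors; raw
#'   answers to the app's "How do you eat?" question).
#' @param pictures Tibble with `picture_id`, `user_id`, `taken_at` (POSIXct),
#'   `has_image` (logical; `FALSE` marks an "empty picture" with no actual
#'   image payload), `self_rating` (the owner's own healthiness rating in
#'   \[0, 1\], `NA` if not given), `description` (free text, `NA` if absent).
#' @param ratings Tibble with `rating_id`, `picture_id`, `rater_id`, `value`
#'   (crowdsourced healthiness rating in \[0, 1\]) and `rated_at` (POSIXct,
#'   may be `NA`).
#' @param likes Tibble with `picture_id`, `peer_id`.
#' @param comments Tibble with `picture_id`, `peer_id`, `text`.
#'
#' @return An object of class `eatlog_cohort`: a named list of the five
#'   tibbles, rows ordered by id.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(n_per_archetype = c(Active = 2), seed = 1))
#' coh
cohort <- function(users, pictures, ratings, likes, comments) {
  users <- tibble::as_tibble(users)
  pictures <- tibble::as_tibble(pictures)
  ratings <- tibble::as_tibble(ratings)
  likes <- tibble::as_tibble(likes)
  comments <- tibble::as_tibble(comments)

  x <- structure(
    list(users = dplyr::arrange(users, .data$user_id),
         pictures = dplyr::arrange(pictures, .data$picture_id),
         ratings = dplyr::arrange(ratings, .data$rating_id),
         likes = dplyr::arrange(likes, .data$picture_id, .data$peer_id),
         comments = dplyr::arrange(comments, .data$picture_id, .data$peer_id)),
    class = "eatlog_cohort")
  validate_cohort(x)
  x
}

validate_cohort <- function(x) {
  u <- x$users; p <- x$pictures; r <- x$ratings
  if (anyDuplicated(u$user_id))
    abort("duplicated user_id in users table")
  if (anyDuplicated(p$picture_id))
    abort("duplicated picture_id in pictures table")
  tz <- u$tz_offset_hours
  if (any(!is.na(tz) & (tz < -12 | tz > 14)))
    abort("tz_offset_hours outside [-12, 14]")
  bad_owner <- setdiff(p$user_id, u$user_id)
  if (length(bad_owner))
    abort(paste0("pictures reference unknown user_id: ",
                 paste(head(bad_owner, 5), collapse = ", ")))
  for (tab in c("ratings", "likes", "comments")) {
    bad <- setdiff(x[[tab]]$picture_id, p$picture_id)
    if (length(bad))
      abort(paste0(tab, " reference unknown picture_id: ",
                   paste(head(bad, 5), collapse = ", ")))
  }
  bad_rater <- setdiff(r$rater_id, u$user_id)
  if (length(bad_rater))
    abort(paste0("ratings reference unknown rater_id: ",
                 paste(head(bad_rater, 5), collapse = ", ")))
  if (nrow(r) && any(r$value < 0 | r$value > 1))
    abort("rating value outside [0, 1]")
  sr <- p$self_rating
  if (any(!is.na(sr) & (sr < 0 | sr > 1)))
    abort("self_rating outside [0, 1]")
  invisible(x)
}

#' @export
print.eatlog_cohort <- function(x, ...) {
  cat("<eatlog_cohort>\n")
  cat(sprintf("  users:    %d\n", nrow(x$users)))
  cat(sprintf("  pictures: %d (%d empty)\n", nrow(x$pictures),
              sum(!x$pictures$has_image)))
  cat(sprintf("  ratings:  %d\n", nrow(x$ratings)))
  cat(sprintf("  likes:    %d   comments: %d\n",
              nrow(x$likes), nrow(x$comments)))
  invisible(x)
}

parse_ts <- function(s, file) {
  s <- as.character(s)
  out <- as.POSIXct(rep(NA_real_, length(s)), origin = "1970-01-01", tz = "UTC")
  present <- !is.na(s) & s != ""
  parsed <- as.POSIXct(s[present], format = TS_FORMAT, tz = "UTC")
  if (anyNA(parsed)) {
    row <- which(present)[which(is.na(parsed))[1]]
    abort(sprintf("malformed timestamp in %s, row %d: '%s'", file, row, s[row]))
  }
  out[present] <- parsed
  out
}

format_ts <- function(ts) {
  ifelse(is.na(ts), "", format(ts, TS_FORMAT, tz = "UTC"))
}

read_table_or_die <- function(dir, file, col_names) {
  path <- file.path(dir, file)
  if (!file.exists(path))
    abort(paste0("missing event-log file: ", file))
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        trim_ws = FALSE, progress = FALSE)
  missing_cols <- setdiff(col_names, names(df))
  if (length(missing_cols))
    abort(sprintf("%s lacks required column(s): %s", file,
                  paste(missing_cols, collapse = ", ")))
  df
}

num_or_na <- function(s) {
  s <- as.character(s)
  s[!is.na(s) & s == ""] <- NA_character_
  as.numeric(s)
}

#' Read an event-log cohort from a directory of CSV files
#'
#' Expects `users.csv`, `pictures.csv`, `ratings.csv`, `likes.csv` and
#' `comments.csv` in the canonical schemas (see [write_cohort()]).
#' Timestamps are ISO-8601 local civil time without an offset suffix.
#' Referential integrity is enforced; violations name the offending ids.
#'
#' @param directory Path containing the five CSV files.
#' @return An `eatlog_cohort`.
#' @export
load_cohort <- function(directory) {
  if (!dir.exists(directory))
    abort(paste0("cohort directory does not exist: ", directory))

  u <- read_table_or_die(directory, "users.csv",
                         c("user_id", "registered_at", "tz_offset_hours", "diet_responses"))
  p <- read_table_or_die(directory, "pictures.csv",
                         c("picture_id", "user_id", "taken_at", "has_image",
                           "self_rating", "description"))
  r <- read_table_or_die(directory, "ratings.csv",
                         c("rating_id", "picture_id", "rater_id", "value", "rated_at"))
  l <- read_table_or_die(directory, "likes.csv", c("picture_id", "peer_id"))
  cm <- read_table_or_die(directory, "comments.csv", c("picture_id", "peer_id", "text"))

  users <- tibble::tibble(
    user_id = u$user_id,
    registered_at = parse_ts(u$registered_at, "users.csv"),
    tz_offset_hours = as.integer(num_or_na(u$tz_offset_hours)),
    diet_responses = lapply(u$diet_responses, function(s) {
      if (is.na(s) || s == "") character(0) else strsplit(s, ";", fixed = TRUE)[[1]]
    }))
  pictures <- tibble::tibble(
    picture_id = p$picture_id,
    user_id = p$user_id,
    taken_at = parse_ts(p$taken_at, "pictures.csv"),
    has_image = p$has_image == "1",
    self_rating = num_or_na(p$self_rating),
    description = dplyr::if_else(is.na(p$description) | p$description == "",
                                 NA_character_, p$description))
  ratings <- tibble::tibble(
    rating_id = r$rating_id,
    picture_id = r$picture_id,
    rater_id = r$rater_id,
    value = as.numeric(r$value),
    rated_at = parse_ts(r$rated_at, "ratings.csv"))
  likes <- tibble::tibble(picture_id = l$picture_id, peer_id = l$peer_id)
  comments <- tibble::tibble(picture_id = cm$picture_id, peer_id = cm$peer_id,
                             text = ifelse(is.na(cm$text), "", cm$text))

  out <- cohort(users, pictures, ratings, likes, comments)
  inform(sprintf("loaded cohort: %d users, %d pictures, %d ratings, %d likes, %d comments",
                 nrow(out$users), nrow(out$pictures), nrow(out$ratings),
                 nrow(out$likes), nrow(out$comments)))
  out
}

#' Write an event-log cohort to a directory of CSV files
#'
#' Writes the five canonical tables with deterministic row order (by id) so
#' repeated writes of the same cohort are byte-identical. Timestamps are
#' serialised as ISO-8601 local civil time (`YYYY-MM-DDTHH:MM:SS`, no
#' offset); `diet_responses` as one semicolon-delimited field (empty string
#' when the user gave no response).
#'
#' @param x An `eatlog_cohort`.
#' @param directory Output directory, created if needed.
#' @return `directory`, invisibly.
#' @export
write_cohort <- function(x, directory) {
  stopifnot(inherits(x, "eatlog_cohort"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(directory))
    abort(paste0("cannot create directory: ", directory))

  u <- x$users
  readr::write_csv(tibble::tibble(
    user_id = u$user_id,
    registered_at = format_ts(u$registered_at),
    tz_offset_hours = u$tz_offset_hours,
    diet_responses = vapply(u$diet_responses, paste, "", collapse = ";")),
    file.path(directory, "users.csv"), na = "", progress = FALSE)

  p <- x$pictures
  readr::write_csv(tibble::tibble(
    picture_id = p$picture_id,
    user_id = p$user_id,
    taken_at = format_ts(p$taken_at),
    has_image = as.integer(p$has_image),
    self_rating = p$self_rating,
    description = p$description),
    file.path(directory, "pictures.csv"), na = "", progress = FALSE)

  r <- x$ratings
  readr::write_csv(tibble::tibble(
    rating_id = r$rating_id,
    picture_id = r$picture_id,
    rater_id = r$rater_id,
    value = r$value,
    rated_at = format_ts(r$rated_at)),
    file.path(directory, "ratings.csv"), na = "", progress = FALSE)

  readr::write_csv(x$likes, file.path(directory, "likes.csv"), na = "",
                   progress = FALSE)
  readr::write_csv(x$comments, file.path(directory, "comments.csv"), na = "",
                   progress = FALSE)
  invisible(directory)
}
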