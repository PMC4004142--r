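# End-to-end orchestration: cleaning -> classification -> inference ->
# trends, emitting machine-readable analogues of the published result
# tables plus the registration-grid scan and an exclusion ledger.

test_cols <- function(ht) {
  if (is.null(ht)) return(tibble::tibble(statistic = NA_real_, df = NA_character_,
                                         p_value = NA_real_, kind = NA_character_))
  tibble::tibble(statistic = ht$statistic,
                 df = paste(signif(ht$df, 10), collapse = ","),
                 p_value = ht$p_value, kind = ht$kind)
}

# valid-picture flag per the first-two-pictures rule: the first picture is
# invalid when under threshold; the second is examined (and possibly
# invalid) only when the first failed; later pictures always count
flag_valid_pictures <- function(summaries, threshold) {
  summaries |>
    dplyr::group_by(.data$user_id) |>
    dplyr::mutate(is_valid = {
      cnt <- .data$n_ratings
      v <- rep(TRUE, dplyr::n())
      if (cnt[1] < threshold) {
        v[1] <- FALSE
        if (dplyr::n() >= 2 && cnt[2] < threshold) v[2] <- FALSE
      }
      v
    }) |>
    dplyr::ungroup()
}

#' Run the full adherence-analysis pipeline on a cohort
#'
#' Applies the exclusion rules, classifies users, and produces
#' machine-readable report tables: adherence counts with per-class usage
#' statistics; valid-picture statistics; adherence by dietary preference
#' (proportions, chi-square homogeneity, Tukey-type post hoc on
#' proportions); first-picture engagement (textual description) and peer
#' feedback (average rating, likes, comments) by adherence group; the
#' Improver/Decliner trend analysis among eligible Actives, overall and by
#' diet; and the Bonferroni-corrected weekday-by-daypart registration grid
#' scan. Degenerate strata (a single diet category, no eligible users)
#' skip the corresponding test with a logged warning rather than failing.
#'
#' @param x An `eatlog_cohort`.
#' @param threshold Validity threshold on peer-rating counts (default 10).
#' @param alpha Significance level for tests and trend calls (default
#'   0.05); the grid scan runs at `alpha / 35`.
#' @param min_pictures,min_period_days Active-level thresholds.
#' @param study_end Optional POSIXct end of the sampling window; late
#'   registrants are flagged in the user table, never reclassified.
#' @return An `eatlog_report`: a list of tibbles plus the run `log`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(
#'   n_per_archetype = c(NonUser = 20, NonActive = 20, SemiActive = 20,
#'                       Active = 10, ActiveImprover = 5), seed = 3))
#' rep <- run_pipeline(coh)
#' rep$adherence
run_pipeline <- function(x, threshold = 10, alpha = 0.05,
                         min_pictures = 10, min_period_days = 7,
                         study_end = NULL) {
  stopifnot(inherits(x, "eatlog_cohort"))
  log <- character(0)
  say <- function(...) log <<- c(log, sprintf(...))

  cleaned <- drop_empty_pictures(x$pictures)
  say("pictures: %d total, %d empty removed, %d analysed",
      nrow(x$pictures), cleaned$n_removed, nrow(cleaned$pictures))
  summaries <- summarize_pictures(cleaned$pictures, x$ratings, x$likes, x$comments)
  summaries <- flag_valid_pictures(summaries, threshold)
  n_invalid <- sum(!summaries$is_valid)
  say("validity rule (threshold %d): %d first/second pictures invalid, %d valid pictures",
      threshold, n_invalid, sum(summaries$is_valid))

  users <- summarize_users(x, threshold = threshold,
                           min_pictures = min_pictures,
                           min_period_days = min_period_days,
                           study_end = study_end)
  say("users: %d; %d without registration time", nrow(users),
      sum(is.na(users$registered_at)))

  exclusions <- tibble::tibble(
    step = c("pictures_input", "empty_pictures_removed", "nonempty_pictures",
             "invalid_first_pictures", "valid_pictures",
             "users_total", "users_without_registration",
             "users_without_valid_first_picture"),
    n = c(nrow(x$pictures), cleaned$n_removed, nrow(cleaned$pictures),
          n_invalid, sum(summaries$is_valid),
          nrow(users), sum(is.na(users$registered_at)),
          sum(is.na(users$first_valid_picture_id))))

  # adherence table (class counts + usage statistics)
  adherence <- users |>
    dplyr::group_by(.data$adherence, .drop = FALSE) |>
    dplyr::summarise(
      n = dplyr::n(),
      pct = 100 * dplyr::n() / nrow(users),
      pictures_mean = mean(.data$n_valid_pictures),
      pictures_sd = stats::sd(.data$n_valid_pictures),
      period_mean = mean(.data$usage_period_days),
      period_sd = stats::sd(.data$usage_period_days),
      .groups = "drop")

  # valid-picture statistics
  vp <- summaries[summaries$is_valid, , drop = FALSE]
  with_desc <- vp$description_length > 0
  with_like <- vp$n_likes > 0
  with_comment <- vp$n_comments > 0
  pictures_tab <- tibble::tibble(
    n_valid_pictures = nrow(vp),
    n_with_description = sum(with_desc),
    pct_with_description = 100 * mean(with_desc),
    description_length_mean = mean(vp$description_length[with_desc]),
    description_length_sd = stats::sd(vp$description_length[with_desc]),
    avg_rating_mean = mean(vp$avg_peer_rating, na.rm = TRUE),
    avg_rating_sd = stats::sd(vp$avg_peer_rating, na.rm = TRUE),
    n_with_like = sum(with_like),
    pct_with_like = 100 * mean(with_like),
    likes_mean_if_any = mean(vp$n_likes[with_like]),
    n_with_comment = sum(with_comment),
    pct_with_comment = 100 * mean(with_comment),
    comments_mean_if_any = mean(vp$n_comments[with_comment]))

  # adherence by dietary preference among users with >= 1 valid picture
  diet_adherence <- NULL
  took_one <- users[users$n_valid_pictures >= 1, , drop = FALSE]
  diets_present <- levels(droplevels(took_one$diet_category))
  if (nrow(took_one) && length(diets_present) >= 2) {
    per_diet <- took_one |>
      dplyr::mutate(diet_category = droplevels(.data$diet_category)) |>
      dplyr::group_by(.data$diet_category) |>
      dplyr::summarise(total = dplyr::n(),
                       actives = sum(.data$adherence == "Active"),
                       users_coarse = sum(.data$adherence %in%
                                            c("SemiActive", "Active")),
                       .groups = "drop")
    row_of <- function(successes, label) {
      pt <- proportion_table(successes, per_diet$total,
                             as.character(per_diet$diet_category))
      ht <- chi2_homogeneity(pt)
      tk <- tukey_hsd_proportions(pt, alpha = alpha)
      props <- paste(signif(successes / per_diet$total, 4), collapse = ";")
      dplyr::bind_cols(
        tibble::tibble(measure = label,
                       categories = paste(pt$labels, collapse = ";"),
                       successes = paste(successes, collapse = ";"),
                       totals = paste(per_diet$total, collapse = ";"),
                       proportions = props),
        test_cols(ht),
        tibble::tibble(posthoc = posthoc_label(tk, pt$labels)))
    }
    diet_adherence <- dplyr::bind_rows(
      row_of(per_diet$actives, "actives_of_valid"),
      row_of(per_diet$users_coarse, "users_of_valid"))
  } else {
    say("diet-adherence comparison skipped: fewer than two diet categories present")
  }

  # first-picture analyses among users with a valid first-or-second picture
  fp <- users |>
    dplyr::filter(!is.na(.data$first_valid_picture_id)) |>
    dplyr::select("user_id", "adherence",
                  picture_id = "first_valid_picture_id") |>
    dplyr::inner_join(summaries, by = c("picture_id", "user_id")) |>
    dplyr::mutate(adherence = droplevels(.data$adherence))
  groups_present <- levels(fp$adherence)

  first_picture_description <- NULL
  first_picture_feedback <- NULL
  if (nrow(fp) && length(groups_present) >= 2) {
    split_by <- function(var, subset = TRUE) {
      d <- fp[subset, , drop = FALSE]
      split(d[[var]], d$adherence, drop = FALSE)
    }
    totals <- as.vector(table(fp$adherence))

    prop_row <- function(flag, label) {
      successes <- as.vector(table(fp$adherence[flag]))
      if (sum(successes) == 0 || sum(successes) == sum(totals)) {
        say("proportion comparison for %s skipped: degenerate table", label)
        return(NULL)
      }
      pt <- proportion_table(successes, totals, groups_present)
      ht <- chi2_homogeneity(pt)
      tk <- tukey_hsd_proportions(pt, alpha = alpha)
      dplyr::bind_cols(
        tibble::tibble(measure = label, groups = paste(groups_present, collapse = ";"),
                       successes = paste(successes, collapse = ";"),
                       totals = paste(totals, collapse = ";")),
        test_cols(ht), tibble::tibble(posthoc = posthoc_label(tk, groups_present)))
    }
    mean_row <- function(var, subset, label) {
      gs <- split_by(var, subset)
      gs <- gs[lengths(gs) > 0]
      if (length(gs) < 2 || sum(lengths(gs)) <= length(gs)) {
        say("ANOVA for %s skipped: insufficient groups", label)
        return(NULL)
      }
      ht <- anova_oneway(gs)
      tk <- tukey_hsd_means(gs, alpha = alpha)
      dplyr::bind_cols(
        tibble::tibble(measure = label, groups = paste(names(gs), collapse = ";"),
                       means = paste(signif(vapply(gs, mean, 0), 6), collapse = ";"),
                       sds = paste(signif(vapply(gs, stats::sd, 0), 6), collapse = ";"),
                       ns = paste(lengths(gs), collapse = ";")),
        test_cols(ht), tibble::tibble(posthoc = posthoc_label(tk, names(gs))))
    }

    first_picture_description <- dplyr::bind_rows(
      prop_row(fp$description_length > 0, "has_description"),
      mean_row("description_length", fp$description_length > 0,
               "description_length_if_any"))
    first_picture_feedback <- dplyr::bind_rows(
      mean_row("avg_peer_rating", TRUE, "avg_peer_rating"),
      mean_row("self_vs_peer_diff", !is.na(fp$self_vs_peer_diff),
               "self_vs_peer_diff"),
      prop_row(fp$n_likes > 0, "has_like"),
      mean_row("n_likes", fp$n_likes > 0, "n_likes_if_any"),
      prop_row(fp$n_comments > 0, "has_comment"),
      mean_row("n_comments", fp$n_comments > 0, "n_comments_if_any"))
  } else {
    say("first-picture comparisons skipped: fewer than two adherence groups with a valid first picture")
  }

  # trends among eligible Actives
  trend_fit <- classify_cohort_trends(users, summaries, alpha = alpha)
  say("eligible Actives: %d (Improvers %d, Decliners %d)",
      nrow(trend_fit$trends), trend_fit$counts[["Improver"]],
      trend_fit$counts[["Decliner"]])
  improver_comparison <- NULL
  if (trend_fit$counts[["Improver"]] >= 2 &&
      nrow(trend_fit$trends) - trend_fit$counts[["Improver"]] >= 2) {
    cmp <- compare_improvers(trend_fit$trends, users)
    improver_comparison <- dplyr::bind_rows(
      dplyr::bind_cols(tibble::tibble(measure = "n_pictures"), test_cols(cmp$n_pictures)),
      dplyr::bind_cols(tibble::tibble(measure = "usage_period_days"),
                       test_cols(cmp$usage_period_days)),
      dplyr::bind_cols(tibble::tibble(measure = "pictures_per_day"),
                       test_cols(cmp$pictures_per_day)))
  } else if (nrow(trend_fit$trends)) {
    say("improver comparison skipped: fewer than two users in a trend class")
  }

  # trend analysis by dietary preference
  trend_by_diet <- NULL
  if (nrow(trend_fit$trends)) {
    td <- trend_fit$trends |>
      dplyr::inner_join(dplyr::select(users, "user_id", "diet_category",
                                      "first_valid_picture_id"),
                        by = "user_id") |>
      dplyr::mutate(diet_category = droplevels(.data$diet_category))
    first_ratings <- fp |> dplyr::select("user_id", first_rating = "avg_peer_rating")
    all_ratings <- summaries |>
      dplyr::filter(.data$n_ratings > 0) |>
      dplyr::group_by(.data$user_id) |>
      dplyr::summarise(all_rating = mean(.data$avg_peer_rating), .groups = "drop")
    td <- td |>
      dplyr::left_join(first_ratings, by = "user_id") |>
      dplyr::left_join(all_ratings, by = "user_id")
    if (length(levels(td$diet_category)) >= 2) {
      diet_groups <- function(var) {
        gs <- split(td[[var]], td$diet_category, drop = FALSE)
        gs[lengths(gs) >= 2]
      }
      mean_row2 <- function(var, label) {
        gs <- diet_groups(var)
        if (length(gs) < 2) return(NULL)
        ht <- anova_oneway(gs)
        tk <- tukey_hsd_means(gs, alpha = alpha)
        dplyr::bind_cols(
          tibble::tibble(measure = label, groups = paste(names(gs), collapse = ";"),
                         means = paste(signif(vapply(gs, mean, 0), 6), collapse = ";"),
                         ns = paste(lengths(gs), collapse = ";")),
          test_cols(ht), tibble::tibble(posthoc = posthoc_label(tk, names(gs))))
      }
      class_row <- function(cls, label) {
        per <- td |> dplyr::group_by(.data$diet_category) |>
          dplyr::summarise(total = dplyr::n(),
                           hits = sum(.data$classification == cls),
                           .groups = "drop")
        if (sum(per$hits) == 0 || sum(per$hits) == sum(per$total)) {
          say("proportion comparison for %s skipped: degenerate table", label)
          return(NULL)
        }
        pt <- proportion_table(per$hits, per$total,
                               as.character(per$diet_category))
        ht <- chi2_homogeneity(pt)
        tk <- tukey_hsd_proportions(pt, alpha = alpha)
        dplyr::bind_cols(
          tibble::tibble(measure = label, groups = paste(pt$labels, collapse = ";"),
                         successes = paste(per$hits, collapse = ";"),
                         totals = paste(per$total, collapse = ";")),
          test_cols(ht), tibble::tibble(posthoc = posthoc_label(tk, pt$labels)))
      }
      trend_by_diet <- dplyr::bind_rows(
        mean_row2("first_rating", "avg_rating_first_picture"),
        mean_row2("all_rating", "avg_rating_all_pictures"),
        class_row("Improver", "improvers"),
        class_row("Decliner", "decliners"))
    } else {
      say("trend-by-diet comparison skipped: fewer than two diet categories among eligible Actives")
    }
  }

  # registration-grid scan (Users vs Dropouts)
  registration_grid <- NULL
  binnable <- users[!is.na(users$weekday), , drop = FALSE]
  grid_of <- function(d) {
    m <- table(factor(d$weekday, levels = 0:6),
               factor(d$interval, levels = INTERVAL_LEVELS))
    matrix(as.integer(m), 7, 5, dimnames = list(WEEKDAY_LEVELS, INTERVAL_LEVELS))
  }
  is_user <- binnable$adherence %in% c("SemiActive", "Active")
  if (sum(is_user) > 0 && sum(!is_user) > 0) {
    registration_grid <- grid_proportion_scan(grid_of(binnable[is_user, ]),
                                              grid_of(binnable[!is_user, ]),
                                              alpha = alpha)
  } else {
    say("registration grid scan skipped: one of the Users/Dropouts groups is empty")
  }

  structure(list(
    settings = list(threshold = threshold, alpha = alpha,
                    min_pictures = min_pictures,
                    min_period_days = min_period_days),
    exclusions = exclusions,
    adherence = adherence,
    pictures = pictures_tab,
    diet_adherence = diet_adherence,
    first_picture_description = first_picture_description,
    first_picture_feedback = first_picture_feedback,
    user_summaries = users,
    trends = trend_fit$trends,
    trend_counts = trend_fit$counts,
    improver_comparison = improver_comparison,
    trend_by_diet = trend_by_diet,
    registration_grid = registration_grid,
    log = log), class = "eatlog_report")
}

#' @export
print.eatlog_report <- function(x, ...) {
  cat("<eatlog_report>\n")
  cat(paste0("  ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Write a report bundle to CSV files and a text summary
#'
#' One CSV per result table (diff-able, deterministic) plus `summary.txt`
#' with the run log. Re-running the pipeline on the same inputs and
#' writing again yields identical files.
#'
#' @param report An `eatlog_report` from [run_pipeline()].
#' @param directory Output directory, created if needed.
#' @return `directory`, invisibly.
#' @export
write_report <- function(report, directory) {
  stopifnot(inherits(report, "eatlog_report"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  tabs <- c("exclusions", "adherence", "pictures", "diet_adherence",
            "first_picture_description", "first_picture_feedback",
            "trends", "improver_comparison", "trend_by_diet",
            "registration_grid")
  for (tb in tabs) {
    if (!is.null(report[[tb]]))
      readr::write_csv(report[[tb]], file.path(directory, paste0(tb, ".csv")),
                       na = "", progress = FALSE)
  }
  writeLines(c("adherence-analysis run summary", "", report$log),
             file.path(directory, "summary.txt"))
  invisible(directory)
}
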