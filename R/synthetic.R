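# Synthetic usage-log cohort generator.
#
# Generates event-log cohorts with the statistical structure the analysis
# assumes: users partitioned into adherence archetypes with realistic
# picture counts and usage periods, per-picture crowdsourced ratings built
# around a user-level healthiness baseline with optional linear drift,
# rating-count distributions that exercise the first-picture validity rule,
# Bernoulli likes/comments and text descriptions with archetype-dependent
# rates, registrations over the weekday-by-daypart grid, and raw dietary
# preference responses. Everything is reproducible from the seed.

# -- distribution laws ---------------------------------------------------

#' Specify a distribution law for the cohort generator
#'
#' A small declarative family of distributions used throughout
#' [cohort_config()]: `constant`, `duniform` (discrete uniform on
#' `lo..hi`), `nbinom` (negative binomial with mean `mu` and dispersion
#' `size`, shifted to start at `lo`; when `hi` is finite the law is the
#' negative binomial conditioned on the bounded support), `exponential`
#' (shifted by `lo`, `mean` is the mean of the exponential part), and
#' `beta` (`shape1`, `shape2`).
#'
#' @param dist One of `"constant"`, `"duniform"`, `"nbinom"`,
#'   `"exponential"`, `"beta"`.
#' @param ... Parameters of the law (`value`; `lo`, `hi`; `mu`, `size`;
#'   `mean`; `shape1`, `shape2`).
#' @return A `law` object.
#' @export
#' @examples
#' law("nbinom", mu = 4.1, size = 2, lo = 2, hi = 9)  # semi-active counts
law <- function(dist, ...) {
  dist <- match.arg(dist, c("constant", "duniform", "nbinom", "exponential", "beta"))
  structure(c(list(dist = dist), list(...)), class = "eatlog_law")
}

law_min <- function(l) {
  switch(l$dist,
         constant = l$value,
         duniform = l$lo,
         nbinom = l$lo %||% 0,
         exponential = l$lo %||% 0,
         beta = 0)
}

law_max <- function(l) {
  switch(l$dist,
         constant = l$value,
         duniform = l$hi,
         nbinom = l$hi %||% Inf,
         exponential = Inf,
         beta = 1)
}

draw_law <- function(l, n) {
  if (n == 0) return(numeric(0))
  switch(l$dist,
    constant = rep(l$value, n),
    duniform = sample(seq(l$lo, l$hi), n, replace = TRUE),
    nbinom = {
      lo <- l$lo %||% 0
      hi <- l$hi %||% Inf
      if (is.finite(hi)) {
        support <- seq(lo, hi)
        w <- stats::dnbinom(support - lo, mu = l$mu - lo, size = l$size)
        if (sum(w) <= 0) abort("nbinom law has no mass on its bounded support")
        sample(support, n, replace = TRUE, prob = w)
      } else {
        lo + rnbinom(n, mu = l$mu - lo, size = l$size)
      }
    },
    exponential = (l$lo %||% 0) + rexp(n, rate = 1 / l$mean),
    beta = rbeta(n, l$shape1, l$shape2))
}

# -- configuration -------------------------------------------------------

#' Configure the synthetic cohort generator
#'
#' Defaults emulate the structure of the original study population: picture
#' counts and usage periods per adherence archetype matched to the
#' published per-class means and SDs (negative-binomial counts and
#' exponential periods are conventions, not claims about the real data);
#' per-picture peer-rating counts with mean about 18.5 and genuine mass
#' below 10 so the validity rule fires; user baselines drawn from a beta
#' law with mean 0.58 and SD about 0.195; description, like and comment
#' rates per archetype from the published first-picture comparisons; a
#' uniform 7x5 registration grid; and dietary responses at the published
#' category frequencies.
#'
#' @param n_per_archetype Named counts over the archetypes `NonUser`,
#'   `NonActive`, `SemiActive`, `Active`, `ActiveImprover`,
#'   `ActiveDecliner` (unnamed archetypes default to 0). The two trending
#'   archetypes are Actives with a built-in rating drift.
#' @param picture_count_law,usage_period_law Named lists of [law()]s per
#'   archetype. Supports must respect the archetype's classification
#'   bounds (e.g. Actives need counts >= 10 and periods >= 7 days);
#'   infeasible laws are rejected.
#' @param rating_count_law [law()] for per-picture peer-rating counts.
#' @param baseline_rating_law [law()] for the user-level mean healthiness
#'   baseline in (0, 1).
#' @param trend_slope Named numeric: rating drift per picture index for
#'   `ActiveImprover` (positive) and `ActiveDecliner` (negative).
#' @param rating_noise_sd Per-picture SD around the user's trend line.
#' @param p_empty_picture Expected share of "empty" (imageless) pictures
#'   added to the log.
#' @param p_test_first_picture Probability that a user's first picture is a
#'   test shot, simulated by forcing its rating count into `0..9`.
#' @param p_self_rating Probability a picture carries the owner's own
#'   rating; `self_rating_bias`/`self_rating_sd` shape its offset from the
#'   picture's peer-mean target.
#' @param p_description,description_length_law Named per-archetype
#'   description probability and length laws (characters, >= 1).
#' @param p_like,p_comment Named per-archetype per-picture probabilities of
#'   receiving at least one like / comment; `likes_extra_mean` and
#'   `comments_extra_mean` are the Poisson means of additional ones.
#' @param registration_grid 7x5 nonnegative weight matrix (weekday Sunday..
#'   Saturday by daypart) for registration times; uniform by default.
#' @param p_missing_registration Share of users without a registration
#'   timestamp.
#' @param diet_weights Named weights over raw "How do you eat?" responses;
#'   `p_no_diet_response` is the share answering nothing;
#'   `p_multi_response` the share adding a second distinct response.
#' @param seed Integer RNG seed; identical configs and seeds give
#'   byte-identical cohorts.
#' @return A validated `cohort_config` object.
#' @export
cohort_config <- function(
    n_per_archetype = c(NonUser = 0, NonActive = 0, SemiActive = 0, Active = 0),
    picture_count_law = list(
      NonUser = law("constant", value = 0),
      NonActive = law("constant", value = 1),
      SemiActive = law("nbinom", mu = 4.1, size = 2, lo = 2, hi = 9),
      Active = law("nbinom", mu = 58.9, size = 0.35, lo = 10)),
    usage_period_law = list(
      NonUser = law("constant", value = 0),
      NonActive = law("constant", value = 0),
      SemiActive = law("exponential", mean = 9.3, lo = 0),
      Active = law("exponential", mean = 39.6, lo = 7)),
    rating_count_law = law("nbinom", mu = 18.5, size = 1.2, lo = 0),
    baseline_rating_law = law("beta", shape1 = 3.14, shape2 = 2.27),
    trend_slope = c(ActiveImprover = 0.005, ActiveDecliner = -0.005),
    rating_noise_sd = 0.15,
    p_empty_picture = 0.0313,
    p_test_first_picture = 0.04,
    p_self_rating = 0.99,
    self_rating_bias = 0.04,
    self_rating_sd = 0.21,
    p_description = c(NonUser = 0.18, NonActive = 0.177, SemiActive = 0.330,
                      Active = 0.529),
    description_length_law = list(
      NonUser = law("nbinom", mu = 20.1, size = 2, lo = 1),
      NonActive = law("nbinom", mu = 20.1, size = 2, lo = 1),
      SemiActive = law("nbinom", mu = 23.4, size = 2, lo = 1),
      Active = law("nbinom", mu = 26.8, size = 2, lo = 1)),
    p_like = c(NonUser = 0.06, NonActive = 0.0622, SemiActive = 0.0867,
               Active = 0.133),
    likes_extra_mean = 0.3,
    p_comment = c(NonUser = 0.02, NonActive = 0.0203, SemiActive = 0.0527,
                  Active = 0.1006),
    comments_extra_mean = 0.7,
    registration_grid = matrix(1, 7, 5),
    p_missing_registration = 0.0149,
    diet_weights = c("I eat everything!" = 0.4633, "Low fat" = 0.0410,
                     "Low carbs, no carbs, or paleo" = 0.0377,
                     "Vegan or vegetarian" = 0.0328,
                     "Complex carb diet" = 0.0126, "Other" = 0.0128,
                     "Gluten free" = 0.0012, "None of the above" = 0.0090),
    p_no_diet_response = 0.4222,
    p_multi_response = 0.03,
    seed = 1L) {

  n <- setNames(rep(0L, length(ARCHETYPES)), ARCHETYPES)
  if (length(n_per_archetype)) {
    bad <- setdiff(names(n_per_archetype), ARCHETYPES)
    if (length(bad)) abort(paste0("unknown archetype: ", paste(bad, collapse = ", ")))
    n[names(n_per_archetype)] <- as.integer(n_per_archetype)
  }
  if (any(n < 0)) abort("archetype counts must be nonnegative")

  # trending archetypes share the Active laws unless overridden
  for (a in c("ActiveImprover", "ActiveDecliner")) {
    picture_count_law[[a]] <- picture_count_law[[a]] %||% picture_count_law$Active
    usage_period_law[[a]] <- usage_period_law[[a]] %||% usage_period_law$Active
    description_length_law[[a]] <- description_length_law[[a]] %||% description_length_law$Active
    p_description[a] <- if (a %in% names(p_description)) p_description[[a]] else p_description[["Active"]]
    p_like[a] <- if (a %in% names(p_like)) p_like[[a]] else p_like[["Active"]]
    p_comment[a] <- if (a %in% names(p_comment)) p_comment[[a]] else p_comment[["Active"]]
  }

  cfg <- structure(list(
    n_per_archetype = n, picture_count_law = picture_count_law,
    usage_period_law = usage_period_law, rating_count_law = rating_count_law,
    baseline_rating_law = baseline_rating_law, trend_slope = trend_slope,
    rating_noise_sd = rating_noise_sd, p_empty_picture = p_empty_picture,
    p_test_first_picture = p_test_first_picture, p_self_rating = p_self_rating,
    self_rating_bias = self_rating_bias, self_rating_sd = self_rating_sd,
    p_description = p_description, description_length_law = description_length_law,
    p_like = p_like, likes_extra_mean = likes_extra_mean,
    p_comment = p_comment, comments_extra_mean = comments_extra_mean,
    registration_grid = registration_grid,
    p_missing_registration = p_missing_registration,
    diet_weights = diet_weights, p_no_diet_response = p_no_diet_response,
    p_multi_response = p_multi_response, seed = as.integer(seed)),
    class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  probs <- c(cfg$p_empty_picture, cfg$p_test_first_picture, cfg$p_self_rating,
             cfg$p_description, cfg$p_like, cfg$p_comment,
             cfg$p_missing_registration, cfg$p_no_diet_response,
             cfg$p_multi_response)
  if (any(probs < 0 | probs > 1)) abort("all probabilities must lie in [0, 1]")
  if (!all(dim(cfg$registration_grid) == c(7, 5)) ||
      any(cfg$registration_grid < 0) || sum(cfg$registration_grid) == 0)
    abort("registration_grid must be a nonnegative 7x5 weight matrix with mass")
  if (cfg$rating_noise_sd < 0) abort("rating_noise_sd must be nonnegative")

  active_like <- c("Active", "ActiveImprover", "ActiveDecliner")
  for (a in ARCHETYPES[cfg$n_per_archetype > 0]) {
    pl <- cfg$picture_count_law[[a]]
    ul <- cfg$usage_period_law[[a]]
    if (is.null(pl) || is.null(ul))
      abort(paste0("no picture-count or usage-period law for archetype ", a))
    if (a %in% active_like) {
      if (law_min(pl) < 10)
        abort(paste0("infeasible config: ", a,
                     " picture-count law admits counts below 10"))
      if (law_min(ul) < 7)
        abort(paste0("infeasible config: ", a,
                     " usage-period law admits periods below 7 days"))
    }
    if (a == "SemiActive" && (law_min(pl) < 2 || law_max(pl) > 9))
      abort("infeasible config: SemiActive picture counts must lie in [2, 9]")
    if (a == "NonActive" && (law_min(pl) != 1 || law_max(pl) != 1))
      abort("infeasible config: NonActive archetype must draw exactly 1 picture")
    if (a == "NonUser" && law_max(pl) != 0)
      abort("infeasible config: NonUser archetype must draw 0 pictures")
  }
  invisible(cfg)
}

#' Class counts the pipeline must recover from a generated cohort
#'
#' When the archetype bounds are deterministic — every peer-rating count is
#' at least the validity threshold and no test first pictures are injected,
#' so the validity rule can never demote a user — the adherence classifier
#' must reproduce the archetype quotas exactly. This returns those expected
#' counts (the three Active-like archetypes all classify as `Active`).
#'
#' @param config A [cohort_config()].
#' @param threshold Validity threshold the pipeline will use (default 10).
#' @return Named integer vector over `NonUser`, `NonActive`, `SemiActive`,
#'   `Active`.
#' @export
expected_class_counts <- function(config, threshold = 10) {
  stopifnot(inherits(config, "cohort_config"))
  if (law_min(config$rating_count_law) < threshold ||
      config$p_test_first_picture > 0)
    abort(paste0("archetype bounds are not deterministic: the rating-count ",
                 "law admits counts below the validity threshold (or test ",
                 "first pictures are enabled), so the validity rule can ",
                 "demote users"))
  n <- config$n_per_archetype
  c(NonUser = unname(n["NonUser"]), NonActive = unname(n["NonActive"]),
    SemiActive = unname(n["SemiActive"]),
    Active = unname(n["Active"] + n["ActiveImprover"] + n["ActiveDecliner"]))
}

# -- generation ----------------------------------------------------------

# random-looking strings of given lengths, vectorised via one letter pool
random_strings <- function(lengths) {
  if (!length(lengths)) return(character(0))
  maxlen <- max(lengths)
  pool <- paste(sample(c(letters, " "), maxlen + 1000, replace = TRUE),
                collapse = "")
  start <- sample.int(1000, length(lengths), replace = TRUE)
  substring(pool, start, start + lengths - 1)
}

# realize k peer ratings with empirical mean exactly m and support [0, 1]:
# center uniform draws on m, then shrink toward m until both ends fit
realize_ratings <- function(m, k) {
  total <- sum(k)
  grp <- rep.int(seq_along(k), k)
  u <- runif(total)
  gmean <- as.vector(rowsum(u, grp) / k[k > 0])[match(grp, which(k > 0))]
  v <- u - gmean + m[grp]
  vmax <- tapply(v, grp, max)
  vmin <- tapply(v, grp, min)
  mg <- m[k > 0]
  s_hi <- ifelse(vmax > 1 & vmax > mg, (1 - mg) / (vmax - mg), 1)
  s_lo <- ifelse(vmin < 0 & vmin < mg, mg / (mg - vmin), 1)
  s <- pmin(1, s_hi, s_lo)
  v <- m[grp] + s[match(grp, which(k > 0))] * (v - m[grp])
  pmin(pmax(v, 0), 1)
}

#' Generate a synthetic event-log cohort
#'
#' Draws a full five-table cohort from a [cohort_config()]: users with
#' registration times on the weekday-by-daypart grid and raw dietary
#' responses; non-empty pictures whose per-picture target healthiness is
#' `clip(baseline + slope * (ordinal - 1) + noise, 0, 1)`; peer ratings
#' realised as individual values whose empirical mean equals that target
#' exactly while staying in \[0, 1\]; interleaved empty pictures; and
#' Bernoulli likes, comments and descriptions at archetype-dependent rates.
#' Users intended as Actives draw at least 10 pictures over at least 7
#' days, so — absent interference from the validity rule — the pipeline
#' recovers every archetype label.
#'
#' The intended archetype of every user is attached as
#' `attr(cohort, "archetypes")` (a tibble of `user_id`, `archetype`); it is
#' generator metadata, not part of the five serialised tables.
#'
#' @param config A [cohort_config()].
#' @return An `eatlog_cohort`, reproducible from `config$seed`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(
#'   n_per_archetype = c(Active = 5, SemiActive = 3), seed = 7))
#' coh
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  n_arch <- config$n_per_archetype
  n_users <- sum(n_arch)
  archetype <- rep(names(n_arch), n_arch)
  user_id <- sprintf("u%06d", seq_len(max(n_users, 0)))

  # registration: grid cell, matching calendar date in the sampling window
  cell <- sample.int(35, n_users, replace = TRUE,
                     prob = as.vector(t(config$registration_grid)))
  wd <- (cell - 1) %/% 5                      # 0 = Sunday
  interval <- (cell - 1) %% 5 + 1
  int_lo <- c(0, 5, 10, 15, 19)[interval]
  int_hi <- c(5, 10, 15, 19, 24)[interval]
  base_sunday <- as.POSIXct("2011-10-16 00:00:00", tz = "UTC")
  day0 <- base_sunday + (7 * sample.int(23, n_users, replace = TRUE) - 7 + wd) * 86400
  hour <- int_lo + floor(runif(n_users) * (int_hi - int_lo))
  registered_at <- day0 + hour * 3600 +
    sample.int(3600, n_users, replace = TRUE) - 1
  registered_at[runif(n_users) < config$p_missing_registration] <- NA
  tz_offset <- sample(c(-8:-5, 0:3), n_users, replace = TRUE,
                      prob = c(rep(0.17, 4), rep(0.08, 4)))
  tz_offset[runif(n_users) < config$p_missing_registration] <- NA

  # dietary responses
  opts <- names(config$diet_weights)
  diet_responses <- lapply(seq_len(n_users), function(i) {
    if (runif(1) < config$p_no_diet_response) return(character(0))
    first <- sample(opts, 1, prob = config$diet_weights)
    if (runif(1) < config$p_multi_response && length(opts) > 1) {
      second <- sample(setdiff(opts, first), 1)
      c(first, second)
    } else first
  })

  users <- tibble::tibble(user_id = user_id, registered_at = registered_at,
                          tz_offset_hours = as.integer(tz_offset),
                          diet_responses = diet_responses)

  # per-user usage draws
  n_pics <- integer(n_users); period <- numeric(n_users)
  for (a in unique(archetype)) {
    idx <- which(archetype == a)
    n_pics[idx] <- as.integer(draw_law(config$picture_count_law[[a]], length(idx)))
    period[idx] <- draw_law(config$usage_period_law[[a]], length(idx))
  }
  period[n_pics <= 1] <- 0
  baseline <- draw_law(config$baseline_rating_law, n_users)
  slope <- ifelse(archetype %in% names(config$trend_slope),
                  config$trend_slope[archetype], 0)

  # non-empty picture skeleton: exact first/last spacing per drawn period
  owner <- rep.int(seq_len(n_users), n_pics)
  ordinal <- sequence(n_pics)
  t0 <- dplyr::coalesce(registered_at,
                        base_sunday + floor(runif(n_users) * 150 * 86400)) +
    floor(runif(n_users) * 86400)
  period_sec <- ceiling(period * 86400)
  taken_at <- as.POSIXct(rep(NA_real_, length(owner)), origin = "1970-01-01",
                         tz = "UTC")
  frac <- runif(length(owner))
  off <- ifelse(ordinal == 1, 0,
         ifelse(ordinal == n_pics[owner], period_sec[owner],
                NA_real_))
  inner <- is.na(off)
  off[inner] <- 1 + floor(frac[inner] * pmax(period_sec[owner][inner] - 2, 0))
  taken_at <- t0[owner] + off
  # inner offsets are unordered; sort within user so ordinal follows time
  ord <- order(owner, taken_at)
  owner <- owner[ord]; taken_at <- taken_at[ord]
  ordinal <- sequence(n_pics)

  # target mean healthiness per picture
  noise <- rnorm(length(owner), 0, config$rating_noise_sd)
  target <- pmin(pmax(baseline[owner] + slope[owner] * (ordinal - 1) + noise, 0), 1)

  # peer-rating counts; optional "test" first pictures with counts in 0..9
  k <- as.integer(draw_law(config$rating_count_law, length(owner)))
  is_first <- ordinal == 1
  test_user <- runif(n_users) < config$p_test_first_picture
  force_test <- is_first & test_user[owner]
  k[force_test] <- sample(0:9, sum(force_test), replace = TRUE)

  # descriptions, self-ratings
  p_desc <- config$p_description[archetype[owner]]
  has_desc <- runif(length(owner)) < p_desc
  desc_len <- integer(length(owner))
  for (a in unique(archetype)) {
    idx <- which(has_desc & archetype[owner] == a)
    desc_len[idx] <- as.integer(draw_law(config$description_length_law[[a]],
                                         length(idx)))
  }
  description <- rep(NA_character_, length(owner))
  description[has_desc] <- random_strings(desc_len[has_desc])
  self_rating <- ifelse(runif(length(owner)) < config$p_self_rating,
                        pmin(pmax(target + rnorm(length(owner),
                                                 config$self_rating_bias,
                                                 config$self_rating_sd), 0), 1),
                        NA_real_)

  nonempty <- tibble::tibble(
    owner = owner, taken_at = taken_at, has_image = TRUE,
    self_rating = self_rating, description = description,
    target = target, k = k)

  # interleaved empty pictures (no image payload, no feedback)
  n_empty_per <- rbinom(n_users, pmax(n_pics, 0),
                        config$p_empty_picture / max(1 - config$p_empty_picture, 1e-9))
  eowner <- rep.int(seq_len(n_users), n_empty_per)
  empties <- tibble::tibble(
    owner = eowner,
    taken_at = t0[eowner] + floor(runif(length(eowner)) *
                                    pmax(period_sec[eowner], 1)),
    has_image = FALSE, self_rating = NA_real_, description = NA_character_,
    target = NA_real_, k = 0L)

  pics <- dplyr::bind_rows(nonempty, empties)
  pics <- pics[order(pics$owner, pics$taken_at, !pics$has_image), , drop = FALSE]
  pics$picture_id <- sprintf("p%08d", seq_len(nrow(pics)))

  pictures <- tibble::tibble(
    picture_id = pics$picture_id, user_id = user_id[pics$owner],
    taken_at = pics$taken_at, has_image = pics$has_image,
    self_rating = pics$self_rating, description = pics$description)

  # peer ratings with per-picture mean pinned to the target
  rated <- pics[pics$k > 0, , drop = FALSE]
  values <- realize_ratings(rated$target, rated$k)
  rgrp <- rep.int(seq_len(nrow(rated)), rated$k)
  ratings <- tibble::tibble(
    rating_id = sprintf("r%09d", seq_along(values)),
    picture_id = rated$picture_id[rgrp],
    rater_id = if (n_users > 0) sample(user_id, length(values), replace = TRUE) else character(0),
    value = values,
    rated_at = rated$taken_at[rgrp] + floor(runif(length(values)) * 7 * 86400))

  # likes and comments on non-empty pictures
  ne <- pics[pics$has_image, , drop = FALSE]
  arch_ne <- archetype[ne$owner]
  liked <- runif(nrow(ne)) < config$p_like[arch_ne]
  n_likes <- ifelse(liked, 1 + rpois(nrow(ne), config$likes_extra_mean), 0)
  lgrp <- rep.int(seq_len(nrow(ne)), n_likes)
  likes <- tibble::tibble(
    picture_id = ne$picture_id[lgrp],
    peer_id = if (length(lgrp)) sample(user_id, length(lgrp), replace = TRUE) else character(0))

  commented <- runif(nrow(ne)) < config$p_comment[arch_ne]
  n_comments <- ifelse(commented, 1 + rpois(nrow(ne), config$comments_extra_mean), 0)
  cgrp <- rep.int(seq_len(nrow(ne)), n_comments)
  comments <- tibble::tibble(
    picture_id = ne$picture_id[cgrp],
    peer_id = if (length(cgrp)) sample(user_id, length(cgrp), replace = TRUE) else character(0),
    text = random_strings(1 + as.integer(rpois(length(cgrp), 15))))

  out <- cohort(users, pictures, ratings, likes, comments)
  attr(out, "archetypes") <- tibble::tibble(user_id = user_id,
                                            archetype = archetype)
  out
}
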