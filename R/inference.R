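# Inference battery: Pearson chi-square homogeneity tests (never with a
# continuity correction, which is what reproduces the published statistics),
# a Bonferroni-corrected weekday-by-daypart grid scan, one-way ANOVA from raw
# data or printed summaries, Tukey HSD for means and for arcsine-transformed
# proportions, and the pooled two-sample t. All p-values are two-sided.

new_test_result <- function(statistic, df, p_value, kind) {
  structure(list(statistic = unname(statistic), df = unname(df),
                 p_value = unname(p_value), kind = kind),
            class = "eatlog_test")
}

#' @export
print.eatlog_test <- function(x, ...) {
  dfs <- paste(signif(x$df, 6), collapse = ", ")
  cat(sprintf("%s(%s) = %.4g, p = %.3g\n", x$kind, dfs, x$statistic, x$p_value))
  invisible(x)
}

#' Build a k-group proportion table
#'
#' Container for a 2-by-k contingency layout given as per-group success
#' counts and totals, the common currency of the homogeneity tests.
#'
#' @param successes,totals Integer vectors of equal length k (k >= 2) with
#'   `0 <= successes <= totals` and positive totals.
#' @param labels Optional group names.
#' @return A `proportion_table` object.
#' @export
proportion_table <- function(successes, totals, labels = NULL) {
  k <- length(successes)
  if (k < 2 || length(totals) != k)
    abort("need k >= 2 groups with matching successes and totals")
  if (any(totals <= 0)) abort("every group total must be positive")
  if (any(successes < 0) || any(successes > totals))
    abort("successes must lie in [0, total] for every group")
  labels <- labels %||% paste0("group", seq_len(k))
  structure(list(labels = labels, successes = as.numeric(successes),
                 totals = as.numeric(totals)),
            class = "proportion_table")
}

#' Pearson chi-square test of homogeneity for k proportions
#'
#' Tests whether k group proportions are equal, using the Pearson statistic
#' on the expanded 2-by-k success/failure table, with no continuity
#' correction, df = k - 1 and an upper-tail chi-square p-value.
#'
#' @param table A [proportion_table()].
#' @return An `eatlog_test` of kind `"chi2"`.
#' @export
#' @examples
#' chi2_homogeneity(proportion_table(c(5783, 6824, 2572), c(32648, 20659, 4863)))
chi2_homogeneity <- function(table) {
  stopifnot(inherits(table, "proportion_table"))
  m <- rbind(table$successes, table$totals - table$successes)
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (any(expected == 0))
    abort("expected cell count of zero; test undefined")
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  new_test_result(ht$statistic, ht$parameter, ht$p.value, "chi2")
}

#' Pearson chi-square for a 2-by-2 table
#'
#' Closed form `N (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`, no continuity
#' correction; identical to [chi2_homogeneity()] on the equivalent
#' two-group table.
#'
#' @param a,b,c,d Cell counts, row-wise (`a`, `b` = first row).
#' @return An `eatlog_test` of kind `"chi2"` with df = 1.
#' @export
#' @examples
#' chi2_2x2(4561, 21259, 23974, 137139)
chi2_2x2 <- function(a, b, c, d) {
  n <- a + b + c + d
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) abort("2x2 table has a zero margin")
  stat <- n * (a * d - b * c)^2 / prod(margins)
  new_test_result(stat, 1, pchisq(stat, 1, lower.tail = FALSE), "chi2")
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha Family-wise level in (0, 1).
#' @param m Number of simultaneous comparisons.
#' @return `alpha / m`.
#' @export
#' @examples
#' bonferroni_alpha(0.05, 35)  # ~0.0014, the grid-scan threshold
bonferroni_alpha <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}

#' Scan the 7-by-5 registration grid for adherence differences
#'
#' For each weekday-by-daypart cell, tests with a 2-by-2 Pearson chi-square
#' whether the share of Users who registered in that cell differs from the
#' share of Dropouts (cell versus all other cells crossed with group), at
#' the Bonferroni level `alpha / 35`. Cells significant with the Users
#' share higher are labelled `users_enriched`; with the Dropouts share
#' higher, `dropouts_enriched`; otherwise `no_difference`.
#'
#' @param users_bins,dropouts_bins 7-by-5 count matrices (rows = weekdays
#'   Sunday..Saturday, columns = dayparts night..evening) of registrations.
#' @param alpha Family-wise level before correction (default 0.05).
#' @return Tibble with 35 rows: `weekday`, `interval`, the two cell counts
#'   and proportions, `chi2`, `p_value` and `label`.
#' @export
grid_proportion_scan <- function(users_bins, dropouts_bins, alpha = 0.05) {
  stopifnot(all(dim(users_bins) == c(7, 5)), all(dim(dropouts_bins) == c(7, 5)))
  nu <- sum(users_bins); nd <- sum(dropouts_bins)
  if (nu == 0 || nd == 0) abort("empty registration grid")
  alpha_cell <- bonferroni_alpha(alpha, 35)

  grid <- tidyr::expand_grid(weekday = 0:6, interval = INTERVAL_LEVELS)
  u <- as.vector(t(users_bins))      # row-major: weekday outer, interval inner
  d <- as.vector(t(dropouts_bins))
  res <- purrr::map2(u, d, function(ui, di) {
    # a cell nobody registered in (or that holds everyone) carries no signal
    if (ui + di == 0 || (nu - ui) + (nd - di) == 0)
      return(c(stat = 0, p = 1))
    ht <- chi2_2x2(ui, nu - ui, di, nd - di)
    c(stat = ht$statistic, p = ht$p_value)
  })
  stat <- vapply(res, `[[`, 0, "stat")
  p <- vapply(res, `[[`, 0, "p")
  pu <- u / nu; pd <- d / nd
  grid |>
    dplyr::mutate(
      users_n = u, dropouts_n = d,
      users_prop = pu, dropouts_prop = pd,
      chi2 = stat, p_value = p,
      label = ifelse(p >= alpha_cell, "no_difference",
              ifelse(pu > pd, "users_enriched", "dropouts_enriched")),
      interval = factor(.data$interval, levels = INTERVAL_LEVELS))
}

#' One-way ANOVA on raw groups
#'
#' Classic fixed-effects one-way ANOVA assuming equal variances:
#' `F = MS_between / MS_within` with df `(k - 1, N - k)`.
#'
#' @param groups List of k numeric vectors (k >= 2, total N > k).
#' @return An `eatlog_test` of kind `"F"` with two df values. Zero
#'   within-group variance with distinct means yields an infinite statistic
#'   and p = 0.
#' @export
anova_oneway <- function(groups) {
  k <- length(groups)
  ns <- lengths(groups)
  if (k < 2 || sum(ns) <= k) abort("need k >= 2 groups and total n > k")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_len(k), ns))
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 0))
  df <- c(k - 1, sum(ns) - k)
  if (ssw == 0) {
    means <- vapply(groups, mean, 0)
    stat <- if (max(means) > min(means)) Inf else 0
    return(new_test_result(stat, df, if (is.infinite(stat)) 0 else 1, "F"))
  }
  tab <- stats::anova(aov(values ~ g))
  new_test_result(tab$`F value`[1], df, tab$`Pr(>F)`[1], "F")
}

#' One-way ANOVA from published group summaries
#'
#' Reconstructs the one-way ANOVA from per-group means, sample standard
#' deviations (n - 1 denominator) and sizes: between-group sum of squares
#' from the means, within-group from the SDs. Needed to check F statistics
#' printed alongside summary tables.
#'
#' @param means,sds,ns Numeric vectors of length k (ns >= 2, sds >= 0).
#' @return An `eatlog_test` of kind `"F"`.
#' @export
#' @examples
#' anova_from_summary(c(0, 2), c(1, 1), c(2, 2))  # F = 4 on df (1, 2)
anova_from_summary <- function(means, sds, ns) {
  k <- length(means)
  stopifnot(k >= 2, length(sds) == k, length(ns) == k,
            all(ns >= 2), all(sds >= 0))
  n <- sum(ns)
  grand <- sum(ns * means) / n
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((ns - 1) * sds^2)
  df <- c(k - 1, n - k)
  if (ssw == 0) {
    stat <- if (ssb > 0) Inf else 0
    return(new_test_result(stat, df, if (is.infinite(stat)) 0 else 1, "F"))
  }
  stat <- (ssb / df[1]) / (ssw / df[2])
  new_test_result(stat, df, pf(stat, df[1], df[2], lower.tail = FALSE), "F")
}

#' Pooled-variance two-sample t test from summaries
#'
#' Student's two-sample t with the pooled variance estimate, df
#' `n1 + n2 - 2`, two-sided p. Accepts printed summaries directly so that
#' published comparisons can be recomputed.
#'
#' @param mean1,sd1,n1 First group's mean, sample SD and size (n >= 2).
#' @param mean2,sd2,n2 Second group's.
#' @return An `eatlog_test` of kind `"t"`. Statistic sign follows
#'   `mean1 - mean2`.
#' @export
#' @examples
#' pooled_t(126.68, 183.73, 481, 51.41, 82.16, 4382)
pooled_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  if (sp2 == 0) {
    stat <- if (mean1 == mean2) 0 else sign(mean1 - mean2) * Inf
    return(new_test_result(stat, df, if (stat == 0) 1 else 0, "t"))
  }
  stat <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  new_test_result(stat, df, 2 * pt(-abs(stat), df), "t")
}

# Pooled t from raw vectors (sample SDs computed internally).
pooled_t_raw <- function(x, y) {
  pooled_t(mean(x), stats::sd(x), length(x), mean(y), stats::sd(y), length(y))
}

#' Tukey HSD multiple comparisons of group means
#'
#' Studentized-range pairwise comparisons of group means with the pooled
#' within-group mean square from the one-way ANOVA (Tukey-Kramer for
#' unequal group sizes), via [stats::TukeyHSD()].
#'
#' @param groups List of k numeric vectors.
#' @param alpha Family-wise level (default 0.05).
#' @return Tibble of all pairs with `diff`, adjusted `p_value` and
#'   `significant` at `alpha`.
#' @export
tukey_hsd_means <- function(groups, alpha = 0.05) {
  k <- length(groups)
  if (k < 2) abort("need at least two groups")
  ns <- lengths(groups)
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_len(k), ns))
  labels <- names(groups) %||% paste0("group", seq_len(k))
  # zero residual variance yields NaN adjusted p-values, treated as no call
  tk <- suppressWarnings(TukeyHSD(aov(values ~ g))$g)
  pair_idx <- utils::combn(k, 2)
  # TukeyHSD orders pairs as "2-1", "3-1", ..., i.e. (j, i) with j > i
  tibble::tibble(
    group1 = labels[pair_idx[1, ]],
    group2 = labels[pair_idx[2, ]],
    diff = -tk[, "diff"][paste0(pair_idx[2, ], "-", pair_idx[1, ])],
    p_value = tk[, "p adj"][paste0(pair_idx[2, ], "-", pair_idx[1, ])],
    significant = !is.na(.data$p_value) & .data$p_value < alpha)
}

#' Tukey-type multiple comparisons of proportions
#'
#' Pairwise comparisons of k binomial proportions after the arcsine square
#' root (angular) transform, following Zar's procedure: each proportion is
#' transformed to `phi = asin(sqrt(p))` (radians), whose large-sample
#' variance `1/(4n)` is free of `p`; pairs are compared with the
#' studentized range on infinite df and the Tukey-Kramer standard error
#' `sqrt((1/(4 n_i) + 1/(4 n_j)) / 2)`. Proportions of exactly 0 or 1 use
#' the standard endpoint adjustment `asin(sqrt(1/(4n)))` and
#' `asin(sqrt(1 - 1/(4n)))`.
#'
#' @param table A [proportion_table()].
#' @param alpha Family-wise level (default 0.05).
#' @return Tibble of all pairs with the studentized-range statistic `q`,
#'   `p_value` and `significant` at `alpha`.
#' @export
#' @examples
#' tukey_hsd_proportions(proportion_table(c(742, 3040, 900, 213),
#'                                        c(18590, 32090, 6291, 1798)))
tukey_hsd_proportions <- function(table, alpha = 0.05) {
  stopifnot(inherits(table, "proportion_table"))
  s <- table$successes; n <- table$totals; k <- length(s)
  p <- s / n
  phi <- asin(sqrt(p))
  phi[s == 0] <- asin(sqrt(1 / (4 * n[s == 0])))
  phi[s == n] <- asin(sqrt(1 - 1 / (4 * n[s == n])))
  pair_idx <- utils::combn(k, 2)
  i <- pair_idx[1, ]; j <- pair_idx[2, ]
  se <- sqrt((1 / (4 * n[i]) + 1 / (4 * n[j])) / 2)
  q <- abs(phi[i] - phi[j]) / se
  pv <- ptukey(q, nmeans = k, df = Inf, lower.tail = FALSE)
  tibble::tibble(group1 = table$labels[i], group2 = table$labels[j],
                 q = q, p_value = pv, significant = pv < alpha)
}

# Render a pairwise-comparison tibble as the compact "post hoc" strings used
# in the report tables ("All groups", "None", "1 and 3, 2 and 3", ...).
posthoc_label <- function(pairs, labels) {
  sig <- pairs[!is.na(pairs$significant) & pairs$significant, , drop = FALSE]
  n_all <- nrow(pairs)
  if (nrow(sig) == 0) return("None")
  if (nrow(sig) == n_all) return("All groups")
  idx <- function(g) match(g, labels)
  paste(sprintf("%d and %d", idx(sig$group1), idx(sig$group2)), collapse = ", ")
}
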