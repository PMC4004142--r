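---
title: "Methods: adherence analysis of dietary self-monitoring event logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adherence analysis of dietary self-monitoring event logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eatlog)
```

`eatlog` analyses usage event logs from a photo-based dietary
self-monitoring app with crowdsourced peer feedback. This vignette is the
package's methods account: the models and rules it implements, the
parameters that matter and why their defaults are what they are, what the
synthetic cohort generator does and does not emulate, and the numerical
edge-case policies.

## Data model and time

A cohort is five cross-referenced tables: users, pictures, peer ratings,
likes and comments. Every rating lives on a 0–1 scale where 0 is maximally
unhealthy ("fat") and 1 maximally healthy ("fit"); a picture's *average
peer rating* is the arithmetic mean of the ratings it received.

All timestamps are **local civil time** — the clock of the user's phone.
The analysis deliberately never converts across time zones: the scientific
questions about time of day ("did the user start during workday lunch
hours?") are questions about the user's own clock. `tz_offset_hours` is
carried as descriptive metadata only. Internally timestamps are `POSIXct`
pinned to a fixed zone purely as a civil-time carrier, and serialised as
ISO-8601 without an offset suffix.

Within a user, pictures are ordered chronologically with ties broken by
ascending `picture_id`, so ordinals are deterministic.

## Exclusion rules

Two exclusions precede all analysis:

1. **Empty pictures** (no actual image payload) are dropped first.
2. **The first-picture validity rule.** In logs of this kind, first
   pictures with very few peer ratings are typically test shots rather
   than food. A picture is *valid* when it received at least `threshold`
   peer ratings (default 10, boundary inclusive: exactly 10 counts). Only
   the first two pictures are ever examined: if the first is valid,
   nothing changes; if not, the second (when it exists and is valid)
   becomes the user's first valid picture and the count drops by one;
   otherwise the user has no valid first picture and the count drops by
   the number of failing pictures among the first two. A user's adjusted
   count is therefore at most two below the raw count, and pictures from
   ordinal 3 onward always count.

The **usage period** is the elapsed (fractional) days between a user's
first and last non-empty picture. The validity rule adjusts picture
*counts* only; the period is not recomputed after exclusions, matching its
definition as the duration of self-monitoring. With at most one picture
the period is 0.

## Adherence, diet and registration classifications

With adjusted count $n$ and period $d$ (days):

| Level | Rule |
|---|---|
| NonUser | $n = 0$ |
| NonActive | $n = 1$ |
| Active | $n \ge 10$ and $d \ge 7$ |
| SemiActive | otherwise ($n \ge 2$, but $n < 10$ or $d < 7$) |

NonUsers and NonActives together are the *Dropouts*; SemiActives and
Actives the *Users*. Both partitions are total: every user lands in
exactly one class. The week boundary is implemented **inclusively**
($d \ge 7.0$); "at least one week" and "longer than 7 days" are both in
circulation for this cut-off and the choice only affects users whose
period is exactly 7.0 days to the second, but it is explicit and
configurable (`min_period_days`). *Pictures per day* is
$n / \max(d, 1)$ so that single-day users are not divided by a near-zero
period.

Dietary preference comes from the raw responses to the app's "How do you
eat?" question, matched case-insensitively against the canonical options.
*Strict* means any restricting option (low fat; low/no carb or paleo;
vegan/vegetarian); *Other* any response that is neither strict nor exactly
"I eat everything!" (complex carb diet, gluten free, "Other", "None of the
above", or free text — including free-text variants like "I eat everything
except…"); *Everything* the exact everything option; *NotDefined* no
response. Users could select several options, hence the precedence
Strict > Other > Everything: a restricting choice anywhere makes the diet
strict regardless of what else was ticked. The mapping is invariant to
response order and duplication.

Registration time is binned into a 7 × 5 grid: weekday 0 (Sunday) … 6
(Saturday) crossed with five dayparts by hour, half-open on the right —
night [0, 5), morning [5, 10), daytime [10, 15), late afternoon [15, 19),
evening [19, 24). Every minute of the week belongs to exactly one of the
35 cells; users without a registration timestamp are excluded from
registration analyses only.

## The inference battery

All p-values are two-sided. The chi-square tests use the Pearson statistic
with **no continuity correction** anywhere; the correction would bias the
k-group homogeneity statistics relative to their classical definition, and
the uncorrected form is what reproduces published statistics of this kind
exactly.

* `chi2_homogeneity()` — Pearson $\sum (O-E)^2/E$ over the expanded
  2 × k success/failure table, df $k-1$.
* `chi2_2x2()` — the closed form $N(ad-bc)^2 / ((a{+}b)(c{+}d)(a{+}c)(b{+}d))$,
  identical to the k = 2 homogeneity test.
* `grid_proportion_scan()` — for each of the 35 registration cells, a
  2 × 2 test of (cell vs rest) × (Users vs Dropouts) at the Bonferroni
  level $\alpha/35 = .0014$; significant cells are labelled by which group
  is over-represented. A cell in which nobody registered carries no signal
  and is labelled `no_difference` directly. Bonferroni keeps the
  family-wise error at most $\alpha$ by construction; a finite Monte-Carlo
  estimate of that rate naturally fluctuates around the bound.
* `anova_oneway()` / `anova_from_summary()` — classical fixed-effects
  one-way ANOVA; the summary form reconstructs the between sum of squares
  from group means and sizes and the within sum from sample SDs (n − 1
  denominator), which is what published group summaries report. The two
  routes agree to numerical precision when the summaries are exact.
* `pooled_t()` — Student's pooled-variance two-sample t with df
  $n_1 + n_2 - 2$, computable directly from printed summaries. Printed
  means/SDs rounded to two decimals bound the achievable agreement with a
  published t to roughly a percent.
* `tukey_hsd_means()` — studentized-range (Tukey–Kramer) pairwise
  comparisons with the pooled within-group mean square.
* `tukey_hsd_proportions()` — "Tukey HSD among proportions" has several
  variants in the literature; this package implements Zar's procedure: the
  arcsine square root (angular) transform
  $\phi_i = \arcsin\sqrt{\hat p_i}$ (radians), whose large-sample variance
  $1/(4n_i)$ is free of $p$; pairs are compared with the studentized range
  on infinite df and the Tukey–Kramer standard error
  $\sqrt{(1/(4n_i) + 1/(4n_j))/2}$. Proportions of exactly 0 or 1 use the
  standard endpoint adjustment $\arcsin\sqrt{1/(4n)}$ and
  $\arcsin\sqrt{1 - 1/(4n)}$ rather than failing. This variant was chosen
  because it is the textbook procedure for post hoc comparison of
  proportions after a homogeneity chi-square, and in the package's tests
  its decisions agree in direction with the 2 × 2 chi-square at the same
  level on large samples.

## Per-user healthiness trends

For each eligible user the average peer ratings of their pictures,
in chronological order starting from the valid first picture, are
regressed on the picture index $1, 2, \dots, N$ by ordinary least squares
— the ordered list of pictures, not real time, is the axis, because
self-monitoring intensity varies and the question is whether successive
recorded meals trend healthier. A significant positive slope
(two-sided $p < \alpha$, default .05) makes the user an *Improver*, a
significant negative slope a *Decliner*, anything else *NoTrend*.

Policies at the edges:

* Eligibility mirrors the first-picture analyses: Actives with a valid
  first-or-second picture. Other adherence groups use the app too briefly
  for a trend to be identifiable.
* Pictures that received no peer rating have no average and are skipped;
  the index runs over the rated pictures in order.
* At least 3 rated pictures are required (the slope t-test needs a
  residual degree of freedom); eligible users with fewer are reported as
  NoTrend with an `NA` slope so the three classes still partition the
  eligible set.
* A perfect (zero-residual) fit has p treated as 0 with the slope's sign;
  a perfectly flat series is NoTrend.

The slope is computed closed-form ($S_{xy}/S_{xx}$, vectorised across
users); the test suite checks it against `stats::lm` as an independent
oracle at 1e-10 relative tolerance.

Improvers are then compared with all other eligible Actives on number of
pictures, usage period and pictures per day with pooled t tests.

## The synthetic cohort generator

The original event logs of apps like this are proprietary, so the
generator is a first-class module: it draws cohorts with the statistical
structure the analysis assumes, making every downstream stage testable.

Each user belongs to an **archetype**: NonUser, NonActive, SemiActive,
Active, plus ActiveImprover and ActiveDecliner (Actives with a built-in
rating drift). Per archetype the generator draws a picture count and a
usage period whose supports respect the classification bounds — NonUsers
draw 0 pictures, NonActives exactly 1, SemiActives 2–9, Active-like
archetypes at least 10 pictures over at least 7 days; configurations that
violate these bounds are rejected as infeasible. The first and last
picture are placed exactly the drawn period apart (rounded up to whole
seconds), with the remaining pictures uniform in between.

Default laws and rates, chosen once as field-realistic values:

* Picture counts: SemiActive negative binomial on [2, 9] with mean 4.1;
  Active 10 + negative binomial with mean 58.9 and SD near 100 (heavily
  overdispersed, as picture counts of engaged users are). Usage periods:
  SemiActive exponential with mean 9.3 days; Active 7 + exponential with
  mean 39.6 days (overall Active mean ≈ 46.6). Negative-binomial counts
  and exponential periods are conventions — published cohort tables report
  only means and SDs, not distributional forms.
* Per-picture peer-rating counts: negative binomial with mean 18.5
  (≈ 7.9M ratings over ≈ 429k pictures in logs of this scale) and enough
  mass below 10 that the validity rule genuinely fires.
* User baseline healthiness: Beta(3.14, 2.27), i.e. mean 0.58 and
  SD ≈ 0.195, matching the observed distribution of average ratings.
* Trend drift: ±0.005 rating units per picture index for the trending
  archetypes; per-picture noise SD 0.15.
* Empty pictures at 3.13% of the log; 4% of users get a "test" first
  picture, simulated by forcing its rating count into 0…9 (few ratings is
  exactly how test shots manifest in the data).
* Description presence 17.7% / 33.0% / 52.9% and like/comment rates per
  archetype from the published first-picture comparisons; description
  lengths negative binomial with archetype-specific means of 20–27
  characters.
* Registration grid uniform over the 35 cells (experiments about grid
  structure must set asymmetric weights explicitly); 1.49% of users lack
  a registration timestamp; dietary responses at the published response
  frequencies with a small rate of multiple responses.

A picture's target mean healthiness is
$\mathrm{clip}(b_u + s_u(i-1) + \varepsilon_i,\ 0,\ 1)$ for baseline
$b_u$, archetype slope $s_u$, ordinal $i$ and Gaussian noise
$\varepsilon_i$. The individual peer ratings are uniform draws recentred
on the target and, when needed, shrunk toward it so that every value stays
in [0, 1] **and the empirical mean equals the target exactly**. This
construction was chosen because every downstream analysis consumes only
the per-picture mean and count; pinning the mean makes the generated
cohort's trend structure exactly the configured one, while individual
rating values remain plausible.

Determinism: identical config + seed yields byte-identical cohorts (the
generator saves and restores the global RNG state). The intended archetype
of each user is attached as an attribute — generator metadata, not part of
the serialised tables.

**What the generator does not emulate.** Real logs have rater-level
idiosyncrasies (harsh/lenient raters, cultural differences), social
network structure in who rates/likes whom, meal-level autocorrelation
beyond a linear drift, selective photographing ("gaming" by recording only
healthy meals), and seasonal or marketing-driven registration waves. Tests
passing on synthetic cohorts therefore demonstrate that the pipeline's
rules, classifications and statistics do what they claim on data with the
assumed structure — not that the assumed structure is the truth about any
real population. Dataset-level outcome percentages of the original app
population (adherence shares, improver shares) are outcomes of a
non-public population, not generator parameters, and the generator makes
no attempt to reproduce them.

## Verification design and problem sizes

The package's checks are built around independent oracles, at sizes chosen
to keep the default suite fast while leaving Monte-Carlo noise well inside
the asserted tolerances:

* Statistic oracles: 1,000 random instances each for chi-square (vs a
  brute-force $\sum(O-E)^2/E$), one-way ANOVA (vs explicit sums of
  squares, and the raw-vs-summary route), and the OLS slope (vs
  `stats::lm`), at 1e-9 relative tolerance or tighter.
* Quota recovery: a 3,000-user mixed-archetype cohort generated with
  rating counts pinned at or above the validity threshold, where the
  classifier must reproduce the archetype quotas exactly (diagonal
  confusion matrix).
* Type-I: 10 seeds × 400 zero-slope Actives × 30 pictures; the
  Improver + Decliner rate must sit within 1.5 percentage points of the
  nominal 5%.
* Power: 1,500 ActiveImprovers with slope 0.005 per picture, noise SD
  0.15 and 30–100 pictures, compared against a 6,000-replicate Monte-Carlo
  power oracle (direct simulation + `lm`) within 3 percentage points.
* Family-wise control: 500 homogeneous multinomial registration grids
  (2,000 users / 10,000 dropouts per replicate) scanned at $\alpha/35$.
  The scan's true family-wise rate is pinned at the Bonferroni bound by
  construction, so the 500-replicate estimate fluctuates by about ±1
  percentage point around 5% across seeds — an estimate slightly above 5%
  at a particular seed reflects that Monte-Carlo noise, not a failure of
  error control.

## Known limitations

* The validity rule is a rating-count proxy for the manual content
  screening an analyst would do on real pictures; no image content is
  ever inspected.
* Users who registered too close to the end of a sampling window cannot
  have reached an Active-length period; `summarize_users(study_end = …)`
  flags them (`late_registrant`) but never reclassifies.
* The trend model is linear in picture index; nonlinear or episodic
  change is reported only through its best linear approximation.
* Self-ratings are optional in the schema; analyses of the self-vs-peer
  difference silently restrict to users who rated their own picture.
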