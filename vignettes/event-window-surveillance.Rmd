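---
title: "Event-window analysis of search-query logs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-window analysis of search-query logs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(querypulse)
library(dplyr)
```

## The problem

Web-search logs are a near-real-time record of what a population wants to
know and do. Around a major societal event — the motivating case is
firearm-related searching around the December 2012 Sandy Hook school
shooting — the interesting questions are behavioural: how much did
firearm-related searching rise, toward which kinds of websites did the
traffic shift (retail, news, educational; commercial, governmental,
advocacy), how does that compare to an event-agnostic control topic over
the same calendar window, and how quickly did the surge fade?

querypulse implements that analysis as a pipeline of small, testable
stages. Because real search-engine logs are proprietary, the package also
ships a fully specified synthetic-log generator with the statistical
structure the analysis assumes, so every stage can be exercised and
validated end to end without any external data.

## The data model

A search log is a tibble of records `(day, query, clicked_url)`, where
`day` is an integer offset from the event (day 0 = the event). The study
geometry is a pair of half-open, equal-length windows: with half-length
$W$ (default 14), *before* covers days $-W \dots -1$ and *after* covers
days $0 \dots W-1$. The event day belongs to the after window: reactions
begin on the day itself, and this keeps the two windows contiguous and of
equal length.

## Query classification

Queries are normalized (Unicode NFKC, lower case, punctuation to spaces,
whitespace collapsed — an idempotent transform) and matched against a
keyword taxonomy. Two matching rules are deliberate:

* **single-word keywords match as token prefixes** — `gun` matches
  "guns" and "gunsmith" but not "begun", and `ammo` does not fire inside
  "mammogram". Raw substring matching over-captures; exact-token matching
  under-captures plurals and compounds. Token-prefix is the middle ground.
* **multi-word keywords match as contiguous substrings** of the
  normalized query (`second amendment`, `brady act`).

A query matching several categories is assigned to exactly one, by a
configurable priority order defaulting to most-specific-first:
`law_related > shooting > ammunition > gun_type > control`. Single
assignment keeps category counts a partition of the log (shares sum to
100%); most-specific-first means "second amendment gun rights" counts as
a law query, not a gun-type query.

The related-query expansion operator (`expand_related_queries()`) grows a
seed set by Pearson correlation of daily count series over the log
itself: each frontier query contributes its top-$k$ correlated queries at
or above `rho_min`, iterated to a fixpoint, with lexicographic
tie-breaking so the closure is deterministic. This emulates, on the log
at hand, the recursive "most correlated searches" discovery workflow that
trend tools offer; it is an emulation grounded in the log's own
correlations, not a replication of any external service. Constant series
get correlation 0 by definition rather than NaN.

## URL classification

Each clicked URL is reduced to its registrable domain (one label plus the
public suffix, subdomains stripped, `en.wikipedia.org` → `wikipedia.org`)
using a frozen public-suffix rule table shipped with the package; live
suffix lists drift, and a pinned snapshot keeps results reproducible.
Multi-part suffixes are respected (`portal.ct.state.us` → `ct.state.us`).
Unparseable URLs become error records, tallied in the run manifest, never
exceptions.

Domains then receive:

* a **TLD category** from ordered suffix rules — `.state.us` (government)
  outranks the `.us` country rule, then `.gov`/`.mil` government, `.com`
  commercial, `.org` noncommercial, `.edu` educational institution,
  everything else *other*;
* a **content category** (retail, news, educational, showbiz, other) by
  exact lookup in a user-editable domain registry — unknown domains are
  *other*, mirroring manual-categorisation workflows;
* an **advocacy view** (gun rights / gun control / none) from the same
  registry. The bundled registry is synthetic (invented, plausible
  domains): the original study's manual registry and advocacy affiliate
  lists were never published, so the fixture is illustrative and is meant
  to be replaced for real analyses;
* a combined **class label**, e.g. `"retail content, .com"`, the unit of
  the cross-tabulations.

## Cross-tabulation statistics

For a query category, `build_crosstab()` lists the top-$k$ (default 4)
classes by volume, a residual row aggregating the remainder, and a total
row. Per row with before/after counts $b, a$:

* before/after percents: $100\,b/(a+b)$ and $100\,a/(a+b)$;
* **percent change** $\Delta\% = 100\,(a-b)/b$, undefined (reported
  missing) when $b = 0$;
* **cumulative percent**: running $100 \sum n_i / N$ against the category
  total $N$, so listed rows show how much of the category the table
  covers.

All internal arithmetic is full precision; percents are rounded only at
reporting, half away from zero, to 2 decimals (base R's round-half-even
would print 0.125% as 0.12%).

Advocacy tables are computed from actual record counts. A separate
constructor, `advocacy_from_shares()`, reproduces published advocacy
tables that print only `(n, before %)` pairs: it reconstructs
`before_n = round(n * before_pct / 100)` and differences integers. The
reconstruction is exact for most published rows but two decimals of
percent cannot always recover the true integer count when `n` is large
(tens of thousands), so isolated reconstructed changes can differ from a
published value in the second decimal; this is information loss in the
printed table, not an arithmetic discrepancy.

`control_contrast()` subtracts the control topic's percent change from
the target's, class by class (falling back to the control total for
classes the control never visits), and flags changes exceeding the
control as event-attributable. The contrast is descriptive — no tests or
intervals — matching the exploratory character of the analysis.

## The synthetic generator

Per category $c$ and day $d$, record counts are independent Poisson draws
with mean

$$\lambda(c,d) = \beta_c \cdot m(c,d) \cdot s(c,d), \qquad
m(c,d) = \begin{cases} 1 & d < 0\\
1 + (\mu_c - 1)\, 2^{-d/h_c} & d \ge 0 \end{cases}$$

where $\beta_c$ is the baseline rate (queries/day), $\mu_c$ the event
multiplier, $h_c$ the halflife (days) of the excess, and $s(c,d)$ an
optional spike multiplier on single listed days. Each record's query is
drawn from category templates (every template embeds one of the
category's keywords, so generated records classify back to their
generating category — a tested invariant) and its URL from a weighted
registry-domain distribution. Poisson counts give a closed-form oracle:
`expected_counts()` returns $\lambda(c,d)$ exactly, and the test suite
checks Monte-Carlo means against it cell by cell at 3 standard errors.

All randomness flows through one seeded stream scoped to the call
(`withr::with_seed`), so a configuration plus seed reproduces a log byte
for byte and never touches the caller's RNG state.

The default configuration (`default_generator_config()`) emulates the
study's qualitative shape at roughly 1/200 scale — about 1,100 firearm
records/day at baseline, shared ~60/22/17/1 percent across gun type /
shooting / ammunition / law queries, matching the observed composition.
Event multipliers (2.7, 12.6, 6.4, 19.5) were chosen so each category's
window-averaged change mirrors the observed relative changes given a
2.5-day halflife, which puts traffic back near baseline roughly ten days
after the event; ×1.5 spikes at days −6 and −11 mimic pre-event news
bumps, and the bicycle control is flat (its event multiplier is pinned
to 1 by construction). These defaults are a qualitative emulation, not a
claim about the true data-generating process.

What the generator deliberately does **not** model: users and sessions
(records are independent), query reformulation chains, weekday/holiday
seasonality, result ranking, or overdispersion beyond Poisson. Passing
tests on synthetic logs therefore validate the *pipeline arithmetic and
estimators* under the stated noise model — they cannot validate
substantive conclusions about real search behaviour, where burstiness and
shared-user correlation would widen every sampling distribution.

## Trend analysis

`daily_series()` produces zero-filled per-day counts by category, TLD
category, content category or advocacy view.

**Spike detection.** A pre-event day is a spike when its count exceeds
`median + k × MAD-sd` of the pre-event days (default $k = 3$, MAD scaled
to be consistent with the normal SD). Median/MAD statistics are used
precisely because the pre-event window *contains* the spikes being
sought; a plain mean/SD would be inflated by them. The rule is invariant
under uniform rescaling of the series and needs at least 5 pre-event
days.

**Return to baseline.** The baseline band is `median + 2 × MAD-sd` of the
pre-event days *excluding* detected spikes. The return day is the first
post-event day opening a run of `consecutive` in-band days. The default
`consecutive = 3` is a conservative reporting rule: it refuses to declare
a return on a single lucky dip. That robustness has a known cost, worked
out analytically on the Poisson model: near the crossing day the count is
at the band edge, so each day is in-band with probability about ½, and
requiring a run of 3 pushes the declared day one to two days past the
true crossing with a right-skewed tail (and, within a 14-day after
window, censors returns later than day $W - 3$). When the quantity of
interest is the *crossing day itself* — as in the package's recovery
experiments, where the decay is tuned so the analytic rate crosses the
band at a known day — `consecutive = 1` is the approximately unbiased
estimator and is what those experiments use; both choices are exposed.

A tested monotonicity property ties the pieces together: on the analytic
expectation series, a larger event multiplier (same halflife) never gives
an earlier return day.

## Validation strategy and problem sizes

The test suite validates each stage against an independent oracle rather
than against itself: keyed-in published table counts pin the percent
arithmetic to known printed values (to ±0.01 after rounding); brute-force
filter-and-count loops written in base R re-derive every cross-tab and
trend count on sampled logs; the closed-form Poisson means check the
generator; and a plain-loop closure recomputation checks the correlation
expansion. Stochastic recovery experiments run the full
generate → classify → tabulate/trend pipeline: 100 logs at 1,000
records/day recover a ×2 step (no decay) as a mean total change within
1% of +100% with the control centred on 0; 100 logs recover ×3 spikes at
days −6/−11 exactly in ≥95% of runs; and with the decay tuned for an
analytic band-crossing at day 10 (baseline 1,000/day, multiplier 12,
halflife ≈ 1.34 days), the estimated crossing day lands in [8, 12] in
≥90% of runs. These sizes keep the whole suite around two minutes while
leaving the Monte-Carlo standard errors far inside the asserted bounds.

## Known limitations

* Registry lookup is exact-match and manual; in real data a long tail of
  rare domains stays uncategorised (*other*), and content conclusions
  inherit whatever selection that tail carries.
* The keyword matcher does no stemming, spelling correction, or semantic
  matching; a taxonomy is only as good as its keyword lists.
* The public-suffix snapshot is small and frozen; exotic suffixes fall
  back to a last-two-labels rule.
* Percent-change contrasts are descriptive. With a single realised
  before/after pair per class there is no within-study replication, and
  the package deliberately reports no inferential statistics.
* Day-level aggregation hides within-day dynamics and user-level
  structure; records are treated as exchangeable within a day.

## A compact example

```{r example, fig.width = 7, fig.height = 4}
cfg <- default_generator_config(seed = 20121214)
log <- generate_log(cfg)
cl <- classify_log(log)

build_crosstab(cl, "gun_type", event_window()) |> glance()

tr <- daily_series(cl, "category", event_window())
detect_spikes(tr)
return_to_baseline_day(tr)
autoplot(tr)
```
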