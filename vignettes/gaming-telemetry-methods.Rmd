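---
title: "Methods: sessionization, behavioral metrics and emotion analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sessionization, behavioral metrics and emotion analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gametel)
```

gametel turns raw competitive-gaming telemetry — one row per played match,
per-second facial-emotion streams inferred from gameplay video, and in-game
event logs — into the behavioral indicators a clinician reviews when
screening for problematic gaming (Internet Gaming Disorder work-ups and
similar). This vignette explains the model behind each computation, the
tunable parameters and their defaults, the design decisions taken where the
problem is genuinely underdetermined, and what the synthetic-data generator
does and does not emulate.

## Sessions from inter-match gaps

The basic behavioral unit is the *session*: a maximal run of consecutive
matches in which each match starts less than a gap threshold after the
previous one finished. The default threshold is 30 minutes; it can also be
derived from data as an empirical quantile (default the 60th percentile) of
the observed inter-match gaps, the way the 30-minute default is calibrated
from real histories.

Three details are worth making explicit, because they are easy to get subtly
wrong:

* **Gap definition.** The gap is measured from the previous match's finish
  to the next match's start — idle time, not cycle time. Telemetry
  occasionally reports overlapping matches; negative gaps are clipped to
  zero rather than rejected.
* **Strict boundary.** A gap *exactly equal* to the threshold starts a new
  session. This reading makes the limit behavior clean: a threshold of zero
  yields one session per match.
* **Quantile definition.** `derive_gap_threshold()` uses linear
  interpolation between order statistics (`stats::quantile()` type 7) and
  records the choice, so a derived threshold is reproducible. For gaps of
  1–100 minutes the 60th percentile is 60.4 minutes, not 60.

Two durations summarize a session. *Played* time is the sum of match
durations. *Connected* time is the session span — first start to last
finish, including the gaps. Played time never exceeds connected time, and it
is invariant under re-sessionization because it depends only on the matches
themselves.

## Clock-time classification

Each match is classified by the local clock time of its start into one of
three day parts — morning, afternoon, evening — and into midweek
(Monday–Friday) versus weekend (Saturday–Sunday). The conventional
anchors (morning from 6 a.m., afternoon from 2 p.m., evening from 10 p.m.)
leave two clock hours unassigned, so the package extends them to three
half-open 8-hour blocks:

* morning \[06:00, 14:00)
* afternoon \[14:00, 22:00)
* evening \[22:00, 06:00)

which are total, balanced and consistent with the anchors; 13:30 is morning
under this extension. Timestamps are stored in UTC; classification reads
the clock in a configurable local timezone (default UTC), because telemetry
platforms report absolute times while "evening" is a statement about the
gamer's local clock. A match is classified by its `started_at` alone and a
session is dated by its `session_start`, so matches that cross midnight or
a block boundary have one unambiguous label.

## Historical metrics

`historical_stats()` computes the full first-consultation report: general
totals, per-session ratios, monthly and weekly averages, and day-part /
weekday breakdowns. The definitions that involved a real choice:

* **Hours per session uses connected time.** A session's duration, as a
  behavioral quantity, includes the short breaks between its matches;
  dividing played hours by sessions would systematically understate the
  time a gamer is bound to the platform.
* **Monthly and weekly denominators count active periods.** A month (or ISO
  week) with no play does not dilute the average: `avg_matches` per month
  is total matches over months with at least one match. A seasonal pause —
  a gamer who stops every June — therefore shows up in the monthly chart
  series (which keeps zero months) but does not drag the monthly averages
  toward zero. The active-week rule mirrors the active-month rule for
  consistency; `n_weeks_played` reports the denominator so the choice is
  auditable.
* **Day-part daily averages use calendar days.** `avg_daily_hours` for a
  part divides the played hours of matches starting in that part by the
  number of calendar days in the requested period — it answers "how much of
  a typical day is spent playing in the evening", not "of a typical active
  day".
* Undefined ratios (no sessions in the period) are reported as explicit
  `NA`/`null`, never silently zero.

The per-month table kept alongside the summary blocks (`by_month`) is what
the chart builders consume; the chart layer is a pure function of report
blocks and never recomputes from raw telemetry.

## Recent metrics

`recent_stats()` is the between-consultation monitor. All windows are
anchored at `as_of`, exclusive: the current week is `[as_of - 7d, as_of)`,
the previous week the 7 days before that. Two conventions required a
decision:

* **The previous-month baseline** is the mean weekly value over the four
  weeks preceding the current window, `[as_of - 35d, as_of - 7d)`. A
  month-over-month comparison of a weekly quantity needs a weekly-scale
  baseline; averaging four whole weeks is less noisy than comparing against
  the same single week one month earlier. For the hours-per-session ratio
  the baseline pools the four weeks (total connected hours of those
  sessions over their count), which equals the session-weighted mean of the
  weekly ratios.
* **Sessions are never split across window boundaries**: a session belongs
  to the window containing its start, keeping session counts integral.

Percent differences are `100 (current - previous) / previous`, rounded half
away from zero to a signed integer percent (base R's `round()` is
round-half-even, which is the wrong convention for reporting); a zero
baseline yields `NA` rather than an infinity. The 13-day daily series
buckets matches into thirteen 24-hour windows ending at `as_of`, labelled
by local calendar date, and always has 13 rows.

## Emotion analytics

Emotion streams are per-second 7-channel percentage vectors (angry,
disgust, fear, happy, sad, surprise, neutral). Recognition backends often
emit unnormalized scores, so frames are renormalized to sum to 100 on
reading; an all-zero frame is an error, not a silent zero.

* **Smoothing** replaces each channel value at second `t` by the median of
  the raw values in the causal window `{t-4, ..., t}`. The window includes
  the current second: a purely lagged window would shift every trace right
  by construction and misalign spikes with the events that caused them.
  Channel-wise medians do not preserve the sum-to-100 property, so smoothed
  frames are *not* renormalized and are intended for plotting; all
  summaries are computed on raw frames.
* **Event windows** are symmetric and inclusive: the per-event statistic is
  the per-channel median over frames within 3 seconds of the event (at most
  7 frames), truncated at stream boundaries with the frame count reported.
  The same window is applied to kills, deaths and round boundaries for
  uniformity, although one-sided windows would be defensible for round
  events.
* **Aggregation across events of a kind** is a median of per-event medians,
  not a pooled-frame median — robust to unequal window truncation and to a
  few events with extreme windows.
* **Match and period averages** are plain per-channel means over all frames
  in scope (linearity keeps them summing to 100); the first/last 5-minute
  contrast uses 300-second spans at either end of a stream and flags spans
  that overlap when a match is shorter than 10 minutes.

Emotion streams carry their own relative clock (video time); a sidecar
mapping table (`stream_id`, `match_id`, `offset_s`) declares the alignment
to match windows, since video timestamps are generally not recoverable from
the platform.

## The synthetic-data generator

Real per-gamer telemetry of this kind is not publicly distributable, so the
package ships a seeded generator that produces match histories, event logs
and emotion streams with *known ground truth*, and the validation suite is
built against it.

A `gamer_profile()` fixes: a weekly session rate (split across weekend and
midweek days by `weekend_fraction` and drawn per day as Poisson counts), a
shifted-geometric matches-per-session distribution with a stated mean,
normal(40, 5) match durations clipped to [20, 70] minutes, lognormal
intra-session gaps with a stated median (clipped below the session
threshold), a day-part mix for session starts, and optional off months with
zero play. The two built-in archetypes encode the qualitative patterns
reported for amateur and professional competitive players: amateurs
(default rate 5/week, 1.8 matches/session, 90 % evening starts, an August
pause) and professionals (3.5/week, 5.3 matches/session, day-balanced,
~4.3 h sessions). Those parameter values were chosen once to reproduce the
reported archetype summaries (evening-dominant short amateur sessions;
professional sessions averaging above four hours) and are not tuned
afterwards.

Placement is designed so that planted quantities are analytically
recoverable:

* A session's start is sampled uniformly over the positions where the whole
  session fits inside its day part's clock block *and* its calendar day, so
  every match of a session shares the planted part and weekday class and
  the expected match fractions equal the profile's mixes.
* Consecutive sessions are kept at least the gap threshold (plus one minute
  of head-room) apart, sampling each start from the still-feasible part of
  its block, sliding to the same part on a following eligible day when the
  block is full. Sessions are never dropped, so planted rates are exact.
* The only drift from the planted mixes comes from *oversize* sessions —
  longer than their block — which anchor at the block start and run over,
  as real sessions do. For the amateur profile these are rare (under half a
  percent of sessions); for professionals, whose evening block fits at most
  ~6 h, they are common enough that day-part fractions are validated only
  qualitatively for that profile.

Emotion streams are per-second Dirichlet draws around a baseline mix
(concentration controls calmness; infinity gives a constant stream). An
event effect raises its channel by a planted number of percentage points
for the onset second plus `duration_s` following seconds, rescaling the
other channels so frames still sum to 100 — this preserves the planted
magnitude exactly in the bumped channel, which is what makes
recovery testable. (Rescaling *all seven* channels instead would shrink a
+30-point bump to roughly +20 depending on baseline, making the planted
size unrecoverable.) With a 3-second effect, the inclusive ±3 s window
holds 4 affected frames out of 7, so the window median sits on the bumped
level; the median-of-4 order statistic biases recovery slightly downward
(a +30 plant is typically recovered as +25 to +29), well inside the ±20 %
validation band.

What the generator does **not** emulate: team structure, round economics,
skill drift over months, correlated emotion dynamics (each second is
conditionally independent given the baseline), recognition dropout, or
circadian variation *within* a day part. Tests passing on generated data
therefore validate the computations and their contracts, not claims about
real populations.

## Validation design and problem sizes

The suite validates every windowed statistic against naive brute-force
recomputation on streams up to 1,000 seconds, sessionization against a
pairwise-scan oracle on 1,000 random histories and against the generator's
planted partitions on 1,000 seeded two-week histories, conservation
invariants (fractions summing to one, played ≤ connected hours, emotion
means summing to 100) across 100 seeds, and generator–analyzer closure —
total matches, match duration, matches per session, played hours, and (for
the amateur archetype) day-part and weekend fractions — against analytic
expectations within three standard errors across 100 seeds of 8-week
histories. The clipped-normal duration mean is computed in closed form for
the closure check. Archetype fixtures span a 24-month window, matching the
observation span the metric suite is designed around.

## Known limitations

* Connected time is a telemetry-only proxy: platform idle time outside
  session spans is invisible to it.
* The weekly-average definitions cannot be reconciled with every published
  summary convention; the active-week rule is an interpretation and is
  exposed in the report so consumers can recompute.
* Day-part classification assumes one timezone per report; travel is not
  modelled.
* Event-aligned medians describe association, not causation; windows
  around closely spaced events can overlap the effects of their neighbors.
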