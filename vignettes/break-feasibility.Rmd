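---
title: "Modeling break-relief feasibility in operating rooms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling break-relief feasibility in operating rooms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(orbreaks)
library(dplyr)
```

## The problem

An anesthesia department wants to know how often an anesthesiologist who is
clinically supervising one, two, or three operating rooms could personally
give a 30-minute lunch break or a 15-minute mid-morning break to the nurse
anesthetist in one of those rooms, without missing induction or emergence in
any supervised room. The answer drives staff scheduling: every break the
supervisor cannot give must be covered by an additional relief practitioner.

The difficulty is that a break can only be promised on the strength of a
*prediction*: at the moment the break would start, nobody knows when the case
will end. `orbreaks` formalizes the planning rule as a per-procedure lower
prediction bound of surgical time and an interval calculus over the rooms a
supervisor covers, then reports feasibility percentages with exact binomial
uncertainty.

## The duration model

Surgical times (incision to dressing, in hours) are modeled per procedure
code as two-parameter log-normal. From the historical cases of a code we keep
the most recent 99 (ties on the start timestamp broken by stable input
order), and compute the sample mean $m$ and SD $s$ of the natural-log times.
The 5% lower prediction bound for one future case of that code is

$$
B = \exp\!\left(m - t_{0.95,\,n-1}\; s \sqrt{1 + 1/n}\right),
$$

the classical Student-t prediction bound for a single future observation: the
next case of the procedure exceeds $B$ with 95% probability if the log-normal
model holds. We deliberately use the prediction-bound form rather than a
tolerance bound: the planning question concerns the next single case, not a
population quantile, and `calibration_simulation()` confirms by Monte Carlo
that the realized lower-tail incidence equals the nominal risk.

Choices worth stating explicitly:

* natural logarithms, hours as the time unit;
* the 99-case cap keeps estimates current without modeling drift;
* a code with fewer than two historical cases has no usable bound. Such
  cases are excluded from every feasibility denominator and the exclusion is
  counted and reported (`excluded_reason`). This is conservative; no
  imputation or pooling across codes is attempted;
* `risk` is configurable (default 0.05) so calibration can be property-tested
  at other levels.

## The suitable interval and the break calculus

For a case starting at time $a$ with bound $B$ and actual end $e$, the period
suitable for a break is

$$
[\,a + 15\ \text{min},\ \min(a + B,\ e)\,].
$$

The 15-minute lead-in covers induction completion, positioning, and initial
documentation. The interval is empty when the predicted safe length does not
even cover the lead-in. One sentence in the source methodology can also be
read as ending the interval at $a + B - 15$ min; we adopt the first reading
(consistent with the accompanying table footnotes describing the window as
"between 15 minutes after the start ... and the end"), and expose the
stricter alternative as `break_policy(bound_end_rule = "subtract_lead_in")`.

A break policy asks for `duration_min` minutes starting inside a clock window
(lunch 11:15–12:45, mid-morning 9:00–10:30, the widened sensitivity window
11:00–13:00, or no window at all). The break must *start* in the window but
may end after it. Feasibility for a single supervised room is simply whether
such a start exists inside the suitable interval.

For multi-room supervision, rooms are cyclically adjacent by room number
among the rooms in use that day at that facility. For each of the index
case's two neighbors we intersect the index suitable interval with each
neighbor case's suitable interval and keep the single longest intersection —
a break is contiguous, so disjoint pieces are never united. A neighbor room
with no case intersecting the index interval imposes no constraint (the
supervisor effectively has one ongoing case there). Then:

* `two_best` / `two_least`: feasibility is evaluated in each neighbor's
  maximum-overlap interval; the OR of the two room results is the
  best-chance pairing, the AND the least-chance;
* `three`: feasibility is evaluated in the intersection of the index
  interval with both rooms' maximum-overlap intervals.

By construction the flags are nested (`three` ⟹ `two_least` ⟹ `two_best`
⟹ `single`), and the test suite verifies exact agreement with an
independent brute force that enumerates every minute of every candidate
break start on randomized small schedules.

Two further conventions the source leaves open:

* neighbor cases without a usable bound have no suitable interval and so
  contribute no constraint — the overlap is defined between bound-truncated
  periods, which do not exist without a bound;
* if two neighbor-case intersections tie in length, the earlier one is used
  (only the OR/AND across pairings matters downstream, so this affects
  nothing but determinism).

## Denominators

Throughout-workday analyses count every case with a computable bound; cases
whose suitable interval is empty stay in the denominator as infeasible.
Windowed analyses count a case only when its suitable interval could meet a
break started in the window: interval start ≤ window end and interval end ≥
window start. This conditioning rule is the largest inference we make — the
source tables clearly use window-dependent denominators (the same suite has
different sample sizes for different windows) without stating the rule — so
it is centralized in one place (`in_denominator`) and flagged here.
Note one consequence: because denominators differ by window, the
throughout-day percentage is not mathematically forced to exceed the
windowed one; the dominance invariant is asserted in the tests only at the
per-case level, where it is exact.

## Summaries

Every percentage is reported with an exact two-sided 99% Clopper-Pearson
interval from Beta quantiles; zero- and all-success rows use the closed
forms. Display rounding is one decimal, half away from zero. The
service-by-weekday staff-scheduling analysis keeps strata with at least five
cases, counts single-room any-time feasibility, and reports one-sided lower
limits at the Šidák level $1-(1-(1-\mathrm{FWER})^{1/m})$ for the realized
stratum count $m$ — with 50 strata and a 5% family-wise error rate this is
the 99.9% level. The facility covariate analysis relates each facility ×
window feasibility percentage to the facility's percentage of denominator
cases at least `duration + lead-in` long; feasibility can never exceed that
retrospective percentage, because the bound is what is knowable in advance.

## The synthetic-schedule generator

No institutional case data are distributed, so the generator produces the
study's statistical shape from a seed:

* three facility archetypes ordered short → long duration: ambulatory (8
  rooms, weighted-median case 0.85 h), pediatric (6 rooms, 1.20 h), adult
  inpatient (10 rooms, 1.80 h). Room counts, the 07:45–17:00 workday, and
  the 30-minute turnover are stand-ins chosen so that typical room lists
  straddle the lunch and mid-morning windows; they are not estimates of any
  institution;
* 50-procedure catalogs per facility: 45 common codes with Zipf(0.9)
  weights plus 5 explicitly rare codes, so a multi-year history contains
  both >99-case codes (exercising the cap) and <5-case codes (exercising
  the sparse-history path). Per-code `mu` and `sigma` are weighted-quantile
  discretizations of LogNormal(log median, 0.45²) and Uniform(0.30, 0.55):
  the seed permutes which code carries which parameters, but the catalog's
  frequency-weighted parameter distribution is the same for every seed.
  This makes the ambulatory < pediatric < adult feasibility ordering a
  property of the design, not of a lucky draw;
* sequential scheduling: in each room each weekday, the first case starts
  at the workday open, each next case follows the previous end plus
  turnover, and cases are appended while they would start before the
  workday close (the last case may overrun it). Durations are drawn
  log-normal per procedure and rounded to whole minutes, matching
  minute-resolved clinical timestamps;
* the historical and future periods share catalogs (stationary
  distributions) and occupy disjoint weekday ranges, historical strictly
  first. Defaults are 756 historical and 252 future weekdays — three years
  and one year.

What the generator does **not** emulate: turnover variability, add-ons and
cancellations, surgeon effects, duration drift, within-day room-count
changes, holidays. Passing tests on these data therefore demonstrate the
correctness and calibration of the *method* under its stated model, not the
percentages any real facility would see.

```{r study, fig.width = 7, fig.height = 4}
study <- run_study(seed = 1, hist_days = 120, future_days = 20,
                   policies = default_policies()[c("lunch", "lunch_anytime")])
glance(study)
autoplot(study$summary)
```

The problem sizes used in the package's own checks are deliberately modest:
the distributed test suite runs studies of 10–30 historical days for
behavioral checks and one 252+252-day study (≥ 5,000 future cases per
facility) for the facility-ordering check, and the Monte-Carlo calibration
uses 100,000 replicates; all are the package's choices of smallest sizes at
which the statistical assertions have comfortable power.

## Numerical conventions

* all interval arithmetic is in minutes from midnight of the case's own
  date, so a case running past midnight keeps a coherent interval;
* POSIXct day arithmetic carries ~1e-13 min of float round-off; interval
  endpoints are snapped to 1e-9 min so minute-resolved schedules compare
  exactly;
* equalities: a future time exactly at the bound is *not* below it; an
  interval with end ≤ start is empty; a zero-length touch of two intervals
  is no overlap; a break may end exactly at the interval end;
* display rounding (one decimal, half away from zero) happens only at
  rendering; all stored statistics are full precision.

## Limitations

The flags are upper bounds on real-world feasibility: intraoperative events,
duties outside the rooms, and walking time between non-adjacent rooms are
out of scope, as are departments where the supervisor need not be present at
induction and emergence, or where long scheduled gaps make in-case breaks
unnecessary. Percentages computed on synthetic archetypes illustrate the
method; any department applying it should feed its own case tables through
`cmd_analyze()`.
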