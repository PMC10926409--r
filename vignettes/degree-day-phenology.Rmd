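---
title: "Degree-day phenology and climate-suitability methods"
author: "phenoforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degree-day phenology and climate-suitability methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoforge)
```

## The problem

Ectotherm development is driven by heat: above a lower developmental
threshold temperature, physiological time accumulates roughly in
proportion to the excess temperature, and many insects need a fixed
amount of this physiological time — degree-days (°C·day) — to move from
one life stage to the next. Survey planners and pest managers use this
to ask three kinds of question: *where* could a pest persist (does the
climate ever get cold enough to kill it, does the season supply enough
heat for a full generation), *when* will a given stage appear at a given
place this year, and *how does this year compare* with recent years.
`phenoforge` implements the computational core for all three on daily
Tmin/Tmax(/precipitation) series — single stations or lat/lon grids —
with a seeded synthetic weather generator so every analytic can be
exercised end-to-end without external data.

## Daily degree-days

Daily weather gives only the day's minimum and maximum temperature, so
the within-day temperature curve $T(t)$, $t \in [0,1]$, must be
modelled. Three standard choices are provided:

* **simple average** — constant at $m = (T_{\min}+T_{\max})/2$;
* **single sine** — $T(t) = m + \alpha \sin 2\pi t$ with
  $\alpha = (T_{\max}-T_{\min})/2$;
* **single triangle** — a symmetric rise $T_{\min} \to T_{\max}$ and
  fall back to $T_{\min}$.

With lower threshold $L$ and optional upper threshold $U$, the daily
degree-days are $\int_0^1 g(T(t))\,dt$ where $g(T) = 0$ below $L$,
$g(T) = T - L$ between the thresholds, and above $U$ either $g(T) = U-L$
(**horizontal cutoff**: development saturates) or $g(T) = 0$
(**vertical cutoff**: development halts). All six method × cutoff
combinations are evaluated in closed form, assembled from two
primitives per curve — the area above a threshold and the fraction of
the day above it (the sine case is the classical Baskerville–Emin
geometry). The tests verify the closed forms against direct numerical
quadrature of the clipped curves; the vertical-cutoff integrand has a
jump discontinuity, so the quadrature oracle locally refines the
subintervals containing the crossing to keep its own error far below
the 10⁻⁶ comparison tolerance.

Numerical notes: `simple_average` with an upper threshold clamps the
mean into $[L, U]$ before subtracting (the degenerate horizontal rule),
and returns 0 above $U$ under a vertical cutoff, mirroring the sine
conventions. A day with $T_{\min} = T_{\max}$ is handled as a constant
curve in every method. `tmax < tmin` is an error; missing temperatures
yield missing degree-days, and a cumulative series stays missing from
the first missing day onward rather than silently imputing.

```{r}
th <- thermalThresholds(10, 30, "single_sine", "horizontal")
ddDay(c(12, 5), c(20, 25), th)
```

## Staged phenology

A `PestProfile` lists ordered life stages, each with its own thresholds
and a degree-day requirement, plus named cumulative-degree-day event
markers. From the profile's start date (default January 1) the model
accrues degree-days under the *active* stage's thresholds. Transitions
use a no-carry rule: when the within-stage total reaches the
requirement at the end of a day, that day's full degree-days credit the
completing stage and the next stage starts the next day. Daily inputs
make sub-day apportioning spurious, and the rule makes the model
reproducible by a plain scalar day-loop, which is exactly how the test
oracle re-implements it.

Event markers are evaluated on the cumulative track, which keeps
accruing after the final stage completes (under the final stage's
thresholds) so that markers beyond the stage-requirement sum remain
reachable. The shipped spongy moth profile is the worked example: egg
3/38 °C and 282 DD, larvae 7.2/41 °C and 583 DD, pupae 6.6/41 °C and
277 DD, with adult emergence marked at a cumulative 1,143 DD and the
end of the flight period at 1,528 DD. The stage requirements sum to
1,142 while the emergence marker is 1,143; both values are kept as
published rather than reconciled, and both are plain text in the
profile file for recalibration. At a constant 20 °C the stages complete
on days 17, 63 and 84, and the cumulative track reaches 1,143 on day
83:

```{r}
d <- seq(as.Date("2021-01-01"), as.Date("2021-12-31"), by = "day")
cube <- DailyWeatherCube(d, rep(20, 365), rep(20, 365))
tl <- runStaged(cube, spongyMothProfile())
tl@transitions
tl@eventDates
```

## Voltinism and climate suitability

**Generations per year** accumulates degree-days across each full
calendar year under one generation-level threshold pair and divides by
the degree-days one generation requires. Completed generations use
`floor()` — a partial generation is not a generation — and the
fractional value is reported alongside, since annual totals near a
multiple of the requirement are sensitive to small forcing changes.
The shipped oak ambrosia beetle profile uses 11.1/38 °C and 1,486 DD
per generation: a constant 25 °C year yields
$365 \times 13.9 = 5073.5$ DD and three completed generations.

**Lethal-cold suitability** asks whether a cell's daily minimum ever
*reached* the lethal threshold during a year; equality counts as
lethal, the conservative reading for a survey-planning product whose
role is to rule areas out only when they are certainly unsuitable. The
oak ambrosia beetle threshold of −21.5 °C is itself derived data: a
−20.3 °C laboratory supercooling point minus a 1.2 °C insulation
constant for the tree interior where the beetle overwinters, and the
profile format stores the two source numbers rather than the result.
Daily minimum temperature (not the daily mean) is tested, again the
conservative choice, and the threshold is a plain argument for
sensitivity analyses.

**Condition day-counts** count days satisfying a comparator on a daily
variable, with a consecutive-day rule: a day counts only if it sits in
a run of at least `minConsecutive` qualifying days, and all days of
qualifying runs count. This keeps the count at most the number of
satisfying days and makes the statistic checkable by a flat run-length
scan. **Hardiness zones** band the mean annual extreme minimum
temperature into the USDA-style 10 °F zones (anchored at −60 °F, 5 °F
half-zones, right-open intervals, clamped to 1a/13b at the ends).
Binary masks from any analytics combine elementwise with AND/OR,
missing values propagating.

**Missing data** follow one rule everywhere: a cell-year with more than
5% of days missing is excluded from that cell's multi-year denominator
and the per-cell usable-year count is reported, rather than imputing.

## Forecast assembly (30-day outlooks)

A stage outlook for "today" ($t_0$) stitches three sources into one
gap-free daily series from January 1 to $t_0 + 30$: observed weather
through $t_0$, a short-term forecast for the next 7 days, and a daily
climatology — the pointwise per-day-of-year mean of Tmin and Tmax over
the most recent 20 years — for the remaining 23 days. The stitch is a
pure concatenation: substituting climatology values into the forecast
slots leaves every downstream degree-day total unchanged, which the
tests assert. The staged model is re-run from the start date over the
assembled series each time (idempotent, and immune to re-anchoring
drift), and the outlook reports the stage at $t_0$, $t_0+7$ and
$t_0+30$ plus any event markers falling inside the window. Year
comparison aligns cumulative degree-day curves by day of year, averages
the 10 most recent prior years pointwise, and flags the current year
"earlier" or "later" than that mean at the anchor day; an exact tie is
reported as "on_pace" rather than forced into either side.

Leap days: climatologies always have 365 rows, with Feb 29
observations pooled into day 59 (Feb 28), and a Feb 29 inside a
forecast horizon draws the day-59 values. The pooled convention (every
observation counts once) was chosen over per-year averaging because it
is what an independent flat re-average produces.

## Synthetic weather

The generator emulates the drivers the real analytics consume: daily
mean temperature is an annual-mean level plus a seasonal cosine
(coldest on day 15, mid-January, a fixed northern-hemisphere phase),
an optional linear latitude gradient, and stationary AR(1) noise
(lag-1 coefficient $\phi$, stationary SD as configured); Tmin and Tmax
sit half the diurnal range below and above the mean, sharing the noise
so their ordering can never invert; scheduled cold snaps override Tmin
on chosen (year, day) pairs; precipitation is i.i.d. exponential. The
generator is seeded and restores the caller's RNG state.

What it deliberately does not reproduce: spatially correlated weather
fields, realistic wet/dry spell structure, heat waves, or
observation-like missingness. Tests built on it therefore demonstrate
the *correctness of the computations* under known ground truth — a
scheduled −25 °C snap must flip exactly its year to unsuitable — not
the field accuracy of any pest forecast, which in production depends on
observed gridded weather and per-pest validation data.

Default test conditions use temperate mid-latitude values (annual mean
12–14 °C, seasonal amplitude 9–11 °C, diurnal range 8–9 °C, noise SD
1.5–3 °C with $\phi$ 0.4–0.6, 2–2.5 mm/day precipitation), 20-year
histories for climatologies and suitability counts, and small grids
(≤ 2×3 cells) — sizes at which every suite, including the 1,000-case
quadrature cross-check at 10⁶ subintervals, completes in a few minutes
on one core.

## Design choices and limitations

* **File formats.** Weather, rasters and timelines read and write
  plain CSV (station series `date,tmin,tmax[,precip]`; grids in long
  format with `lat,lon` columns; rasters with `#` metadata headers).
  Internal units are °C and mm; Fahrenheit input is converted exactly
  at read time. Profiles and scenarios are hand-editable text.
* **Single-day methods only**: no double-sine/triangle variants using
  the next day's Tmin, no hourly data, and no intermediate cutoff.
* **No biology beyond heat**: no diapause, chill requirements,
  photoperiod cues, or multi-year life cycles; voltinism is a thermal
  potential, not a survival prediction.
* **No spatial modelling**: cells are independent; no interpolation,
  reprojection, host-distribution or land-cover overlays.
* The default method is single sine with horizontal cutoff — the
  common operational choice — and is configurable per stage in every
  profile stanza.
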