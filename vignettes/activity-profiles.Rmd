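---
title: "Methods: 24-h activity profiles from epoch-level acceleration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 24-h activity profiles from epoch-level acceleration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actiprofile)
```

This vignette documents the statistical procedure the package
implements, the choices that were genuinely open and how they were
resolved, and what the synthetic test bed does and does not establish
about real data.

## From raw signal to epoch series

The unit of analysis is the epoch-level ENMO series. Per sample,

ENMO = max(0, sqrt(x² + y² + z²) − 1 g) × 1000 (mg),

assuming an autocalibrated tri-axial signal in g. Truncation of the
(calibration-error-driven) negative magnitudes is applied **per
sample**, before epoch averaging: this matches the convention of the
widely used processing pipelines, and the alternative (truncating the
epoch mean) differs only through calibration error, which is out of
scope here. Samples are averaged over fixed epochs (default 5 s)
aligned to clock boundaries — the first epoch starts at a multiple of
the epoch length from midnight and partial leading/trailing epochs are
dropped — so that every processed dataset slices into identical
midnight-to-midnight days. Epoch length must divide 86 400 s; a full
day has 86 400/epoch-length epochs (17 280 at 5 s).

Timestamps are handled as timezone-naive local clock time.
Daylight-saving transitions are a documented limitation: a 23- or 25-h
civil day is not modelled, and recordings spanning a transition should
be split at it.

## Wear screening and imputation

The validity rules are: a day is **valid** when *strictly more* than
16 h of its epochs are worn; a participant is **included** with at
least 3 valid days *and* worn data present, pooled over all days, in
every 15-min period of the 24-h cycle. The pooled reading of the
15-min-coverage rule was an open choice (the alternative requires
coverage within every single day); pooling is the weaker and, in our
judgement, intended requirement, since its purpose is to make the
time-of-day imputation well defined — which only needs one worn donor
per clock slot somewhere in the recording.

Non-wear detection is delegated by most studies to their processing
tool's default. Here it is explicit and parameterised: 60-min windows
evaluated on a 15-min grid, where each 15-min clock block is tested
against the window centred on it (truncated at the recording's ends)
and flagged alone. With raw-signal summaries (per-epoch, per-axis mean
and SD in mg) a window is non-wear when at least two of three axes have
windowed SD < 13 mg and windowed range < 50 mg; the windowed SD is
pooled exactly from the per-epoch moments (law of total variance,
equal-sized epochs), while the range is necessarily approximated by the
range of per-epoch means. Without raw summaries an
epoch-only fallback flags windows in which every epoch ENMO is below
13 mg with range below 50 mg. On the epoch scale a motionless monitor
and very quiet sleep can be indistinguishable, so wear flags supplied
by an upstream device pipeline are preferred when present — the
command-line `metrics` step trusts file flags and makes re-detection
opt-in. Centre-block flagging trims genuinely
non-worn spans by up to half a window at each boundary; we prefer that
conservatism (under-flagging costs a slightly inflated wear time,
over-flagging destroys data) and it is why the span-recovery test
asserts containment rather than equality.

Imputation replaces each non-wear epoch by the mean of the **worn**
values at the same clock position on the participant's other days, and
re-flags it imputed. "Similar time-points" is resolved to the exact
epoch clock position — the simplest faithful reading — and the donor
set spans all other days regardless of day type by default, switchable
to weekday/weekend-matched donors (`donor = "weekday_matched"`). The
operation never alters worn epochs and is idempotent; a clock position
worn on no day raises an error naming the position (such a participant
is already excluded by the coverage rule).

## The metrics

All metrics are computed on the complete imputed 24-h series, per day,
then averaged (unweighted) over the qualifying days — never on a pooled
multi-day histogram. Weekday (Mon–Fri) and weekend (Sat–Sun) strata are
averaged within stratum, so the two stratum means recombine to the
all-day mean only under explicit 5:2 weighting.

**Average acceleration** is the arithmetic mean epoch ENMO (mg).

**Intensity gradient**: epochs are assigned to half-open 25-mg bins
[edge, edge + 25) up to a 4 000-mg ceiling, with a final open-ended bin
[4 000, ∞) carrying nominal midpoint 4 012.5 mg; the gradient is the
OLS slope of ln(minutes in bin) on ln(midpoint). Empty bins are
excluded (ln 0 is undefined and an empty bin carries no time
information); at least three non-empty bins are required, otherwise the
gradient is an error rather than a number. The open-ended bin is
included in the fit when non-empty: excluding observed high-intensity
time would bias the slope upward, and its midpoint misspecification is
bounded by the bin width for all plausible data. Natural logarithms
throughout. The 25-mg width and 4 000-mg ceiling are the published
conventions of the metric and are exposed as arguments.

**MX** is the nearest-rank order statistic: with
k = X·60/epoch-length, the k-th largest epoch value of the day.
Nearest rank (no interpolation) guarantees the verbal definition — at
least X minutes of the day lie at or above the reported acceleration —
holds exactly on the discrete epoch multiset, and makes MX commute with
positive affine rescaling, which the harmonisation tests exploit. X
must convert to a whole number of epochs. Imputed epochs count like
worn ones in every metric.

Epoch length is a comparability boundary: coarser epochs smooth out
high-intensity activity, so `cohort_metrics()` refuses to mix profiles
computed at different epoch lengths unless explicitly overridden.

## Translation

Cut-points live in a YAML registry and are applied only after metric
computation. A value exactly on a threshold **meets** it (≥): the
definitional quote covers only the strictly-greater case, and we chose
the convention under which a profile engineered to sit exactly on a
guideline passes it. Percentile curves use the standard
linear-interpolation empirical quantile (type 7); an individual's
percentile rank uses the mid-rank definition
100·(#below + ½·#equal)/n, which is symmetric under ties. Within-metric
standardisation uses the sample SD (n − 1). Tertiles cut at ranks
⌈n/3⌉ and ⌈2n/3⌉ with ties broken by stable row order — an arbitrary
but deterministic rule, documented because no convention is standard.
The ActiGraph preset (scale 1/0.9) is a ballpark affine lift onto the
GENEActiv/Axivity scale, not a calibration.

## Radar geometry

Axis k (0-based, K axes) sits at angle π/2 − 2πk/K: the first axis at
the top, subsequent axes clockwise, default order M1/3DAY, M120, M60,
M30, M15, M5. The radial scale is linear and starts at 0 mg (the
published figures do not state their origin; starting at zero keeps
polygon areas monotone in the values). In raw mode the outer radius
defaults to the maximum plotted value rounded up to a clean step; in
standardised mode the radial range is a symmetric z interval (default
±2.5 SD) and a dashed black circle marks z = 0, which is exactly the
cohort mean of every metric. Values outside the radial range are
clipped, never dropped. Rendering is deterministic, and every figure is
accompanied by a CSV of the exact plotted values.

## The synthetic test bed

`generate_day()` builds a day whose intensity distribution is a
discretised power law: time per 25-mg bin proportional to
midpoint^(−g), converted to whole epoch counts by largest-remainder
rounding (exactly 1 440 min per day), with epoch values drawn uniformly
within their bin. The fitted intensity gradient is therefore −g by
construction, the truth the recovery tests check. Two generator-side
choices matter:

- Allocation runs over bins up to 1 000 mg: 5-s epoch means above
  ~1 g are rare in free-living wrist data, and the ceiling bounds the
  sparse-tail discreteness of a single day.
- Bins whose expected time falls below one epoch are dropped before
  rounding — a single day cannot represent them, and forcing 0/1 counts
  into the far tail flattens the realised log-log slope. With this rule
  the recovery error is below 0.04 in slope units for g ≤ 3.

The lowest-valued epochs form a contiguous 8-h sleep block at the start
of the day and the rest are shuffled across waking hours, so
arrangement-invariant metrics are unaffected while M480 behaves
realistically; optional non-wear is inserted as contiguous 1-h gaps.
An optional volume target rescales the day multiplicatively, which
leaves the log-log slope unchanged. A fixed seed reproduces a cohort
bit for bit. `fixture_with_mx()` inverts the MX definition exactly:
epochs ranked (k_{i−1}, k_i] take the i-th target value, so the
requested MX values are recovered bit for bit.

What the generator does **not** emulate: autocorrelated bouts and
diurnal timing of activity, device noise and calibration error,
between-day behavioural variation, or any temporal pattern of
accumulation. Tests passing on this test bed therefore establish the
correctness of the estimators on their own definitions — order
statistics, histogram fits, screening rules — not the field validity of
the metrics, which rests on the cited calibration and cohort
literature.

## Problem sizes and numerical tolerances

The test suite exercises 200 full days for MX-oracle equivalence,
1 000 days for monotonicity, 3 days per exponent for slope recovery, a
30-participant cohort for truth-recovery rank correlation and a
50 × 7-day cohort for the end-to-end pipeline — sizes chosen to give
stable stochastic checks on one CPU in a few minutes. Exact identities
(MX, imputation means, standardisation moments) are asserted to 1e-12
or bit-for-bit; regression equalities against independent oracles to
1e-9; stochastic recoveries at the ±0.1 slope and 0.9 rank-correlation
levels implied by the generator's construction.

## Known limitations

Daylight-saving and timezone changes; device binary formats (CSV only);
gravity autocalibration is assumed done upstream; non-wear detection is
a published heuristic, not a re-implementation of any specific device
toolchain default; bout-based metrics, the most-active *continuous* X
minutes, and temporal-accumulation summaries are out of scope; metric
values are wear-site and (approximately) brand specific, so profiles
should only be compared within wear site, same epoch length, and after
affine harmonisation where brands differ.
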