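---
title: "Methods: diurnal phase of relative search volume across DST transitions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diurnal phase of relative search volume across DST transitions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsvphase)
```

## The scientific question

Daylight Saving Time moves the civil clock by 60 minutes while solar time
stays put. If the timing of a behaviour — here, issuing a particular Google
search — is driven purely by the social clock, its diurnal peak expressed
in UTC should move by the full hour at the transition; if it is driven
purely by the endogenous circadian clock entrained to solar time, the UTC
peak should not move at all. Partial shifts between 0 and 60 minutes
indicate mixed control. `rsvphase` estimates that shift from hourly
relative search volume (RSV), and provides a synthetic observation model
rich enough to validate every stage by parameter recovery.

## The observation model the generator emulates

Google Trends delivers hourly RSV in 7-day windows. Two properties of that
delivery shape the whole analysis:

* **Private scales.** Each window is independently drawn from a sampled
  fraction of traffic and rescaled so its maximum is 100, then rounded to
  integers. Levels are therefore not comparable across windows.
* **Two-day overlaps.** Pulling windows every 5 days leaves 48 shared
  hourly points between consecutive windows, which is the only information
  linking their scales.

`sim_config()` / `simulate_rsv()` reproduce this pipeline from a known
ground truth. The latent hourly intensity is

$$I(t) = \max\!\Big(0,\; \big[B + A\cos\tfrac{2\pi(c(t)-\varphi(t))}{24}\big]
\cdot g_w^{\,\mathbb{1}[\text{weekend}]} \cdot s(t) + \varepsilon_t\Big),$$

where \(c(t)\) is local civil time (CET = UTC+1 before / CEST = UTC+2
after a spring transition, reversed in autumn, switching at 01:00 UTC on
the last Sunday of March or October), \(\varphi(t)\) the local acrophase,
\(g_w\) a weekend level gain on local Saturdays/Sundays, \(s(t)\) optional
one-day event spikes, and \(\varepsilon_t\) i.i.d. Gaussian noise. After
the transition the local acrophase moves so that the *UTC* acrophase steps
by exactly `social_fraction` × 60 minutes — an advance in spring, a delay
in autumn. The per-day true UTC acrophase is stored with each simulation,
so recovery tests have an exact target.

### Default parameters and why

| parameter | default | rationale |
|---|---|---|
| `baseline` | 50 (arb. units) | mid-scale level; only ratios matter after max-scaling |
| `amplitude` | 20 | peak-to-trough ratio ≈ 2.3, typical of strongly rhythmic night-time queries, while keeping the nightly trough far from the 0–100 quantization floor |
| `acrophase_local` | 3 h | insomnia-like peak shortly after local midnight |
| `social_fraction` | 1 | the null expectation of a fully clock-driven behaviour |
| `weekend_gain` | 1.2 | visible weekend modulation without dominating the rhythm |
| `noise_sd` | 2 | 10 % of amplitude, giving per-day acrophase errors of ~0.1 h |
| `segment_scale_jitter` | 0.2 (log-SD) | run-to-run rescaling of the magnitude observed when re-downloading windows; no published value exists, chosen for plausibility |
| `days_before`, `days_after` | 15, 15 | the comparison windows used throughout |

Noise is additive Gaussian on intensity rather than Poisson on counts: RSV
is already a ratio of an undisclosed sample, so no count scale exists, and
Gaussian noise keeps variance configurable independently of level.
Negative intensities are clamped at 0 (RSV is non-negative); with the
default parameters the clamp is never active. The simulated span is
extended past `days_after` to the next length of the form 7 + 5k days so
the series tiles exactly into weekly segments; the extra tail days are
outside both analysis windows.

What the generator does *not* emulate: individual users with chronotype
distributions, multi-region aggregation, slow seasonal trends in search
interest, daily-resolution exports, and the heavy-tailed burstiness of
real query streams. Passing recovery tests therefore demonstrate the
*pipeline's* correctness under a plausible observation model, not that
real RSV satisfies the model.

## Stitching

For consecutive segments the normalization coefficient is the ratio of the
48-h *sums* over the shared days,
\(c_k = \sum \text{ref} / \sum \text{inc}\), estimated against the
already-normalized predecessor so coefficients chain multiplicatively back
to the first week (coefficient 1). The sum ratio was chosen over a mean of
pointwise ratios because night-time hours of low-volume terms sit near
zero and make pointwise ratios explode; a least-squares ratio
\(\sum \text{ref}\cdot\text{inc} / \sum \text{inc}^2\) is kept in the test
suite as an independent oracle and agrees within 2 % on jittered noiseless
overlaps. On shared days the earlier segment's values are retained — the
incoming overlap is used only for coefficient estimation — keeping the
stitched series single-valued. An all-zero incoming overlap is an error,
not a silent coefficient of 1: it means the data are too sparse to stitch.

Without rounding, stitching inverts arbitrary per-segment rescaling to
machine precision. With integer quantization the dominant error is the
±0.5 rounding step at the nightly trough of the 0–100 scale; at the
default peak-to-trough ratio the stitched series stays within 2 % of the
latent intensity (after one global rescaling), which the acceptance tests
enforce over multiple seeds.

## Daily rhythm fits

Each complete calendar UTC day (24 points) gets a three-parameter cosinor
fit via the linear parameterization above; the normal equations are solved
exactly. Choices worth recording:

* **Period fixed at 24 h.** Phase, not period, is the scientific target;
  24 points cannot support period estimation anyway.
* **Significance.** Overall regression F on (2, 21) df. Calibration is
  verified: on flat noise-only days the 5 % nominal level is hit within
  binomial error over 1,000 simulated days.
* **Rhythmicity Index.** `RI = r × 2A`, the correlation between fit and
  data times the fitted peak-to-trough range. The fitted range `2A` is
  used rather than the raw `max − min` because the latter grows with noise
  even for arrhythmic days.
* **Degenerate days.** A constant day returns amplitude 0, `p = 1` and an
  undefined (`NA`) acrophase, so the significance filter removes it; this
  mirrors treating unfittable days as missing rather than erroring the
  whole run.
* **Day boundary.** Calendar UTC days. The cosinor acrophase is circular
  within the day, so peaks near midnight are estimated without bias at the
  day edge; no sliding window is needed. The transition day itself (clock
  change at 01:00 UTC) belongs to neither comparison window.
* **Filter boundary.** Days with `p` exactly equal to `alpha` are kept;
  the removal rule is strictly `p > alpha`.

The acrophase estimator is validated against a brute-force grid search
(mesor and non-negative amplitude profiled at each candidate phase on a
0.01 h grid) and against the generator's ground truth (±0.05 h on
noiseless days).

## Circular phase statistics

Daily acrophases are clock times: windows straddling midnight are common
(several reference words peak within ±30 min of 00:00). All averaging is
therefore circular — the direction of the mean unit vector — and all
interval statistics (quartiles, IQR fences, t-tests, ANOVA, slopes) are
computed after unwrapping phases to the representative in
(reference − 12 h, reference + 12 h], with the circular mean of the sample
as reference. A linear mean would mis-handle exactly the near-midnight
cases. A perfectly dispersed sample (resultant length < 1e-9) has no
defined mean and errors.

Outlier removal is the Tukey boxplot rule on the unwrapped phases:
quartiles by linear interpolation of order statistics (the default
convention; recorded because fence membership at the boundary depends on
it), fences at 1.5 × IQR, points exactly on a fence kept. With fewer than
4 phases the filter is skipped with a notice. Note a small-sample property
of the rule: when the central half of a window is very tight (low noise)
and a systematic effect such as weekend modulation pushes a few days into
the tails, more than a quarter of a window can be legitimately fenced off
— this is the rule working as defined, not a circular artifact, and the
tests distinguish the two.

The signed phase difference maps (post − pre) × 60 to (−720, 720]
minutes: negative = advance, positive = delay. This reproduces all 22
printed differences of the bundled reference table exactly, including
both midnight-wrapping rows.

## Pre/post comparison and year trends

`compare_windows()` uses the classic equal-variance two-sample Student
t-test on the unwrapped daily phases (the equal-variance form, not Welch,
matching standard usage for balanced 15-day windows); zero within-group
variance is handled explicitly (p = 1 for identical means, 0 otherwise)
rather than erroring. Sides with fewer than 2 retained days flag the
t-test as undefined while still reporting the delta.

For trends across study years the package reports two complementary
summaries rather than a repeated-measures ANOVA: a one-way ANOVA of daily
phases across years, and an OLS slope of phase on year in minutes/year
with its t-test. Daily phases within a year are not repeated measures of
one subject in any useful sense here, and the two summaries answer the two
actual questions — "does phase differ by year?" and "how fast does it
drift?" — directly. Both are calibrated and validated by simulation
(null rejection rate within binomial error of 5 % over 500 replicates;
a built-in −6 min/year drift recovered within ±2 min/year).

`run_pipeline()` pools the retained daily phases across years for its
"combined" rows (rather than averaging yearly means): a single pre/post
phase per word and season is the natural summary of the pooled days, and
with balanced windows the two choices nearly coincide.

## Problem sizes used in validation

The test suite runs entirely on synthetic data: 31–32-day simulations
(744–768 hourly points, 6 segments) per pipeline run; 20 replicate seeds
per social-fraction level for the recovery curve (0, 0.25, 0.5, 0.75, 1);
1,000 flat days for F-test calibration; 500 replicates of 6 × 15 phases
for ANOVA calibration; 200 noisy days for acrophase-recovery statistics.
These sizes give binomial confidence intervals tight enough to detect
mis-calibration while keeping the full suite around ten seconds.

## Known limitations

* The cosinor is a single harmonic; markedly non-sinusoidal waveforms
  (sharp evening spikes) will fit with reduced amplitude and a phase
  pulled toward the waveform's centre of mass. The significance filter
  removes days where this fails badly, but a multi-harmonic extension is
  out of scope.
* The stitching coefficient assumes overlap days are representative; a
  one-day event spike inside an overlap biases the coefficient for the
  whole chain downstream of it.
* The civil-time rule is hard-coded to CET/CEST; other zones and the
  (rare) years with different transition rules are out of scope.
* The generator's jitter magnitude has no published reference value; all
  quantitative recovery claims are conditional on the stated defaults.
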