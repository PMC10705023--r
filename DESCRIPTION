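Package: rsvphase
Title: Diurnal Phase Analysis of Relative Search Volume Around Daylight
    Saving Time Transitions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to estimate the diurnal peak phase of hourly relative
    search volume (RSV) time series and to quantify how that phase shifts
    across the transitions to and from Daylight Saving Time. Provides a
    synthetic RSV generator that emulates the Google Trends observation
    model (per-window 0-100 rescaling, weekly segments with two-day
    overlaps, weekend modulation, a configurable social-coupling fraction
    of the 60-minute civil-clock shift), chain normalization of
    overlapping segments onto a common scale, single-harmonic cosinor
    fitting of each calendar day with an F-test of rhythmicity and a
    Rhythmicity Index, circular phase averaging with Tukey boxplot
    outlier removal, signed circular phase differences in minutes,
    pre/post-transition comparison by Student t-test, and across-year
    phase-trend tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
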