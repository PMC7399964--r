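---
title: "Methods: from call audio to a longitudinal mental-health index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from call audio to a longitudinal mental-health index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(voicevitals)
```

## Overview

`voicevitals` implements a voice-based monitoring pipeline in four layers:

1. **speech signal** — utterance segmentation, pitch tracking, intensity;
2. **affect scoring** — prosodic features → five emotion intensities → a
   per-utterance vitality score in [0, 1];
3. **monitoring** — per-call vitality with validity rules, the 14-day
   mental-activity index, analysis-dataset construction, retention;
4. **cohort statistics** — normality goodness of fit with effect size w,
   two-group contrasts with Cohen's d, correlations, and regional pre/post
   event windows.

A fifth layer, the seeded simulator, generates both speech-like audio and
whole longitudinal cohorts so that every other layer can be exercised —
and its estimators validated by parameter recovery — without any real
recordings. This vignette documents the model choices, the parameters that
matter, and what the simulations do and do not establish.

## Utterance segmentation

An utterance is a continuous stretch of speech bounded by breath pauses. We
detect utterances with a two-threshold hold-time state machine on per-frame
peak absolute amplitude (frames of `frame_s = 0.01` s):

* a frame is *speech* if its peak amplitude ≥ `amplitude_threshold`
  (default 0.02 of full scale);
* an utterance *opens* when speech persists for `onset_hold_s`
  (default 0.1 s) and starts at the beginning of that speech run;
* silences shorter than `offset_hold_s` (default 0.35 s) are bridged —
  plosive closures and short breaths do not split an utterance;
* a silence run of at least `offset_hold_s` *closes* the utterance at its
  last speech frame; a trailing open utterance closes at signal end.

Utterance intervals are half-open `[start_s, end_s)` and frame-quantized.
The hold times and threshold are conventional voice-activity-detection
magnitudes rather than estimates of any particular deployed system, which is
why all four are configurable and recorded with the results. Peak amplitude
(not RMS) is used for the speech/silence decision as the most literal
reading of amplitude thresholding; the RMS envelope exists separately as an
affect feature.

Two properties pin the implementation down and are enforced by tests against
an independently written per-frame scan: raising the threshold can never
increase total segmented speech, and prepending silence translates all
boundaries exactly.

## Pitch tracking

Per 10 ms hop, F0 is the inverse of the best lag of the short-time
normalized cross-correlation within `[f0_min, f0_max]` (defaults 60–400 Hz,
adult conversational speech), computed over a window of about 2.5 periods of
`f0_min` centred on the frame. Numerical details that matter:

* **Subharmonic suppression.** Any integer multiple of the true period
  correlates as well as the period itself, so the tracker takes the
  *shortest local maximum* whose correlation reaches 95% of the global
  peak — not the global argmax, and not a band-edge lag that merely clears
  the bar. Without this rule a pure 200 Hz tone intermittently reads as
  66.7 Hz.
* **Parabolic interpolation** of the correlation peak gives sub-sample lag
  resolution; on pure tones the error is well under 1 Hz, and the test
  suite requires ± 2 Hz.
* **Voicing.** A frame is unvoiced (F0 = 0) when the correlation peak is
  below `voicing_threshold = 0.3` or the frame is essentially silent
  (RMS < 1e-5). Voiced F0 values are clamped to the search band, so the
  band-containment invariant `f0 ∈ [f0_min, f0_max]` holds by construction.

## The affect layer is a stand-in

Commercial emotion-from-voice engines do not publish their models. The
affect layer here is therefore an explicitly documented surrogate with the
same *shape*: deterministic, per-utterance, five named emotion intensities
(calmness, anger, joy, sorrow, excitement) in [0, 1], combined into one
vitality score. Each emotion is a logistic function of the eight prosodic
features divided by fixed reference scales (200 Hz, 25 Hz, 100 Hz/s, 80 Hz,
1, 0.15, 0.5, 3 s), so zeroed features yield exactly `plogis(bias)` and the
weights are comparable across features. The default weights were chosen once
so that flat, steady, moderate-energy speech reads calm; low-energy
low-variability monotone reads sorrowful; and energetic, variable speech
reads joyful/excited — with the vitality combination

\[ v = \mathrm{clip}\big(0.5 + w_{pos}\tfrac{joy + calm - 1}{2}
        - w_{neg}\tfrac{sorrow + anger - 1}{2}
        + w_{exc}(excite - 0.5),\ 0,\ 1\big) \]

(defaults \(w_{pos} = w_{neg} = 0.4\), \(w_{exc} = 0.1\)) centring neutral
lively speech near 0.55, the region observed for healthy speakers in
published deployments of such systems. Tests assert orderings (calm >
excited for a flat tone; depressed prosody scores below lively prosody) and
the exact closed form of the combination, never absolute emotion magnitudes,
which would be meaningless for a surrogate. The whole parameterization
round-trips through YAML so alternative calibrations are configuration, not
code.

## Monitoring rules

* **Call vitality** is the arithmetic mean of per-utterance vitality, valid
  only for calls ≥ 10 s with ≥ 6 scored utterances; invalid calls carry no
  score at all. Both minima are arguments, and dataset sizes are tested to
  be monotone under stricter minima.
* **Mental activity** at time *t* uses the half-open window
  \((t - 14\,\mathrm{d},\ t]\): the anchoring call itself counts, calls
  exactly 14 days old do not. With fewer than 5 vitality points the index
  is absent. The published description of such indices names a moving
  average *and variation* without a formula; we take
  `clip(mean − k·sd, 0, 1)` with sample SD and `k = 1`, a documented
  surrogate consistent with the observed ordering (mental-activity means
  sit below vitality means by roughly one within-user SD). `k` is an
  argument everywhere it appears.
* **Days used** is the floor of elapsed time from consent to the last
  analyzed call, 0 with no analyzed call — so a user who stops the same day
  counts 0. The retention curve is the fraction of users with
  `days_used ≥ d`; it is 1 at `d = 0` by construction.
* **User-dataset anchoring.** Per user: the first valid vitality strictly
  after the initial (earliest) BDI record, and the latest mental-activity
  point within ± 14 days of the BDI time. "Within 2 weeks" is directionally
  ambiguous in prose, so both directions are accepted by default, a
  pre-BDI point wins ties, and `ma_direction = "before"`/`"after"` narrows
  the window. Users missing either anchor are excluded.
* **Completion-time trimming** keeps BDI records with completion time in
  [80, 300] s, endpoints inclusive; a percentile mode (drop bottom/top 10%)
  is available when the band should adapt to the data.

## Cohort statistics

* **Normality.** χ² goodness of fit with *equal-probability* bins under the
  normal fitted by sample mean/SD; `n_bins = max(5, min(20, n/50))`,
  df = bins − 3 (two fitted parameters), precondition n ≥ 5·bins. The
  effect size is \(w = \sqrt{\chi^2/n}\), with w < 0.1 conventionally a
  negligible departure — the relevant criterion when n is large enough to
  reject any point null. Because the bins follow the fitted normal, w is
  exactly invariant under affine transformation of the sample (tested).
* **Two-group contrasts.** Welch's t by default (robust to the unequal SDs
  typical of sex-stratified vitality), Student optional; Cohen's d always
  uses the pooled SD. A summary-statistic mode reproduces the raw-data
  result exactly from exact summaries, and lets printed tables (counts,
  means, SDs) be re-analyzed; from such printed, *rounded* summaries d is
  reproducible only to ~±0.01–0.02, which is why printed effect sizes are
  treated as approximate anchors, not oracles. Zero-variance ties
  degenerate to d = 0, p = 1.
* **Percentages** display half-up to two decimals (with a 1e-9 guard
  against binary representation of decimal ties); an exhaustive category
  set sums to 100 within rounding.
* **Event windows.** Per region: mean vitality over \((event - 14d, event)\)
  vs \([event, event + 14d)\); and per user the most recent mental-activity
  value from *any* time before the event vs the most recent within the
  14-day post window, averaged per region. Empty windows yield `NA`, never
  zero. No multiple-testing correction is applied anywhere, matching common
  practice in the observational studies this tooling targets; the
  documentation says so rather than silently adjusting.

## The simulator: what it emulates, and what it does not

`generate_call_audio()` renders planned utterances as harmonic stacks
(fundamental + 2 harmonics, linear F0 glides, 4 Hz amplitude modulation,
5 ms edge ramps) over a Gaussian noise floor. This gives full knowledge of
ground truth — boundaries and F0 trajectories — for round-trip tests, but it
is *not* speech: no formants, no consonants, no channel effects. Passing
round-trip tests shows the segmentation/pitch chain is correct on its own
terms, not that it is robust to real telephony audio.

`generate_cohort()` draws, per user: sex (P(man) = 0.6257), age
(N(39.97, 12.14²) truncated at 18), region from a national mix with one
exposed region, a latent vitality trait, consent uniform over the study
window, exponential dropout (hazard 0.01/day), Poisson call arrivals (mean
gap 6.37 h), per-call validity failures (5% short calls, 10% under 6
utterances), and BDI records every ~90 days with
`score = round(clip(29 − 30·latent + N(0, 10), 0, 63))` and lognormal
completion times placing ~10% below 80 s and ~10% above 300 s. The per-sex
trait parameters are chosen so the *marginal* valid-call vitality matches
the calibration anchors 0.57 (SD 0.095, men) and 0.53 (SD 0.085, women):
the between-user trait SD is \(\sqrt{sd_{sex}^2 - sd_{noise}^2}\) with
per-call noise SD 0.08. These anchors, and the call-gap and demographic
constants, are published summary statistics of a real deployment used as
generator defaults — they calibrate the simulation, they are not quantities
the package claims to estimate from data.

The event model steps exposed users' traits down by δ at the event date,
recovering exponentially with a 180-day default half-life (long, because
observed post-disaster trajectories show no recovery within months). The
simulator does not model: recall effects, seasonal or diurnal structure,
device heterogeneity, informative dropout (dropout is independent of the
trait), or any dependence of call *timing* on mental state. Analyses that
would be sensitive to those mechanisms are therefore only validated against
the mechanisms the generator contains.

## Parameter recovery and problem sizes

The test suite validates the event estimator by parameter recovery: inject
δ ∈ {0.02, 0.05, 0.10} with 2 regions × ~50 users, a 42-day study with the
event at day 21, recovery half-life ∞ (so the injected step equals the
windowed effect exactly), 200 seeded replicates per δ, and require the mean
recovered post-minus-pre difference to sit within 2 standard errors of −δ.
With the default 180-day half-life the shock decays by a factor ≈ 0.974
averaged over the 14-day post window; the ∞ half-life isolates estimator
bias from that known attenuation. Null calibration (δ = 0) is checked
separately as a difference-in-differences against the control region.

Other suite scales, chosen to make the oracle comparisons exhaustive while
keeping a full run around a minute: 500 random burst signals (≤ 8 s, 1 kHz)
against the segmentation frame-scan oracle; 1,000 random user histories
against the brute-force window oracle; 10,000-draw normal and mixture
samples for the w regimes; ~20,000 valid calls for the
law-of-large-numbers check on the generator marginals (cluster-aware
standard errors, since calls within a user share a trait).

## Known limitations

* The affect layer is a surrogate; absolute vitality values are only
  meaningful relative to its own calibration. Cross-system comparability
  would require fitting the logistic layer to labeled data.
* Segmentation is energy-based and assumes a quiet channel; it has no noise
  model and will over-segment under nonstationary background noise.
* The moving-average index weights all window points equally; recency
  weighting is plausible but unspecified in the sources this design
  follows, so it is not implemented.
* Timestamps are handled in UTC throughout; calendar-day semantics
  ("same-day stop") follow UTC days, which can differ from the user's local
  calendar.
* The chi-square normality test requires n ≥ 5·bins and is insensitive to
  departures that preserve bin counts; with very small user datasets the
  automatic bin count floors at 5 and p-values become coarse.
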