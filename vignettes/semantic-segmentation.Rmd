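---
title: "Semantic segmentation of time series with flossr: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic segmentation of time series with flossr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flossr)
```

## The model

A *regime* is a contiguous stretch of a uniformly sampled series generated by
one discrete state of the underlying system — one exercise, one posture, one
hemodynamic condition. Semantic segmentation infers the boundaries between
regimes without any model of what the regimes contain. The working assumption
is purely local self-similarity: within a regime, a subsequence's nearest
neighbor (under z-normalized Euclidean distance) lies in the *same* regime,
because that is where similarly shaped patterns live.

The machinery is the Matrix Profile: for each subsequence `T[i, i+L)` of
length `L`, find the nearest neighbor `j` elsewhere in the series, excluding
trivial matches (`|i - j| <= floor(L/2)`, where a window would otherwise match
a shifted copy of itself). Each pair `(i, j)` is an *arc*. The Arc Curve
`AC[x]` counts arcs spanning position `x` (an arc covers `min(i,j) <= x <
max(i,j)`, half-open, so the increment/decrement sweep and the literal
crossing count provably agree). If few arcs cross `x`, subsequences on the
two sides of `x` do not look like each other: `x` is a boundary candidate.

Raw counts are biased — near the edges there are few arcs that *could* cross.
The Idealized Arc Curve (IAC) is the expected count under a structureless
null in which every arc points to an effectively random location. The
Corrected Arc Curve is `CAC[x] = min(AC[x] / IAC[x], 1)`, a unit-free value
in `[0, 1]` whose deep minima are candidate boundaries and which is
commensurate across sensors, sampling rates and bit depths.

Three null models are used, matching three search geometries:

* **Bidirectional (batch)** — closed form `2 i (n-1-i)/(n-1)` (0-based `i`):
  an inverted parabola with height about `n/2`, which is exactly proportional
  to the beta(2,2) density. We use the symmetric form that is zero at *both*
  ends rather than `2 i (n-i)/n` (zero only on the left); the difference is
  at most one count and the symmetric form reflects the actual geometry: no
  arc can cross before the first or after the last position. The closed form
  is verified against a Monte-Carlo simulation in the test suite.
* **One-directional (streaming)** — arcs only point backward in time, which
  yields a lower, right-skewed expectation. Rather than committing to
  unpublished parameters of a fitted beta curve we use a seeded empirical
  Monte-Carlo mean (`simulate_null_arc_curve()`), cached per curve length;
  200 replicates put the Monte-Carlo error well under the decision scales
  involved.
* **Constrained uniform** — under a temporal constraint (below) the null
  expectation is flat away from the boundaries of the admissible band; the
  interior constant is estimated empirically and the first and last
  `tc_samples` positions are forced to CAC = 1 (uninformative).

## Parameters that matter

* `L` (samples) — the subsequence length, the method's only essential
  parameter. Set it to roughly one period of the repeated pattern; the
  score-vs-L curve is flat over a broad range, and
  `learn_subsequence_length()` estimates it from an unlabeled snippet by
  appending a copy of the snippet resampled to 95% of its length
  (`make_length_training_pair()`): a barely perceptible rate change that is
  nevertheless a true, labeled regime boundary at exactly `|snippet|`.
* `exclusion_halfwidth` (default `floor(L/2)`) — trivial-match radius.
  Raising it removes short arcs; lowering it below `L/2` lets windows match
  overlapping copies of themselves and floods the curve with meaningless
  short arcs.
* `tc_samples` — the temporal constraint, `floor(TC_seconds * rate)`. Use it
  when the *same* regime can recur after interruptions (sets of exercise
  repetitions, intermittent arrhythmia): without it, arcs between the
  disconnected instances cross the interior boundaries and erase their CAC
  valleys. Set `TC` to the approximate maximum segment duration in the
  domain (e.g. 30 s for repetition exercise at 100 Hz gives 3000 samples).
  Note the side effect: the first and last `tc_samples` positions of the
  curve become uninformative by construction, so `TC` must be smaller than
  the distance of the first/last boundary from the series ends.
* `num_boundaries` — REA extracts this many CAC minima, masking `5 L` on
  each side of each pick (the repetition assumption: two true boundaries
  cannot be closer than a few pattern lengths). `extract_regimes_k()` takes
  a regime count instead and passes `k - 1`.
* Streaming (`floss_config()`): `window_w >= 4 L` so several repetitions are
  in view; `report_every` thins event output (the per-event cumulative-sum
  recompute is cheap, so the default is 1); an optional alert `threshold`,
  with successive alerts within `5 L` merged.
* `learn_threshold()` — alert level from *negative-only* training snippets:
  population mean minus three population standard deviations of the
  per-snippet minimum CAC, clipped to `[0, 1]`. The population (divide-by-n)
  standard deviation is fixed so results are reproducible; with the
  documented worked example (mean 0.671, sd 0.194) the threshold is 0.089.

## What the synthetic generator emulates — and what it does not

`make_regime_series()` concatenates quasi-periodic regimes (sine, smoothed
square, sawtooth, pulse train, or an unstructured noise walk), each with at
least four repetitions, plus white noise at a stated SNR; default 20 dB,
a mid-range wearable/physiological noise level. `make_transition_gap()`
splices low-amplitude (5% of series sd) smoothed noise between regimes,
mimicking "transient activity" rest periods. `distort()` provides six
realistic corruptions (2x downsampling, 8-bit quantization, a ten-degree
linear trend, 20 dB additive noise, a 5-point moving average, and 3% random
deletion refilled by linear interpolation).

Interpretation choices for the distortions, fixed once:

* "ten degrees" is aspect-dependent, so the ramp spans `tan(10°) x range(x)`
  over the series length — ten visual degrees on a unit-aspect plot;
* "twenty dB of noise" is read as SNR = 20 dB (signal power / noise power =
  100), the standard convention;
* "smoothing with default settings" is a centered moving average of window
  5, the default of the originating tool; the property tested (argmin
  stability) is insensitive to the exact window.

What a green test on these fixtures does *not* establish: real physiological
or accelerometer morphology (ABP dicrotic notches, gait asymmetry),
non-stationary drift within a regime, autocorrelated noise, missing-data
bursts, or multi-channel clock skew. The generator produces the *mechanism*
the method exploits (repeated within-regime shapes, distinct across regimes)
at stated noise levels — nothing more.

## Numerical choices

* Distance profiles use the FFT cross-correlation plus rolling-moment
  recurrence for series of length >= 256 and a direct sweep below, where FFT
  round-off is proportionally largest; both paths agree with an explicit
  z-normalization oracle to 1e-8.
* Zero-variance (flat) windows have no z-normalization; their normalized
  form is defined as the all-zeros vector (distance 0 to another flat
  window, `sqrt(L)` to anything else), with a warning. Output is never NaN.
* Nearest-neighbor ties break toward the smallest admissible index;
  REA ties break toward the lowest position. Everything is deterministic
  given input, parameters and seeds.
* CAC positions where the null expects fewer than 1 crossing are set to 1
  (uninformative edges) rather than dividing by a vanishing expectation.
* Subsequences with no admissible left neighbor (early positions of a
  one-directional profile) carry the sentinel `NA_integer_` / `Inf` and are
  skipped in arc counting.
* Monte-Carlo null curves are seeded and cached per `(length, trials,
  seed)`, so batch runs and streams are reproducible end to end.

## Streaming design

Arcs point strictly backward in time, so a newly arrived subsequence needs
one distance-profile call (`O(w log w)`) and never changes an existing
entry. Eviction is the subtle direction: dropping the oldest sample removes
the oldest *entry* in O(1), but retained entries may have pointed at the
evicted subsequence. Leaving them dangling would make the stream state
drift away from the batch left-only profile of the current window — and
batch equivalence is this module's central correctness contract, tested at
every checkpoint. The resolution here: egress repairs exactly the dangling
entries, one distance-profile call each. The first entry past the exclusion
zone always points at the window head, so every egress repairs at least one
entry; empirically the count behaves like `ln m` rather than `m`, and the
test suite asserts structurally that repair work never exceeds the dangler
count (no rescans). This trades the advertised strict O(1) eviction for
exact streaming/batch equivalence with small, event-driven repair cost — a
deliberate design choice, documented here rather than hidden.

Positions are 1-based throughout the R API (the natural R convention);
files written by the CLI use 0-based indices, stated in their headers.

## Evaluation metric

`score_segmentation()` maps every predicted boundary to its nearest
ground-truth boundary (many-to-one allowed) and returns
`sum(|pred - mapped|) / (n_pred * n)`, in `[0, 1]`. Two caveats are
inherent and documented: unmatched ground-truth points are not directly
penalized (mapping runs predictions to truth), and the denominator uses the
*predicted* count — duplicating every prediction leaves the score unchanged.
`compare_scores()` implements the conservative benchmark rule that a method
only *wins* when its score is below half its rival's.

## Known limitations

* Regimes must contain several repetitions of a conserved pattern; single
  gestures and purely stochastic level shifts are out of scope.
* A high CAC minimum is absence of evidence for a change, not evidence of
  absence — hence the `"no_evidence"` label.
* Fusion across channels requires index-aligned curves (equal length);
  resample channels to a common rate first.
* The number of boundaries (or an alert threshold learned from training
  data) must be supplied; the package does not estimate the number of
  regimes.
* Choosing which channels to fuse is the caller's responsibility.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
out <- make_regime_series(list(
  regime_spec("sine", 25, 400),
  regime_spec("sawtooth", 25, 400)), seed = 1)
cac <- fluss(out$series, subseq_params(25))
bd <- extract_regimes(cac, num_boundaries = 1)
bd$positions        # close to the true boundary at 400
score_segmentation(bd$positions, out$truth, length(out$series))$value
```
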