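---
title: "Quantifying the little auk vocal repertoire and its contextual valence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the little auk vocal repertoire and its contextual valence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aukcalls)
```

## The scientific problem

The little auk (*Alle alle*) is a highly vocal, colonial Arctic seabird whose
adults produce eight discrete call types over the mating and incubation
periods: *single*, *clucking*, *classic*, *terror*, *handling*, *low trill*,
*short* and *short-trill*. Two questions structure the analysis this package
implements:

1. **Repertoire discreteness** — are the eight visually/contextually defined
   call types acoustically distinct? This is answered by classifying calls
   from their measured acoustic parameters and comparing the classification
   rate with a permutation null.
2. **Vocal expression of contextual valence** — production contexts can be
   assigned a putative affective valence from fitness considerations
   (partner interaction promotes fitness, hence *positive*; predator
   presence and human handling threaten it, hence *negative*). Do calls from
   positive contexts differ acoustically from negative-context calls?

Because the field recordings are an external deposit, the package ships a
**synthetic call generator** whose defaults reproduce the published per-type
summary statistics (means and SDs of nine acoustic parameters per call
type). Every downstream stage is exercised against that generator, which
makes the whole pipeline testable, deterministic under a seed, and honest
about what it can and cannot validate (see *Limitations*).

## The acoustic parameter set

Each call is reduced to a 15-element feature vector: fundamental-frequency
statistics (`f0_min`, `f0_max`, `f0_mean`, `f0_start`, `f0_end`,
`f0_range`), modulation summaries (`f0_abs_slope`, the mean absolute local
contour slope in Hz/s; `f0_var`, the cumulative absolute f0 change per
second of voiced span, Hz/s; `am_rate` and `fm_rate`, the per-second counts
of amplitude-envelope peaks and contour direction reversals), spectral
energy quartiles `q25`/`q50`/`q75` and the spectral centre of gravity, and
the annotated `duration`.

The f0 tracker is a windowed-autocorrelation tracker in the Praat family:
per frame, the mean-subtracted, Hann-windowed autocorrelation is
taper-corrected by the window's own autocorrelation, searched for peaks
between `1/ceiling` and `1/floor`, and refined by parabolic interpolation.
A frame is voiced iff its best peak reaches the voicing threshold; a
lowest-cost path across per-frame candidates (transition cost proportional
to `|log2(f0[i]/f0[i-1])|`, plus a small static per-octave cost favouring
higher-frequency candidates) suppresses octave errors.

Tunable parameters, defaults and rationale:

| parameter | default | why |
|---|---|---|
| pitch floor / ceiling | 300 / 1600 Hz | brackets the species' observed f0 (≈600–1210 Hz) with margin |
| frame / hop | 40 / 10 ms | ≥ 12 pitch-floor periods per frame; 100 contour frames/s |
| voicing threshold | 0.45 | clean harmonic frames score > 0.9; white noise < 0.1 |
| octave costs | 0.35 jump, 0.05 static | standard tracker practice; only tie-breaks near-equal peaks |
| AM prominence | 10% of envelope max | ignores ripple while counting genuine modulation lobes |
| FM hysteresis | 1% of mean f0 (≥ 2 Hz) | a direction reversal must exceed tracker jitter to count |

For calls shorter than five default frames the frame shrinks to
`duration/5` (floored at 8 ms): the shortest call types (clucking and
handling, 90–110 ms on average) would otherwise yield one or two frames
whose centres miss the low-f0 edges of an arched contour. This is a
package choice; all settings are exposed as arguments.

Exact definitions of the slope-type measures vary between analysis scripts
in this literature; here `f0_abs_slope` and `f0_var` are defined as above,
isolated in `f0_statistics()` so an alternative convention is a one-line
substitution.

## The synthetic generator

`default_specs()` carries one spec per call type: Gaussian distributions
for nine measured parameters, a contour family, a harmonic count and a
noise level. `synthesize_call()` draws realised parameters (negative draws
are redrawn rather than clipped, to avoid probability mass piling up at
zero; durations have a 10 ms physical floor), builds a harmonic stack
(default 10 partials, 1/k amplitude roll-off, capped below Nyquist) whose
f0 follows the contour, applies sinusoidal amplitude modulation (depth 0.5
— only a modulation *rate* is published, so the depth is a package choice)
and additive Gaussian noise at 25 dB SNR (the selection filter keeps only
high-SNR calls, so synthetic calls emulate the retained ones).

Contour families are assigned from the qualitative call descriptions:
arched pulses for the short single-unit types, sinusoidal vibrato (trill)
for the trilled types, a fixed three-syllable series for the classic call
and a uniformly drawn 2–6 identical-syllable series for the terror call.
The arch is parameterised so its voiced time-average equals the drawn
`f0_mean` and its excursion the drawn `f0_range`; conveniently, with the
published clucking mean and range this reproduces the published clucking
min/max means almost exactly.

`sample_feature_table()` is the fast path for the statistical stages: it
draws each parameter **independently** from its per-type Gaussian, skipping
waveform synthesis. No covariance structure between parameters is
published, so independence is the only defensible default; consequences are
listed under *Limitations*. Derived columns (`f0_range = f0_max − f0_min`,
start/end, slope and variation) follow contour-shape closed forms; the
range is deliberately *not* forced non-negative, because repairing the
occasional inversion of independently drawn min/max would bias the very
marginals the recovery targets depend on.

Determinism: every generator entry point takes a seed; corpus generation
derives per-call seeds from the master seed, so any call can be regenerated
in isolation, and repeated runs are byte-identical.

## Repertoire discrimination

Features are standardised and decomposed by correlation-matrix PCA
(`prcomp`): the parameters mix Hz, seconds and s⁻¹, so covariance PCA
would be dominated by the high-variance upper quartile. Components with
eigenvalue > 1 are retained (Kaiser criterion) and a linear discriminant
(`MASS::lda`) with equal class priors — the design is balanced — is fitted
on the retained scores.

The headline statistic is the leave-one-out correct classification rate.
Two cross-validation modes are provided:

* `"refit"` (default): scaling, PCA, retention and the discriminant are
  all refit on each fold's n−1 calls — no information from the held-out
  call leaks into the transformation.
* `"global"`: one global PCA followed by `lda(CV = TRUE)`, the common
  shortcut in field workflows. It leaks the global rotation into each fold
  and typically differs by a small amount; it is provided for comparison.

The permutation test shuffles call-type labels 1000 times and recomputes
the full leave-one-out rate per shuffle. Because the standardisation and
PCA never see the labels, the per-fold projections are computed once and
shared across shuffles — numerically identical to refitting them per
shuffle, roughly twenty times faster. The p-value uses the add-one
estimator `(1 + #[null ≥ observed]) / (1 + N)`, so the smallest attainable
value at 1000 shuffles is 1/1001. For a balanced k-class design the null
mean sits at 1/k (12.5% for eight types) — verified directly in the test
suite for k = 2, 4 and 8.

## Valence analysis

`assign_valence()` maps call types to their contextual valence:
clucking → positive; terror and handling → negative; low trill, short and
short-trill → likely negative; single and classic → unknown. Only
positive/negative calls enter inference (90 calls in the reference
design); likely-negative and unknown calls are carried through summaries
but excluded from the models, because their contexts do not support a
confident assignment.

The multivariate test enters the first five PC scores into a MANOVA with
valence as the explanatory variable and call type as a control fixed
factor; Pillai's trace is used (the standard default, robust to mild
assumption violations), with sequential sums of squares and valence fitted
first. Call type is *nested* within valence in this design — each type
carries exactly one valence — so the call-type factor is partially aliased
with valence; the model reports this aliasing explicitly rather than
silently dropping it. Fitting valence first attributes the shared
between-group variance to valence, which matches the stated role of call
type as a *control* entered after the factor of interest.

The eight univariate models are ordinary least squares of each raw
parameter on valence with negative as the reference level, so the intercept
is the negative-group mean and the effect the positive-minus-negative
difference; for a single binary factor these equal the group sample means
*exactly*, which the tests assert to machine precision. Wald t-based 95%
intervals, R² and adjusted R² accompany each model.

## Numerical choices and degenerate inputs

* Autocorrelation is computed by FFT (Wiener–Khinchin) over all frames at
  once; frames are zero-padded to the next power of two, which changes
  nothing but the grid the spectrum is evaluated on. The display/analysis
  window of the spectrogram stays the published 715-sample Hann window
  even though computation is padded to 1024.
* All-unvoiced contours are returned, not raised; the contour statistics
  raise only when fewer than two voiced frames exist, and the error carries
  the offending call id.
* Zero-variance feature columns are dropped from PCA with a warning (they
  cannot be standardised); constant responses make the MANOVA degenerate
  and raise.
* If a class drops below two training members in a cross-validation fold
  (possible only in unbalanced or tiny designs), that class is excluded
  from the fold's discriminant and the held-out call is predicted among the
  remaining classes.
* Selection ties are broken by `call_id` lexicographic order; all analyses
  canonicalise row order by `call_id`, so input row order never changes any
  output.

## Problem sizes used in the checks

The shipped tests and the acceptance script run the reference design
(8 × 30 calls, 1000 permutations) for the permutation null and the design
counts; waveform-level recovery uses 30 synthetic calls per examined type;
linear-model recovery averages 100 replicate 90-call tables; the MANOVA
type-I calibration uses 500 null simulations; smaller structured instances
(20-call oracle comparisons, k ∈ {2, 4, 8} null centring at 12 calls per
class and 150 shuffles) cover the method-level properties.

## Limitations

* **Independence of drawn features.** The fast-path table draws parameters
  independently within a call, so cross-parameter correlations (e.g. the
  various f0 statistics of one call) are absent. Classification on such
  tables is, if anything, conservative relative to correlated real data for
  a fixed set of marginals; the permutation null is unaffected (it is
  label-based). Occasional rows have `f0_max < f0_min`; they are kept, see
  above.
* **Truncation bias on short-duration types.** Redrawing negative
  durations with a 10 ms floor inflates the handling-call mean duration
  (0.11 ± 0.10 truncated ≈ 0.139 s), so the recovered duration intercept
  averages ≈ 0.235 s against the published 0.22 s — within the sampling
  tolerance at n = 90, and a direct consequence of modelling a
  strictly-positive quantity with a Gaussian whose SD rivals its mean.
* **Acoustic realism.** The generator produces harmonic stacks with
  parametric contours: no formants, no vocal-tract filtering, no colony
  background noise, no reverberation. Passing recovery tests therefore
  validates the *measurement and statistics chain*, not the tracker's
  robustness to every field condition.
* **Unpublished definitions.** Start/end f0, absolute slope and f0
  variation have no published per-type distributions; their generator
  ground truths are contour-derived package conventions, and they are
  excluded from quantitative recovery targets (the model code paths are
  identical to the targeted parameters).
* **No arousal, no caller identity.** Valence is a two-level contextual
  attribution; arousal and individual identity are outside the design, and
  per-individual random effects are impossible because callers are unknown.
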