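---
title: "Methods: movement complexity and behavioural recurrence in the still-face paradigm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: movement complexity and behavioural recurrence in the still-face paradigm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(infantdyn)
```

## The two-level analysis

`infantdyn` analyses infant movement in the still-face paradigm — the
A-B-A-B-A sequence of five 2-minute episodes (Play, still-face 1, reunion 1,
still-face 2, reunion 2) in which the caregiver twice becomes unresponsive —
at two levels:

1. **Motor kinematics.** Tri-axial free acceleration (gravity already
   subtracted on-device) from wearable sensors at the torso, both wrists and
   both ankles, sampled at 100 Hz, is reduced to a per-phase acceleration
   magnitude series and characterised by *multiscale permutation entropy*
   and *complexity indices*.
2. **Behavioural micro-dynamics.** Second-by-second codes of five emotional
   self-regulation (ER) behaviours (oral-tactile self-comforting, attentional
   distraction via object manipulation, social interactive, motor
   stimulatory, distancing) plus "none", 120 samples per still-face phase,
   are characterised by *chromatic auto-recurrence quantification*.

The inferential layer (mixed models, contrasts) is deliberately not
reimplemented: the pipeline emits tidy per-participant/sensor/phase tables
that any statistics package can model.

## Motor pipeline

### Filtering

Each axis is low-pass filtered with a Butterworth filter, cutoff 20 Hz
(human movement carries ~90% of its spectral power below 20–30 Hz; higher
frequencies are treated as noise). Two details are open choices and are
therefore explicit, configurable parameters:

* **Order** (default 4): a common biomechanics default; the source
  description fixes only "low pass 20 Hz Butterworth".
* **Zero-phase application** (forward-backward, squaring the magnitude
  response): ordinal patterns are sensitive to phase warping, so a
  phase-distorting single pass would bias the entropy estimates.

No DSP package being available as a dependency, the design (analog
prototype poles, frequency pre-warping, bilinear transform) and the
forward-backward pass live in `R/butterworth.R`. The implementation is
validated against the closed-form digital Butterworth magnitude response
`|H(f)| = 1/sqrt(1 + (tan(pi f/fs)/tan(pi fc/fs))^(2n))`; reflection
padding is sized from the largest pole modulus so the zero-state startup
transient decays below 1e-13 inside the pad.

### Magnitude, segmentation, mean acceleration

The acceleration magnitude is the per-sample Euclidean norm of the three
filtered axes — the only reading of "vector sum at each time point" that
yields one value per sample. Phases are cut at externally supplied
annotations (a two-column phase table; intervals are half-open, 0-based);
a complete 2-min phase at 100 Hz has 12,000 samples, and shorter phases
are flagged incomplete and excluded from entropy analysis (no imputation).
Mean acceleration uses two-sided Tukey fences `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`
with type-7 (linear interpolation) quartiles; for nonnegative magnitudes
the lower fence is usually vacuous.

### Improved multiscale permutation entropy

Permutation entropy (PE) is the Shannon entropy of the distribution of
*ordinal patterns* — the permutation sorting each window of `m`
consecutive (lag-spaced) samples — normalized by `log(m!)` to `[0, 1]`.
Parameters follow the source study: `m = 4`, `lag = 1`, 50 scale factors.
Ties are broken by temporal order (stable sort), the standard Bandt-Pompe
convention; filtered accelerations rarely tie, but quantized data can.

Coarse-graining at scale `s` averages consecutive non-overlapping windows
of `s` samples, exposing dynamics at `fs / s` Hz. At scale 50 a phase
leaves only 240 points, so the *improved* multiscale estimator computes PE
on all `s` offset-shifted coarse-grainings and combines them. Two
combination rules exist in the literature and the source is silent on
which was used; both are implemented behind `combine=`:

* `"mean"` (default, documented): average of the `s` per-offset entropies;
* `"pooled"`: entropy of the pooled pattern histogram.

The variance-reduction property that motivates the improved estimator is
asserted in the acceptance suite (scale-50 estimates across seeds have
strictly lower variance than single-offset coarse-graining).

### Complexity index and frequency bands

The complexity index (CI) is the area under the MSE curve — the sum of PE
over a scale range; overall CI uses scales 1–50. Because scale `s`
examines `fs / s` Hz, EEG-convention bands map onto scale ranges via
`scale = round(fs / f)` (round half-up; configurable to floor/ceiling
since the source fixes only the anchor *scale 50 ↔ 2 Hz*). At
`fs = 100`, `max_scale = 50`:

| band  | edges (Hz) | scales |
|-------|-----------|--------|
| gamma | 30–45     | 2–3    |
| beta  | 14–30     | 3–7    |
| alpha | 8–13.5    | 7–13   |
| theta | 4.5–7.5   | 13–22  |
| delta | 0.5–4     | 25–50  |

The delta lower edge (0.5 Hz) would need scale 200 and is clamped to 50 —
forced by 50 being the highest computed scale. Adjacent bands may share an
edge scale; every output row records the realized `scale_low`/`scale_high`
so ranges are auditable. Note the ten printed band edges de-duplicate to
**seven** distinct scale factors under this mapping ({2,3,7,13,22,25,50});
a reduction to six edge scales is only obtained if the theta/delta
boundary is collapsed, which the available text does not settle —
`edge_scales()` therefore derives whatever the configured rounding yields
rather than hard-coding a set.

## Chromatic RQA

For categorical data, recurrence needs no embedding or radius: point
`(i, j)` recurs iff the states at `i` and `j` are equal **and** belong to
the target set (the five ER states; "none" never recurs — the chromatic
restriction). The line of identity is excluded by default (auto-RQA
standard; configurable). Measures:

* **RR** — `100 · (recurrent points) / (T² − T)` (denominator `T²` with
  the LOI included): how much behaviour is repeated.
* **LAM** — percentage of recurrent points on vertical lines of at least
  `v_min = 3` samples (3 s at 1 Hz): stability of behavioural bouts.
  Defined as 0 for an empty plot.
* **TT** — mean length of qualifying vertical lines, in seconds; reported
  as missing (never 0) when no line qualifies, so downstream averages are
  not biased. Lines truncated by the plot border count at observed length.
* **ENTb** — Shannon entropy (bits) of the distribution of rectangular
  block sizes. The plot of a categorical sequence is a union of rectangles:
  each ordered pair of same-state ER bouts of lengths `a`, `b` contributes
  an `a × b` block. ENTb is computed over the block-size histogram
  (integer bins). This is the least-specified measure in the source; the
  implemented convention classifies block sizes with the LOI *included*
  (`a × a` for a bout paired with itself), which (i) makes the sum of
  block sizes equal the recurrent-point count of the LOI-included plot and
  (ii) satisfies the boundary behaviour that all-equal-length bouts give a
  single size bin and ENTb = 0. Removing LOI points from diagonal block
  *sizes* would break (ii) by splitting every diagonal block into its own
  bin.

All four measures are verified against an independent naive full-matrix
scan, exhaustively over all 3^8 sequences of length 8 and on random
length-120 sequences.

## Synthetic data: what it emulates, and what a green test establishes

The cohort data are restricted-access, so the generators stand in for
them. They are *statistical* stand-ins — they reproduce the data's shape,
spectral band structure and bout structure, not infant biomechanics.

**Acceleration.** Each axis is a sum over the five bands of unit-variance
Gaussian noise confined to the band by brick-wall FFT masking, scaled by
`amplitude × phase_effect × group_effect`, plus a white measurement-noise
floor. FFT masking (rather than a band-pass filter) was chosen so band
edges are exact and injected band effects are cleanly auditable; since
only the product amplitude×effect matters, the choice does not affect the
recovery logic. Default amplitudes decay from delta (0.8 m/s²) to gamma
(0.1 m/s²) with a 0.05 m/s² noise floor — movement-like low-frequency
dominance producing trimmed mean magnitudes of order 1–2 m/s². Effects
default to 1 and are injected explicitly by tests.

A consequence of PE's invariance to amplitude worth stating plainly: a
band-amplitude effect is recoverable in a band's own CI only where that
band *competes with slower content*. Doubling the beta amplitude whitens
the coarse-grained signal at beta scales (CI rises; the beta
parameter-recovery criterion). But scaling the delta amplitude leaves the
delta-scale signal — already delta-dominated — ordinally unchanged, and
instead *smooths* the small-scale signal; the suite asserts this
invariance rather than a fictitious delta-band recovery. Green parameter
recovery therefore establishes that relative-power shifts are detected
where the method can see them, not that any injected effect is localized
to its own band.

**Behaviour.** Alternating bouts: a state is drawn from the occupancy
distribution (consecutive bouts differ when possible), a bout length from
a fixed/geometric/lognormal distribution parameterized by its mean, until
120 samples. Bout lengths are drawn by inverse transform on shared
uniforms, so sequences under the same seed are coupled and lengths are
monotone in the mean — making the "doubling the mean bout length never
lowers TT/LAM" criterion a near-structural property. Defaults (dominant
distraction state, 40% "none", geometric bouts with 4 s mean) land the
measures near the cohort-level intercepts reported for this paradigm
(RR ~ 15–20%, LAM ~ 75–80%, TT ~ 4–6 s); they are a fixed stated world,
not tuned quantities, and no test asserts those absolute values.

## Numerical choices and degenerate inputs

* Natural log for PE (irrelevant after `log(m!)` normalization); `0·log 0 = 0`.
* Windows are fully contained; no wraparound; offsets whose coarse-grained
  series cannot hold one embedding window are skipped, and scales with no
  valid offset truncate the curve with a warning.
* A PE estimate from fewer than `5·m!` windows warns but does not error.
* Quantile type 7 for Tukey fences; all-identical values exclude nothing.
* Sub-seeds are derived from the base seed by a 2^31-bounded string hash of
  the (group, phase, sensor, participant) key, so any cell of the design is
  reproducible in isolation.
* Determinism: identical configuration + seed gives byte-identical tidy
  tables end-to-end.

## Known limitations

* The generator's band noise is Gaussian and stationary; real infant
  movement is intermittent and non-Gaussian. Absolute entropy levels from
  the generator are not calibrated to cohort values.
* ENTb follows the block convention above; other RQA software may bin
  differently, so compare ENTb across tools only with matched definitions.
* The frequency-band reduction inherits the rounding ambiguity described
  above; realized scale ranges are always emitted alongside the values.
* Cross-RQA of caregiver–infant dyads and surrogate analyses are out of
  scope.
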