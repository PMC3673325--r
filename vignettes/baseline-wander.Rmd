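---
title: "Removing ECG baseline wander by adaptive filtering and single-channel ICA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Removing ECG baseline wander by adaptive filtering and single-channel ICA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgbaseline)
```

## The problem and the modelling assumption

Baseline wander is the slow drift (roughly 0.05–0.5 Hz) that respiration,
electrode impedance changes and movement add to an ECG. Because the ECG
itself has diagnostic content from about 0.05 Hz upward (the ST segment in
particular), removing the drift with a fixed high-pass filter distorts the
signal: any cutoff high enough to block the wander also passes through the
waves' own low-frequency energy.

This package instead treats the wander as a *statistically independent
source* mixed into the recording, and removes it by blind source
separation. Since only one lead is available, a pseudo-multichannel matrix
is manufactured by delay embedding, and independent component analysis
separates a baseline component that is then aligned, rescaled and
subtracted. The key assumptions are:

* the wander is (approximately) independent of the cardiac signal and
  non-Gaussian enough for a negentropy-based contrast to find it;
* it is narrowband and slow, so delayed copies of the record span its
  subspace and its components score high on low-frequency power
  concentration;
* it is zero-mean on the analysis timescale — the DC level of a record is
  the ECG's own isoelectric offset, not drift (this drives one design
  decision below).

## Pipeline stages and their parameters

`remove_baseline()` runs, in order:

1. *(optional)* a 60 Hz adaptive notch (`powerline = TRUE`) for
   mains-contaminated records;
2. the DC-referenced adaptive notch, whose **interference estimate** — the
   near-DC band the notch would remove — is the low-frequency *sub-signal*.
   Feeding ICA this sub-signal rather than the raw record removes the
   broadband cardiac energy that would otherwise dominate the embedding;
3. delay embedding into `n_channels = 60` copies stepped by
   `delay_step = 10` samples (1.18 s total span at 500 Hz);
4. fixed-point ICA with `n_components = 20`, contrast `g1` (tanh, a₁ = 1);
5. selection of baseline components by the fraction of periodogram power
   below `f_cut = 0.8 Hz`;
6. projection onto the undelayed channel and a shift/elevation/gain
   least-squares adjustment against a target;
7. subtraction: `clean = signal − baseline`.

### The adaptive notch filter

An N-tap LMS noise canceller with an analytic sinusoidal reference
`C·cos(w_r kT + θ)`. Design formulas exposed for verification:
`notch_transfer()` (the converged |H|, exactly 0 at `w_r`, exactly 1
everywhere if `N·∂·C² = 0`) and `notch_bandwidth()`
(`BW = N∂C²/(2T)` rad/s). Presets:

| mode | N | ∂ | C | reference | bandwidth |
|------|---|---|---|-----------|-----------|
| `dc` | 10 000 | 10⁻⁴ | 0.1 | constant (w_r = 0) | 2.5 rad/s ≈ 0.40 Hz |
| `powerline` | 2048 | 10⁻³ | 0.1 | 60 Hz | 5.12 rad/s ≈ 0.81 Hz |

The tap count N controls the time-varying part of the response through
`β = sin(N w_r T)/sin(w_r T)`; `β/N` shrinks as N grows, which is why both
presets use large N. Stability needs `∂ < 1/λ_max` of the reference
correlation matrix; `lms_cancel()` warns using the trace bound
`λ_max ≤ N·E[x²]` and aborts with the sample index if the weight norm
crosses a guard (10¹²). The DC filter's C is a free design knob (the
bandwidth scales with C²); 0.1 puts the sub-band edge slightly below the
conventional 0.5 Hz wander limit.

Two start-up conventions coexist deliberately. `lms_cancel()` zero-pads the
delay line before the first sample (deterministic, assumption-free — the
documented transient is ≈ N samples). `notch_filter()` instead pre-fills
the line with the reference's analytic continuation for k < 0, which is
exact for a deterministic sinusoid and matters for the DC filter: with
N = 10 000 and zero padding, a 10 000-sample record would spend its whole
length filling the line, and the effective bandwidth would ramp from zero —
short-record performance collapses. Weights always start at zero, so the
identity `output + interference = input` holds from the first sample in
both conventions.

### Fixed-point ICA

Centering, whitening by eigendecomposition of the covariance
(`z = D V^{−1/2} Dᵀ y`, symmetric form in the full-rank case), then one-unit
fixed-point iterations with Gram–Schmidt deflation. Numerical choices:

* **Convergence** is directional and sign-invariant:
  `|⟨w_new, w_old⟩| > 1 − tol`, `tol = 10⁻⁶`, `max_iter = 500`. A
  non-converged component is flagged, not fatal; each component restarts up
  to 3 times from fresh seeded directions first.
* **Initialization**: seeded uniform random unit vectors drawn from a
  private RNG stream — the caller's RNG state is untouched and results are
  byte-reproducible per seed.
* **Dimension handling**: eigenvalues below `10⁻¹² × λ_max` are dropped
  with a rank warning. When fewer components than channels are requested
  the whitening keeps only the leading `n_components` eigen-directions
  (PCA order), the standard FastICA preprocessing. This matters here: the
  delay embedding of a narrowband sub-signal is numerically near-singular,
  and whitening *all* 60 dimensions would amplify dozens of numerically
  empty directions to unit variance, leaving deflation to wade through
  noise before reaching the wander subspace. With the reduction, 20
  components comfortably contain the baseline subspace at desk-scale
  runtime.
* `negentropy()` computes `E{G(v)}` for the Gaussian reference by 64-node
  Gauss–Hermite quadrature rather than simulation, so the only sampling
  noise in `J(y) = (E[G(y)] − E[G(v)])²` comes from the data.

### Selection, projection, adjustment

ICA returns components in arbitrary order, sign and scale. The baseline is
identified spectrally: each component's score is the fraction of its
periodogram power below `f_cut` (DC bin excluded; ties to the lower index).
If no component reaches `min_score = 0.2` the pipeline aborts rather than
subtract a non-baseline component.

One subtlety the synthetic data exposes: when the wander contains several
narrowband sources (e.g. separate respiratory and electrode-drift
components), ICA legitimately splits it into several components, each
scoring high individually. `remove_baseline()` therefore treats **all**
components with score ≥ `score_threshold = 0.5` as baseline (always
including the top scorer) and sums their contributions on the undelayed
channel — which reduces to the classic single-component choice when only
one exists.

The adjustment fits `gain·raw(k − shift) + elevation` to a target by
closed-form affine least squares at every integer shift in
`shift_range = [0, 1180]` (twice the embedding span; the scan covers
embedding-induced group delay with margin) and keeps the smallest mean
squared residual. Two refinements:

* **Per-component gains.** When several components were selected, each gets
  its own gain by multiple least squares at the scan-chosen shift. The DC
  notch attenuates the upper wander band more than the lower one, and one
  scalar gain cannot undo frequency-dependent attenuation; per-component
  gains can. The scalar fit is nested in this model (all gains equal), so
  the residual never worsens and the `error₂ ≤ error₁` guarantee survives.
* **Elevation policy.** In *reference* mode (target = a reference baseline,
  e.g. `lowess_baseline()`) the elevation is free — this mirrors the
  classical shift/elevation adjustment. In *blind* mode the target is the
  record's own zero-phase Butterworth low-pass below `f_cut`, whose DC
  level contains the ECG's beat mean; fitting an elevation would transfer
  that offset into the "baseline" and shift the isoelectric line of the
  cleaned signal. Blind mode therefore fits through the origin: components
  are zero-mean and the wander is modelled as zero-mean, so the DC belongs
  to the ECG.

Edge policy: the embedding truncates to the common support (no padding);
the adjusted baseline holds its edge values outside the shifted support.
`error₂ ≤ error₁` is guaranteed on the fitted overlap, which the estimate
reports (`overlap`).

### The reference method and the metrics

`lowess_baseline()` is robust locally weighted regression: a degree-1
polynomial fitted by weighted least squares over the `span = 1500` nearest
samples (3 s at 500 Hz — the span is read as a sample count and exposed as
a parameter) with tricube distance weights, then 2 bisquare reweighting
rounds with residuals scaled by six times their median absolute value, which
is what lets the smoother ignore QRS complexes as outliers. Interior
windows are symmetric; at the edges the window slides to stay in bounds.
The implementation is compiled; the test suite pins it to a brute-force
per-point weighted-least-squares oracle at 10⁻⁸.

`baseline_error()` is the mean of squared differences (a root-mean-square
variant is exposed via `rms = TRUE`, since printed error magnitudes alone
cannot disambiguate the two conventions); `error_reduction()` is
`(error₁ − error₂)/error₁` and `average_error_reduction()` its mean across
records, reported as a fraction.

## What the synthetic generator emulates — and what it does not

`synth_ecg()` builds each record as an exact sum of four components
(`mixture = ecg + wander + powerline + noise`), so every recovery metric has
a ground truth:

* beats at a programmed heart rate (default 72 bpm, ±5% uniform RR jitter),
  each a sum of five Gaussian bumps with typical lead-II proportions and a
  unit R amplitude;
* wander as a sparse sum of sinusoids confined to 0.05–0.5 Hz (defaults:
  0.10, 0.21, 0.33 Hz — a slow electrode-drift component plus two
  respiratory-band components — with amplitudes 0.7/0.4/0.2), optionally
  modulated by a piecewise-linear envelope to emulate slowly drifting
  severity;
* optional 60 Hz sine and white Gaussian noise (default SD 0.02).

`lbnp_like_suite()` draws per-record frequencies, phases, amplitudes
(log-uniform peak between 0.2× and 3× the R amplitude) and envelopes to
emulate a cohort spanning mild to severe drift. The validation suite runs
20 such records of 60 s at 500 Hz with peaks between 0.5× and 2×, and a
10-record drifting-envelope set truncated to 10 000 samples.

Passing tests on this generator shows the pipeline separates additive,
band-limited, quasi-sinusoidal drift from a quasi-periodic beat train at
realistic amplitude ratios. It does **not** show robustness to ectopic
beats, respiration-modulated QRS amplitudes, electrode pop artifacts,
non-stationary heart rates, or wander with broadband structure — real
recordings contain all of these, and the sinusoidal wander model is the
main idealization.

## Measurement choices in the validation suite

* Empirical frequency responses use the coherent cross-spectral estimator
  `|Σ conj(IN)·OUT| / Σ|IN|²` over non-overlapping segments after
  discarding the `max(N, 2 s)` start-up samples, with segment lengths
  chosen so 60 Hz falls on an exact bin. On a white-noise probe the
  adaptive filter's output also contains LMS misadjustment noise
  concentrated near the reference frequency, so the measured notch depth
  fluctuates with the probe realization even though the converged transfer
  function is exactly zero there (a sinusoidal probe shows the much deeper
  attenuation directly).
* The empirical notch width uses the integrated-deficit estimator
  `(2/π)∫(1 − |Ĥ|²) df` over 55–65 Hz, which for a second-order notch
  equals the −3 dB width and averages estimator noise over the whole skirt;
  locating the two −3 dB crossings directly is far noisier at this record
  length.
* End-to-end recovery is scored by correlation with the true wander,
  sub-0.5 Hz residual power reduction, and the `error₁`/`error₂` pair
  against the locally-weighted-regression baseline (reference-mode
  adjustment, where the inequality is guaranteed by the search set).
* Problem sizes (60 s records, 20-record cohorts, 10-seed ICA ensembles,
  50-sample LOWESS toys) were chosen to exercise the stated conditions at
  desk scale.

## Known limitations

* Single-lead only; no multi-lead fusion.
* The wander model underlying selection is narrowband: drift whose power
  spreads above `f_cut` will be partially missed, and the DC notch's soft
  roll-off attenuates the upper wander band (the per-component gains
  compensate only for what the components retain).
* Records much shorter than the embedding span plus filter length cannot be
  processed (the embedding refuses them with the required minimum).
* File input is CSV (one or two columns, or the generator's record format);
  binary waveform formats are out of scope for the reader.
* The CLI is a thin wrapper over the R API; it processes one record per
  invocation and has no streaming mode.
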