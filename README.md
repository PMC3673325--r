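# ecgbaseline

Baseline wander — the slow (≈0.05–0.5 Hz) drift that respiration, electrode
impedance changes and body movement superimpose on an electrocardiogram —
overlaps the spectrum of the ECG's own low-frequency features (notably the
ST segment), so a plain high-pass filter cannot remove it without distorting
the waves a clinician reads. `ecgbaseline` implements a hierarchical
blind-source-separation approach for **single-lead** recordings that treats
the wander as an independent latent source:

1. **Adaptive LMS notch filter.** An N-stage tapped-delay-line noise
   canceller with sinusoidal reference `x_k = C·cos(w_r k T + θ)` and weight
   update `w_{k+1} = w_k + ∂ ε_k x_k`. Its converged response is the notch

   `H(z) = (z² − 2z·cos(w_r T) + 1) / (z² − 2(1 − N∂C²/4)z·cos(w_r T) + (1 − N∂C²/2))`

   with approximate bandwidth `BW = N∂C²/(2T)` rad/s. A DC-referenced
   instance (N = 10 000, ∂ = 10⁻⁴, C = 0.1) splits off the low-frequency
   *sub-signal*; a 60 Hz instance (N = 2048, ∂ = 10⁻³, C = 0.1) optionally
   removes powerline interference.
2. **Delay embedding.** The single-channel sub-signal is expanded into 60
   pseudo-channels delayed in steps of 10 samples, giving ICA a multichannel
   input.
3. **Fixed-point ICA** (written from scratch): centering, eigendecomposition
   whitening `z = D V^{−1/2} Dᵀ y`, and the one-unit negentropy rule
   `w′ = E{z g(wᵀz)} − E{g′(wᵀz)} w` with deflation, using the standard
   contrasts g₁ = tanh(a₁y), g₂ = y·exp(−a₂y²/2), g₃ = y³.
4. **Selection and adjustment.** Components whose spectral power concentrates
   below 0.8 Hz are labelled baseline, projected back onto the undelayed
   channel, and aligned to a target (the record's own low-pass trend, or a
   reference baseline) by a shift/elevation/gain least-squares fit before
   subtraction.

A robust locally weighted regression smoother (tricube weights, bisquare
robustness iterations, span 1500 samples) is included as the reference
method, together with the evaluation metrics `error₁`, `error₂` (mean
squared differences against the reference baseline) and the per-record and
average error reductions `(error₁ − error₂)/error₁`. A synthetic ECG
generator with exact ground truth (Gaussian P-QRS-T beats, band-limited
wander, optional powerline and noise) makes every stage testable without
clinical data.

## Worked example

```r
library(ecgbaseline)

rec <- synth_ecg(synth_spec(duration = 60, seed = 42))
rec
#> <synth_record: 60.0 s @ 500 Hz, 72 beats, wander RMS 0.578>

result <- remove_baseline(rec$mixture, pipeline_config(seed = 1))
result$estimate
#> <baseline_estimate: shift=0 samples, elevation=0, gain=[1.062, 4.966, 0.8986], mse=0.007863>

cor(result$estimate$baseline$samples, rec$wander_true$samples)
#> [1] 0.993
```

Three independent components scored ≥ 0.97 on low-frequency concentration
(the generator's wander holds three narrowband sources, which ICA separates)
and each received its own gain; the reassembled baseline correlates 0.993
with the ground-truth wander. Comparing against the locally weighted
regression reference on the same record:

```r
ref  <- remove_baseline_reference(rec$mixture)
e1   <- baseline_error(result$estimate$raw_component$samples,
                       ref$baseline$samples[1:29410])
est2 <- adjust_baseline(result$estimate$raw_component, ref$baseline,
                        shift_range = c(0, 1180))
error_report(e1, est2$mse, 29410)
#> <error_report: error1=0.02347 error2=0.01346 reduction=42.63%>
```

`error₂ ≤ error₁` holds by construction of the shift search, so the adjusted
baseline never agrees with the reference method less than the raw component
does.

The same operations are available from a shell via the launcher in
`inst/exec/ecgbaseline` (subcommands `synth`, `notch`, `filter`, `reference`,
`compare`; CSV in, CSV + JSON report out).

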