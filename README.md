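# phonoseg

Heart sound segmentation and timing diagnostics for phonocardiograms
(PCG), in R.

A phonocardiogram records the heart's sounds through a chest microphone.
`phonoseg` finds the first (S1) and second (S2) heart sounds in a
single-channel recording and derives the diagnostic timing parameters
clinicians read from them: the heartbeat interval **T11** (instantaneous
heart rate = 60/T11 bpm), the systolic duration **T12**, the diastolic
duration **T21 = T11 − T12**, the heart sound widths **T1**/**T2**, and
the systole/diastole ratio **r = T12 / (T11 − T12)**.  It is aimed at
people building or evaluating low-cost PCG instrumentation, where
robustness to noise, motion and variable gain matters more than studio
conditions.

## Method in brief

Detection is built on a beat-tracking idea from music analysis: a beat is
a point of maximal *spectral change*, not of maximal loudness.

1. Resample to 32 kHz and low-pass at 1000 Hz with a zero-phase filter.
2. Compute the onset strength envelope: windows of `N ≈ Fs/8` samples in
   half-window hops, power summed into twenty 50 Hz bands, and
   `Γ(k) = Σ_m |S_m(k) − S_m(k−1)|²`.
3. Estimate one global tempo from the envelope's autocorrelation and
   extract a beat sequence by dynamic programming, maximizing
   `Σ Γ(t_i) − λ Σ (log(Δt_i/τ))²` — onset reward minus a tempo-conformance
   penalty.
4. Remove the detected sequence by multiplying the envelope with
   `W(t) = 1 − Σ_i 0.8·exp(−(t−μ_i)²/2σ²)` and track a second time: the
   two passes yield the two interleaved sound sequences.
5. Label which sequence is S1 using interval-timing rules (separations in
   [0.22 s, 1.3 × median]) and the higher infrasonic-band variance of the
   systolic segment; pair S1→S2 into cycles, dropping unpaired beats.
6. Measure T1/T2 widths on the Shannon energy envelope
   (mean of −x²·log x², 20 %-of-peak width) and assemble the report.

A seeded synthetic-PCG generator with exact ground truth
(`synthetic_spec()` / `synthesize()` / `benchmark_spec()`) makes every
stage testable without recordings.

## Worked example

```r
library(phonoseg)

sim    <- synthesize(synthetic_spec(duration_s = 30,
                                    hr_profile = hr_constant(72),
                                    seed = 42))
report <- analyze(sim$audio)
report
#> <pcg_report: 36 cycles over 30.0 s, mean HR 72.0 bpm, success rate 1.000>

glance(report)
#> # A tibble: 1 × 9
#>   n_cycles mean_hr_bpm median_t11_s median_t12_s median_t21_s median_t1_width_s
#>      <int>       <dbl>        <dbl>        <dbl>        <dbl>             <dbl>
#> 1       36        72.0        0.834        0.293        0.543              0.09
#>   median_t2_width_s mean_ratio success_rate
#>               <dbl>      <dbl>        <dbl>
#> 1              0.07      0.537            1

evaluate_detection(sim$truth, report$labeled)
#> # A tibble: 1 × 6
#>   recall precision timing_rmse_s n_matched n_truth n_detected
#>    <dbl>     <dbl>         <dbl>     <int>   <int>      <int>
#> 1      1         1       0.00216        72      72         72
```

The 36 cycles are the paired S1/S2 events found in 30 s at 72 bpm; the
median intervals say systole occupies 0.293 s of each 0.834 s beat
(ratio r ≈ 0.54), and every true event was recovered with ~2 ms timing
error.  `tidy(report)` returns the per-cycle table; `autoplot(report,
type = ...)` draws the T12-vs-T11 scatter, the width scatter, and the
interval/ratio trends.

Real recordings enter through `read_wav()` (or a path passed straight to
`analyze()`); a thin command-line wrapper ships in
`inst/cli/phonoseg.R` with `analyze`, `simulate` and `evaluate`
subcommands.

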