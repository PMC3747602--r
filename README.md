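# sdppg

Second-derivative photoplethysmogram (SDPPG) analysis for arterial-stiffness
estimation in R.

The AC waveform of a finger PPG changes from wavy to triangular as arteries
stiffen with age. Its second derivative (the acceleration plethysmogram)
resolves that change into five systolic waves — a, b, c, d, e — and the
**ageing index**

    AGI = (b − c − d − e) / a

summarizes them as a single dimensionless proxy for vascular age. Measured
naively beat by beat, AGI is dominated by noise amplified through
differentiation. This package implements a low-variance estimation
pipeline:

1. FIR band separation (Hamming windowed-sinc, 30 Hz low-pass order 500,
   0.5 Hz high-pass order 4000, delay-compensated);
2. 2nd/4th derivatives via smooth noise-robust differentiators (5-point
   kernel, exact on quadratics, zero response at Nyquist);
3. foot-to-foot beat segmentation and **time normalization** of every
   recurrence to a 1 s base (fundamental at 1 Hz, harmonics at integer Hz);
4. a verified equiripple (Parks–McClellan) low-pass on the normalized base
   — passband edge 6 Hz, 1 Hz transition, ripple ≤ 0.001 in both bands —
   passing the fundamental plus 5 harmonics and crushing everything above;
5. alignment of beats at the 50% level of the systolic rising front,
   ensemble averaging, and a–e detection via zero crossings of the averaged
   4th derivative (with the standard fallback for missing c/d waves).

Around the core it provides the beat-to-beat dispersion statistics
(`sd_about_reference()`, `sd_group_average()`), the passband-edge
optimization sweep (`edge_frequency_sweep()`, 4–14 Hz grid), cohort-level
AGI-vs-age regression with Bland–Altman differences and a Welch group test
(`cohort_analysis()`), a simplified per-beat baseline for dispersion
comparisons (`baseline_per_beat()`), and a fully annotated synthetic PPG
generator (`generate_recording()`, `generate_cohort()`) used by the test
suite. A command-line front end lives in `inst/cli/sdppg.R`
(`analyze`, `sweep`, `cohort`, `simulate`).

Who it is for: physiological signal-processing researchers working with
pulse-wave recordings who need a reproducible, testable AGI implementation,
and methodologists studying variance-reduction choices (normalization,
filtering, ensemble averaging) in derivative-based waveform indices.

## Worked example

```r
library(sdppg)

# a synthetic subject: ~27 s of 1 kHz finger PPG with period jitter,
# respiratory drift and broadband noise, stiffness dialled mid-range
tpl <- beat_template(stiffness = 0.55)
rec <- generate_recording(tpl, recording_spec(n_beats = 30, seed = 42))

res <- analyze_ppg(rec$signal, run_config(n_beats = 15))
f <- res$avg_features
sprintf("true (annotated) AGI: %.4f", rec$annotations$agi)
#> "true (annotated) AGI: -0.3494"
sprintf("estimated AGI:        %.4f", f$agi)
#> "estimated AGI:        -0.3452"
sprintf("ratios: b/a = %.3f, c/a = %.3f, d/a = %.3f, e/a = %.3f",
        f$b_over_a, f$c_over_a, f$d_over_a, f$e_over_a)
#> "ratios: b/a = -0.822, c/a = -0.549, d/a = -1.481, e/a = 1.554"
round(res$sds, 4)
#>      agi b_over_a c_over_a d_over_a e_over_a   t_a_ms   t_b_ms   t_c_ms
#>   0.0345   0.0290   0.0314   0.0379   0.0567   1.3609   1.2164   1.8602
#>   t_d_ms   t_e_ms
#>   1.7667   2.6998
```

The estimate sits within 0.005 of the generator's annotated ground truth,
and the beat-to-beat dispersion of AGI about the averaged-waveform value
(`res$sds["agi"]`, here 0.035) is a few percent of the index's
physiological range — that dispersion is the quantity the 6 Hz edge and the
ensemble averaging exist to minimize. Wave-peak time dispersions are
reported in ms on the normalized 1 s base.

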