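---
title: "SDPPG analysis and the ageing index: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{SDPPG analysis and the ageing index: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdppg)
```

## The measurement problem

The AC component of a finger photoplethysmogram (PPG) changes shape with
vascular age: compliant young arteries give a wavy pulse with a pronounced
dicrotic limb, stiff arteries a more triangular one. The second derivative
of the PPG (SDPPG, also called the acceleration plethysmogram) resolves
this shape change into five alternating systolic waves — a (maximum),
b (minimum), c (maximum), d (minimum), e (maximum) — whose normalized
amplitudes summarize arterial stiffness through the ageing index

$$AGI = \frac{b - c - d - e}{a}.$$

Computed beat by beat on raw derivatives, AGI is noisy: higher-frequency
content and noise, strongly amplified by differentiation, move the detected
peaks between different phases of consecutive beats, so the beat-to-beat
standard deviation of AGI can be a large fraction of its physiological
range. Everything in this package exists to drive that dispersion down
while leaving the index itself unbiased, so that subjects with genuinely
different stiffness can be told apart.

## The pipeline

`analyze_ppg()` runs the following stages on a single recording at the
canonical 1 kHz rate (inputs at other rates are spline-resampled on
ingestion; all fixed filter orders are meaningful only at 1 kHz).

1. **Band separation.** A Hamming windowed-sinc low-pass (30 Hz cutoff,
   order 500) removes broadband noise; a windowed-sinc high-pass (0.5 Hz,
   order 4000) removes the DC level and baseline drift. Both are linear
   phase and are compensated by their integer group delay `order/2`; the
   first and last `order/2` samples of each stage are discarded rather than
   padded, so nothing downstream sees fabricated transients. A recording
   must therefore be at least ~4.5 s longer than the material analyzed.
   Filtering is forward-only with delay compensation (not forward–backward):
   a constant delay would cancel in AGI but not in absolute wave times,
   which the dispersion statistics also track.
2. **Smooth differentiation.** The 2nd and 4th derivatives are obtained by
   repeated application of the 5-point smooth noise-robust differentiator
   $f'(t_0) \approx [2(f_{1}-f_{-1}) + (f_{2}-f_{-2})]/(8h)$. The kernel is
   exact on quadratics, tracks the ideal differentiator within 1% up to
   15 Hz at 1 kHz (where nearly all PPG power lives), and has a zero of
   tangency at Nyquist, so it does not amplify the high-frequency noise the
   way a first difference does. The 5-point member is the shortest of the
   family and suppresses least; longer kernels are available via
   `run_config(snrd_length = …)`.
3. **Beat segmentation.** Beats are delimited foot-to-foot:
   steepest-rise points are local maxima of the smoothed first derivative
   above half the median prominent-peak height with a 0.3 s refractory
   period, and each foot is the signal minimum in the 0.35 s window before
   a rise point. A median-based inter-beat-interval correction removes rise
   points that split one beat into two short fragments (a noise spike on
   the dicrotic limb can do this). Durations outside 0.3–2 s are discarded.
4. **Time normalization.** Each recurrence, with enough surrounding context
   to support the next filter, is cubic-spline resampled so the beat spans
   exactly 1 s. This pins the pulse fundamental at 1 Hz and every harmonic
   at an integer frequency, so a fixed-edge filter treats the harmonics of
   every beat — and of every subject — identically.
5. **Equiripple low-pass.** The normalized beat (and its derivative
   companions) are filtered with a Parks–McClellan low-pass: passband edge
   6 Hz, transition band 1 Hz, maximum deviation 0.001 in both bands. With
   a 1 Hz transition the band between harmonics 6 and 7 carries no signal,
   so the filter passes the fundamental plus five harmonics essentially
   untouched (ripple ≤ 0.1%) and suppresses everything from the 7th up by
   ≥ 60 dB. The derivatives are filtered as derivatives (differentiation
   happened *before* resampling); the time scaling introduces a
   `duration^k` factor per beat that cancels in every normalized ratio.
6. **Alignment and averaging.** Each beat's reference point is the
   sub-sample time where the PPG first crosses halfway between its foot
   and systolic peak on the upstroke — a point much better defined than
   either the foot (wavy diastole) or the peak (state-dependent). Beats are
   shifted so these references coincide and the PPG, SDPPG and 4th
   derivative are averaged pointwise over the common support, attenuating
   anything not phase-locked to the upstroke by roughly $1/\sqrt{n}$.
7. **Wave detection.** Zero crossings of the averaged 4th derivative
   partition the systolic window; wave a is the SDPPG maximum in the first
   crossing interval holding a dominant positive interior maximum, and
   b, c, d, e follow in the successive intervals with alternating polarity.
   When the SDPPG has no extremum of the expected polarity in an interval —
   the classic "missing c/d" morphology — the wave is placed at the 4th
   derivative's extremum there, which marks the underlying inflection. The
   same detector runs on every individual normalized beat (its own d4
   guiding it) to produce the per-beat values entering the dispersion
   statistics.

### Dispersion statistics and edge optimization

For each statistic $x$ (AGI, the four ratios, and the five peak times in
ms) the per-subject dispersion is taken about the averaged-waveform value
$x_{avg}$, not the sample mean:

$$SD = \sqrt{\frac{\sum_{i=1}^{n}(x_a(i) - x_{avg})^2}{n - 1}},$$

and dispersions are averaged arithmetically over subjects.
`edge_frequency_sweep()` repeats the whole per-beat pipeline across a grid
of passband edges (default 4–14 Hz in 1 Hz steps) and reports the group
dispersion per statistic and the argmin edge. The expected shape is a
U-curve: below ~6 Hz the harmonics that *form* c and d are suppressed, the
fallback placement takes over and disagrees between single beats and the
average; above it, noise harmonics pass and are amplified fourfold per
differentiation order. Subject/edge cells where detection fails are
excluded from the group average and logged, not imputed.

### Cohort statistics

`fit_agi_age()` fits AGI on age by ordinary least squares over the healthy
group (the Gaussian identity-link GLM), reporting the Pearson correlation
and residual SD. `bland_altman_vs_model()` gives each record's difference
from the fitted line with per-group means and SDs, and `compare_groups()`
applies the unpaired Welch unequal-variance t-test to the healthy and
patient differences. A paired design is impossible for groups of unequal
size, so the unpaired test the parenthetical "two-sample assuming unequal
variances" describes is what is implemented.

### The simplified per-beat baseline

`baseline_per_beat()` reproduces the conventional analysis that the
pipeline improves on: band separation and smooth differentiation only,
waves detected on each raw beat from its own 4th-derivative zero crossings,
no normalization, no equiripple stage, no averaging. It exists for
dispersion comparisons and is deliberately minimal; it is not a faithful
reimplementation of any specific published system and is excluded from
quantitative claims.

## The synthetic generator

Tests and demonstrations run on `generate_recording()`, which emulates
exactly the structure the algorithm assumes and annotates the ground truth:

- a **Gaussian-sum beat template** (systolic upstroke, late-systolic
  shoulder, dicrotic wave) represented by its Fourier series truncated at
  `n_harmonics` (default 6). Truncation makes the clean template exactly
  band-limited on the normalized base, so the 6 Hz equiripple stage is
  transparent to it and annotated wave amplitudes are directly comparable
  with the pipeline's output. A `stiffness` parameter in [0, 1] morphs the
  component table between a compliant and a stiff endpoint; the endpoints
  were chosen by numeric search so the clean-template AGI is strictly
  monotone in stiffness and spans about [−1.94, +0.60], containing the
  physiological range with margin (this monotonicity is what makes
  `stiffness_for_agi()` well defined, and it is verified by tests);
- **beat-to-beat period jitter** (3% SD by default, clipped at ±3 SD),
  **baseline drift** (0.2 Hz, 30% of the AC swing — a respiratory rate),
  **white broadband noise** (2% of the AC RMS by default; 10% ≈ 20 dB SNR
  for the degradation studies), an optional powerline tone, and a DC
  offset. Defaults emulate a one-minute resting recording: 70 beats of
  0.9 s mean period at 1 kHz;
- annotations carry the true beat boundaries and the clean template's wave
  times/amplitudes and AGI, computed analytically from the truncated
  Fourier series at 10⁴ points per period with the same zero-crossing
  detection rule.

`generate_cohort()` draws ages uniformly per group, sets each subject's
target AGI from a linear model (default slope 0.019/yr, intercept −1.556,
residual SD 0.126, patient offset +0.359) and inverts the monotone
stiffness→AGI map so each subject's clean template attains its target
within 0.01.

What the generator does *not* emulate — and hence what passing tests do
not establish about real data: motion artifacts, sensor coupling changes,
arrhythmic or ectopic beats, beat-shape variability within a subject,
non-white sensor noise, and any hemodynamic (Windkessel-type) coupling
between period and pulse shape. Results on synthetic cohorts validate the
numerics and the statistical machinery, not clinical performance.

## Numerical choices

- **Equiripple design.** The classical Herrmann–Rabiner formula
  (`estimate_pm_order()`, floor truncation; 3255 for 0.001/0.001 ripples,
  1 Hz transition, 1 kHz) slightly underestimates the order that actually
  meets the ripple: the realized deviation at 3255 is ≈ 0.00107.
  `design_pm_lowpass()` therefore verifies the designed response on a
  dense FFT grid and steps the order up until both bands meet 0.001
  (landing near 3291 for the 6 Hz edge), skipping orders where the Remez
  exchange fails to converge. Filters of even length carry a half-sample
  group delay; the residual half-sample shift is removed by spline
  interpolation, which is essentially exact for signals band-limited to
  ≤ 8 Hz at 1 kHz.
- **Context windows.** Per-recurrence filtering needs half the filter
  length of valid context on each side of the beat; the window is derived
  from the actual filter length (half-length + 160 samples on the
  normalized grid, scaled by the beat duration in original time). Beats too
  close to the recording edges are skipped with a count.
- **Search window.** Wave detection searches [ref − 0.2 s, ref + 0.7 s] on
  the normalized base. The a wave — the curvature maximum low on the
  upstroke — *precedes* the 50% rising-front reference, and its opening
  zero crossing sits up to ~0.14 s before it; at a 4 Hz edge the e wave's
  closing crossing falls ~0.6 s after it. Both bounds are configurable
  (`search_pre_s`, `search_window_s`).
- **Dominance floor for a.** On noisy averaged waveforms a residual ripple
  ahead of the upstroke can present a tiny positive local maximum; wave a
  must reach 20% of the window's SDPPG maximum to be accepted (the true
  initial wave is always within a factor ~2 of the dominant excursion).
- **Ties and degenerate inputs.** Equal extrema resolve to the earliest
  time. Beats without a detectable rising front are rejected from the
  average (counted); per-beat detection failures yield flagged rows, not
  aborts; a subject/edge sweep cell that fails is excluded from the group
  average and logged.
- **Resampling.** Cubic splines throughout: at 1 kHz the 30 Hz-limited
  signal is oversampled ≥ 16×, where spline error is negligible and, unlike
  Fourier methods, no ringing is introduced at window edges.

## Problem sizes used by the test suite

The suite and the acceptance checks run entirely on synthetic data built
at test time: recordings of 20–30 beats (15 analyzed, matching the
recommended segment length), cohorts of 21 healthy + 20 patient records,
100 random waveforms for the detector/oracle equivalence, 50 seeds for the
pipeline-versus-baseline dispersion comparison, and a 10-subject cohort at
edges {4, 6, 14} Hz for the dispersion-minimum check. These sizes were
chosen so the full suite exercises every stage end to end in well under a
minute on one core.

## Known limitations

- The wave detector assumes the five-wave systolic morphology; waveforms
  violating the polarity sequence fail loudly rather than relabeling waves.
- The baseline mode is qualitative (see above).
- PPG amplitude is treated as dimensionless throughout; only normalized
  ratios and times are physiologically interpretable, which the AGI
  normalization makes safe.
- The synthetic beat family, while spanning the AGI range, exaggerates the
  dicrotic e wave relative to typical adult recordings; detector tie-break
  behavior near equal-amplitude a/e waves is covered by tests, but real
  recordings should be inspected before trusting a single subject's index.
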