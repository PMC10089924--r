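---
title: "Models and methods behind astrostate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind astrostate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

astrostate links four kinds of signals from awake-mouse cortical
recordings — a fluorescent norepinephrine (NE) sensor imaged with a
two-photon microscope, astrocyte and neuronal Ca²⁺, behavioral arousal
measures (pupil, wheel), and the local field potential (LFP) — and
provides the resampling statistics appropriate for such nested data.
This vignette explains the models, the tunable parameters, the numerical
choices, and what the synthetic-data tests do and do not demonstrate.

## The hemodynamic attenuation model

Single-wavelength two-photon imaging of a bright, widely expressed
sensor picks up apparent fluorescence changes that are really changes in
light absorption by hemoglobin as blood volume fluctuates. With no
reflectance channel available for conventional correction, the pixel
model is multiplicative:

$$Y_k(t) = F_k(t)\,e^{h_k(t)} + N(t), \qquad
  e^{h_j(t)} = e^{a\,h_k(t) + b}\;(j \neq k),$$

i.e. the attenuation exponent is a shared time course scaled per pixel.
Three identifiability facts shape the implementation:

* **Scale is not identifiable from a fit.** The intercept $b$ and any
  constant factor of $F_k$ enter the log-regression identically, so a
  fitted correction recovers $F_k$ up to a per-pixel positive constant.
  The exact-inversion contract (relative error $< 10^{-6}$) therefore
  holds when the correction is applied with the *known* $(a, b, h)$ of a
  noiseless movie — the corrector inverts the generative model exactly —
  while the fitted pipeline is validated by correlation with the true
  signal, which is scale-free.
* **Slow sensor signal must not be fit.** A centered 100-frame moving
  average is subtracted from every pixel before fitting, so only
  fluctuations faster than the window (50 s at 2 Hz) inform the
  regression. The window shrinks symmetrically at the recording edges;
  a centered window introduces no phase shift, which matters because the
  fitted curve is subsequently divided out sample-by-sample.
* **The log needs a positive argument.** The detrended curve is
  zero-mean, so an offset must be added before taking logarithms. The
  package adds back each pixel's raw mean (processed curve
  $= Y - \mathrm{MA}(Y) + \bar Y$). To first order
  $\log(\bar Y + x) \approx \log \bar Y + x/\bar Y$, so the fitted slope
  is the attenuation gain in relative-fluorescence units, directly
  comparable across pixels of different brightness. An
  amplitude-dependent offset (e.g. one derived from the trace minimum)
  would instead make the slope scale with each pixel's total fluctuation
  amplitude, which is dominated by sensor signal in bright pixels and
  destroys the gain ranking that reporter-pixel selection depends on.
  Traces supplied to `fit_attenuation()` that are already strictly
  positive are used as-is; without supplied offsets a minimum-based
  fallback is applied.

### Reference selection and refinement

The initial reference is the connected region of `region_size` pixels
(default 9) minimizing mean-projection intensity, found by greedy
dimmest-neighbor growth from every seed with ties broken by the smallest
row-major pixel index — vascular lumens are dark and nearly free of
sensor expression, so their trace is (scaled) attenuation. The region
size and the "minimal fluorescence" rule are exposed as parameters
because neither has a canonical value; 9 pixels is small enough to stay
inside a capillary cross-section at typical zoom.

Refinement replaces the reference by a weighted average of pixel curves
with the fitted $a$ as weight, then detrends and refits; three rounds by
default, stopping early when successive references correlate above
0.999. Two guards keep this iteration from poisoning itself:

* curves enter in **relative units** (divided by their mean brightness),
  otherwise bright signal-carrying pixels dominate dim vascular ones by
  sheer photon count;
* only the **most attenuated quartile** of pixels receives weight. The
  true sensor signal is shared across pixels, so with all pixels
  weighted the refined reference converges to a mixture of attenuation
  and signal, and the correction then subtracts real signal everywhere.
  Restricting to high-$a$ pixels mirrors, on the opposite tail, the same
  percentile logic used for reporter selection. On synthetic sessions
  this changes recovery from a deliberately contaminated initial
  reference from non-improving to monotone (final-trace correlation
  0.40 → 0.96 over three rounds).

Reporter pixels are ranks in the half-open percentile band
$(1\%, 25\%]$ of ascending $a$ (nearest-rank, ties by pixel index): the
bottom 1% often contains artifacts, and the retained mask size is
exactly $\lfloor 0.25n \rfloor - \lfloor 0.01n \rfloor$. Fewer than 100
pixels is refused rather than silently rounding the percentiles.

## Behavior

Wheel breaks are samples where $|dV|$ of the optoswitch voltage exceeds
its mean by two standard deviations (a fixed 0.1 V threshold when the
s.d. is below 0.1, where the adaptive rule produces false positives);
contiguous suprathreshold samples count once, and speed is breaks/s
times the tab spacing, at 1 Hz. Tab spacing depends on wheel geometry
and must be supplied. Movement bouts are runs at ≥ 10 cm/s with gaps
≤ 2 s merged; stationary analyses exclude ±10 s around every bout.

Pupil diameter is low-pass filtered to 0.5 Hz with a zero-phase
fourth-order Butterworth (the realization is a package choice; only the
cutoff is canonical), min–max normalized to [0, 1] per recording, and
differentiated as first difference × rate with exact-zero derivatives
inheriting the previous sign. Dilation events are maximal positive-
derivative runs with total change > 10% of maximum — the threshold is
read as absolute (fraction-of-maximum units), not relative to the
pre-event diameter, matching the normalized trace the rule operates on.

## Ca²⁺ events and alignment analytics

Astrocyte event tables keep events with area > 10 µm² (the threshold is
dimensionally an area; config-exposed), duration ≥ 2 frames, and
detection p < 0.05. Population fluorescence divides each trace by its
own maximum before averaging, bounding the result in [0, 1] for
nonnegative input. Neuronal events are deconvolved amplitudes
> 3 s.d. above the mean.

Cross-correlations z-score both traces, resample to a common 10 or
30 Hz by linear interpolation (the resampling method is a package
choice), NA-pad unequal lengths, and correlate pairwise-complete per
lag; lags with fewer than 10 valid pairs are undefined. The sign
convention is that a negative peak lag means the first argument leads.
Phasic NE peaks are local maxima with topographic prominence ≥ 1
trace-s.d.; the amplitude class is the floor of the prominence in s.d.
units and duration is width at half prominence, linearly interpolated.

Photometry preprocessing removes bleaching by linear detrend, z-scores,
then low-passes with a zero-phase Hamming-window FIR (2 Hz cutoff,
0.5 Hz transition sets the order at 3.3·rate/0.5 taps). A numerically
exact ramp detrends to zero and stays zero instead of having
floating-point residue amplified by the z-score. Startle onsets come
from a four-parameter logistic fit (Levenberg–Marquardt); the onset is
the earliest local extremum of the fitted curve's analytic fourth
derivative before the midpoint. That extremum sits at a fixed position
$u^* \approx -3.14$ in the dimensionless argument $u = k(t - t_0)$, so
the onset is $t_0 + u^*/k$ — deterministic given the fit, noise-free by
construction. Which fourth-derivative feature constitutes "the onset" is
genuinely open; the earliest pre-midpoint extremum is the most
conservative choice (farthest upstream feature that is still a local
landmark of the rise).

## Spectral estimation

All spectral estimates use DPSS (Slepian) multitapers computed from the
symmetric tridiagonal form of the concentration problem — exact up to
1200 samples, spline-interpolated from a 1024-point solution and
re-orthonormalized beyond that (concentration error is negligible at the
time-bandwidth products used here). Tapers have unit energy, and
one-sided PSDs satisfy Parseval: band-integrated power equals
time-domain variance (0.02% on a pure tone).

Parameter sets follow the conventions of the analyses they serve: band
power uses time-bandwidth 2.5 with 2 tapers over 5 s moving windows
(non-overlapping by default; the step is configurable since overlap is
unstated), LF = 2–7 Hz (the running-evoked 7–10 Hz band is excluded by
band definition, not by masking samples), HF = 70–100 Hz. Full spectra
use time-bandwidth 6 with 8 tapers; total power sums all bins and
relative band power uses half-open bands so a partition sums to exactly
one. Sensor spectra cut the trace into 10 min segments (median-padded),
use time-bandwidth 3 with 5 tapers, report [3×10⁻³, 0.9] Hz (clipped to
Nyquist with a warning), and fit a power-law exponent by OLS on log
power vs log frequency excluding the lowest resolvable bin.

LFP preprocessing subtracts the best-fit line and applies a zero-phase
second-order IIR notch at 60 Hz with 2 Hz bandwidth (realization is a
package choice; only "60 Hz noise was removed" is canonical). A 5 Hz
tone passes with < 1 dB loss.

Event-triggered spectrograms take the median across events at each
(time, frequency) bin — the median, not the mean, is used for
spectrograms throughout — then divide each frequency row by its own
median over the window, making the per-frequency median exactly 1 and
the result dimensionless and scale-invariant. Event windows are sliced
from one precomputed whole-recording spectrogram on a fixed grid
(alignment jitter ≤ half the spectrogram step), which makes
shuffled-onset nulls cheap: 200 null draws reuse the same grid.

## Arousal principal component

PCA runs on the z-scored cells × frames matrix; each PC time course and
the pupil are resampled to 10 Hz and the PC with maximal |Pearson r|
against pupil diameter is the arousal PC. PC sign is arbitrary, so it is
fixed by positive pupil correlation; the trace is normalized by its
absolute maximum (absolute, so predominantly negative traces are handled
sensibly). Event responses are window-median-normalized and averaged
over the event period shifted by two frames, the lag of the
arousal-associated neuronal response.

## Resampling statistics

The hierarchical bootstrap resamples with replacement at every nesting
level — mice, recordings within each sampled mouse, observations within
each sampled recording (a depth flag can stop at recordings, since the
canonical depth is unstated). For two conditions the statistic is the
difference of means, each arm resampled within its own hierarchy. The
one-sided p-value is the proportion of resamples whose statistic
contradicts the tested direction, floored at 1/n_resamples (p = 0 is
never reported). `direction = "auto"` takes the direction from the
observed sign — convenient for exploration, but effectively two-sided
with doubled error; a confirmatory test should declare the direction.
Calibration: over 1000 simulated null cohorts (5 mice × 4 recordings ×
20 observations, recording-level variability dominating animal identity
as is typical for repeated imaging sessions), the one-sided type-I error
at α = 0.05 is ≈ 0.05–0.06; with few top-level clusters the bootstrap-t
behavior makes `auto` roughly double that, which is why the calibration
contract is stated one-sided.

The paired treatment-effect bootstrap resamples the treatment arm's
per-recording differences 10⁴ times; the p-value is the proportion of
resampled mean differences that fail to pass the observed control-arm
extreme (below the maximum for increases, above the minimum for
decreases) — the control extremes are fixed observed bounds, not
re-resampled, reading the procedure literally.

Shuffled-onset nulls draw uniform onsets with an edge margin equal to
the analysis half-window (circular shifting of the true onsets is
offered as an alternative); null distributions are invariant in
distribution to circular shifts of the underlying signal.

## The synthetic-session generator

`simulate_session()` plants the causal chain the analyses are meant to
expose: movement bouts (Poisson, ≥ 15 s apart, 2–6 s long) evoke pupil
dilations; spontaneous stationary dilations occur at 1.5/min; every
dilation (plus independent extras up to `ne_phasic_rate`) triggers a
phasic NE transient in one of three amplitude classes (1/2/3 s.d.) whose
decay constants grow with class (3.5/5/6.5 s), on top of 1/f^β tonic NE
(β defaults to 0.95); astrocyte events follow NE onsets by
`astro_lag_s` (default 2 s) with probability 0.9; HF→LF cortical state
transitions are planted at a configurable fraction of astrocyte event
times, with LF→HF recoveries at random times in between, so every
HF→LF transition is event-locked. The LFP is band-limited noise carriers
(2–7 and 70–100 Hz) gated by state (LF epochs: 30/4 µV; HF epochs:
8/12 µV) over a 1/f background, with gain switches smoothed over 0.25 s.
Astrocyte Ca²⁺ kernels rise in 1 s and decay in 3.5 s, close enough in
centroid to the NE kernels that the NE→astrocyte cross-correlation peak
falls within half a second of the planted lag.

The optional pixel movie uses vascular pixels (10% of the field, as a
contiguous block) with constant low fluorescence and top-of-range gain;
other pixels couple to z-scored NE at 8% per s.d. with per-pixel
strength. The attenuation time course is 0.05–0.5 Hz band-limited noise
at exponent s.d. 0.3 plus movement-locked dips of 0.25 — a conspicuous
artifact, consistent with the motivation for correcting at all — and
additive noise s.d. 0.6 puts single-pixel SNR near 10.

What passing recovery tests shows: the pipeline inverts its own
generative model, ranks pixel gains correctly under realistic noise, and
the analytics recover planted lags, exponents, loadings and state
transitions at the stated tolerances. What it does not show: robustness
to motion, out-of-plane fluorescence, nonstationary vessel geometry,
non-multiplicative (excitation-side) hemodynamics, or indicator
kinetics, none of which the generator emulates; the attenuation time
course itself is a stand-in, since no quantitative model of vascular
fluctuations is established.

## Problem sizes

Recovery tests run on 100–200 pixel movies of 1,400–2,000 frames,
10–20 min sessions, and 200-cohort calibration studies — sizes chosen so
the full suite and the acceptance script each complete in a couple of
minutes on one CPU while leaving every effect size far from its
tolerance boundary.
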