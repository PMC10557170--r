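---
title: "Sleep spindle metrics and simulated clinical-trial power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep spindle metrics and simulated clinical-trial power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindlepower)
```

## The scientific question

Sleep spindles are brief (0.5–2 s) bursts of 10–16 Hz ("sigma") oscillatory
activity that mark stage-2 NREM sleep. Because spindles occupy only a few
percent of NREM2 time — typically under two events per minute — summary
metrics computed over *all* of NREM2 (sigma band power, or C3–C4 sigma
coherence) dilute whatever signal the spindles carry. A study that tracks a
longitudinal change in spindle physiology with whole-stage sigma metrics may
therefore need far more subjects than one that first isolates the spindles
with an automated detector and computes the same metrics over the detected
segments only.

`spindlepower` implements the full chain needed to quantify that trade-off:

1. a synthetic sleep-EEG cohort generator with known ground truth,
2. preprocessing (zero-phase band-pass, NREM2 segmentation, Hjorth-based
   artifact screening),
3. a Morlet-wavelet spindle detector,
4. multitaper sigma power and epoch-averaged C3–C4 coherence, computed over
   all NREM2 and over detected-spindle segments,
5. a subsampled simulated-clinical-trial engine that estimates, for each
   metric, the sample size needed to demonstrate a paired decline.

## Metric definitions

All spectral metrics live in the sigma band, 10–16 Hz. Recordings are
band-pass filtered 0.3–35 Hz and split into 10-s analysis windows tiled over
NREM2-scored 30-s epochs. For channels $x =$ C3 and $y =$ C4, multitaper
auto- and cross-spectral densities $S_{xx}, S_{yy}, S_{xy}$ are estimated per
window with Slepian tapers (half-bandwidth 1 Hz, i.e. time–bandwidth product
$NW = 10$ and 19 tapers for a 10-s window), and coherence is the magnitude of
the *epoch-averaged* cross-spectrum,

$$C(f) = \frac{\left|\mathrm{E}[S_{xy}(f)]\right|}
              {\sqrt{\mathrm{E}[S_{xx}(f)]\,\mathrm{E}[S_{yy}(f)]}},$$

averaged over the sigma band. Identical channels give exactly 1, and the
magnitude makes the estimate invariant to a polarity flip. "NREM2 sigma"
power/coherence uses every artifact-free 10-s NREM2 window; "spindle sigma"
uses the merged union of detected spindle intervals as the analysis windows
instead. Only this interval-restricted reading can produce the order-of-
magnitude power contrast that ~1-s spindles embedded in 10-s windows imply;
using the *containing* windows would cap the contrast near the spindle duty
cycle. A recording with no detected spindles yields missing (not zero)
spindle metrics, and missingness propagates through cohort summaries.

## The spindle detector

The detector follows the standard wavelet recipe with its published default
parameters: a complex Morlet wavelet centred at $f_c = 13.5$ Hz with 7
cycles, magnitude-squared coefficients smoothed by a 0.1-s moving average,
a core threshold of $4.5\times$ the mean smoothed power over artifact-free
NREM2, an extent (boundary) threshold of $2\times$ that mean, events merged
when separated by less than 0.5 s, durations confined to $[0.5, 3]$ s, and a
spectral quality score

$$q = \log_2 \frac{(\text{event sigma}/\text{event broadband})}
                  {(\text{baseline sigma}/\text{baseline broadband})}$$

with events below $q = 0$ discarded. A candidate event is a maximal
supra-boundary run containing at least one supra-core sample; the two-level
rule matters because a Hann-enveloped burst spends only ~60% of its duration
above a single $4.5\times$ threshold, so a single-threshold detector
systematically truncates events and misses those shorter than about 0.75 s.
With the boundary rule the detector recovers over 90% of injected events at
an envelope SNR of 5 with zero observed false discoveries (the acceptance
suite verifies both).

Artifact screening computes Hjorth activity (on a log scale), mobility and
complexity per scored 30-s epoch and channel, flags epochs deviating more
than 3 SD from the across-epoch mean on any parameter, and iterates twice
with flagged epochs removed from the reference statistics; 10-s analysis
windows inherit their 30-s epoch's flag. Three SD is the usual convention
for this iterated screen; at 2 SD the union over two channels, three
parameters and two iterations flags over 10% of perfectly clean recordings,
which would contradict the screen's purpose.

## The synthetic cohort generator

The generator is first-class, tested code: every downstream stage is
validated against its ground truth.

**Background.** Each channel is a weighted sum of a shared and a private
1/f-shaped noise source (weights $\sqrt{w}$ and $\sqrt{1-w}$ with $w$ the
background coherence — for stationary sources this yields population
coherence $w$ exactly), plus an independently generated slow-wave (delta)
component with a steep roll-off above 3 Hz. Two slow log-normal amplitude
envelopes (SD 0.15 for the broadband part, 0.4 for the slow-wave part,
control points every 30 s, shared across channels so coherence is
untouched) make the background realistically non-stationary between epochs.
This matters: with an epoch-stationary background the between-epoch variance
of every Hjorth parameter collapses toward zero and the artifact screen
would flag exactly the spindle-bearing epochs as outliers. The 1/f amplitude
profile is flattened below 0.5 Hz so that drift the 0.3 Hz high-pass removes
anyway does not dominate the nominal RMS.

**Spindles.** Events arrive as a Poisson process at the configured density
within N2 intervals, with duration $\sim U(0.5, 2)$ s and carrier
$\sim U(13, 14)$ Hz centred on the detector's default $f_c$. Each event is a
Hann-windowed sinusoid injected into both channels; the C4 copy is
phase-shifted by a per-event offset $\delta \sim N(0, -2\ln\rho)$, so the
population coherence over spindle segments is
$|\mathrm{E}[e^{i\delta}]| = \rho$ exactly while the envelope amplitude
stays exactly at its nominal value on both channels. An alternative —
mixing a shared and a private sinusoid with $\sqrt{\rho}$ weights — gives
the same population coherence but makes each event's amplitude depend on
the random phase difference between the two sources, ranging from
near-cancellation to constructive doubling; that destroys any notion of a
controlled envelope SNR, so the phase-offset construction is used for the
deterministic bursts (the stochastic background keeps the weight-mixing
construction, where random amplitudes are exactly what is wanted).

**Paired cohorts.** Subject-level parameters are jittered around a template
(15% CV on density and amplitude; ±0.03 on coherences; ages Normal with SD
8 years, truncated at 40; follow-up intervals Uniform 3–8 years). Each
visit's spindle and background coherences additionally receive independent
night-to-night jitter (SD 0.04 by default). This term is essential to
emulating a longitudinal study honestly: recordings taken years apart
differ in electrode placement and physiological state, so paired metric
differences in real cohorts carry biological visit-to-visit variability on
top of estimator noise. Without it the spindle-restricted metric is
penalised by its larger estimator variance alone, while the whole-stage
metric — which inherits background variability in reality — looks
artificially stable. The only systematic visit effect is the configured
spindle-coherence decline, floored at zero.

**What the generator does not emulate:** K-complexes, arousals,
slow-oscillation coupling, ECG interference, apnea-related fragmentation,
or realistic sleep-architecture statistics beyond NREM2 coverage (the
hypnogram generator uses fixed-order stage cycles with gamma-distributed
durations, aiming only for plausible N2 fractions). Passing tests therefore
show that the *analysis chain* is correct and well-calibrated under
controlled conditions, not that the detector's sensitivity or the metric
contrasts will take the same numerical values on clinical recordings.

## The trial simulator

For a paired cohort table and sample size $n$, each replicate draws $n$
subjects *without replacement* (subsampling, not bootstrap), applies a
two-sided paired t-test at $\alpha = 0.05$ to the baseline-minus-follow-up
differences, and power is the fraction of significant replicates, with
Monte-Carlo standard error $\sqrt{\hat p(1-\hat p)/R}$. The desk default is
$R = 10{,}000$ replicates (MC SE ≤ 0.005); $10^5$ is available where
large-study precision is wanted. All-zero differences count as $p = 1$
(conservative). The independent oracle is the closed-form noncentral-t
power with noncentrality $d\sqrt{n}$ and $n-1$ degrees of freedom; the test
suite requires agreement within two Monte-Carlo standard errors across a
$(d, n)$ grid, and type-I calibration within $[0.04, 0.06]$ under a null
cohort. Replicate streams are seeded per (design seed, $n$), so every grid
point is reproducible in isolation and grid points can run in any order or
in parallel; within a grid point replicates are drawn sequentially from the
seeded stream. The minimal sample size is the smallest grid $n$ whose
estimated power reaches the target (default 95%); an unreachable target is
an explicit error, never a silent extrapolation.

## The benchmark cohort

`benchmark_cohort_config()` fixes the desk-scale conditions under which the
package demonstrates the headline ordering — that spindle-restricted
coherence needs fewer trial subjects than NREM2-wide coherence to detect a
decline confined to spindles: 32 subjects, 15 minutes of condensed NREM2
per visit (only NREM2 is analysed, so the recordings contain just that
stage), density 2/min, spindle amplitude equal to the background RMS,
background coherence 0.45, spindle coherence 0.62 declining by 0.28 at
follow-up. Relative to a multi-year epidemiological drift the decline is
deliberately scaled up, for the same reason the cohort is scaled down: with
32 subjects and quarter-hour recordings, a realistic 0.04 decline would sit
far below both metrics' noise floors and every power curve would be flat.
The scaled conditions preserve the structural facts the comparison depends
on — the NREM2-wide metric sees the decline diluted by the background's
share of sigma energy while inheriting the background's night-to-night
variability, and the spindle metric sees the full decline with higher
estimator variance — and the acceptance suite requires the spindle metric
to dominate the power curve and reach 95% power at a strictly smaller
sample size in at least 19 of 20 independently seeded cohorts
(sample-size grid 4–32 in steps of 4, 2,000 replicates per point).

## Numerical choices and degenerate inputs

- Multitaper windows share one zero-padded frequency grid (the smallest
  5-smooth length at or above the longest window) so variable-length
  spindle segments average per frequency; PSDs are scaled so the integral
  over frequency recovers signal variance (verified by a white-noise
  Parseval test). Spindle segments shorter than the nominal window widen
  their bandwidth so at least $NW = 3$ (5 tapers) is always averaged.
- Slepian tapers come from the symmetric tridiagonal eigenproblem, cached
  per (length, bandwidth, taper count) for the session.
- The band-pass is a zero-phase Butterworth cascade (2nd-order high-pass at
  0.3 Hz, 4th-order low-pass at 35 Hz, each run forward-backward);
  timestamps are never phase-shifted, the 13.5 Hz passband error is below
  1%, and 50 Hz mains is attenuated by more than 20 dB at 250 Hz sampling.
- Time is always seconds from recording start; intervals are half-open;
  epoch indices are 0-based; partial trailing 30-s epochs are dropped.
- Degenerate statistics follow conservative conventions: zero-variance
  differences give $p = 1$ (or 0 when the mean is nonzero), fewer than
  three epochs skip artifact screening with a warning, an empty detector
  baseline and a zero spectral denominator are errors.
- EDF output is 16-bit with per-channel physical scaling in microvolts and
  1-s records; quantisation error is bounded by the channel range divided
  by $2^{16}$.

## Known limitations

- ECG interference subtraction is not implemented; on real recordings with
  strong cardiac artifact the detector baseline will be inflated.
- The detector implements the wavelet pipeline's primary options only; no
  slow/fast spindle subtyping, slow-oscillation coupling, or chirp
  analysis.
- Sigma power is absolute, not relative to broadband power.
- The trial engine models exactly the published design — paired t-tests on
  per-subject metric means with no covariate adjustment and no
  multiple-testing correction across the sample-size grid.
- Reproducing the source study's numerical results (minimum sample sizes of
  60 vs 115, mean coherences, 0.02/0.04 declines) requires the original
  multi-thousand-subject polysomnography cohort, which is distributed under
  a data-use agreement; this package ships the machinery and a synthetic
  stand-in, not those data.
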