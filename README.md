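# spindlepower

Sleep-spindle metrics for clinical-trial design: wavelet spindle detection,
sigma power and C3–C4 coherence over NREM2 sleep EEG, and subsampled
simulated-trial power analysis — with a synthetic cohort generator so the
whole chain runs and tests without access to clinical polysomnography data.

## The problem

Sleep spindles are 0.5–2 s bursts of 10–16 Hz ("sigma") EEG activity, the
hallmark of stage-2 NREM sleep, and a candidate biomarker in aging,
psychiatric and drug studies. Spindle activity is often summarized by sigma
band power or inter-hemispheric sigma coherence computed over *all* of
NREM2 — but spindles occupy only a few percent of NREM2 (typically under
two per minute), so whole-stage averages dilute the signal. This package
quantifies the consequence for study design: given a paired (baseline /
follow-up) decline in spindle coherence, how many subjects does a trial
need to detect it with sigma metrics computed over all NREM2, versus the
same metrics restricted to automatically detected spindles?

## What it computes

* **Detection** — complex Morlet wavelet power at `fc = 13.5` Hz (7 cycles),
  smoothed 0.1 s; events are maximal runs above `2×` the mean NREM2 power
  containing a sample above `4.5×`, merged across gaps `< 0.5` s, kept for
  durations in `[0.5, 3]` s and sigma-enrichment quality `q ≥ 0`.
* **Spectral metrics** — multitaper (Slepian, half-bandwidth 1 Hz) PSD/CSD
  on 10-s NREM2 windows; sigma power `∫₁₀¹⁶ S(f) df` and epoch-averaged
  magnitude coherence
  `C = |E[S_C3C4]| / √(E[S_C3C3]·E[S_C4C4])`,
  band-averaged over 10–16 Hz; both computed per recording over all NREM2
  ("NREM2 sigma") and over merged detected-spindle intervals
  ("spindle sigma").
* **Trial power** — for each metric, repeated subsampling of `n` subjects
  without replacement, a two-sided paired t-test at α = 0.05 per replicate,
  power = significant fraction; validated against closed-form noncentral-t
  power (`ncp = d√n`, `df = n − 1`); minimal `n` reaching 95% power.
* **Synthesis** — paired cohorts of two-channel (C3/C4) EDF recordings:
  1/f background with controllable inter-channel coherence and slow
  amplitude modulation, Hann-windowed spindle bursts with exactly
  controllable coherence and amplitude, hypnograms, and ground-truth event
  tables.

## Worked example

Simulate a small paired cohort in which spindle coherence declines between
visits, analyze it, and compare the sample sizes the two coherence metrics
would need in a trial:

```r
library(spindlepower)

cfg <- benchmark_cohort_config(seed = 1)   # 32 subjects, condensed NREM2
cohort  <- generate_paired_cohort(cfg$cohort, cfg$template)
metrics <- analyze_cohort(cohort)          # filter, detect, measure

design <- trial_design(n_grid = seq(4, 32, 4), reps = 2000, seed = 1)
cv_n2 <- power_curve(metrics_to_paired(metrics, "n2_sigma_coherence"),
                     design, "NREM2 sigma coherence")
cv_sp <- power_curve(metrics_to_paired(metrics, "spindle_sigma_coherence"),
                     design, "spindle sigma coherence")
summary(cv_n2)
summary(cv_sp)
```

```
Power curve for 'NREM2 sigma coherence' (alpha = 0.05, 2000 reps)
Smallest n with power >= 0.95: 32
Power curve for 'spindle sigma coherence' (alpha = 0.05, 2000 reps)
Smallest n with power >= 0.95: 8
```

The decline was injected only into the spindles, and the spindle-restricted
metric demonstrates it with a quarter of the subjects: averaging sigma
coherence over all of NREM2 dilutes the change with background activity
(which also fluctuates night to night), while the detector-restricted
metric sees it undiluted. `plot(cv_sp, cv_n2)` draws both curves with
Monte-Carlo error bars. Per-recording detail is in `metrics`
(`spindle_density`, `n2_sigma_power`, `spindle_sigma_power`, both
coherences); on these synthetic conditions sigma power inside spindle
segments runs roughly 20-fold above the NREM2-wide average, matching the
scale of contrast reported for large clinical cohorts.

A file-based pipeline with the same stages (EDF in, TSV/CSV/JSON out) is
available via `run_simulate()`, `run_detect()`, `run_metrics()`,
`run_trial_power()` / `run_pipeline()` with a YAML config, or from the
shell through the thin CLI at `inst/cli/spindlepower`. Real recordings can
enter through `read_edf()` + `read_hypnogram_csv()`.

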