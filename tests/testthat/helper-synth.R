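# shared fixtures, all generated in code

# two-channel recording with given sinusoid frequencies (or 0 for silence)
sine_recording <- function(f3, f4, fs = 125, dur = 10, amp = 1) {
  t <- seq(1 / fs, dur, by = 1 / fs)
  mk <- function(f) if (f > 0) amp * sin(2 * pi * f * t) else rep(0, length(t))
  eeg_recording(cbind(C3 = mk(f3), C4 = mk(f4)), fs = fs)
}

# condensed all-N2 hypnogram of `minutes` minutes
n2_hypnogram <- function(minutes) hypnogram(rep("N2", minutes * 2))

# default synthetic study recording: SNR 5 spindles at 2/min in pure N2
default_study_recording <- function(seed, minutes = 10) {
  synthesize_recording(subject_spec(), n2_hypnogram(minutes), seed = seed)
}

# paired channels built by source mixing: population coherence ~ rho
mixed_noise_recording <- function(rho, n_epochs, seed, fs = 125, epoch_s = 10) {
  n <- n_epochs * epoch_s * fs
  set.seed(seed)
  sh <- spindlepower:::pink_noise(n, fs)
  p1 <- spindlepower:::pink_noise(n, fs)
  p2 <- spindlepower:::pink_noise(n, fs)
  eeg_recording(cbind(C3 = sqrt(rho) * sh + sqrt(1 - rho) * p1,
                      C4 = sqrt(rho) * sh + sqrt(1 - rho) * p2), fs = fs)
}

epoch_grid <- function(n_epochs, epoch_s = 10) {
  cbind((0:(n_epochs - 1)) * epoch_s, (1:n_epochs) * epoch_s)
}
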