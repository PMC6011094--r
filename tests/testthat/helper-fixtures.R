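# shared fixtures: all synthetic, generated at test time

clean_record <- function(heart_rate_bpm = 75, duration_s = 30, seed = 3,
                         hr_jitter_frac = 0.02, fs = 300) {
  generate_clean(synth_spec(fs = fs, duration_s = duration_s,
                            heart_rate_bpm = heart_rate_bpm,
                            hr_jitter_frac = hr_jitter_frac, seed = seed))
}

noisy_record <- function(amps, heart_rate_bpm = 80, seed = 11, ...) {
  sp <- synth_spec(heart_rate_bpm = heart_rate_bpm,
                   noise_amplitudes = amps, seed = seed, ...)
  add_noise(generate_clean(sp), sp)
}

tone_record <- function(freqs, amps = rep(1, length(freqs)), fs = 300,
                        duration_s = 60) {
  t <- seq(0, duration_s, by = 1 / fs)
  x <- numeric(length(t))
  for (i in seq_along(freqs)) x <- x + amps[i] * sin(2 * pi * freqs[i] * t)
  ecg_record(x, fs = fs, source_id = "tone")
}

# fraction of true R peaks recovered within +/- tol_s
detector_sensitivity <- function(peaks, true_rpeaks, fs, tol_s = 0.05) {
  tol <- tol_s * fs
  mean(vapply(true_rpeaks,
              function(r) any(abs(peaks$indices - r) <= tol), logical(1)))
}
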