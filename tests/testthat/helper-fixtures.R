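# Shared fixtures: short synthetic sessions so unit tests stay fast.
# Durations 60/90/60 s keep every epoching contract exercised; tests that
# need the LF band of the tachogram (f_low < 0.15 requires T > 80 s) use
# 120/180/120 s.

short_durations <- c(pre = 60, mti = 90, post = 60)
hrv_durations <- c(pre = 120, mti = 180, post = 120)

make_eeg <- function(seed = 1L, mti = list(), durations = short_durations,
                     ...) {
  gen_eeg_session(eeg_effect_profile(mti = mti), durations = durations,
                  fs = 256, seed = seed, ...)
}

make_ecg <- function(seed = 1L, profile = autonomic_profile(),
                     durations = hrv_durations, noise_sd = 0.02) {
  gen_ecg_session(profile, durations = durations, fs = 256, seed = seed,
                  noise_sd = noise_sd)
}

make_emg <- function(seed = 1L, profile = emg_profile(),
                     durations = short_durations) {
  gen_emg_session(profile, durations = durations, fs = 512, seed = seed)
}

# sine of exactly n samples
sine_wave <- function(freq, fs, dur_s, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * (0:(round(dur_s * fs) - 1L)) / fs + phase)
}
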