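test_that("generators are pure functions of profile and seed", {
  expect_identical(make_eeg(seed = 31)$recording$data,
                   make_eeg(seed = 31)$recording$data)
  expect_identical(make_ecg(seed = 32)$recording$data,
                   make_ecg(seed = 32)$recording$data)
  expect_identical(make_emg(seed = 33)$recording$data,
                   make_emg(seed = 33)$recording$data)
  expect_false(identical(make_eeg(seed = 31)$recording$data,
                         make_eeg(seed = 32)$recording$data))
  # the global RNG stream is left untouched
  set.seed(99); before <- .Random.seed
  invisible(make_eeg(seed = 31))
  expect_identical(.Random.seed, before)
})

test_that("generated EEG band powers match the requested multipliers within 10%", {
  prof <- eeg_effect_profile(mti = list(O1 = c(Alpha = 2), T3 = c(Delta = 0.5)))
  g <- gen_eeg_session(prof, durations = short_durations, fs = 256, seed = 41)
  fs <- 256
  seg <- g$segmentation
  measure <- function(ch, band, period) {
    idx <- marphysio:::interval_sample_idx(seg[[period]], fs,
                                           ncol(g$recording$data))
    band_power(welch_psd(g$recording$data[ch, idx], fs, seg_length = 2),
               band)
  }
  base <- c(Delta = 40, Theta = 20, Alpha = 15, SlowBeta = 8, FastBeta = 5)
  expect_equal(measure("O1", c(8, 12), "pre"), base[["Alpha"]],
               tolerance = 0.1 * base[["Alpha"]])
  expect_equal(measure("O1", c(8, 12), "mti"), 2 * base[["Alpha"]],
               tolerance = 0.1 * 2 * base[["Alpha"]])
  expect_equal(measure("T3", c(1, 4), "mti"), 0.5 * base[["Delta"]],
               tolerance = 0.1 * 0.5 * base[["Delta"]])
  expect_equal(measure("C4", c(18, 30), "mti"), base[["FastBeta"]],
               tolerance = 0.1 * base[["FastBeta"]])
})

test_that("EEG profiles reject unknown channels, bands and non-positive multipliers", {
  expect_error(eeg_effect_profile(mti = list(Pz = c(Alpha = 2))),
               "unknown channel")
  expect_error(eeg_effect_profile(mti = list(O1 = c(Gamma = 2))),
               "unknown band")
  expect_error(eeg_effect_profile(mti = list(O1 = c(Alpha = 0))), "> 0")
})

test_that("a quiet autonomic profile produces a constant R-R series", {
  prof <- autonomic_profile(pre = list(mean_rr = 800, a_lf = 0, a_hf = 0,
                                       jitter = 0))
  g <- gen_ecg_session(prof, durations = c(pre = 60, mti = 60, post = 60),
                       fs = 256, seed = 51, noise_sd = 0.001)
  expect_true(all(abs(g$true_rr - 800) < 1e-9))
  tg <- clean_rr(tachogram(detect_r_peaks(
    bandpass(g$recording$data[1, ], 1, 40, fs = 256), 256)))
  td <- time_domain_hrv(tg)
  expect_lt(td$STDRR, 3)                      # grid quantization only
  expect_equal(td$pRR50, 0)
})

test_that("HF-dominant modulation is recovered as LF/HF below one", {
  prof <- autonomic_profile(pre = list(mean_rr = 800, a_lf = 5, a_hf = 60,
                                       jitter = 2))
  g <- gen_ecg_session(prof, durations = c(pre = 300, mti = 60, post = 60),
                       fs = 256, seed = 52, noise_sd = 0.01)
  tg <- clean_rr(tachogram(detect_r_peaks(
    bandpass(g$recording$data[1, ], 1, 40, fs = 256), 256)))
  expect_lt(spectral_lf_hf(tg, c(0, 300))$LF_HF, 1)
})

test_that("autonomic profiles that could leave the physiologic RR range are rejected", {
  expect_error(autonomic_profile(pre = list(mean_rr = 200, a_lf = 0,
                                            a_hf = 0, jitter = 0)),
               "profile")
  expect_error(autonomic_profile(pre = list(mean_rr = 800, a_lf = 400,
                                            a_hf = 200, jitter = 10)),
               "profile")
  expect_error(emg_profile(centroid = c(pre = 10, mti = 100, post = 100)),
               "analysis band")
})

test_that("EMG generator controls centroid and RMS per period", {
  prof <- emg_profile(centroid = c(pre = 110, mti = 110, post = 110),
                      rms = c(pre = 5, mti = 5, post = 5))
  g <- gen_emg_session(prof, durations = short_durations, fs = 512, seed = 61)
  s <- emg_session_summary(g$recording, g$segmentation)
  z <- s$features$value[s$features$feature == "rms_z" &
                          s$features$period != "pre"]
  expect_lt(max(abs(z)), 0.5)
  # per-period RMS is exact by construction
  seg <- g$segmentation
  for (p in c("pre", "mti", "post")) {
    idx <- marphysio:::interval_sample_idx(seg[[p]], 512,
                                           ncol(g$recording$data))
    expect_equal(epoch_rms(g$recording$data[1, idx]), 5, tolerance = 1e-6)
  }
  expect_error(gen_emg_session(prof, fs = 256), "gate")
})
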