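test_that("band-pass rejects DC, preserves passband, attenuates stopband", {
  fs <- 256
  # the slow 1-Hz high-pass transient needs ~10 s to decay below 1e-6
  dc <- rep(5, 30 * fs)
  y <- bandpass(dc, 1, 30, fs = fs)
  trim <- (10 * fs):(20 * fs)
  expect_lt(max(abs(y[trim])), 1e-6 * 5)
  # 10 Hz inside 1-30 Hz passes within 1%
  x10 <- sine_wave(10, fs, 30)
  y10 <- bandpass(x10, 1, 30, fs = fs)
  amp <- max(abs(y10[trim]))
  expect_equal(amp, 1, tolerance = 0.01)
  # 60 Hz attenuated by >= 40 dB
  x60 <- sine_wave(60, fs, 30)
  y60 <- bandpass(x60, 1, 30, fs = fs)
  expect_lt(max(abs(y60[trim])), 10^(-40 / 20))
  expect_error(bandpass(x10, 1, 200, fs = fs), "filter-design")
})

test_that("filters are zero-phase", {
  fs <- 256
  x <- sine_wave(8, fs, 8)
  y <- bandpass(x, 1, 30, fs = fs)
  cc <- ccf(y, x, lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("notch comb removes mains and harmonics, preserves neighbours", {
  fs <- 512
  expect_equal(notch_frequencies(60, 200, 512), c(60, 120, 180))
  x60 <- sine_wave(60, fs, 10)
  y60 <- notch_comb(x60, base = 60, up_to = 200, fs = fs)
  trim <- fs:(9 * fs)
  expect_lt(sqrt(mean(y60[trim]^2)), 0.03 * sqrt(mean(x60[trim]^2)))
  x100 <- sine_wave(100, fs, 10)
  y100 <- notch_comb(x100, base = 60, up_to = 200, fs = fs)
  expect_equal(max(abs(y100[trim])), 1, tolerance = 0.02)
})

test_that("artifact masks drop exactly the overlapping epochs", {
  g <- make_eeg(seed = 5)
  rec <- g$recording
  # empty mask leaves the recording unchanged
  rec0 <- apply_artifact_mask(rec, artifact_mask())
  expect_equal(rec0$data, rec$data)
  all_starts <- marphysio:::clean_epoch_starts(c(0, 60), 3, 1.5, NULL)
  # one 3-s bad span: exactly the epochs overlapping [12, 15) are dropped
  m <- artifact_mask(12, 3, "all")
  kept <- marphysio:::clean_epoch_starts(c(0, 60), 3, 1.5, m)
  dropped <- setdiff(all_starts, kept)
  expect_equal(sort(dropped), c(10.5, 12, 13.5))
  # enumeration oracle: an epoch [s, s+3) overlaps [12, 15) iff s in (9, 15)
  expect_true(all(dropped > 12 - 3 & dropped < 15))
  expect_true(all(kept <= 9 | kept >= 15))
  # channel-specific spans only affect that channel
  mc <- artifact_mask(12, 3, "O1")
  expect_length(marphysio:::clean_epoch_starts(c(0, 60), 3, 1.5, mc, "Fp1"),
                length(all_starts))
  # full-recording mask -> empty period downstream
  full <- artifact_mask(0, 210, "all")
  expect_error(
    eeg_band_power_series(apply_artifact_mask(rec, full), g$segmentation),
    "empty-period")
  expect_error(apply_artifact_mask(rec, artifact_mask(200, 100, "all")),
               "outside")
})

test_that("automatic artifact detection flags pulses and nothing else", {
  for (s in 1:3) {
    g <- make_eeg(seed = s, durations = c(pre = 20, mti = 30, post = 20))
    rec <- bandpass(g$recording, 1, 30)
    expect_equal(nrow(auto_artifact_mask(rec, z_threshold = 5)), 0)
  }
  g <- make_eeg(seed = 9, durations = c(pre = 20, mti = 30, post = 20))
  rec <- g$recording
  rec$data["C3", (35 * 256):(35 * 256 + 50)] <- 500   # injected pulse
  m <- auto_artifact_mask(rec, z_threshold = 5)
  expect_true(any(m$channel == "C3" & m$onset <= 35 & m$onset + m$duration > 35))
  expect_equal(nrow(auto_artifact_mask(rec, z_threshold = Inf)), 0)
})

test_that("ocular component removal cleans frontal blinks and spares occipital alpha", {
  g <- make_eeg(seed = 11, blink_rate = 0.25)
  rec <- bandpass(g$recording, 1, 30)
  blink_band <- function(r, ch) {
    band_power(welch_psd(r$data[ch, ], 256, seg_length = 4), c(0.5, 4))
  }
  alpha_o1 <- function(r) {
    band_power(welch_psd(r$data["O1", ], 256, seg_length = 2), c(8, 12))
  }
  out <- remove_ocular_component(rec, seed = 2)
  expect_true(attr(out, "ocular_removed"))
  expect_lt(blink_band(out, "Fp1") / blink_band(rec, "Fp1"), 0.5)
  expect_lt(abs(alpha_o1(out) / alpha_o1(rec) - 1), 0.05)
  # a second pass finds no blink component
  out2 <- remove_ocular_component(out, seed = 2)
  expect_false(attr(out2, "ocular_removed"))
  # blink-free data: nothing removed
  g0 <- make_eeg(seed = 12)
  out0 <- remove_ocular_component(bandpass(g0$recording, 1, 30), seed = 2)
  expect_false(attr(out0, "ocular_removed"))
  expect_lt(attr(out0, "ocular_score"), 0.75)
  # channel order never changes
  expect_equal(rownames(out$data), rec$channel_labels)
})
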