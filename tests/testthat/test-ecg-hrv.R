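test_that("R peaks are recovered exactly on clean traces and robustly in noise", {
  prof <- autonomic_profile()
  g <- gen_ecg_session(prof, durations = c(pre = 60, mti = 60, post = 60),
                       fs = 256, seed = 3, noise_sd = 0.001)
  x <- bandpass(g$recording$data[1, ], 1, 40, fs = 256)
  pk <- detect_r_peaks(x, 256)
  expect_equal(length(pk), length(g$true_peaks))
  expect_lt(max(abs(pk - g$true_peaks)), 1 / 256 + 1e-9)  # within one sample
  # 10:1 SNR (1 mV QRS vs 0.1 mV noise)
  g2 <- gen_ecg_session(prof, durations = c(pre = 100, mti = 100, post = 100),
                        fs = 256, seed = 4, noise_sd = 0.1)
  x2 <- bandpass(g2$recording$data[1, ], 1, 40, fs = 256)
  pk2 <- detect_r_peaks(x2, 256)
  sens <- mean(vapply(g2$true_peaks,
                      function(tp) min(abs(pk2 - tp)) <= 0.010, logical(1)))
  prec <- mean(vapply(pk2,
                      function(p) min(abs(g2$true_peaks - p)) <= 0.010,
                      logical(1)))
  expect_gte(sens, 0.99)
  expect_gte(prec, 0.99)
  expect_error(detect_r_peaks(rep(0.3, 2560), 256), "no-peaks")
})

test_that("a flatline segment yields no spurious detections", {
  prof <- autonomic_profile()
  g <- gen_ecg_session(prof, durations = c(pre = 40, mti = 40, post = 40),
                       fs = 256, seed = 6, noise_sd = 0.02)
  x <- g$recording$data[1, ]
  x[(40 * 256):(80 * 256)] <- 0                    # lead disconnect
  pk <- detect_r_peaks(bandpass(x, 1, 40, fs = 256), 256)
  expect_equal(sum(pk > 41 & pk < 79), 0)
  expect_gt(sum(pk < 40), 30)                      # still detects elsewhere
})

test_that("R-R cleaning interpolates out-of-range runs in place", {
  tg <- tachogram(cumsum(c(0, rep(0.8, 10))))
  expect_identical(clean_rr(tg)$rr_ms, tg$rr_ms)   # all valid: unchanged
  # one long interval between 800s
  rr <- c(800, 800, 1600, 800, 800, 800, 800, 800, 800, 800)
  tg2 <- tachogram(cumsum(c(0, rr / 1000)))
  cl2 <- clean_rr(tg2)
  expect_equal(cl2$rr_ms[3], 800)
  expect_equal(sum(cl2$interpolated), 1)
  # run of invalid values: linear interpolation between flanking valid RRs
  rr3 <- c(800, 200, 1900, 800, rep(800, 16))
  tg3 <- tachogram(cumsum(c(0, rr3 / 1000)))
  cl3 <- clean_rr(tg3)
  expect_equal(cl3$rr_ms[2:3], c(800, 800))
  expect_length(cl3$rr_ms, length(rr3))            # count never changes
  expect_identical(clean_rr(cl3)$rr_ms, cl3$rr_ms) # idempotent
  # quality gate
  rr4 <- c(rep(2000, 3), rep(800, 7))
  expect_error(clean_rr(tachogram(cumsum(c(0, rr4 / 1000)))), "quality")
  expect_error(clean_rr(tachogram(c(0, 0.8, 1.6))), ">= 4")
})

test_that("time-domain features match hand-computed values", {
  const <- tachogram(cumsum(c(0, rep(0.8, 20))))
  td <- time_domain_hrv(const)
  expect_equal(td$meanRR, 800)
  expect_equal(td$STDRR, 0)
  expect_equal(td$pRR50, 0)
  alt <- tachogram(cumsum(c(0, rep(c(0.77, 0.83), 10))))
  expect_equal(time_domain_hrv(alt)$pRR50, 100)    # every difference 60 ms
  # brute-force oracle over successive differences
  rr <- c(800, 840, 850)
  tg <- tachogram(cumsum(c(0, rr / 1000)))
  oracle <- 100 * sum(abs(diff(rr)) > 50) / (length(rr) - 1)
  expect_equal(time_domain_hrv(tg)$pRR50, oracle)
  expect_equal(oracle, 0)
  expect_error(time_domain_hrv(const, window = c(0, 0.9)),
               "insufficient-data")
})

test_that("Poincare descriptors obey their algebraic identities", {
  pre_stats <- list(mean = 800, sd = 50)
  const <- tachogram(cumsum(c(0, rep(0.8, 30))))
  pc <- poincare(const, pre_stats)
  expect_equal(pc$SD1, 0)
  expect_equal(pc$SD2, 0)
  # SD1 == RMSSD / sqrt(2) exactly (population convention)
  set.seed(9)
  rr <- 800 + rnorm(300, sd = 40)
  tg <- tachogram(cumsum(c(0, rr / 1000)))
  pc2 <- poincare(tg, pre_stats)
  z <- (rr - 800) / 50
  rmssd <- sqrt(mean(diff(z)^2))
  expect_equal(pc2$SD1, rmssd / sqrt(2), tolerance = 1e-9)
  # i.i.d. series: SD1 and SD2 agree within sampling error
  expect_equal(pc2$SD1, pc2$SD2, tolerance = 0.15 * pc2$SD2)
  # variance identity: SD1^2 + SD2^2 ~ 2 Var(z) for long series
  v <- mean((z - mean(z))^2)
  expect_equal(pc2$SD1^2 + pc2$SD2^2, 2 * v, tolerance = 0.05 * 2 * v)
  expect_error(poincare(tg, list(mean = 800, sd = 0)), "degenerate-baseline")
})

test_that("tachogram spectra separate LF and HF content", {
  # single 0.25 Hz oscillation -> essentially pure HF
  prof_hf <- autonomic_profile(pre = list(mean_rr = 800, a_lf = 0, a_hf = 50,
                                          jitter = 2))
  g <- gen_ecg_session(prof_hf, durations = c(pre = 300, mti = 90, post = 90),
                       fs = 256, seed = 5, noise_sd = 0.01)
  tg <- clean_rr(tachogram(detect_r_peaks(
    bandpass(g$recording$data[1, ], 1, 40, fs = 256), 256)))
  sp <- spectral_lf_hf(tg, c(0, 300))
  expect_gte(sp$HF / (sp$LF + sp$HF), 0.95)
  # equal amplitudes at 0.1 and 0.25 Hz -> LF/HF ~ 1
  prof_eq <- autonomic_profile(pre = list(mean_rr = 800, a_lf = 30, a_hf = 30,
                                          jitter = 2))
  g2 <- gen_ecg_session(prof_eq, durations = c(pre = 300, mti = 90, post = 90),
                        fs = 256, seed = 6, noise_sd = 0.01)
  tg2 <- clean_rr(tachogram(detect_r_peaks(
    bandpass(g2$recording$data[1, ], 1, 40, fs = 256), 256)))
  sp2 <- spectral_lf_hf(tg2, c(0, 300))
  expect_equal(sp2$LF_HF, 1, tolerance = 0.1)
  # adaptive cutoff: f_low = 12 / T below 300 s
  expect_equal(spectral_lf_hf(tg2, c(0, 240))$f_low, 0.05)
  expect_equal(adaptive_f_low(240), 0.05)
  expect_equal(adaptive_f_low(600), 0.04)
  expect_error(spectral_lf_hf(tg2, c(0, 50)), "window-too-short")
  expect_error(spectral_lf_hf(tg2, c(0, 70)), "LF-undefined")
})

test_that("LF, HF and the out-of-band remainder partition total power", {
  prof <- autonomic_profile()
  g <- make_ecg(seed = 8, profile = prof,
                durations = c(pre = 200, mti = 90, post = 90))
  tg <- clean_rr(tachogram(detect_r_peaks(
    bandpass(g$recording$data[1, ], 1, 40, fs = 256), 256)))
  sp <- spectral_lf_hf(tg, c(0, 200))
  psd <- sp$psd                                    # normalized density
  below <- 100 * band_power(psd, c(0, sp$f_low))
  above <- 100 * band_power(psd, c(0.4, 2))
  expect_equal(sp$LF + sp$HF + below + above, 100, tolerance = 1e-6 * 100)
})

test_that("session HRV summaries carry the sign convention and effect directions", {
  prof <- autonomic_profile(
    pre = list(mean_rr = 800, a_lf = 45, a_hf = 18, jitter = 8),
    mti = list(mean_rr = 800, a_lf = 20, a_hf = 50, jitter = 8),
    post = list(mean_rr = 800, a_lf = 45, a_hf = 18, jitter = 8))
  g <- gen_ecg_session(prof, durations = hrv_durations, fs = 256, seed = 12,
                       noise_sd = 0.02)
  s <- hrv_session_summary(g$recording, g$segmentation)
  d <- s$deltas
  get <- function(pair, feat) d$delta[d$pair == pair & d$feature == feat]
  expect_gt(get("mti-pre", "HF"), 0)
  expect_lt(get("mti-pre", "LF"), 0)
  expect_lt(get("mti-pre", "LF_HF"), 0)
  # antisymmetry: mti-pre = -(pre-mti) = (mti-post) when post == pre profile
  feats <- unique(d$feature)
  mp <- d$delta[d$pair == "mti-pre"][match(feats, d$feature[d$pair == "mti-pre"])]
  pp <- s$features$value[s$features$period == "post"]
  pr <- s$features$value[s$features$period == "pre"]
  expect_equal(d$delta[d$pair == "post-pre"], pp - pr)
  # identical profiles in all periods -> deltas near zero
  g0 <- make_ecg(seed = 13)
  s0 <- hrv_session_summary(g0$recording, g0$segmentation)
  td0 <- s0$deltas[s0$deltas$feature %in% c("meanRR"), ]
  expect_lt(max(abs(td0$delta)), 25)
})
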