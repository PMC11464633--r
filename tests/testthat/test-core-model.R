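test_that("central_window centers, passes short periods through, and is idempotent", {
  expect_equal(unclass(central_window(c(0, 900), 15)),
               c(start = 0, end = 900))
  expect_equal(unclass(central_window(c(0, 600), 5)),
               c(start = 150, end = 450))
  # periods shorter than the target are used in their entirety
  expect_equal(unclass(central_window(c(0, 200), 5)),
               c(start = 0, end = 200))
  # off-origin, non-integer trim
  w <- central_window(c(10, 325.4), 5)
  expect_equal(unname(w[2] - w[1]), 300)
  expect_true(w[1] >= 10 && w[2] <= 325.4)
  # idempotence
  for (iv in list(c(0, 600), c(3.2, 700.7), c(0, 120))) {
    w1 <- central_window(iv, 5)
    expect_equal(unclass(central_window(w1, 5)), unclass(w1))
  }
  expect_error(central_window(c(5, 5), 5), "invalid-segmentation")
})

test_that("make_epochs produces the documented offset grid", {
  e <- make_epochs(9, 3, 1.5)
  expect_equal(as.numeric(e), c(0, 1.5, 3, 4.5, 6))
  expect_equal(as.numeric(make_epochs(3, 3, 1.5)), 0)
  # count = floor((10 - 2) / 1) + 1 = 9
  expect_length(make_epochs(10, 2, 1), 9)
  # trailing remainder discarded: last epoch ends <= duration
  e2 <- make_epochs(10.4, 3, 1.5)
  expect_true(all(as.numeric(e2) + 3 <= 10.4))
  expect_error(make_epochs(2.5, 3, 1.5), "too-short")
  expect_error(make_epochs(10, 2, 2), "overlap")
})

test_that("50%-overlap epochs cover interior samples exactly twice", {
  offs <- as.numeric(make_epochs(12, 3, 1.5))
  fs <- 10
  cover <- numeric(12 * fs)
  for (o in offs) {
    idx <- (floor(o * fs) + 1):(floor((o + 3) * fs))
    cover[idx] <- cover[idx] + 1
  }
  interior <- (3 * fs + 1):((max(offs)) * fs)  # skip boundary epochs
  expect_true(all(cover[interior] == 2))
})

test_that("recording construction enforces montage, rates and finiteness", {
  d <- matrix(rnorm(8 * 256), nrow = 8)
  rec <- recording(d, 256, "EEG", channel_labels = c("Fp1", "Fp2", "T3", "T4",
                                                     "C3", "C4", "O1", "O2"))
  expect_s3_class(rec, "recording")
  expect_equal(recording_duration(rec), 1)
  expect_error(recording(d, 128, "EEG",
                         channel_labels = rownames(rec$data)), ">= 256")
  expect_error(recording(d, 256, "EEG",
                         channel_labels = c("Fz", "Fp2", "T3", "T4",
                                            "C3", "C4", "O1", "O2")),
               "montage")
  d2 <- d; d2[3, 5] <- NaN
  expect_error(recording(d2, 256, "EEG",
                         channel_labels = rownames(rec$data)), "non-finite")
  # EMG eligibility gate is 512 Hz
  emg_lo <- recording(matrix(rnorm(300), 1), 256, "EMG")
  emg_hi <- recording(matrix(rnorm(600), 1), 512, "EMG")
  expect_false(emg_eligible(emg_lo))
  expect_true(emg_eligible(emg_hi))
})

test_that("period segmentation validates ordering and comes from labels only", {
  seg <- period_segmentation(c(0, 60), c(60, 150), c(150, 210))
  expect_s3_class(seg, "period_segmentation")
  expect_error(period_segmentation(c(0, 60), c(50, 150), c(150, 210)),
               "ordered")
  expect_error(period_segmentation(c(0, 60), c(60, 150), c(150, 210),
                                   duration = 200), "duration")
  ann <- data.frame(onset = c(0, 60, 150), duration = c(60, 90, 60),
                    label = c("pre", "Mti", "POST"))
  seg2 <- segmentation_from_annotations(ann)   # case-insensitive
  expect_equal(unclass(seg2$mti), c(start = 60, end = 150))
  expect_error(segmentation_from_annotations(ann[1:2, ]),
               "invalid-segmentation")
  # absent labels are never inferred
  ann$label <- c("baseline", "music", "after")
  expect_error(segmentation_from_annotations(ann), "invalid-segmentation")
})

test_that("band scheme must be contiguous and ordered", {
  expect_equal(band_scheme()$band,
               c("Delta", "Theta", "Alpha", "SlowBeta", "FastBeta"))
  bad <- default_bands(); bad$low[2] <- 5
  expect_error(band_scheme(bad), "contiguous")
  bad2 <- default_bands(); bad2$high[1] <- 0.5
  expect_error(band_scheme(bad2), "low must be")
})
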