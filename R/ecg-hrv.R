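# R-peak detection, R-R cleaning, and time / nonlinear (Poincare) /
# frequency (LF-HF) heart-rate-variability analysis.
#
# Conventions fixed here (and in the methods vignette):
#   * each R-R value is time-stamped at its terminating peak;
#   * STDRR uses the sample (n-1) SD; Poincare SD1/SD2 use the population
#     convention, SD1 uncentered so SD1 == RMSSD/sqrt(2) exactly;
#   * tachogram Welch: Hann, segment length min(T, 200 s) at 4 Hz, 50%
#     overlap -> 0.005-Hz grid with 0.04 / 0.15 / 0.4 Hz on-grid.

RR_MIN_MS <- 300
RR_MAX_MS <- 1500
HRV_RESAMPLE_HZ <- 4
HRV_WELCH_SEG_S <- 200

#' Detect R peaks in a band-passed ECG trace
#'
#' Derivative-energy detector: the squared derivative is integrated over a
#' 120-ms moving window; local maxima of the envelope separated by at least a
#' 250-ms refractory period and exceeding an adaptive threshold (a fraction of
#' the running median of recent accepted peak heights, with an absolute floor
#' so flatline segments yield no spurious detections) are accepted, and each
#' peak time is refined to the maximum of the trace within +/- 60 ms.
#'
#' @param x single-channel ECG, already band-passed 1-40 Hz.
#' @param fs sampling rate (Hz).
#' @param threshold_frac fraction of the running peak-height median used as
#'   acceptance threshold (default 0.4).
#' @return numeric vector of peak times (s), strictly increasing.
#' @export
detect_r_peaks <- function(x, fs, threshold_frac = 0.4) {
  stopifnot(is.numeric(x), all(is.finite(x)), fs > 0)
  if (max(x) - min(x) <= 0) stop("no-peaks: flat signal")
  d <- c(0, diff(x)) * fs
  env <- stats::filter(d^2, rep(1 / round(0.12 * fs), round(0.12 * fs)),
                       sides = 2)
  env[is.na(env)] <- 0
  env <- as.numeric(env)
  refr <- round(0.25 * fs)
  # candidate local maxima of the envelope
  n <- length(env)
  is_max <- c(FALSE, env[2:(n - 1)] >= env[1:(n - 2)] &
                     env[2:(n - 1)] > env[3:n], FALSE)
  cand <- which(is_max)
  floor_thr <- 0.02 * stats::quantile(env, 0.99, names = FALSE)
  if (floor_thr <= 0) stop("no-peaks: flat signal")
  cand <- cand[env[cand] > floor_thr]
  if (length(cand) == 0L) stop("no-peaks: nothing above threshold")
  cand <- cand[order(cand)]
  accepted <- integer(0)
  recent <- numeric(0)
  thr <- threshold_frac * stats::quantile(env[seq_len(min(n, 10 * fs))],
                                          0.99, names = FALSE)
  for (i in cand) {
    if (length(accepted) && i - accepted[length(accepted)] < refr) {
      # within refractory: keep the larger of the two
      if (env[i] > env[accepted[length(accepted)]]) {
        accepted[length(accepted)] <- i
      }
      next
    }
    if (env[i] >= max(thr, floor_thr)) {
      accepted <- c(accepted, i)
      recent <- utils::tail(c(recent, env[i]), 8L)
      thr <- threshold_frac * stats::median(recent)
    }
  }
  if (length(accepted) == 0L) stop("no-peaks: nothing above threshold")
  # refine each detection to the trace maximum within +/- 60 ms
  half <- round(0.06 * fs)
  peaks <- vapply(accepted, function(i) {
    lo <- max(1L, i - half); hi <- min(length(x), i + half)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1))
  peaks <- sort(unique(peaks))
  # enforce refractory on the refined positions
  keep <- c(TRUE, diff(peaks) >= refr)
  (peaks[keep] - 1L) / fs
}

#' Tachogram: R-R intervals from peak times
#'
#' @param peak_times strictly increasing peak times (s).
#' @return object of class `tachogram`: list with `peak_times`, `rr_ms`
#'   (interval ending at `peak_times[-1]`), `valid` mask and `interpolated`
#'   record.
#' @export
tachogram <- function(peak_times) {
  stopifnot(is.numeric(peak_times), all(diff(peak_times) > 0))
  rr <- diff(peak_times) * 1000
  structure(list(peak_times = peak_times, rr_ms = rr,
                 valid = rep(TRUE, length(rr)),
                 interpolated = rep(FALSE, length(rr))),
            class = "tachogram")
}

#' @export
print.tachogram <- function(x, ...) {
  cat(sprintf("<tachogram> %d intervals, mean RR %.1f ms, %d interpolated\n",
              length(x$rr_ms), mean(x$rr_ms), sum(x$interpolated)))
  invisible(x)
}

#' Clean physiologically implausible R-R intervals
#'
#' Intervals above 1.5 s or below 0.3 s are marked invalid and each invalid
#' run is replaced by linear interpolation between the flanking valid values
#' (invalid head/tail runs take the nearest valid value). The number of
#' intervals never changes and the operation is idempotent.
#'
#' @param tg a [tachogram()] with >= 4 intervals.
#' @param max_invalid_frac abort threshold on the invalid fraction
#'   (default 0.2).
#' @return cleaned `tachogram` with the `interpolated` record updated.
#' @export
clean_rr <- function(tg, max_invalid_frac = 0.2) {
  stopifnot(inherits(tg, "tachogram"))
  rr <- tg$rr_ms
  if (length(rr) < 4L) stop("clean_rr: need >= 4 intervals")
  bad <- rr < RR_MIN_MS | rr > RR_MAX_MS
  if (!any(bad)) return(tg)
  if (mean(bad) > max_invalid_frac) {
    stop(sprintf("quality: %.1f%% of intervals outside [%d, %d] ms",
                 100 * mean(bad), RR_MIN_MS, RR_MAX_MS))
  }
  idx <- seq_along(rr)
  rr[bad] <- stats::approx(idx[!bad], rr[!bad], xout = idx[bad],
                           rule = 2)$y
  tg$rr_ms <- rr
  tg$valid <- !bad & tg$valid
  tg$interpolated <- tg$interpolated | bad
  tg
}

# intervals of a tachogram whose terminating peak lies in [window)
rr_in_window <- function(tg, window) {
  ends <- tg$peak_times[-1L]
  tg$rr_ms[ends >= window[1L] & ends < window[2L]]
}

#' Time-domain HRV features
#'
#' `meanRR` (ms), `STDRR` (sample SD, ms), and `pRR50`: the percentage of
#' successive R-R differences strictly exceeding 50 ms.
#'
#' @param tg a cleaned [tachogram()].
#' @param window half-open analysis window (s); defaults to everything.
#' @return named list `meanRR`, `STDRR`, `pRR50`.
#' @export
time_domain_hrv <- function(tg, window = NULL) {
  rr <- if (is.null(window)) tg$rr_ms else rr_in_window(tg, as_interval(window))
  if (length(rr) < 2L) stop("insufficient-data: < 2 intervals in window")
  list(meanRR = mean(rr),
       STDRR = stats::sd(rr),
       pRR50 = 100 * mean(abs(diff(rr)) > 50))
}

#' Poincare descriptors of a PRE-normalized tachogram
#'
#' R-R values are z-scored by the patient's PRE mean and SD, then consecutive
#' pairs `(z_n, z_{n+1})` form the Poincare cloud. `SD1` (dispersion
#' perpendicular to the identity line) is the uncentered population RMS of
#' `(z_n - z_{n+1}) / sqrt(2)`, making `SD1 == RMSSD / sqrt(2)` an exact
#' identity; `SD2` (along the identity line) is the centered population SD of
#' `(z_n + z_{n+1}) / sqrt(2)`.
#'
#' @param tg a cleaned [tachogram()].
#' @param pre_stats list with `mean` and `sd` of the PRE window's R-R (ms);
#'   `sd` must be > 0.
#' @param window optional analysis window (s).
#' @return list `SD1`, `SD2`, `SD1_SD2`, and `cloud` (data.frame `z`, `z_next`).
#' @export
poincare <- function(tg, pre_stats, window = NULL) {
  stopifnot(is.list(pre_stats), !is.null(pre_stats$mean), !is.null(pre_stats$sd))
  if (!is.finite(pre_stats$sd) || pre_stats$sd <= 0) {
    stop("degenerate-baseline: PRE SD is zero")
  }
  rr <- if (is.null(window)) tg$rr_ms else rr_in_window(tg, as_interval(window))
  if (length(rr) < 3L) stop("insufficient-data: < 3 intervals")
  z <- (rr - pre_stats$mean) / pre_stats$sd
  z1 <- z[-length(z)]; z2 <- z[-1L]
  d <- (z1 - z2) / sqrt(2)
  s <- (z1 + z2) / sqrt(2)
  sd1 <- sqrt(mean(d^2))
  sd2 <- sqrt(mean((s - mean(s))^2))
  list(SD1 = sd1, SD2 = sd2,
       SD1_SD2 = if (sd2 > 0) sd1 / sd2 else NA_real_,
       cloud = data.frame(z = z1, z_next = z2))
}

#' LF / HF spectral balance of the tachogram
#'
#' The R-R series (anchored at terminating peak times) is cubic-spline
#' resampled onto a uniform 4-Hz grid over the window, mean-subtracted, and a
#' Welch PSD is taken over the whole window. The density is normalized by the
#' total power (integral over 0-2 Hz); LF is the Simpson integral over
#' `[f_low, 0.15]` Hz and HF over `[0.15, 0.4]` Hz, both as percentages of
#' total power. For windows shorter than 300 s the lower cutoff rises
#' proportionally, `f_low = max(0.04, 12 / T)`, to keep at least 12
#' oscillation cycles in the window.
#'
#' @param tg a cleaned [tachogram()] covering the window.
#' @param window half-open window (s), duration >= 60 s.
#' @return list `LF`, `HF` (percent of total power), `LF_HF` (ratio of the
#'   unscaled integrals), `f_low`, and the normalized `psd`.
#' @export
spectral_lf_hf <- function(tg, window) {
  window <- as_interval(window)
  T <- interval_duration(window)
  if (T < 60) stop("window-too-short: ", T, " s < 60 s")
  f_low <- max(0.04, 12 / T)
  if (f_low >= 0.15) stop("LF-undefined: f_low = ", f_low, " >= 0.15 Hz")
  ends <- tg$peak_times[-1L]
  sel <- ends >= window[1L] - 2 & ends < window[2L] + 2   # small margin
  if (sum(sel) < 8L) stop("insufficient-data: too few intervals in window")
  grid <- seq(window[1L], window[2L], by = 1 / HRV_RESAMPLE_HZ)
  grid <- grid[grid < window[2L]]
  rr_t <- stats::spline(ends[sel], tg$rr_ms[sel], xout = grid,
                        method = "natural")$y
  rr_t <- rr_t - mean(rr_t)
  psd <- welch_psd(rr_t, HRV_RESAMPLE_HZ,
                   seg_length = min(T, HRV_WELCH_SEG_S),
                   overlap_frac = 0.5, detrend = TRUE)
  total <- simpson_integral(psd$density, psd$freq)
  if (total <= 0) stop("insufficient-data: zero tachogram power")
  lf_raw <- band_power(psd, c(f_low, 0.15))
  hf_raw <- band_power(psd, c(0.15, 0.4))
  psd$density <- psd$density / total
  list(LF = 100 * lf_raw / total, HF = 100 * hf_raw / total,
       LF_HF = if (hf_raw > 0) lf_raw / hf_raw else NA_real_,
       f_low = f_low, psd = psd)
}

#' Adaptive lower LF cutoff
#'
#' `f_low = max(0.04, 12 / T)` for a window of `T` seconds: the standard
#' 0.04 Hz edge when the window holds at least 12 cycles of it, raised
#' proportionally otherwise.
#'
#' @param T window duration in seconds.
#' @return cutoff frequency in Hz.
#' @export
adaptive_f_low <- function(T) max(0.04, 12 / T)

#' Full HRV summary of one session
#'
#' Detects peaks on the filtered ECG channel, cleans the R-R series, and
#' computes the nine-feature set (meanRR, STDRR, pRR50, SD1, SD2, SD1/SD2,
#' LF, HF, LF/HF) per period over the central analysis windows, plus the
#' pairwise deltas MTI-PRE, POST-PRE and MTI-POST (first minus second).
#'
#' @param rec an ECG [recording()] (raw; filtered internally 1-40 Hz).
#' @param segmentation a [period_segmentation()].
#' @param window_minutes central-window targets (minutes).
#' @return list with `features` (data.frame period x feature), `deltas`
#'   (data.frame pair x feature), and the cleaned `tachogram`.
#' @export
hrv_session_summary <- function(rec, segmentation,
                                window_minutes = c(pre = 5, mti = 15,
                                                   post = 5)) {
  stopifnot(inherits(rec, "recording"), rec$modality == "ECG")
  fs <- rec$sampling_rate
  x <- bandpass(rec$data[1L, ], 1, 40, fs = fs)
  tg <- clean_rr(tachogram(detect_r_peaks(x, fs)))
  wins <- lapply(c(pre = "pre", mti = "mti", post = "post"), function(p) {
    central_window(segmentation[[p]], window_minutes[[p]])
  })
  pre_rr <- rr_in_window(tg, wins$pre)
  pre_stats <- list(mean = mean(pre_rr), sd = stats::sd(pre_rr))
  feats <- lapply(names(wins), function(p) {
    td <- time_domain_hrv(tg, wins[[p]])
    pc <- poincare(tg, pre_stats, wins[[p]])
    sp <- spectral_lf_hf(tg, wins[[p]])
    data.frame(period = p,
               feature = c("meanRR", "STDRR", "pRR50", "SD1", "SD2",
                           "SD1_SD2", "LF", "HF", "LF_HF"),
               value = c(td$meanRR, td$STDRR, td$pRR50, pc$SD1, pc$SD2,
                         pc$SD1_SD2, sp$LF, sp$HF, sp$LF_HF),
               stringsAsFactors = FALSE)
  })
  features <- do.call(rbind, feats)
  pairs <- list(c("mti", "pre"), c("post", "pre"), c("mti", "post"))
  deltas <- do.call(rbind, lapply(pairs, function(pr) {
    a <- features[features$period == pr[1L], ]
    b <- features[features$period == pr[2L], ]
    data.frame(pair = paste(pr[1L], pr[2L], sep = "-"), feature = a$feature,
               delta = a$value - b$value[match(a$feature, b$feature)],
               stringsAsFactors = FALSE)
  }))
  list(features = features, deltas = deltas, tachogram = tg)
}
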