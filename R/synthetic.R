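# Synthetic session generators with known ground truth.
#
# Every generator is a pure function of (profile, seed). Band-limited signals
# are constructed by spectral shaping of white noise (build the spectrum in
# the frequency domain, inverse-transform, rescale to the exact target power)
# rather than cascaded filters, so per-band power is controlled exactly.

# Gaussian noise whose power is confined to [low, high) Hz and equals `power`
# exactly in the empirical (variance) sense.
bandlimited_noise <- function(n, fs, low, high, power) {
  stopifnot(n > 8, high > low, power >= 0)
  if (power == 0) return(numeric(n))
  freqs <- (0:(n - 1L)) * fs / n
  sel <- (freqs >= low & freqs < high) | (freqs > fs - high & freqs <= fs - low)
  spec <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n))
  spec[!sel] <- 0
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x <- x - mean(x)
  v <- stats::var(x) * (n - 1) / n
  if (v <= 0) stop("bandlimited_noise: degenerate band")
  x * sqrt(power / v)
}

# ---- EEG --------------------------------------------------------------------

#' EEG effect profile: per-channel, per-band, per-period power multipliers
#'
#' Multipliers are relative to PRE (= 1 by definition). `mti` and `post` are
#' named lists `channel -> named numeric vector of band multipliers`; bands
#' and channels not mentioned stay at 1.
#'
#' @param mti,post multiplier specifications (see description).
#' @param base_power named per-band PRE power (uV^2); the default follows the
#'   typical 1/f-like resting EEG profile.
#' @param channels EEG montage labels.
#' @param scheme a [band_scheme()].
#' @return object of class `eeg_effect_profile`: channel x band x period
#'   multiplier array plus the base powers.
#' @export
eeg_effect_profile <- function(mti = list(), post = list(),
                               base_power = c(Delta = 40, Theta = 20,
                                              Alpha = 15, SlowBeta = 8,
                                              FastBeta = 5),
                               channels = EEG_MONTAGE,
                               scheme = band_scheme()) {
  bands <- scheme$band
  stopifnot(all(bands %in% names(base_power)))
  mult <- array(1, dim = c(length(channels), length(bands), 3L),
                dimnames = list(channels, bands, c("pre", "mti", "post")))
  fill <- function(spec, period) {
    for (ch in names(spec)) {
      if (!ch %in% channels) stop("profile: unknown channel ", ch)
      v <- spec[[ch]]
      if (!all(names(v) %in% bands)) {
        stop("profile: unknown band in ", ch, ": ",
             paste(setdiff(names(v), bands), collapse = ", "))
      }
      if (any(v <= 0)) stop("profile: multipliers must be > 0")
      mult[ch, names(v), period] <<- v
    }
  }
  fill(mti, "mti"); fill(post, "post")
  structure(list(mult = mult, base_power = base_power[bands],
                 scheme = scheme, channels = channels),
            class = "eeg_effect_profile")
}

#' Generate a synthetic EEG session
#'
#' Each channel is a sum over bands of band-limited Gaussian noise whose
#' within-band power in period p equals `multiplier(p)` times the PRE power
#' for that band. Periods are concatenated PRE -> MTI -> POST and annotated.
#' Optional blink transients (biphasic low-frequency pulses, largest on
#' Fp1/Fp2) can be injected for ocular-removal testing.
#'
#' @param profile an [eeg_effect_profile()].
#' @param durations named period durations in seconds (`pre`, `mti`, `post`).
#' @param fs sampling rate (>= 256 Hz).
#' @param seed RNG seed; fixed seed implies identical sample streams.
#' @param blink_rate blinks per second (0 disables).
#' @return list with `recording` and `segmentation`.
#' @export
gen_eeg_session <- function(profile,
                            durations = c(pre = 300, mti = 900, post = 300),
                            fs = 256, seed = 1L, blink_rate = 0) {
  stopifnot(inherits(profile, "eeg_effect_profile"), fs >= 256,
            all(durations > 0))
  periods <- c("pre", "mti", "post")
  ns <- round(durations[periods] * fs)
  scheme <- profile$scheme
  with_seed(seed, {
    chunks <- lapply(periods, function(p) {
      mat <- matrix(0, nrow = length(profile$channels), ncol = ns[[p]])
      for (ci in seq_along(profile$channels)) {
        ch <- profile$channels[ci]
        for (bi in seq_len(nrow(scheme))) {
          b <- scheme$band[bi]
          pw <- profile$base_power[[b]] * profile$mult[ch, b, p]
          mat[ci, ] <- mat[ci, ] +
            bandlimited_noise(ns[[p]], fs, scheme$low[bi], scheme$high[bi], pw)
        }
      }
      mat
    })
    data <- do.call(cbind, chunks)
    if (blink_rate > 0) {
      total_s <- sum(durations)
      n_blink <- stats::rpois(1, blink_rate * total_s)
      if (n_blink > 0) {
        t_blink <- sort(stats::runif(n_blink, 0.5, total_s - 0.5))
        # biphasic ~0.4-s pulse, spectral content < 4 Hz
        tt <- seq(-0.2, 0.2, by = 1 / fs)
        pulse <- 150 * sin(pi * tt / 0.2) * exp(-(tt / 0.12)^2)
        weights <- c(Fp1 = 1, Fp2 = 1, T3 = 0.25, T4 = 0.25,
                     C3 = 0.35, C4 = 0.35, O1 = 0.08, O2 = 0.08)
        for (tb in t_blink) {
          i0 <- round(tb * fs)
          idx <- i0 + seq_along(tt)
          idx_ok <- idx >= 1 & idx <= ncol(data)
          for (ci in seq_along(profile$channels)) {
            w <- weights[[profile$channels[ci]]]
            data[ci, idx[idx_ok]] <- data[ci, idx[idx_ok]] +
              w * pulse[idx_ok]
          }
        }
      }
    }
    bounds <- cumsum(c(0, durations[periods]))
    seg <- period_segmentation(c(bounds[1L], bounds[2L]),
                               c(bounds[2L], bounds[3L]),
                               c(bounds[3L], bounds[4L]))
    ann <- data.frame(onset = bounds[1:3], duration = unname(durations[periods]),
                      label = c("PRE", "MTI", "POST"))
    list(recording = recording(data, fs, "EEG",
                               channel_labels = profile$channels,
                               annotations = ann),
         segmentation = seg)
  })
}

# ---- ECG --------------------------------------------------------------------

#' Autonomic profile for synthetic R-R series
#'
#' Per-period mean RR plus LF and HF sinusoidal modulation amplitudes and
#' white jitter: `RR_n = meanRR + a_LF sin(2 pi f_LF t_n) + a_HF sin(2 pi
#' f_HF t_n) + eps_n`, with `eps` i.i.d. Gaussian truncated at +/- 3 SD.
#'
#' @param pre,mti,post named lists with `mean_rr` (ms), `a_lf`, `a_hf` (ms),
#'   `jitter` (ms SD).
#' @param f_lf,f_hf oscillation frequencies, inside the LF / HF bands.
#' @return object of class `autonomic_profile`.
#' @export
autonomic_profile <- function(pre = list(mean_rr = 800, a_lf = 40, a_hf = 20,
                                         jitter = 10),
                              mti = pre, post = pre,
                              f_lf = 0.1, f_hf = 0.25) {
  stopifnot(f_lf >= 0.04, f_lf < 0.15, f_hf >= 0.15, f_hf < 0.4)
  per <- list(pre = pre, mti = mti, post = post)
  for (p in names(per)) {
    v <- per[[p]]
    stopifnot(all(c("mean_rr", "a_lf", "a_hf", "jitter") %in% names(v)))
    if (v$mean_rr < RR_MIN_MS || v$mean_rr > RR_MAX_MS) {
      stop("profile: mean RR outside [", RR_MIN_MS, ", ", RR_MAX_MS, "] ms")
    }
    if (v$a_lf < 0 || v$a_hf < 0 || v$jitter < 0) {
      stop("profile: amplitudes must be >= 0")
    }
    worst <- v$a_lf + v$a_hf + 3 * v$jitter
    if (v$mean_rr - worst < RR_MIN_MS || v$mean_rr + worst > RR_MAX_MS) {
      stop("profile: modulation could push RR outside [",
           RR_MIN_MS, ", ", RR_MAX_MS, "] ms")
    }
  }
  structure(list(periods = per, f_lf = f_lf, f_hf = f_hf),
            class = "autonomic_profile")
}

# Ricker (Mexican-hat) QRS-like template, 80 ms total width, unit amplitude.
qrs_template <- function(fs, width_s = 0.08, amplitude = 1) {
  tt <- seq(-width_s / 2, width_s / 2, by = 1 / fs)
  sigma <- width_s / 6
  amplitude * (1 - (tt / sigma)^2) * exp(-tt^2 / (2 * sigma^2))
}

#' Generate a synthetic ECG session
#'
#' Builds the R-R sequence from an [autonomic_profile()], places a
#' Mexican-hat QRS-like template (80 ms wide, 1 mV) at each cumulative peak
#' time on a baseline with additive white noise, and returns the true peak
#' times for detector validation.
#'
#' @param profile an [autonomic_profile()].
#' @param durations named period durations (s).
#' @param fs sampling rate (>= 256 Hz).
#' @param seed RNG seed.
#' @param noise_sd additive baseline noise SD in mV (0.1 is ~10:1 SNR against
#'   the 1-mV QRS peak).
#' @return list with `recording`, `segmentation`, `true_peaks` (s) and
#'   `true_rr` (ms).
#' @export
gen_ecg_session <- function(profile,
                            durations = c(pre = 300, mti = 900, post = 300),
                            fs = 256, seed = 1L, noise_sd = 0.02) {
  stopifnot(inherits(profile, "autonomic_profile"), fs >= 256)
  periods <- c("pre", "mti", "post")
  bounds <- cumsum(c(0, durations[periods]))
  total_s <- bounds[4L]
  with_seed(seed, {
    t <- 0.2
    peaks <- t
    rrs <- numeric(0)
    while (TRUE) {
      p <- periods[findInterval(t, bounds, rightmost.closed = TRUE)]
      v <- profile$periods[[p]]
      eps <- stats::rnorm(1, 0, v$jitter)
      eps <- max(min(eps, 3 * v$jitter), -3 * v$jitter)
      rr <- v$mean_rr + v$a_lf * sin(2 * pi * profile$f_lf * t) +
        v$a_hf * sin(2 * pi * profile$f_hf * t) + eps
      t <- t + rr / 1000
      if (t >= total_s - 0.2) break
      peaks <- c(peaks, t)
      rrs <- c(rrs, rr)
    }
    n <- round(total_s * fs)
    x <- stats::rnorm(n, 0, noise_sd)
    tpl <- qrs_template(fs)
    half <- (length(tpl) - 1L) %/% 2L
    for (pk in peaks) {
      i0 <- round(pk * fs) + 1L
      idx <- (i0 - half):(i0 - half + length(tpl) - 1L)
      ok <- idx >= 1 & idx <= n
      x[idx[ok]] <- x[idx[ok]] + tpl[ok]
    }
    true_peaks <- (round(peaks * fs)) / fs   # template maxima on the grid
    seg <- period_segmentation(c(bounds[1L], bounds[2L]),
                               c(bounds[2L], bounds[3L]),
                               c(bounds[3L], bounds[4L]))
    list(recording = recording(matrix(x, nrow = 1L), fs, "ECG",
                               channel_labels = "ECG1"),
         segmentation = seg, true_peaks = true_peaks, true_rr = rrs)
  })
}

# ---- EMG --------------------------------------------------------------------

#' EMG spectral/amplitude profile
#'
#' @param centroid named per-period spectral-centroid targets (Hz, within
#'   20-200).
#' @param rms named per-period RMS amplitudes (uV).
#' @return object of class `emg_profile`.
#' @export
emg_profile <- function(centroid = c(pre = 110, mti = 103.5, post = 111.5),
                        rms = c(pre = 8, mti = 8, post = 8)) {
  stopifnot(all(c("pre", "mti", "post") %in% names(centroid)),
            all(c("pre", "mti", "post") %in% names(rms)))
  if (any(centroid < EMG_BAND[1L] | centroid > EMG_BAND[2L])) {
    stop("profile: centroid outside the 20-200 Hz analysis band")
  }
  structure(list(centroid = centroid, rms = rms), class = "emg_profile")
}

#' Generate a synthetic EMG session
#'
#' Gaussian noise shaped by a unimodal spectral power envelope (Gaussian in
#' frequency, SD 30 Hz, truncated to 20-200 Hz) whose centroid matches the
#' period's target within about 2 Hz; the RMS is scaled per period.
#'
#' @param profile an [emg_profile()].
#' @param durations named period durations (s).
#' @param fs sampling rate (>= 512 Hz, the EMG analysis gate).
#' @param seed RNG seed.
#' @return list with `recording` and `segmentation`.
#' @export
gen_emg_session <- function(profile,
                            durations = c(pre = 300, mti = 900, post = 300),
                            fs = 512, seed = 1L) {
  stopifnot(inherits(profile, "emg_profile"))
  if (fs < 512) stop("gate: EMG generation requires fs >= 512 Hz")
  periods <- c("pre", "mti", "post")
  with_seed(seed, {
    chunks <- lapply(periods, function(p) {
      n <- round(durations[[p]] * fs)
      freqs <- (0:(n - 1L)) * fs / n
      f_fold <- pmin(freqs, fs - freqs)
      env <- exp(-((f_fold - profile$centroid[[p]])^2) / (2 * 30^2))
      env[f_fold < EMG_BAND[1L] | f_fold > EMG_BAND[2L]] <- 0
      spec <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)) *
        sqrt(env)
      x <- Re(stats::fft(spec, inverse = TRUE)) / n
      x <- x - mean(x)
      x * profile$rms[[p]] / sqrt(mean(x^2))
    })
    data <- matrix(unlist(chunks), nrow = 1L)
    bounds <- cumsum(c(0, durations[periods]))
    seg <- period_segmentation(c(bounds[1L], bounds[2L]),
                               c(bounds[2L], bounds[3L]),
                               c(bounds[3L], bounds[4L]))
    ann <- data.frame(onset = bounds[1:3],
                      duration = unname(durations[periods]),
                      label = c("PRE", "MTI", "POST"))
    list(recording = recording(data, fs, "EMG", channel_labels = "EMG1",
                               annotations = ann),
         segmentation = seg)
  })
}

# ---- clinical ---------------------------------------------------------------

#' Generate a synthetic clinical-scores table
#'
#' Integer VAS (0-10) per session PRE/POST and integer HADS subscales (0-21)
#' at first/last timepoint, with configurable mean shifts and a configurable
#' fraction of patients missing the last HADS timepoint. Out-of-range draws
#' are clipped with a warning.
#'
#' @param n_patients number of patients (>= 2).
#' @param sessions_per_patient sessions per patient (the last patient can be
#'   given fewer via `short_last_patient`).
#' @param vas_shift mean POST - PRE VAS shift.
#' @param hads_anxiety_shift,hads_depression_shift mean last - first shifts.
#' @param missing_last_frac fraction of patients with no last HADS timepoint.
#' @param vas_pre_mean mean of the PRE VAS draw.
#' @param vas_noise_sd,hads_noise_sd SD of the session/patient noise added to
#'   the shifted scores (0 gives exact shifts).
#' @param seed RNG seed.
#' @return list of two data.frames shaped like the study's clinical table:
#'   `sessions` (`patient`, `session`, `vas_pre`, `vas_post`) and `patients`
#'   (`patient`, `age`, `sex`, `burn_type`, `severity`, `hads_anx_first`,
#'   `hads_anx_last`, `hads_dep_first`, `hads_dep_last`).
#' @export
gen_clinical_table <- function(n_patients = 9, sessions_per_patient = 2,
                               vas_shift = -0.76,
                               hads_anxiety_shift = -1.9,
                               hads_depression_shift = -1.6,
                               missing_last_frac = 0,
                               vas_pre_mean = 2.5, vas_noise_sd = 1.4,
                               hads_noise_sd = 2, seed = 1L) {
  stopifnot(n_patients >= 2)
  clip <- function(x, lo, hi, what) {
    out <- pmin(pmax(x, lo), hi)
    if (any(out != x)) warning("clipped out-of-range ", what, " scores")
    out
  }
  with_seed(seed, {
    patients <- data.frame(
      patient = seq_len(n_patients),
      age = sample(18:65, n_patients, replace = TRUE),
      sex = sample(c("Male", "Female"), n_patients, replace = TRUE,
                   prob = c(0.85, 0.15)),
      burn_type = sample(c("Thermal", "Electric"), n_patients, replace = TRUE,
                         prob = c(0.7, 0.3)),
      severity = sample(1:3, n_patients, replace = TRUE,
                        prob = c(0.5, 0.45, 0.05)),
      stringsAsFactors = FALSE)
    anx_first <- clip(round(stats::rnorm(n_patients, 6, 4)), 0, 21, "HADS")
    dep_first <- clip(round(stats::rnorm(n_patients, 4, 3)), 0, 21, "HADS")
    anx_last <- clip(round(anx_first + hads_anxiety_shift +
                             stats::rnorm(n_patients, 0, hads_noise_sd)),
                     0, 21, "HADS")
    dep_last <- clip(round(dep_first + hads_depression_shift +
                             stats::rnorm(n_patients, 0, hads_noise_sd)),
                     0, 21, "HADS")
    n_missing <- round(missing_last_frac * n_patients)
    if (n_missing > 0) {
      drop <- sample.int(n_patients, n_missing)
      anx_last[drop] <- NA_integer_
      dep_last[drop] <- NA_integer_
    }
    patients$hads_anx_first <- anx_first
    patients$hads_anx_last <- anx_last
    patients$hads_dep_first <- dep_first
    patients$hads_dep_last <- dep_last
    rows <- list()
    for (p in seq_len(n_patients)) {
      for (s in seq_len(sessions_per_patient)) {
        pre <- clip(round(stats::rnorm(1, vas_pre_mean, 2.4)), 0, 10, "VAS")
        post <- clip(round(pre + vas_shift +
                             stats::rnorm(1, 0, vas_noise_sd)), 0, 10, "VAS")
        rows[[length(rows) + 1L]] <- data.frame(patient = p, session = s,
                                                vas_pre = pre, vas_post = post)
      }
    }
    list(sessions = do.call(rbind, rows), patients = patients)
  })
}
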